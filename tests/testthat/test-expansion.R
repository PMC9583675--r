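test_that("top-25% frequency labeling counts and tie-breaks as specified", {
  co <- tibble::tibble(
    individual_id = "A",
    cdr3aa = sprintf("AA%02d", 1:8),
    freq = c(0.4, 0.2, 0.1, 0.1, 0.08, 0.06, 0.04, 0.02))
  lab <- label_frequency(co)
  expect_equal(sum(lab$freq_label == "high_freq"), 2L)  # ceil(0.25 * 8)
  expect_equal(lab$cdr3aa[lab$freq_label == "high_freq"], c("AA01", "AA02"))

  one <- label_frequency(tibble::tibble(individual_id = "A", cdr3aa = "X",
                                        freq = 1))
  expect_equal(one$freq_label, "high_freq")

  # all-equal frequencies: lexicographically smallest CDR3aa win
  ties <- tibble::tibble(individual_id = "A",
                         cdr3aa = c("DD", "BB", "CC", "AA"), freq = 0.25)
  lt <- label_frequency(ties)
  expect_equal(sort(lt$cdr3aa[lt$freq_label == "high_freq"]), "AA")

  # invariance under uniform rescaling
  sc <- co; sc$freq <- sc$freq * 7
  expect_equal(label_frequency(sc)$freq_label, lab$freq_label)
  expect_error(label_frequency(co[0, ]), "empty")
})

test_that("frequency labeling aggregates nucleotide variants per CDR3aa", {
  co <- tibble::tibble(
    individual_id = "A",
    cdr3aa = c("AA1", "AA1", "AA2", "AA3"),
    freq = c(0.2, 0.25, 0.3, 0.25))
  lab <- label_frequency(co)
  expect_equal(nrow(lab), 3L)
  # AA1 aggregates to 0.45 and takes the single high_freq slot
  expect_equal(lab$freq_label[lab$cdr3aa == "AA1"], "high_freq")
})

test_that("expansion score follows the log-ratio formula and is antisymmetric", {
  expect_equal(expansion_score(0, 0), 0)
  expect_equal(expansion_score(5, 5), 0)
  expect_equal(expansion_score(3, 1), log(2))
  expect_equal(expansion_score(0, 5), log(1 / 6))
  for (h in 0:6) {
    for (l in 0:6) {
      expect_equal(expansion_score(h, l), -expansion_score(l, h))
    }
  }
})

test_that("per-group expansion records compose labels and scores", {
  co <- tibble::tibble(
    individual_id = "A",
    cdr3aa = sprintf("AA%02d", 1:8),
    freq = c(0.4, 0.2, 0.1, 0.08, 0.07, 0.06, 0.05, 0.04))
  lab <- label_frequency(co)  # AA01, AA02 high_freq
  grouping <- tibble::tibble(
    cdr3aa = sprintf("AA%02d", 1:8),
    label = c(rep("high_public", 4), rep("private", 4)))
  rec <- expansion_by_group(lab, grouping)
  hp <- rec[rec$label == "high_public", ]
  expect_equal(c(hp$n_highfreq, hp$n_lowfreq), c(2L, 2L))
  expect_equal(hp$score, 0)
  pr <- rec[rec$label == "private", ]
  expect_equal(pr$score, expansion_score(0, 4))

  # a group with 3 high-freq and 1 low-freq scores ln 2
  g2 <- tibble::tibble(cdr3aa = sprintf("AA%02d", 1:8),
                       label = c(rep("g", 4), rep("other", 4)))
  lab2 <- lab
  lab2$freq_label <- c("high_freq", "high_freq", "high_freq", rep("low_freq", 5))
  r2 <- expansion_by_group(lab2, g2)
  expect_equal(r2$score[r2$label == "g"], log(2))
})

test_that("systematically expanded public clones score above private ones", {
  set.seed(23)
  inds <- sprintf("I%02d", 1:6)
  rows <- list()
  for (id in inds) {
    # 20 public CDR3aa (shared by construction) drawn with larger frequencies
    pub_f <- stats::rexp(20, rate = 1)
    pri_f <- stats::rexp(60, rate = 10)
    f <- c(pub_f, pri_f); f <- f / sum(f)
    rows[[id]] <- tibble::tibble(
      individual_id = id,
      cdr3aa = c(sprintf("PUB%02d", 1:20), sprintf("PRI_%s_%02d", id, 1:60)),
      freq = f)
  }
  co <- dplyr::bind_rows(rows)
  lab <- label_frequency(co)
  grouping <- tibble::tibble(cdr3aa = unique(co$cdr3aa))
  grouping$label <- ifelse(grepl("^PUB", grouping$cdr3aa), "public", "private")
  rec <- expansion_by_group(lab, grouping)
  med <- tapply(rec$score, rec$label, stats::median)
  expect_gt(med["public"], med["private"])
})

test_that("Games-Howell reduces to the Welch t-test for two groups", {
  set.seed(29)
  for (i in 1:5) {
    x <- c(stats::rnorm(18, 0, 1), stats::rnorm(31, 0.4, 2.5))
    g <- rep(c("a", "b"), c(18, 31))
    gh <- games_howell(x, g)
    wt <- stats::t.test(x[g == "b"], x[g == "a"])
    expect_equal(gh$p, wt$p.value, tolerance = 1e-6)
    expect_equal(gh$diff, unname(diff(rev(wt$estimate))), tolerance = 1e-12)
  }
})

test_that("Games-Howell holds its size on identically distributed groups", {
  set.seed(37)
  hits <- 0L
  n_rep <- 300L
  for (i in seq_len(n_rep)) {
    x <- stats::rnorm(100)
    g <- rep(c("a", "b"), each = 50)
    if (games_howell(x, g)$p > 0.05) hits <- hits + 1L
  }
  # nominal rejection rate 5%; 0.92 leaves ~3 binomial SDs of slack
  expect_gte(hits / n_rep, 0.92)
})

test_that("Games-Howell detects a large shift and respects invariances", {
  set.seed(43)
  x <- c(stats::rnorm(30, 0), stats::rnorm(30, 5), stats::rnorm(30, 0.2))
  g <- rep(c("a", "b", "c"), each = 30)
  gh <- games_howell(x, g)
  expect_lt(gh$p[gh$group_i == "a" & gh$group_j == "b"], 1e-6)
  # invariance under relabeling and constant shift
  gh_shift <- games_howell(x + 100, g)
  expect_equal(gh$p, gh_shift$p, tolerance = 1e-10)
  relabel <- c(a = "z", b = "y", c = "x")[g]
  gh_rel <- games_howell(x, relabel)
  key <- function(d) {
    apply(cbind(d$group_i, d$group_j), 1, function(r) paste(sort(r), collapse = ""))
  }
  expect_equal(sort(gh$p), sort(gh_rel$p), tolerance = 1e-10)
  expect_error(games_howell(c(1, 1, 1, 2, 3, 4), rep(c("a", "b"), each = 3)),
               "zero-variance")
  expect_error(games_howell(1:5, c("a", "a", "a", "a", "b")), "at least two")
})

test_that("position frequency matrices tally residues per position", {
  pfm <- position_frequency_matrix(rep("CACDTLGDTDKLIF", 10))
  expect_equal(dim(pfm), c(14L, 20L))
  expect_true(all(abs(rowSums(pfm) - 1) < 1e-12))
  expect_true(all(apply(pfm, 1, max) == 1))  # one-hot rows

  two <- position_frequency_matrix(c("CA", "CD"))
  expect_equal(two[1, "C"], 1)
  expect_equal(two[2, "A"], 0.5)
  expect_equal(two[2, "D"], 0.5)

  expect_error(position_frequency_matrix(c("CA", "CAD")), "share one length")

  # simulated length stratum against a direct per-position tally
  sim <- simulate_cohort(small_cfg(151L), ref = test_ref())
  strat <- sim$cohort$cdr3aa[nchar(sim$cohort$cdr3aa) == 13 &
                               sim$cohort$j == "TRDJ1"]
  strat <- utils::head(strat, 100)
  pfm2 <- position_frequency_matrix(strat)
  chars <- do.call(rbind, strsplit(strat, ""))
  for (pos in c(1, 5, 13)) {
    tab <- table(chars[, pos]) / length(strat)
    expect_equal(pfm2[pos, names(tab)], c(tab)[names(tab)],
                 ignore_attr = TRUE)
  }
})
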