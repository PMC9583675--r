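test_that("translation follows the standard code and flags stops", {
  expect_equal(translate_cdr3("TGTGCCTGTGACACCCTGGGGGATACCGATAAACTCATCTTT"),
               "CACDTLGDTDKLIF")
  expect_equal(translate_cdr3("TGTGCC"), "CA")
  expect_true(is.na(translate_cdr3("TGTTAAGCCTGTGACACCCTG")))
  expect_error(translate_cdr3("TGTGC"), "divisible by 3")
  expect_error(translate_cdr3("TGTGCN"), "non-ACGT")
})

test_that("N-insertion formula evaluates with per-junction clipping", {
  expect_equal(compute_n_insertions(14, 15, 23, 24), 0L)
  expect_equal(compute_n_insertions(14, -1, -1, 24), 9L)
  expect_equal(compute_n_insertions(14, 17, 21, 24), 4L)
  expect_equal(compute_n_insertions(c(14, 14), c(15, -1), c(23, -1), c(24, 24)),
               c(0L, 9L))
  expect_error(compute_n_insertions(14, -1, -1, 14), "jstart")
})

test_that("the fixture D-less transcript re-aligns to 9 N-insertions", {
  al <- align_to_germline("TGTGCCTGTGACACCCTAGGCGATACCGATAAACTCATCTTT",
                          test_ref())
  expect_equal(al$v_match_len, 15L)
  expect_equal(al$vend, 14L)
  expect_equal(al$j, "TRDJ1")
  expect_equal(al$j_match_len, 18L)
  expect_equal(al$jstart, 24L)
  expect_equal(al$d, ".")
  expect_equal(al$n_insertions, 9L)
})

test_that("the fixture TRDD3 transcript re-aligns to 0 N-insertions", {
  al <- align_to_germline("TGTGCCTGTGACACCCTGGGGGATACCGATAAACTCATCTTT",
                          test_ref())
  expect_equal(al$d, "TRDD3")
  expect_equal(c(al$dstart, al$dend), c(15L, 23L))
  expect_equal(al$n_insertions, 0L)
})

test_that("an exact germline V-D-J concatenation yields zero insertions", {
  ref <- test_ref()
  nt <- paste0(ref$seq[ref$name == "TRDV2"], ref$seq[ref$name == "TRDD3"],
               ref$seq[ref$name == "TRDJ1"])
  al <- align_to_germline(nt, ref)
  expect_equal(al$n_insertions, 0L)
  expect_equal(al$dstart, al$vend + 1L)
  expect_equal(al$jstart, al$dend + 1L)
  expect_equal(al$d_match_len, nchar(ref$seq[ref$name == "TRDD3"]))
})

test_that("inverted-orientation D search finds the TRDD2 transcript", {
  # not a claim about the source annotation pipeline: forward-only search
  # (the default) leaves this transcript D-less
  nt <- "TGTGCCTGTGACACCCTAGGAGACACCGATAAACTCATCTTT"
  fwd <- align_to_germline(nt, test_ref())
  expect_equal(fwd$d, ".")
  inv <- align_to_germline(nt, test_ref(),
                           alignment_params(allow_inverted_d = TRUE))
  expect_equal(inv$d, "TRDD2")
  expect_true(inv$d_inverted)
  expect_equal(inv$n_insertions, 2L)
})

test_that("aligner rejects degenerate input", {
  expect_error(align_to_germline("TGTGCC", test_ref()), "shorter than 9")
  expect_error(align_to_germline("AAAGCCTGTGACACCCTGGGGGATACCGATAAACTCATCTTT",
                                 test_ref()), "V anchor")
})

test_that("greedy alignment matches the brute-force decomposition oracle", {
  ref <- test_ref()
  cfg <- simulation_config(n_individuals = c(CB = 1L),
                           n_insertion_mean = c(CB = 2.0),
                           trim_mean_v = 2, trim_mean_j = 3, seed = 55L)
  set.seed(55)
  tr <- simulate_rearrangement(cfg, "CB", 150L, ref = ref)
  tr <- tr[nchar(tr$cdr3nt) <= 45L, ]
  expect_gt(nrow(tr), 50L)
  for (i in seq_len(nrow(tr))) {
    al <- align_to_germline(tr$cdr3nt[i], ref)
    bf <- oracle_align(tr$cdr3nt[i], ref)
    expect_equal(al$v_match_len, bf$vlen)
    expect_equal(al$j_match_len, bf$jlen)
    expect_equal(al$d_match_len, bf$dlen)
    expect_equal(al$v_match_len + al$j_match_len + al$d_match_len, bf$total)
  }
})

test_that("annotation recovers simulator truth on unambiguous records", {
  ref <- test_ref()
  cfg <- simulation_config(n_individuals = c(CB = 1L), seed = 77L)
  set.seed(77)
  tr <- simulate_rearrangement(cfg, "CB", 600L, ref = ref)
  ann <- annotate_repertoire(
    tr[, c("cdr3nt", "cdr3aa", "v", "d", "j", "vend", "dstart", "dend", "jstart")],
    ref)
  expect_true(all(ann$productive))
  # maximal matching can only absorb junction bases, never miss templated ones
  expect_true(all(ann$vend >= tr$vend))

  # unambiguous = anchored prefix/suffix matches stop exactly at the true
  # junctions and the true D block is long enough to be called
  v_seq <- ref$seq[ref$kind == "V"][1]
  j_seq <- ref$seq[match(tr$j, ref$name)]
  clean_v <- vapply(seq_len(nrow(tr)), function(i) {
    oracle_lcp(tr$cdr3nt[i], v_seq) == tr$vend[i] + 1L
  }, NA)
  clean_j <- vapply(seq_len(nrow(tr)), function(i) {
    oracle_lcs_suffix(tr$cdr3nt[i], j_seq[i]) ==
      nchar(tr$cdr3nt[i]) - tr$jstart[i]
  }, NA)
  d_len <- ifelse(tr$dstart >= 0L, tr$dend - tr$dstart + 1L, 0L)
  # restrict to D-less truths with short middles (no spurious D possible)
  idx <- which(clean_v & clean_j & d_len == 0L & tr$n_insertions < 5L)
  expect_gt(length(idx), 30L)
  expect_equal(ann$vend[idx], tr$vend[idx])
  expect_equal(ann$jstart[idx], tr$jstart[idx])
  expect_equal(ann$d[idx], tr$d[idx])
  expect_equal(ann$n_insertions[idx], tr$n_insertions[idx])
})

test_that("zero-noise simulation annotates to zero insertions throughout", {
  ref <- test_ref()
  cfg <- simulation_config(
    n_individuals = c(CB = 1L), n_insertion_mean = c(CB = 0),
    trim_mean_v = 0, trim_mean_d5 = 0, trim_mean_d3 = 0, trim_mean_j = 0,
    seed = 9L)
  set.seed(9)
  tr <- simulate_rearrangement(cfg, "CB", 120L, ref = ref)
  ann <- annotate_repertoire(
    tr[, c("cdr3nt", "cdr3aa", "v", "d", "j", "vend", "dstart", "dend", "jstart")],
    ref)
  expect_true(all(ann$n_insertions == 0L))
})

test_that("unproductive records are flagged without aborting the batch", {
  rep <- read_sa62()
  rep$cdr3nt[3] <- "TGTTAATGTGACACACTGGGGGATACCGATAAACTCATCTTT"  # in-frame stop
  ann <- annotate_repertoire(rep, test_ref())
  expect_false(ann$productive[3])
  expect_true(is.na(ann$n_insertions[3]))
  expect_true(all(ann$productive[-3]))
  expect_equal(unique(ann$cdr3aa[-3]), "CACDTLGDTDKLIF")
})
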