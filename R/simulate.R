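#' Simulation configuration for TRDV2 repertoire cohorts
#'
#' Defines the generative model for multi-individual Vdelta2+ repertoire
#' cohorts: age-group-dependent TRDJ usage and TdT activity (per-junction
#' Poisson N-insertion means), TRDD usage (including no-D rearrangements),
#' geometric exonuclease trimming at each segment end, and a power-law clone
#' size distribution. Defaults emulate the study conditions of a cord-blood /
#' infant / adult cohort: TRDJ3- and TRDJ2-dominant usage in cord blood
#' (TRDJ2 at 15.9%) switching to TRDJ1 dominance in adults (TRDJ2 at 2.1%),
#' marginal TRDJ4, low TdT activity before birth, and a cohort of
#' 11 CB + 55 infant + 23 adult individuals at roughly 2,400 productive
#' rearrangements each.
#'
#' @param n_individuals Named integer vector: individuals per age group.
#' @param n_rearrangements_per_individual Productive rearrangements retained
#'   per individual (rejection sampling enforces productivity).
#' @param j_usage Named list of probability vectors over TRDJ1-4, one per age
#'   group.
#' @param d_usage Probability vector over TRDD1-3 and `none`.
#' @param trim_mean_v,trim_mean_d5,trim_mean_d3,trim_mean_j Mean geometric
#'   trimming (nt) at the V 3' end, D 5'/3' ends and J 5' end.
#' @param n_insertion_mean Named vector: mean Poisson N-insertions per
#'   junction per age group (the TdT-activity knob).
#' @param clone_size_alpha Power-law exponent for clone sizes (> 1).
#' @param seed Integer seed; mandatory, every run is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_individuals = c(CB = 11L, infant = 55L, adult = 23L),
    n_rearrangements_per_individual = 2400L,
    j_usage = list(
      CB     = c(TRDJ1 = 0.100, TRDJ2 = 0.159, TRDJ3 = 0.720, TRDJ4 = 0.021),
      infant = c(TRDJ1 = 0.450, TRDJ2 = 0.090, TRDJ3 = 0.440, TRDJ4 = 0.020),
      adult  = c(TRDJ1 = 0.800, TRDJ2 = 0.021, TRDJ3 = 0.159, TRDJ4 = 0.020)),
    d_usage = c(TRDD1 = 0.05, TRDD2 = 0.15, TRDD3 = 0.70, none = 0.10),
    trim_mean_v = 1, trim_mean_d5 = 1, trim_mean_d3 = 1, trim_mean_j = 2,
    n_insertion_mean = c(CB = 0.5, infant = 1.5, adult = 3.0),
    clone_size_alpha = 2.0,
    seed = NULL) {
  if (is.null(seed)) stop("simulation_config requires an explicit integer seed")
  groups <- names(n_individuals)
  stopifnot(length(groups) >= 1L, all(n_individuals >= 1L),
            n_rearrangements_per_individual >= 1L,
            all(groups %in% names(j_usage)),
            all(groups %in% names(n_insertion_mean)),
            all(n_insertion_mean >= 0),
            trim_mean_v >= 0, trim_mean_d5 >= 0, trim_mean_d3 >= 0,
            trim_mean_j >= 0, clone_size_alpha > 1)
  for (g in groups) {
    p <- j_usage[[g]]
    if (!setequal(names(p), c("TRDJ1", "TRDJ2", "TRDJ3", "TRDJ4")) ||
        abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
      stop("j_usage[['", g, "']] must be a probability vector over TRDJ1-4")
    }
    if (all(p == 0)) stop("all-zero J usage vector")
  }
  if (!"none" %in% names(d_usage) || abs(sum(d_usage) - 1) > 1e-12 ||
      any(d_usage < 0)) {
    stop("d_usage must be a probability vector over TRDD segments plus 'none'")
  }
  structure(list(
    n_individuals = n_individuals,
    n_rearrangements_per_individual = as.integer(n_rearrangements_per_individual),
    j_usage = j_usage, d_usage = d_usage,
    trim_mean_v = trim_mean_v, trim_mean_d5 = trim_mean_d5,
    trim_mean_d3 = trim_mean_d3, trim_mean_j = trim_mean_j,
    n_insertion_mean = n_insertion_mean,
    clone_size_alpha = clone_size_alpha,
    seed = as.integer(seed)), class = "simulation_config")
}

# Uniform random nucleotide strings of the given lengths.
random_nt <- function(lens) {
  out <- rep("", length(lens))
  total <- sum(lens)
  if (total == 0L) return(out)
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  idx <- rep.int(seq_along(lens), lens)
  chunks <- split(bases, idx)
  out[as.integer(names(chunks))] <- vapply(chunks, paste, "", collapse = "")
  out
}

# Geometric trim sizes with the configured mean, capped.
rtrim <- function(n, mean, cap) {
  if (mean <= 0) return(integer(n))
  pmin(stats::rgeom(n, prob = 1 / (1 + mean)), cap)
}

#' Simulate productive TRDV2 rearrangements for one age group
#'
#' Draws J and D segments by the configured usage, trims geometric numbers of
#' bases from the segment ends, inserts Poisson numbers of uniform-random
#' nucleotides at each junction, and keeps only productive chains (in frame,
#' stop-free, starting at the conserved Cys and ending at the conserved Phe)
#' by rejection sampling, so junction statistics stay unbiased conditional on
#' productivity. Uses the current RNG state; seed via `set.seed()` or
#' [simulate_cohort()].
#'
#' A drawn D segment whose templated bases are entirely trimmed away leaves a
#' single-junction, D-less rearrangement (`d = "."`), exactly as such a chain
#' would be annotated.
#'
#' @param cfg [simulation_config()].
#' @param age_group Group key into `cfg$j_usage` / `cfg$n_insertion_mean`.
#' @param n Number of productive rearrangements to return.
#' @param ref Germline reference tibble.
#' @return A truth-record tibble: `cdr3nt`, `cdr3aa`, true `v`/`d`/`j` calls,
#'   true 0-based junction positions, per-junction N strings `n1`/`n2`, and
#'   `n_insertions` (total inserted bases).
#' @export
simulate_rearrangement <- function(cfg, age_group, n = 1L,
                                   ref = load_germline_reference()) {
  stopifnot(inherits(cfg, "simulation_config"),
            age_group %in% names(cfg$j_usage), n >= 1L)
  v_seq <- ref$seq[ref$kind == "V"][1]
  j_seqs <- stats::setNames(ref$seq[ref$kind == "J"], ref$name[ref$kind == "J"])
  d_seqs <- stats::setNames(ref$seq[ref$kind == "D"], ref$name[ref$kind == "D"])
  lambda <- cfg$n_insertion_mean[[age_group]]
  jp <- cfg$j_usage[[age_group]]
  dp <- cfg$d_usage

  acc <- list()
  got <- 0L
  while (got < n) {
    m <- max(200L, ceiling((n - got) / 0.25))
    j_name <- sample(names(jp), m, replace = TRUE, prob = jp)
    d_name <- sample(names(dp), m, replace = TRUE, prob = dp)
    has_d <- d_name != "none"
    d_len <- ifelse(has_d, nchar(d_seqs[d_name]), 0L)

    tv <- rtrim(m, cfg$trim_mean_v, nchar(v_seq) - 3L)
    tj <- rtrim(m, cfg$trim_mean_j, nchar(j_seqs[j_name]) - 3L)
    td5 <- rtrim(m, cfg$trim_mean_d5, max(d_len))
    td3 <- rtrim(m, cfg$trim_mean_d3, max(d_len))

    v_part <- substr(rep(v_seq, m), 1L, nchar(v_seq) - tv)
    j_part <- substr(j_seqs[j_name], tj + 1L, nchar(j_seqs[j_name]))
    d_part <- ifelse(has_d & td5 + td3 < d_len,
                     substr(d_seqs[pmax(1L, match(d_name, names(d_seqs)))],
                            td5 + 1L, d_len - td3), "")
    two_junctions <- d_part != ""

    n1 <- random_nt(stats::rpois(m, lambda))
    n2 <- rep("", m)
    n2[two_junctions] <- random_nt(stats::rpois(sum(two_junctions), lambda))

    cdr3nt <- paste0(v_part, n1, d_part, n2, j_part)
    len <- nchar(cdr3nt)
    in_frame <- len %% 3L == 0L
    aa <- rep(NA_character_, m)
    if (any(in_frame)) aa[in_frame] <- translate_cdr3(cdr3nt[in_frame])
    keep <- !is.na(aa) & substr(aa, 1L, 1L) == "C" &
      substr(aa, nchar(aa), nchar(aa)) == "F"
    if (!any(keep)) next

    vend <- nchar(v_part) - 1L
    dstart <- ifelse(two_junctions, nchar(v_part) + nchar(n1), -1L)
    dend <- ifelse(two_junctions, dstart + nchar(d_part) - 1L, -1L)
    jstart <- len - nchar(j_part)
    batch <- tibble::tibble(
      cdr3nt = unname(cdr3nt), cdr3aa = unname(aa),
      v = "TRDV2",
      d = unname(ifelse(two_junctions, d_name, ".")),
      j = unname(j_name),
      vend = unname(vend), dstart = unname(dstart), dend = unname(dend),
      jstart = unname(jstart),
      n1 = n1, n2 = n2,
      n_insertions = unname(nchar(n1) + nchar(n2)),
      trim_v = tv, trim_j = unname(tj),
      trim_d5 = unname(ifelse(has_d, td5, NA_integer_)),
      trim_d3 = unname(ifelse(has_d, td3, NA_integer_))
    )[keep, ]
    acc[[length(acc) + 1L]] <- batch
    got <- got + nrow(batch)
  }
  utils::head(dplyr::bind_rows(acc), n)
}

#' Simulate a multi-individual repertoire cohort
#'
#' Generates every individual's repertoire with [simulate_rearrangement()],
#' assigns clone sizes from a discrete power law (exponent
#' `clone_size_alpha`), merges identical nucleotide transcripts within an
#' individual, and normalizes frequencies. The same amino-acid CDR3 arising
#' independently in several individuals (convergent recombination) is
#' preserved, never deduplicated across individuals. Bit-identical output is
#' guaranteed for a fixed `cfg$seed`.
#'
#' @param cfg [simulation_config()].
#' @param ref Germline reference tibble.
#' @return A list with `cohort` (clonotype tibble over all individuals, true
#'   annotation columns) and `truth` (per-rearrangement truth records with
#'   `individual_id`/`age_group`).
#' @export
simulate_cohort <- function(cfg, ref = load_germline_reference()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  cohort <- list()
  truth <- list()
  for (g in names(cfg$n_individuals)) {
    for (i in seq_len(cfg$n_individuals[[g]])) {
      id <- sprintf("%s%02d", g, i)
      tr <- simulate_rearrangement(cfg, g, cfg$n_rearrangements_per_individual,
                                   ref = ref)
      tr <- tibble::add_column(tr, individual_id = id, age_group = g,
                               .before = 1L)
      u <- stats::runif(nrow(tr))
      tr$count <- pmin(1e6, floor(u^(-1 / (cfg$clone_size_alpha - 1))))
      clon <- tr |>
        dplyr::group_by(.data$cdr3nt) |>
        dplyr::summarise(
          individual_id = dplyr::first(.data$individual_id),
          age_group = dplyr::first(.data$age_group),
          count = as.integer(sum(.data$count)),
          cdr3aa = dplyr::first(.data$cdr3aa),
          v = dplyr::first(.data$v), d = dplyr::first(.data$d),
          j = dplyr::first(.data$j),
          vend = dplyr::first(.data$vend), dstart = dplyr::first(.data$dstart),
          dend = dplyr::first(.data$dend), jstart = dplyr::first(.data$jstart),
          .groups = "drop") |>
        dplyr::arrange(dplyr::desc(.data$count), .data$cdr3nt)
      clon$freq <- clon$count / sum(clon$count)
      clon <- clon[, c("individual_id", "age_group", clonotype_columns())]
      cohort[[id]] <- clon
      truth[[id]] <- tr
    }
  }
  list(cohort = dplyr::bind_rows(cohort), truth = dplyr::bind_rows(truth))
}
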