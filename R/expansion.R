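#' Label high- and low-frequency CDR3aa within each individual
#'
#' Within each individual, distinct CDR3aa sequences (frequencies summed
#' over their nucleotide variants) are ranked from most to least frequent;
#' the top `ceiling(quantile * n)` are `high_freq`, the rest `low_freq`.
#' Ties at the boundary are broken by lexicographic CDR3aa order, so the
#' labeling is deterministic and invariant to uniform rescaling of the
#' frequencies.
#'
#' @param cohort Clonotype tibble (one or many individuals).
#' @param quantile Fraction labelled high-frequency (default 0.25).
#' @return A tibble `individual_id`, `cdr3aa`, `freq` (aggregated),
#'   `freq_label`.
#' @export
label_frequency <- function(cohort, quantile = 0.25) {
  if (!nrow(cohort)) stop("empty repertoire")
  stopifnot(quantile > 0, quantile <= 1)
  cohort |>
    dplyr::group_by(.data$individual_id, .data$cdr3aa) |>
    dplyr::summarise(freq = sum(.data$freq), .groups = "drop") |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$cdr3aa, .by_group = TRUE) |>
    dplyr::mutate(freq_label = ifelse(
      dplyr::row_number() <= ceiling(quantile * dplyr::n()),
      "high_freq", "low_freq")) |>
    dplyr::ungroup()
}

#' Expansion status score
#'
#' `ln((n_highfreq + 1) / (n_lowfreq + 1))` for a group of CDR3aa sequences
#' within one individual. Positive scores mean the group holds more
#' high-frequency than low-frequency sequences; the +1 terms keep empty
#' groups finite (score 0 when both counts are 0 or equal).
#'
#' @param n_highfreq,n_lowfreq Non-negative counts (vectorized).
#' @return Numeric score(s).
#' @examples
#' expansion_score(3, 1)  # log(2)
#' @export
expansion_score <- function(n_highfreq, n_lowfreq) {
  stopifnot(all(n_highfreq >= 0), all(n_lowfreq >= 0))
  log((n_highfreq + 1) / (n_lowfreq + 1))
}

#' Expansion status per individual and group
#'
#' Joins frequency labels to a grouping of CDR3aa (typically the publicity
#' label, optionally crossed with J usage), counts high-/low-frequency
#' members per individual and group, and scores each cell with
#' [expansion_score()]. Empty cells score 0 by the formula and carry
#' `n_highfreq = n_lowfreq = 0`.
#'
#' @param labeling Output of [label_frequency()].
#' @param grouping Tibble mapping `cdr3aa` to group column(s) (e.g. the
#'   `cdr3aa`/`label` columns of [classify_publicity()]).
#' @param group_cols Names of the grouping columns.
#' @return A tibble `individual_id`, grouping columns, `n_highfreq`,
#'   `n_lowfreq`, `score`.
#' @export
expansion_by_group <- function(labeling, grouping, group_cols = "label") {
  labeling |>
    dplyr::inner_join(grouping[, c("cdr3aa", group_cols)], by = "cdr3aa",
                      relationship = "many-to-many") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("individual_id", group_cols)))) |>
    dplyr::summarise(
      n_highfreq = sum(.data$freq_label == "high_freq"),
      n_lowfreq = sum(.data$freq_label == "low_freq"),
      .groups = "drop") |>
    dplyr::mutate(score = expansion_score(.data$n_highfreq, .data$n_lowfreq))
}

#' Games-Howell post-hoc test
#'
#' Pairwise comparisons of group means without assuming equal variances or
#' sample sizes: each pair is tested with the studentized-range statistic
#' `q = |mean_i - mean_j| / SE * sqrt(2)`, `SE = sqrt(s_i^2/n_i + s_j^2/n_j)`,
#' against the studentized-range distribution with the total number of
#' groups and Welch-Satterthwaite degrees of freedom. The procedure is
#' familywise by construction; no further multiplicity correction is
#' applied.
#'
#' @param x Numeric vector of observations.
#' @param g Grouping factor/vector of the same length (>= 2 groups, each
#'   with n >= 2 and nonzero variance).
#' @return A tibble with one row per unordered group pair: `group_i`,
#'   `group_j`, `diff` (mean_j - mean_i), `se`, `df`, `q`, `p`.
#' @export
games_howell <- function(x, g) {
  stopifnot(length(x) == length(g))
  g <- factor(g)
  k <- nlevels(g)
  if (k < 2L) stop("need at least two groups")
  ns <- tapply(x, g, length)
  if (any(ns < 2L)) stop("every group needs at least two observations")
  means <- tapply(x, g, mean)
  vars <- tapply(x, g, stats::var)
  if (any(vars == 0)) stop("zero-variance group: Games-Howell is undefined")
  pairs <- utils::combn(levels(g), 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- vars[[i]] / ns[[i]] + vars[[j]] / ns[[j]]
    df <- se2^2 / ((vars[[i]] / ns[[i]])^2 / (ns[[i]] - 1L) +
                     (vars[[j]] / ns[[j]])^2 / (ns[[j]] - 1L))
    q <- abs(means[[j]] - means[[i]]) / sqrt(se2) * sqrt(2)
    c(diff = means[[j]] - means[[i]], se = sqrt(se2), df = df, q = q,
      p = stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
  })
  tibble::tibble(group_i = pairs[1, ], group_j = pairs[2, ],
                 diff = unname(res["diff", ]), se = unname(res["se", ]),
                 df = unname(res["df", ]), q = unname(res["q", ]),
                 p = unname(res["p", ]))
}

#' Position frequency matrix for equal-length CDR3aa sequences
#'
#' Per-position residue probabilities for a length stratum of CDR3aa
#' sequences, ready for sequence-logo rendering. Sequences are stacked
#' as-is: within a fixed (J segment, length) stratum the alignment is the
#' identity, so no multiple sequence alignment is needed.
#'
#' @param sequences Character vector of equal-length amino-acid sequences.
#' @return A length x 20 matrix; rows are positions (each summing to 1),
#'   columns the 20 standard residues.
#' @export
position_frequency_matrix <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) {
    stop("sequences must share one length (stratify by length first)")
  }
  ab <- sort(aa_alphabet())
  chars <- matrix(unlist(strsplit(sequences, "")), nrow = length(sequences),
                  byrow = TRUE)
  if (any(!chars %in% ab)) stop("unknown residue in input sequences")
  pfm <- t(apply(chars, 2L, function(col) {
    tabulate(match(col, ab), nbins = length(ab)) / length(col)
  }))
  colnames(pfm) <- ab
  rownames(pfm) <- seq_len(lens)
  pfm
}
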