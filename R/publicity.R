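#' Classify CDR3aa publicity across individuals
#'
#' A CDR3 amino-acid sequence found in exactly one individual is `private`;
#' one shared by at least `threshold` of the cohort (by default 10%, i.e. 9
#' or more individuals in an 89-individual cohort) is `high_public`; the
#' remainder (shared by 2 individuals up to the threshold) is `low_public`.
#' Presence is counted once per individual, regardless of clone size or of
#' how many nucleotide variants encode the sequence there.
#'
#' @param cohort Clonotype tibble covering at least two individuals.
#' @param threshold High-public share fraction (`share_fraction >= threshold`).
#' @return A tibble with one row per distinct CDR3aa: `cdr3aa`, `n_sharing`,
#'   `share_fraction`, `label`, plus cohort-wide `n_nt_variants` and the
#'   distinct D calls `d_usages` (list column, `"."` included).
#' @export
classify_publicity <- function(cohort, threshold = 0.10) {
  n_ind <- length(unique(cohort$individual_id))
  if (n_ind < 2L) stop("publicity is undefined for a single-individual cohort")
  rec <- cohort |>
    dplyr::group_by(.data$cdr3aa) |>
    dplyr::summarise(
      n_sharing = dplyr::n_distinct(.data$individual_id),
      n_nt_variants = dplyr::n_distinct(.data$cdr3nt),
      d_usages = list(sort(unique(.data$d))),
      .groups = "drop")
  rec$share_fraction <- rec$n_sharing / n_ind
  rec$label <- ifelse(rec$n_sharing == 1L, "private",
                      ifelse(rec$share_fraction >= threshold,
                             "high_public", "low_public"))
  rec[, c("cdr3aa", "n_sharing", "share_fraction", "label",
          "n_nt_variants", "d_usages")]
}

#' Synonymous-transcript multiplicity per CDR3aa
#'
#' Counts, for every amino-acid CDR3, how many distinct nucleotide
#' transcripts encode it (convergent recombination), together with the D
#' segments observed among those transcripts and the number of sharing
#' individuals. `scope = "cohort"` pools transcripts across the whole
#' cohort; `scope = "individual"` counts within each individual separately.
#'
#' @param cohort Clonotype tibble.
#' @param scope `"cohort"` or `"individual"`.
#' @return A tibble keyed by `cdr3aa` (and `individual_id` for individual
#'   scope) with `n_nt_variants`, `d_usages` (list column) and `n_sharing`.
#' @export
transcript_multiplicity <- function(cohort, scope = c("cohort", "individual")) {
  scope <- match.arg(scope)
  sharing <- cohort |>
    dplyr::group_by(.data$cdr3aa) |>
    dplyr::summarise(n_sharing = dplyr::n_distinct(.data$individual_id),
                     .groups = "drop")
  keys <- if (scope == "cohort") "cdr3aa" else c("individual_id", "cdr3aa")
  cohort |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_nt_variants = dplyr::n_distinct(.data$cdr3nt),
      d_usages = list(sort(unique(.data$d))),
      .groups = "drop") |>
    dplyr::left_join(sharing, by = "cdr3aa")
}

#' Fraction of CDR3aa with many synonymous transcripts, per publicity label
#'
#' For each individual and publicity label, the fraction of that
#' individual's distinct CDR3aa generated by at least `min_variants` unique
#' nucleotide transcripts within the individual. Labels with no members in
#' an individual are reported as missing (no row), not as 0.
#'
#' @param cohort Clonotype tibble.
#' @param publicity Output of [classify_publicity()] on the same cohort.
#' @param min_variants Transcript-count threshold (default 5).
#' @return A tibble `individual_id`, `label`, `n_cdr3aa`, `fraction`.
#' @export
multi_transcript_fraction <- function(cohort, publicity, min_variants = 5L) {
  per_ind <- transcript_multiplicity(cohort, scope = "individual")
  per_ind |>
    dplyr::left_join(publicity[, c("cdr3aa", "label")], by = "cdr3aa") |>
    dplyr::group_by(.data$individual_id, .data$label) |>
    dplyr::summarise(
      n_cdr3aa = dplyr::n(),
      fraction = mean(.data$n_nt_variants >= min_variants),
      .groups = "drop")
}

#' Fraction of CDR3aa rearranged from more than one D segment
#'
#' For each publicity label, the fraction of CDR3aa whose transcripts use at
#' least two distinct real TRDD segments. The absent-D sentinel `"."` is not
#' a segment and never counts toward the rule.
#'
#' @param records Output of [classify_publicity()] (cohort-scope `d_usages`).
#' @return A tibble `label`, `n_cdr3aa`, `fraction`.
#' @export
multi_d_fraction <- function(records) {
  n_real_d <- vapply(records$d_usages, function(d) sum(d != "."), 0L)
  tibble::tibble(label = records$label, multi_d = n_real_d >= 2L) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n_cdr3aa = dplyr::n(), fraction = mean(.data$multi_d),
                     .groups = "drop")
}

#' Overlap of public CDR3aa sequences between age groups
#'
#' Publicity is computed within each group's own individuals (public = found
#' in at least two of that group's individuals); the overlap of the
#' resulting public sets gives the Venn cells.
#'
#' @param cohort Clonotype tibble.
#' @param groups Age-group labels to compare (2 or 3).
#' @return A list with `sizes` (named per-group public set sizes) and
#'   `cells` (tibble of Venn regions: `region`, `count`; regions are
#'   exclusive cells like `"CB&adult"`).
#' @export
group_overlap <- function(cohort, groups = c("CB", "adult")) {
  unknown <- setdiff(groups, unique(cohort$age_group))
  if (length(unknown)) stop("unknown group label(s): ",
                            paste(unknown, collapse = ", "))
  stopifnot(length(groups) >= 2L, length(groups) <= 3L)
  pub <- lapply(groups, function(g) {
    sub <- cohort[cohort$age_group == g, , drop = FALSE]
    sh <- tapply(sub$individual_id, sub$cdr3aa,
                 function(x) length(unique(x)))
    names(sh)[sh >= 2L]
  })
  names(pub) <- groups
  all_pub <- unique(unlist(pub))
  if (!length(all_pub)) {
    return(list(sizes = vapply(pub, length, 0L),
                cells = tibble::tibble(region = character(), count = integer())))
  }
  membership <- vapply(pub, function(s) all_pub %in% s,
                       logical(length(all_pub)))
  if (length(all_pub) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1L, function(m) paste(groups[m], collapse = "&"))
  cells <- tibble::tibble(region = pattern) |>
    dplyr::count(.data$region, name = "count")
  list(sizes = vapply(pub, length, 0L), cells = cells)
}
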