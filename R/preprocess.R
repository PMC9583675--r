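#' Filtering and down-sampling parameters
#'
#' Defaults follow the pre-processing applied before distance analysis:
#' keep CDR3aa lengths of 14-22 residues, drop TRDJ4 rearrangements, and
#' down-sample every age group to the smallest group's number of unique
#' CDR3aa sequences.
#'
#' @param min_len_aa,max_len_aa Inclusive CDR3aa length bounds.
#' @param excluded_j Segment names whose rearrangements are removed.
#' @param per_group_target Per-group number of unique CDR3aa to retain, or
#'   `"min-group-size"`.
#' @param seed Seed for the down-sampling draw.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_len_aa = 14L, max_len_aa = 22L,
                          excluded_j = "TRDJ4",
                          per_group_target = "min-group-size",
                          seed = 1L) {
  stopifnot(min_len_aa <= max_len_aa)
  if (!identical(per_group_target, "min-group-size")) {
    stopifnot(is.numeric(per_group_target), per_group_target >= 1)
  }
  structure(list(min_len_aa = as.integer(min_len_aa),
                 max_len_aa = as.integer(max_len_aa),
                 excluded_j = excluded_j,
                 per_group_target = per_group_target,
                 seed = as.integer(seed)),
            class = "filter_params")
}

#' Apply length and J-segment filters to a cohort
#'
#' Retains clonotypes whose CDR3aa length lies within the configured bounds
#' and whose J call is not excluded. Removal counts per criterion are
#' reported via `message()`. Unproductive records (if present) are removed
#' first.
#'
#' @param cohort Annotated clonotype tibble.
#' @param params [filter_params()].
#' @return The filtered cohort tibble.
#' @export
filter_clonotypes <- function(cohort, params = filter_params()) {
  keep_prod <- if ("productive" %in% names(cohort)) cohort$productive else
    rep(TRUE, nrow(cohort))
  len <- nchar(cohort$cdr3aa)
  keep_len <- len >= params$min_len_aa & len <= params$max_len_aa
  keep_j <- !cohort$j %in% params$excluded_j
  message(sprintf(
    "filter_clonotypes: removed %d unproductive, %d by length, %d by J segment (of %d)",
    sum(!keep_prod), sum(keep_prod & !keep_len),
    sum(keep_prod & keep_len & !keep_j), nrow(cohort)))
  cohort[keep_prod & keep_len & keep_j, , drop = FALSE]
}

#' Randomly down-sample each age group to a common size
#'
#' The sampling unit is the unique CDR3aa sequence within an age group:
#' each group is reduced to `per_group_target` distinct CDR3aa (uniformly,
#' without replacement, deterministic under the configured seed), and all
#' clonotype records carrying a selected CDR3aa are retained, so
#' per-individual structure survives. Groups already at or below the target
#' are left unchanged, which makes the operation idempotent.
#'
#' @param cohort Clonotype tibble with `age_group`.
#' @param params [filter_params()]; `per_group_target` may be a count or
#'   `"min-group-size"` (the smallest group's unique-CDR3aa count).
#' @param strict Error (rather than skip) when a numeric target exceeds a
#'   group's size.
#' @return The down-sampled cohort tibble.
#' @export
downsample_by_group <- function(cohort, params = filter_params(),
                                strict = FALSE) {
  sizes <- vapply(split(cohort$cdr3aa, cohort$age_group),
                  function(x) length(unique(x)), 0L)
  target <- if (identical(params$per_group_target, "min-group-size")) {
    min(sizes)
  } else {
    as.integer(params$per_group_target)
  }
  if (strict && any(sizes < target)) {
    stop("down-sampling target ", target, " exceeds group size(s): ",
         paste(names(sizes)[sizes < target], collapse = ", "))
  }
  set.seed(params$seed)
  keep <- rep(TRUE, nrow(cohort))
  for (g in sort(names(sizes))) {
    in_g <- cohort$age_group == g
    uniq <- sort(unique(cohort$cdr3aa[in_g]))
    if (length(uniq) <= target) next
    chosen <- sample(uniq, target)
    keep[in_g] <- cohort$cdr3aa[in_g] %in% chosen
  }
  cohort[keep, , drop = FALSE]
}
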