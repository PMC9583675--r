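#' Cohort-level summary tables
#'
#' Aggregates the descriptive statistics reported for repertoire cohorts:
#' J-segment usage composition per age group, publicity-label composition
#' per age group, CDR3aa length distribution, N-insertion summaries and the
#' fraction of sequences with 10 or more N-insertions per group.
#'
#' J usage and length are tallied over distinct CDR3aa per group (each
#' distinct sequence counted once); publicity composition is the share of a
#' group's distinct CDR3aa in each publicity class.
#'
#' @param cohort Annotated clonotype tibble.
#' @param publicity Optional output of [classify_publicity()]; publicity
#'   tables are skipped when absent.
#' @param high_insertion_min Threshold for the high-insertion fraction
#'   (default 10 N-insertions).
#' @return A named list of tibbles: `j_usage`, `length_distribution`,
#'   `n_insertion_summary`, `high_insertion_fraction`, and (given
#'   `publicity`) `publicity_composition`.
#' @export
summarize_cohort <- function(cohort, publicity = NULL,
                             high_insertion_min = 10L) {
  uniq <- cohort |>
    dplyr::group_by(.data$age_group, .data$cdr3aa) |>
    dplyr::summarise(j = dplyr::first(.data$j),
                     n_insertions = min(.data$n_insertions),
                     .groups = "drop")
  j_usage <- uniq |>
    dplyr::count(.data$age_group, .data$j, name = "n") |>
    dplyr::group_by(.data$age_group) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  length_distribution <- uniq |>
    dplyr::mutate(len = nchar(.data$cdr3aa)) |>
    dplyr::count(.data$age_group, .data$len, name = "n")
  n_ins <- cohort |>
    dplyr::filter(!is.na(.data$n_insertions)) |>
    dplyr::group_by(.data$age_group)
  n_insertion_summary <- n_ins |>
    dplyr::summarise(mean = mean(.data$n_insertions),
                     median = stats::median(.data$n_insertions),
                     q1 = stats::quantile(.data$n_insertions, 0.25),
                     q3 = stats::quantile(.data$n_insertions, 0.75),
                     .groups = "drop")
  high_insertion_fraction <- n_ins |>
    dplyr::summarise(
      fraction = mean(.data$n_insertions >= high_insertion_min),
      .groups = "drop")
  out <- list(j_usage = j_usage,
              length_distribution = length_distribution,
              n_insertion_summary = n_insertion_summary,
              high_insertion_fraction = high_insertion_fraction)
  if (!is.null(publicity)) {
    pres <- cohort |>
      dplyr::distinct(.data$age_group, .data$cdr3aa) |>
      dplyr::left_join(publicity[, c("cdr3aa", "label")], by = "cdr3aa")
    out$publicity_composition <- pres |>
      dplyr::count(.data$age_group, .data$label, name = "n") |>
      dplyr::group_by(.data$age_group) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  out
}
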