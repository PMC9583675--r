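# Shared configuration for the analysis drivers. Every script sources this
# file, so the whole workflow is reproducible from one seed.
#
# Cohort shape mirrors the study design (11 cord-blood, 55 infant, 23 adult
# individuals); 600 productive rearrangements per individual puts the
# simulated cohort at the ~50,000-sequence scale of the post-filter dataset
# while keeping each driver's runtime in minutes.

library(vd2rep)

ANALYSIS_SEED <- 20260901L

analysis_config <- function() {
  simulation_config(
    n_individuals = c(CB = 11L, infant = 55L, adult = 23L),
    n_rearrangements_per_individual = 600L,
    seed = ANALYSIS_SEED)
}

results_path <- function(...) {
  p <- file.path("results", ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}

annotated_cohort_path <- function() results_path("data", "cohort_annotated.tsv")
filtered_cohort_path <- function() results_path("data", "cohort_filtered.tsv")

read_analysis_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
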