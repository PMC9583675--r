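# Expansion analysis: labels the top 25% of each individual's CDR3aa as
# high-frequency, scores publicity groups with the expansion status score,
# compares N-insertion counts between age groups with the Games-Howell
# test, and exports a position frequency matrix for one (J, length)
# stratum.

source("analysis/00_config.R")

ann <- read_analysis_cohort(annotated_cohort_path())
pub <- classify_publicity(ann, threshold = 0.10)

lab <- label_frequency(ann, quantile = 0.25)
rec <- expansion_by_group(lab, pub[, c("cdr3aa", "label")])
readr::write_tsv(rec, results_path("expansion_records.tsv"))

med <- tapply(rec$score, rec$label, stats::median)
cat("Median expansion status score by publicity label:\n")
print(round(med, 3))

gh_exp <- games_howell(rec$score, rec$label)
cat("\nGames-Howell comparison of expansion scores between labels:\n")
print(as.data.frame(gh_exp))
readr::write_tsv(gh_exp, results_path("games_howell_expansion.tsv"))

# N-insertions by age group, one value per distinct transcript
u <- ann[!duplicated(ann[c("age_group", "cdr3nt")]) & !is.na(ann$n_insertions), ]
gh_ins <- games_howell(u$n_insertions, u$age_group)
cat("\nGames-Howell comparison of N-insertions between age groups:\n")
print(as.data.frame(gh_ins))
readr::write_tsv(gh_ins, results_path("games_howell_n_insertions.tsv"))

# logo-ready position frequencies for the most prevalent TRDJ1 stratum
j1 <- ann$cdr3aa[ann$j == "TRDJ1" & !is.na(ann$n_insertions)]
len <- as.integer(names(which.max(table(nchar(j1)))))
pfm <- position_frequency_matrix(unique(j1[nchar(j1) == len]))
readr::write_tsv(tibble::as_tibble(pfm, rownames = "position"),
                 results_path(sprintf("pfm_trdj1_len%d.tsv", len)))
cat(sprintf("\nWrote position frequency matrix for TRDJ1 length-%d stratum (%d sequences)\n",
            len, sum(nchar(unique(j1)) == len)))
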