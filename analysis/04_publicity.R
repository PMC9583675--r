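# Publicity analysis: classifies every CDR3aa as private / low public /
# high public, quantifies convergent recombination (synonymous-transcript
# multiplicity, multi-D usage) and the overlap of public repertoires
# between age groups.

source("analysis/00_config.R")

ann <- read_analysis_cohort(annotated_cohort_path())

pub <- classify_publicity(ann, threshold = 0.10)
cat("Publicity composition over", nrow(pub), "distinct CDR3aa:\n")
print(table(pub$label))

pub_flat <- pub
pub_flat$d_usages <- vapply(pub$d_usages, paste, "", collapse = ",")
readr::write_tsv(pub_flat, results_path("publicity_table.tsv"))

rep <- summarize_cohort(ann, publicity = pub)
readr::write_tsv(rep$publicity_composition,
                 results_path("publicity_composition_by_group.tsv"))

# synonymous-transcript multiplicity rises with publicity
mult <- pub |>
  dplyr::group_by(label) |>
  dplyr::summarise(mean_nt_variants = mean(n_nt_variants),
                   max_nt_variants = max(n_nt_variants), .groups = "drop")
cat("\nTranscript multiplicity by publicity label (cohort scope):\n")
print(as.data.frame(mult))
readr::write_tsv(mult, results_path("transcript_multiplicity_by_label.tsv"))

md <- multi_d_fraction(pub)
cat("\nFraction of CDR3aa rearranged from >1 TRDD segment:\n")
print(as.data.frame(md))
readr::write_tsv(md, results_path("multi_d_fraction.tsv"))

mtf <- multi_transcript_fraction(ann, pub, min_variants = 5L)
mtf_sum <- mtf |>
  dplyr::group_by(label) |>
  dplyr::summarise(median_fraction = stats::median(fraction), .groups = "drop")
cat("\nPer-individual fraction of CDR3aa with >=5 transcripts (median):\n")
print(as.data.frame(mtf_sum))
readr::write_tsv(mtf, results_path("multi_transcript_fraction.tsv"))

ov <- group_overlap(ann, c("CB", "infant", "adult"))
cat("\nPublic-repertoire overlap between age groups (Venn cells):\n")
print(as.data.frame(ov$cells))
readr::write_tsv(ov$cells, results_path("public_overlap_venn.tsv"))
readr::write_tsv(tibble::tibble(group = names(ov$sizes), n_public = ov$sizes),
                 results_path("public_set_sizes.tsv"))
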