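# vd2rep

Analysis of human Vδ2+ T-cell receptor (TRD) repertoires across age groups.

Human Vγ9Vδ2+ T cells carry a semi-invariant γ chain paired with a highly
diverse TRDV2 δ chain whose CDR3 is created by V(D)J recombination,
exonuclease trimming and non-templated (N) nucleotide insertion by TdT.
Many Vδ2+ CDR3 amino-acid sequences are **public** — found in a large
fraction of unrelated individuals — and publicity is tightly linked to
germline-like rearrangement (few N-insertions) and to **convergent
recombination**: many distinct nucleotide transcripts, sometimes using
different TRDD segments, encoding the same amino-acid CDR3. `vd2rep`
implements the computations needed to characterize this structure, for
immunologists working with bulk TCR-seq clonotype tables:

- **Junction re-annotation** — deterministic maximal anchored matching of a
  CDR3 nucleotide sequence against the germline TRDV2 / TRDD1–3 / TRDJ1–4
  reference, and N-insertion counting from 0-based junction positions:
  with a D segment, `N = (Jstart − Dend − 1) + (Dstart − Vend − 1)`;
  without, `N = Jstart − Vend − 1`.
- **Publicity classification** — a CDR3aa present in one individual is
  *private*; in ≥ 10 % of the cohort, *high public* (9 or more of 89
  individuals); otherwise *low public*.
- **Convergent recombination** — per-CDR3aa synonymous transcript
  multiplicity, multi-TRDD usage, and public-repertoire overlap between
  age groups.
- **CDR3 distance** — a TCRdist-style metric: after trimming the conserved
  flanks (3 N-terminal, 2 C-terminal residues), each mismatch costs
  `min(4, 4 − BLOSUM62(a, b))` (floored at 0), gaps cost 4, and the CDR3
  sum is weighted ×3; a pluggable 2-D embedding (metric MDS by default)
  visualizes the matrix.
- **Expansion status** — per individual, the top 25 % of CDR3aa by
  frequency are *high-frequency*; a group of sequences is scored
  `ln((n_highfreq + 1)/(n_lowfreq + 1))`.
- **Games–Howell post-hoc test** — pairwise mean comparisons under unequal
  variances and sample sizes, via the studentized-range distribution with
  Welch–Satterthwaite degrees of freedom.
- **Cohort simulator** — a V(D)J rearrangement generator for
  multi-individual TRDV2 cohorts with age-dependent TRDJ usage and TdT
  activity, geometric trimming, Poisson insertions, power-law clone sizes
  and a productivity filter; it provides ground truth for every
  downstream stage, so no external data is required.

## Worked example

Eight synonymous transcripts of the public CDR3 `CACDTLGDTDKLIF` observed
in one donor ship as a packaged fixture. All eight translate to a single
amino-acid sequence, and re-aligning the transcript recorded without a D
segment against the germline reference recovers its 9 N-insertions:

```r
library(vd2rep)
ref  <- load_germline_reference()
sa62 <- read_clonotype_table(
  system.file("extdata", "sa62_cacdtlgdtdklif.tsv", package = "vd2rep"),
  individual_id = "SA62", age_group = "adult")

unique(translate_cdr3(sa62$cdr3nt))
#> [1] "CACDTLGDTDKLIF"

transcript_multiplicity(sa62, scope = "individual")$n_nt_variants
#> [1] 8

align_to_germline(sa62$cdr3nt[sa62$d == "."], ref)[, c("d", "vend", "jstart", "n_insertions")]
#> # A tibble: 1 × 4
#>   d      vend jstart n_insertions
#>   <chr> <int>  <int>        <int>
#> 1 .        14     24            9
```

The multiplicity of 8 within a single donor, spanning two different TRDD
segments plus a D-less rearrangement, is convergent recombination at work:
publicity of an amino-acid sequence grows with the number of nucleotide
routes that reach it.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that chain the
package's functions into the full study on a simulated cohort
(11 cord-blood, 55 infant, 23 adult individuals; seed fixed in
`analysis/00_config.R`); each writes its tables under `results/`:

```sh
Rscript analysis/01_table1_worked_example.R   # fixture annotation
Rscript analysis/02_simulate_and_annotate.R   # cohort, J usage, N-insertions
Rscript analysis/03_preprocess.R              # 14-22 aa / no-TRDJ4 filter, down-sampling
Rscript analysis/04_publicity.R               # publicity, multiplicity, Venn overlap
Rscript analysis/05_distance_embedding.R      # distance matrix, 2-D embedding
Rscript analysis/06_expansion.R               # expansion scores, Games-Howell
```

Scripts 03–06 read the tables written by script 02.

## Package layout

- `R/` — implementation (IO, annotation, simulator, preprocessing,
  publicity, distance, expansion statistics).
- `inst/extdata/` — germline TRD reference FASTA and the eight-transcript
  donor fixture.
- `vignettes/vd2rep-methods.Rmd` — the methods vignette: model,
  parameters, design choices, limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
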