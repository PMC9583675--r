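---
title: "Methods: annotation, publicity and expansion analysis of Vδ2+ TCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation, publicity and expansion analysis of Vδ2+ TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vd2rep)
```

`vd2rep` analyses bulk TCR-seq clonotype tables of human Vδ2+ (TRDV2)
δ chains: it re-annotates V(D)J junctions, counts N-insertions, classifies
public versus private amino-acid CDR3s, quantifies convergent
recombination, computes a biochemically informed CDR3 distance, and scores
clonal expansion. A cohort simulator generates ground-truth data with the
statistical structure these analyses assume. This vignette records the
models, the tunable parameters, and the design decisions.

## Coordinate conventions and data model

A clonotype is one row of a tab-separated table: read `count`, frequency
`freq`, nucleotide CDR3 (`cdr3nt`, conserved Cys codon through conserved
Phe codon), amino-acid CDR3 (`cdr3aa`), segment calls `v`/`d`/`j`, and
junction positions `VEnd`, `DStart`, `DEnd`, `JStart`. Positions are
**0-based inclusive indices into `cdr3nt`**: `VEnd` is the last
V-templated base, `JStart` the first J-templated base, `DStart`/`DEnd` the
first/last D-templated base. This convention is chosen so that the
N-insertion count evaluates directly as

$$N = (J_{start} - D_{end} - 1) + (D_{start} - V_{end} - 1)$$

for D-carrying rearrangements and $N = J_{start} - V_{end} - 1$ without D
usage, with each junction term clipped at zero. Files using 1-based
positions are converted at read time (`positions_base = 1`). An absent D
segment is `"."` in the text column and `-1` in the position columns.

The germline reference holds CDR3-proximal regions only: TRDV2 from the
conserved Cys codon to the segment 3' end, TRDD1–3 in full, TRDJ1–4 from
the segment 5' end through the conserved Phe codon. Full gene sequences
are unnecessary because every quantity here is defined inside the CDR3.
The TRDV2, TRDD1–3 and TRDJ1 entries follow the IMGT reference; the
TRDJ2–4 entries are excerpts reconstructed from their canonical CDR3 tail
motifs and are exercised only by the simulator, which is self-consistent
(it generates from and is annotated against the same reference).

## Junction re-annotation

`align_to_germline()` uses deterministic maximal anchored matching:

1. **V**: the longest prefix of `cdr3nt` matching the V germline prefix
   (both anchored at the Cys codon).
2. **J**: the longest suffix matching each J germline suffix (anchored at
   the Phe codon); the J with the longest match wins, ties resolve to the
   lowest segment number. If the V and J matches would overlap, J yields.
3. **D**: the germline D with the longest contiguous match lying wholly
   between the V and J matches, accepted only at `min_d_match` (default 5)
   nucleotides or more; D yields to both V and J, so overlapping bases are
   never double-counted. Ties prefer forward orientation, then the lowest
   segment number, then the leftmost placement. Inverted-orientation D
   search (`allow_inverted_d`) is off by default.

Mismatch budgets for the V/J anchors default to 0 (exact matching). The
defaults were fixed before any tuning: `min_d_match = 5` is the smallest
threshold at which chance matches of the short TRDD segments (8–13 nt)
stop producing spurious D calls in the packaged worked example, and it
reproduces that example's filed annotations — the D-carrying transcripts
keep their TRDD3 calls and the D-less transcript annotates with 9
N-insertions.

Two caveats are worth recording. First, maximal matching resolves
junction ambiguity greedily: when the first inserted base happens to equal
the next germline base, the V (or J) match absorbs it. Such decompositions
are genuinely ambiguous; the simulator round-trip tests therefore assert
exact recovery only on records whose maximal matches stop exactly at the
true junctions, and assert bounds (annotated V end ≥ true V end) elsewhere.
Second, aligners that score mismatches (as MiXCR does) can annotate
individual transcripts differently from exact matching; one fixture
transcript carries a filed N-count of 1 that exact matching renders as 2
for precisely this reason. The package treats the exact-matching result as
its definition.

The objective is lexicographic — maximal V, then maximal J, then the
longest admissible D — not "maximal total templated bases": the two differ
when shortening the J match would let a sub-threshold D block cross
`min_d_match`. The lexicographic rule is the one the worked example's
filed annotations follow, and the brute-force oracle in the test suite
enumerates decompositions under the same objective.

## Publicity and convergent recombination

`classify_publicity()` counts, per amino-acid CDR3, the number of
individuals containing it (once per individual, regardless of clone size
or of how many nucleotide variants encode it): one individual → *private*;
a share of the cohort at or above the threshold (default 10 %) →
*high public* (with 89 individuals the minimal high-public count is 9);
otherwise *low public*. The boundary is implemented directly as
`share_fraction >= threshold`, with no rounding arithmetic on counts.

`transcript_multiplicity()` counts distinct `cdr3nt` per `cdr3aa` at
cohort or individual scope, with the D segments observed among the
variants. In the multi-D criterion (`multi_d_fraction()`), the absent-D
sentinel `"."` does not count as a segment: "rearranged from more than one
D segment" requires two *real* TRDD calls. Group-overlap Venn cells are
computed with publicity assessed within each age group's own individuals
(public there means ≥ 2 of that group's individuals).

## CDR3 distance and embedding

`cdr3_pair_distance()` follows the TCRdist penalty scheme: trim 3 residues
from the CDR3 start and 2 from the end (the conserved flanks), then score
each aligned position `0` if identical and otherwise
`min(cap, cap − BLOSUM62(a,b))` floored at 0, with `cap = 4`; gaps cost 4
each and the CDR3 sum is weighted ×3. For unequal lengths the shorter
sequence receives one contiguous gap block at the position minimizing the
total penalty (leftmost on ties) — deterministic and cheap. All parameters
are exposed in `distance_params()`.

Because every record analysed here carries the same TRDV2 chain, the
CDR1/CDR2/CDR2.5 terms of the full multi-CDR recipe are identical for all
pairs and cancel from every comparison; the implementation therefore
computes the CDR3 term only, and `build_distance_matrix()` refuses
non-uniform V calls when they are supplied.

`embed_2d()` is a deliberately thin contract over a precomputed distance
matrix. The default backend is classical metric MDS (`stats::cmdscale`),
which is deterministic; any function
`f(matrix, seed, n_neighbors, min_dist)` — e.g. a UMAP wrapper — can be
substituted. The embedding is visualization plumbing: the only property
the tests pin down is that well-separated clusters stay separated
(silhouette > 0.5 on a two-cluster construction).

## Expansion status

Within each individual, distinct CDR3aa (frequencies summed over their
nucleotide variants) are ranked by frequency; the top
`ceiling(0.25 · n)` are labelled high-frequency, ties broken
lexicographically so the labelling is deterministic and invariant to
uniform rescaling. A group of sequences in one individual scores
$\ln\big((n_{high} + 1)/(n_{low} + 1)\big)$; the +1 terms keep empty
groups finite and make the score antisymmetric under swapping the counts.
Whether the original procedure used a rank count or a frequency quantile,
and its tie policy, is not specified anywhere; the rank-count-with-ceiling
reading was chosen for reproducibility.

Group comparisons use the Games–Howell post-hoc test: for groups $i, j$,
$SE = \sqrt{s_i^2/n_i + s_j^2/n_j}$, Welch–Satterthwaite degrees of
freedom, $q = |\bar x_i - \bar x_j| / SE \cdot \sqrt 2$, and a p-value
from the studentized-range distribution with $k$ groups
(`stats::ptukey`). The procedure is familywise by construction, so no
further multiplicity correction is applied. At $k = 2$ it reduces exactly
to the two-sided Welch t-test, which the test suite asserts to $10^{-6}$.

Sequence-logo inputs (`position_frequency_matrix()`) use length-stratified
raw stacking: within a fixed (J segment, CDR3 length) stratum — the unit
in which logos are displayed — alignment is the identity, so no multiple
sequence alignment is needed and no external MSA dependency is taken. The
matrix is length × 20 with positions as rows, each row a probability
distribution.

## The cohort simulator

`simulate_cohort()` generates per-individual repertoires with the
statistical structure the analyses assume, and emits truth records
(segments, junctions, inserted bases) alongside:

| parameter | default | meaning |
|---|---|---|
| `n_individuals` | CB 11, infant 55, adult 23 | cohort design |
| `n_rearrangements_per_individual` | 2400 | productive chains kept per individual |
| `j_usage` | CB: J1 .100/J2 .159/J3 .720/J4 .021; infant: .45/.09/.44/.02; adult: .80/.021/.159/.02 | age-dependent TRDJ choice; CB is TRDJ3/TRDJ2-dominant (TRDJ2 15.9 %) switching to TRDJ1 dominance in adults |
| `d_usage` | D1 .05, D2 .15, D3 .70, none .10 | TRDD choice, TRDD3-dominant |
| `trim_mean_v/d5/d3/j` | 1/1/1/2 nt | geometric exonuclease trimming means |
| `n_insertion_mean` | CB 0.5, infant 1.5, adult 3.0 | Poisson mean insertions per junction — the TdT-activity knob |
| `clone_size_alpha` | 2.0 | power-law clone-size exponent |

A rearrangement draws J and D, trims geometric numbers of bases from the
segment ends (never into the conserved Cys/Phe codons), inserts Poisson
numbers of uniform-random nucleotides at each junction, and is kept only
if productive: in frame, stop-free, starting C and ending F. Productivity
is enforced by **rejection sampling** rather than frame-forcing, so
junction statistics stay unbiased *conditional on productivity*; the
conditioning itself imparts a small (≈ 2 %) downward shift on the
realized insertion mean visible only at very large sample sizes, which is
why parameter-recovery tests work at the 3-standard-error level. A drawn
D whose templated bases are entirely trimmed away leaves a single-junction
D-less chain, exactly as such a chain would be annotated. Clone sizes are
floor-Pareto with exponent `clone_size_alpha`; identical transcripts
within an individual are merged, while identical amino-acid sequences
arising in different individuals are kept — that is the convergent
recombination the publicity analysis measures.

Where the study design left values unstated (trimming and insertion
distributions, D usage), defaults were chosen once as biologically
plausible for TRD and are not tuned: geometric/Poisson junction models
are the simplest standard choice, and the TdT ordering CB < infant <
adult is the one property the downstream analyses rely on.
P-nucleotides are not modelled separately — the junction-position formula
absorbs them into the N count — and thymic selection, γ-chain pairing and
sequencing error are out of scope. Simulated repertoires are therefore a
well-controlled idealization: passing tests demonstrate correctness of
the computations, not that real repertoires obey geometric trimming or
Poisson insertion statistics.

## Pre-processing

`filter_clonotypes()` keeps CDR3aa of 14–22 residues and drops TRDJ4
rearrangements (defaults in `filter_params()`); `downsample_by_group()`
reduces every age group to a common number of **unique CDR3aa** (the
smallest group's count by default), sampling uniformly without replacement
under a fixed seed and retaining all clonotype records of the selected
sequences, so per-individual structure survives. Unique sequences — not
reads — are the sampling unit because the downstream publicity and
distance analyses operate on distinct sequences. Equal per-group targets
are used; both operations are idempotent and seed-deterministic.

## Problem sizes and numerical choices

The test suite runs cohorts of 9–13 individuals at 120–1,500
rearrangements each, 10,000-rearrangement draws for simulator-fidelity
checks, and 50-sequence distance matrices against a naive oracle; the
analysis drivers use 89 individuals × 600 rearrangements (≈ 50,000
records, the scale of the post-filter dataset) and 450-sequence distance
matrices. Frequencies are validated to sum to 1 within 1e-9;
probability vectors to 1e-12; frequency renormalization triggers above
1e-6 deviation from `count/total`. All ties anywhere (J choice, D
placement, frequency ranking, down-sampling) are broken deterministically,
and every stochastic entry point takes an explicit seed.

## Known limitations

- Exact anchored matching will not reproduce annotations that
  mismatch-tolerant aligners produced for individual transcripts; it is,
  however, deterministic and auditable.
- The publicity thresholds act on unique-sequence presence; UMI-level
  abundance corrections are out of scope.
- The CDR3-only distance is valid only within a fixed V gene (enforced);
  comparing across V genes requires the full multi-CDR recipe.
- The default embedding is metric MDS, which preserves global geometry
  rather than the local-neighborhood emphasis of UMAP; conclusions should
  rest on the distance matrix, not on the 2-D picture.
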