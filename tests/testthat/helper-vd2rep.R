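# Shared fixtures and independent micro-oracles for the test suite.

test_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- load_germline_reference()
    ref
  }
})

sa62_path <- function() {
  system.file("extdata", "sa62_cacdtlgdtdklif.tsv", package = "vd2rep",
              mustWork = TRUE)
}

read_sa62 <- function() {
  read_clonotype_table(sa62_path(), individual_id = "SA62", age_group = "adult")
}

# A small, fast simulation configuration for property tests.
small_cfg <- function(seed, ...) {
  simulation_config(
    n_individuals = c(CB = 3L, infant = 3L, adult = 3L),
    n_rearrangements_per_individual = 120L,
    seed = seed, ...)
}

# --- independent micro-oracles ------------------------------------------

# Plain longest common prefix / suffix lengths, coded without the package.
oracle_lcp <- function(x, y) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  n <- min(length(a), length(b))
  i <- 0L
  while (i < n && a[i + 1L] == b[i + 1L]) i <- i + 1L
  i
}
oracle_lcs_suffix <- function(x, y) {
  a <- rev(strsplit(x, "")[[1]]); b <- rev(strsplit(y, "")[[1]])
  n <- min(length(a), length(b))
  i <- 0L
  while (i < n && a[i + 1L] == b[i + 1L]) i <- i + 1L
  i
}

# Brute-force V(D)J decomposition: over all anchored V prefix lengths, all
# anchored J suffix lengths and all D blocks lying wholly between them,
# pick the decomposition under the aligner's stated objective (maximal V,
# then maximal J, then the longest admissible D block). Enumerates
# independently of the package's incremental scanning.
oracle_align <- function(cdr3nt, ref, min_d_match = 5L) {
  n <- nchar(cdr3nt)
  v <- ref$seq[ref$kind == "V"][1]
  j_seqs <- ref$seq[ref$kind == "J"]
  d_seqs <- ref$seq[ref$kind == "D"]
  vmax <- oracle_lcp(cdr3nt, v)
  stopifnot(vmax >= 3L)
  # every contiguous block of cdr3nt occurring in some D segment
  blocks <- NULL
  for (p in seq_len(n)) {
    for (len in seq_len(min(max(nchar(d_seqs)), n - p + 1L))) {
      s <- substr(cdr3nt, p, p + len - 1L)
      if (any(vapply(d_seqs, function(d) grepl(s, d, fixed = TRUE), NA))) {
        blocks <- rbind(blocks, c(start = p, end = p + len - 1L, len = len))
      } else break  # extending a non-matching block cannot match
    }
  }
  jsuf_max <- max(vapply(j_seqs, function(js) oracle_lcs_suffix(cdr3nt, js), 0L))
  best <- NULL
  for (vlen in vmax:3) {
    jm <- min(jsuf_max, n - vlen)
    if (jm < 1L) next
    for (jlen in jm:1) {
      lo <- vlen + 1L
      hi <- n - jlen
      dbest <- 0L
      if (!is.null(blocks) && hi >= lo) {
        ok <- blocks[, "start"] >= lo & blocks[, "end"] <= hi
        if (any(ok)) dbest <- max(blocks[ok, "len"])
      }
      if (dbest < min_d_match) dbest <- 0L
      if (is.null(best) ||
          vlen > best$vlen ||
          (vlen == best$vlen && jlen > best$jlen) ||
          (vlen == best$vlen && jlen == best$jlen && dbest > best$dlen)) {
        best <- list(total = vlen + jlen + dbest, vlen = vlen, jlen = jlen,
                     dlen = dbest)
      }
    }
  }
  best
}

# Independently coded TCRdist-style penalty for a single residue pair.
oracle_pair_penalty <- function(a, b, blosum, cap = 4) {
  if (a == b) return(0)
  max(0, min(cap, cap - blosum[a, b]))
}

# Cohort where sequence SEQ_k appears in exactly k of n individuals.
sharing_cohort <- function(counts, n_individuals, extra_nt_variants = 0L) {
  rows <- list()
  base_nt <- "TGTGCCTGTGACACCCTGGGGGATACCGATAAACTCATCTTT"
  for (k in seq_along(counts)) {
    aa <- sprintf("SEQ%03d", k)   # synthetic label; only identity matters
    for (i in seq_len(counts[k])) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        individual_id = sprintf("I%03d", i), age_group = "adult",
        count = 1L, freq = 1, cdr3nt = paste0(base_nt, k, "_", 1),
        cdr3aa = aa, v = "TRDV2", d = ".", j = "TRDJ1",
        vend = 14L, dstart = -1L, dend = -1L, jstart = 24L)
    }
  }
  co <- dplyr::bind_rows(rows)
  # make sure every individual exists even if it carries nothing else
  pad <- tibble::tibble(
    individual_id = sprintf("I%03d", seq_len(n_individuals)),
    age_group = "adult", count = 1L, freq = 1,
    cdr3nt = sprintf("PAD%03d", seq_len(n_individuals)),
    cdr3aa = sprintf("PADAA%03d", seq_len(n_individuals)),
    v = "TRDV2", d = ".", j = "TRDJ1",
    vend = 14L, dstart = -1L, dend = -1L, jstart = 24L)
  dplyr::bind_rows(co, pad)
}
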