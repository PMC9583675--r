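#' Translate CDR3 nucleotide sequences
#'
#' Standard genetic code translation of in-frame CDR3 nucleotide sequences.
#' A sequence containing an in-frame stop codon is unproductive and yields
#' `NA` instead of an amino-acid string.
#'
#' @param cdr3nt Character vector of DNA sequences; each length must be a
#'   multiple of 3 and contain only A/C/G/T.
#' @return Character vector of amino-acid sequences, `NA` where unproductive.
#' @examples
#' translate_cdr3("TGTGCCTGTGACACCCTGGGGGATACCGATAAACTCATCTTT")
#' @export
translate_cdr3 <- function(cdr3nt) {
  if (!length(cdr3nt)) return(character())
  if (any(is.na(cdr3nt))) stop("cdr3nt must not contain NA")
  cdr3nt <- toupper(cdr3nt)
  if (any(!grepl("^[ACGT]*$", cdr3nt))) stop("cdr3nt contains non-ACGT characters")
  if (any(nchar(cdr3nt) %% 3L != 0L)) stop("cdr3nt length must be divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cdr3nt),
                                           no.init.codon = TRUE))
  aa[grepl("*", aa, fixed = TRUE)] <- NA_character_
  unname(aa)
}

#' Germline alignment parameters
#'
#' @param min_d_match Minimum contiguous nucleotide match required to call a
#'   D segment (default 5; shorter middle matches are treated as chance and
#'   the rearrangement is annotated D-less).
#' @param allow_inverted_d Also search D segments in inverted (reverse
#'   complement) orientation.
#' @param allow_v_mismatches,allow_j_mismatches Mismatch budget inside the
#'   anchored V-prefix / J-suffix match (default 0, exact matching).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(min_d_match = 5L, allow_inverted_d = FALSE,
                             allow_v_mismatches = 0L, allow_j_mismatches = 0L) {
  stopifnot(min_d_match >= 1L, allow_v_mismatches >= 0L, allow_j_mismatches >= 0L)
  structure(list(min_d_match = as.integer(min_d_match),
                 allow_inverted_d = isTRUE(allow_inverted_d),
                 allow_v_mismatches = as.integer(allow_v_mismatches),
                 allow_j_mismatches = as.integer(allow_j_mismatches)),
            class = "alignment_params")
}

# Longest prefix of x matching the prefix of ref with at most max_mm
# mismatches (both anchored at position 1).
anchored_prefix_len <- function(x, ref, max_mm = 0L) {
  a <- charToRaw(x); b <- charToRaw(ref)
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  mm <- cumsum(a[seq_len(n)] != b[seq_len(n)])
  len <- which(mm <= max_mm)
  if (!length(len)) 0L else max(len)
}

reverse_chars <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), "", USE.NAMES = FALSE)
}

revcomp <- function(x) chartr("ACGT", "TGCA", reverse_chars(x))

# Longest common substring between a (search space) and b (segment);
# returns 0-based leftmost start in a, or len 0 if none.
longest_common_substring <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  top <- min(na, nb)
  if (top > 0L) {
    for (len in seq(top, 1L)) {
      best <- Inf
      for (i in seq_len(nb - len + 1L)) {
        pos <- regexpr(substr(b, i, i + len - 1L), a, fixed = TRUE)
        if (pos > 0L && pos < best) best <- pos
      }
      if (is.finite(best)) return(list(len = len, start_a = as.integer(best) - 1L))
    }
  }
  list(len = 0L, start_a = NA_integer_)
}

#' N-insertion count from junction positions
#'
#' Counts non-templated junction nucleotides from 0-based inclusive segment
#' positions on the CDR3 nucleotide sequence. For rearrangements with a D
#' segment the count is `(jstart - dend - 1) + (dstart - vend - 1)`, each
#' junction clipped at 0; without D usage it is `jstart - vend - 1`, clipped
#' at 0.
#'
#' @param vend Last V-templated base (0-based).
#' @param dstart,dend First/last D-templated base, or `-1` when no D segment
#'   is used.
#' @param jstart First J-templated base (0-based).
#' @return Integer vector of N-insertion counts.
#' @examples
#' compute_n_insertions(14, -1, -1, 24)  # D-less: 24 - 14 - 1 = 9
#' compute_n_insertions(14, 17, 21, 24)  # (17-14-1) + (24-21-1) = 4
#' @export
compute_n_insertions <- function(vend, dstart, dend, jstart) {
  vend <- as.integer(vend); dstart <- as.integer(dstart)
  dend <- as.integer(dend); jstart <- as.integer(jstart)
  if (any(jstart <= vend)) stop("jstart must exceed vend")
  d_absent <- dstart < 0L
  if (any(!d_absent & (dend < dstart | dstart <= vend | jstart <= dend))) {
    stop("D positions must satisfy vend < dstart <= dend < jstart")
  }
  out <- integer(length(vend))
  out[d_absent] <- pmax(0L, jstart[d_absent] - vend[d_absent] - 1L)
  out[!d_absent] <- pmax(0L, dstart[!d_absent] - vend[!d_absent] - 1L) +
    pmax(0L, jstart[!d_absent] - dend[!d_absent] - 1L)
  out
}

#' Re-align a CDR3 nucleotide sequence to the germline reference
#'
#' Deterministic maximal anchored matching: the V match is the longest
#' anchored prefix of `cdr3nt` against the V germline (which starts at the
#' conserved Cys codon), the J match is the longest anchored suffix against
#' each candidate J germline (which ends at the conserved Phe codon), taking
#' the J with the longest match (ties broken by segment name order). A D
#' segment is then assigned as the germline D with the longest contiguous
#' match wholly inside the untemplated middle region, provided it reaches
#' `min_d_match` nucleotides; D yields to both V and J, so overlapping bases
#' are never double-counted. N-insertions follow [compute_n_insertions()].
#'
#' @param cdr3nt A single DNA sequence (conserved Cys codon through conserved
#'   Phe codon, >= 9 nt).
#' @param ref Germline reference tibble from [load_germline_reference()].
#' @param params [alignment_params()].
#' @return A one-row tibble: `v`, `d`, `j` calls, `vend`, `dstart`, `dend`,
#'   `jstart` (0-based inclusive), `v_match_len`, `d_match_len`,
#'   `j_match_len`, `d_inverted`, `n_insertions`.
#' @export
align_to_germline <- function(cdr3nt, ref, params = alignment_params()) {
  stopifnot(length(cdr3nt) == 1L, inherits(params, "alignment_params"))
  al <- align_core(toupper(cdr3nt), compile_reference(ref, params), params)
  tibble::as_tibble(al)
}

# Precompute the per-call constants of the aligner.
compile_reference <- function(ref, params) {
  vs <- ref[ref$kind == "V", , drop = FALSE]
  js <- ref[ref$kind == "J", , drop = FALSE]
  ds <- ref[ref$kind == "D", , drop = FALSE]
  if (!nrow(vs) || !nrow(js) || !nrow(ds)) {
    stop("reference must contain at least one V, one D and one J segment")
  }
  vs <- vs[order(vs$name), ]; js <- js[order(js$name), ]; ds <- ds[order(ds$name), ]
  d_cand <- data.frame(name = ds$name, seq = ds$seq, inverted = FALSE,
                       stringsAsFactors = FALSE)
  if (params$allow_inverted_d) {
    d_cand <- rbind(d_cand, data.frame(name = ds$name, seq = revcomp(ds$seq),
                                       inverted = TRUE, stringsAsFactors = FALSE))
  }
  list(v_names = vs$name, v_seqs = vs$seq,
       j_names = js$name, j_rev = reverse_chars(js$seq),
       d_cand = d_cand)
}

align_core <- function(cdr3nt, cref, params) {
  if (!grepl("^[ACGT]+$", cdr3nt)) stop("cdr3nt contains non-ACGT characters")
  n <- nchar(cdr3nt)
  if (n < 9L) stop("cdr3nt shorter than 9 nt")

  v_lens <- vapply(cref$v_seqs, anchored_prefix_len, 0L, x = cdr3nt,
                   max_mm = params$allow_v_mismatches, USE.NAMES = FALSE)
  vi <- which.max(v_lens)
  v_match_len <- v_lens[vi]
  if (v_match_len < 3L) stop("no V anchor match (conserved TGT prefix not found)")
  vend <- v_match_len - 1L

  rev_nt <- reverse_chars(cdr3nt)
  j_lens <- vapply(cref$j_rev, anchored_prefix_len, 0L, x = rev_nt,
                   max_mm = params$allow_j_mismatches, USE.NAMES = FALSE)
  ji <- which.max(j_lens)  # ties resolve to the first segment in name order
  j_match_len <- j_lens[ji]
  if (j_match_len < 1L) stop("no J suffix match against the reference")
  jstart <- n - j_match_len
  if (jstart <= vend) {  # J yields to V on overlap
    jstart <- vend + 1L
    j_match_len <- n - jstart
  }

  mid_len <- jstart - vend - 1L
  d_name <- "."; dstart <- -1L; dend <- -1L; d_match_len <- 0L; d_inverted <- FALSE
  if (mid_len >= params$min_d_match) {
    middle <- substr(cdr3nt, vend + 2L, jstart)  # 1-based window (vend, jstart)
    hits <- lapply(cref$d_cand$seq, longest_common_substring, a = middle)
    lens <- vapply(hits, `[[`, 0L, "len")
    if (max(lens) >= params$min_d_match) {
      # forward orientation and lower segment name win ties (d_cand is ordered)
      di <- which.max(lens)
      d_name <- cref$d_cand$name[di]
      d_inverted <- cref$d_cand$inverted[di]
      d_match_len <- lens[di]
      dstart <- vend + 1L + hits[[di]]$start_a
      dend <- dstart + d_match_len - 1L
    }
  }

  list(v = cref$v_names[vi], d = d_name, j = cref$j_names[ji],
       vend = vend, dstart = dstart, dend = dend, jstart = jstart,
       v_match_len = v_match_len, d_match_len = d_match_len,
       j_match_len = j_match_len, d_inverted = d_inverted,
       n_insertions = compute_n_insertions(vend, dstart, dend, jstart))
}

#' Annotate every clonotype in a repertoire or cohort
#'
#' Runs [translate_cdr3()] and [align_to_germline()] over each clonotype.
#' Unproductive records (stop codon, frame error) and alignment failures are
#' flagged, never aborted on: `productive` is `FALSE` and the inferred
#' columns are `NA`/sentinel for such rows, and downstream analyses drop
#' them. Inferred segment calls and junction positions replace the incoming
#' `v`/`d`/`j`/`vend`/`dstart`/`dend`/`jstart` columns; `n_insertions` and
#' `productive` columns are appended.
#'
#' @param rep Clonotype tibble (one individual or a bound cohort).
#' @param ref Germline reference from [load_germline_reference()].
#' @param params [alignment_params()].
#' @return The input tibble with inferred annotation columns.
#' @export
annotate_repertoire <- function(rep, ref, params = alignment_params()) {
  n <- nrow(rep)
  aa <- rep(NA_character_, n)
  ok_frame <- nchar(rep$cdr3nt) %% 3L == 0L & grepl("^[ACGT]+$", rep$cdr3nt)
  if (any(ok_frame)) aa[ok_frame] <- translate_cdr3(rep$cdr3nt[ok_frame])
  productive <- !is.na(aa)

  res <- list(v = rep(NA_character_, n), d = rep(NA_character_, n),
              j = rep(NA_character_, n),
              vend = rep(NA_integer_, n), dstart = rep(NA_integer_, n),
              dend = rep(NA_integer_, n), jstart = rep(NA_integer_, n),
              n_insertions = rep(NA_integer_, n))
  cref <- compile_reference(ref, params)
  todo <- which(productive)
  # identical transcripts (convergent recombination) are aligned once
  uniq <- unique(rep$cdr3nt[todo])
  als <- lapply(uniq, function(s) {
    tryCatch(align_core(s, cref, params), error = function(e) NULL)
  })
  names(als) <- uniq
  for (i in todo) {
    al <- als[[rep$cdr3nt[i]]]
    if (is.null(al)) {
      productive[i] <- FALSE
      next
    }
    res$v[i] <- al$v; res$d[i] <- al$d; res$j[i] <- al$j
    res$vend[i] <- al$vend; res$dstart[i] <- al$dstart
    res$dend[i] <- al$dend; res$jstart[i] <- al$jstart
    res$n_insertions[i] <- al$n_insertions
  }
  out <- rep
  out$cdr3aa <- ifelse(productive, aa, out$cdr3aa)
  out$v <- res$v; out$d <- res$d; out$j <- res$j
  out$vend <- res$vend; out$dstart <- res$dstart
  out$dend <- res$dend; out$jstart <- res$jstart
  out$n_insertions <- res$n_insertions
  out$productive <- productive
  out
}
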