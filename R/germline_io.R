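#' Path to the packaged TRD germline reference
#'
#' CDR3-proximal excerpts of the human TRD locus segments used by Vdelta2+
#' chains: TRDV2 (conserved Cys codon to the segment 3' end), TRDD1-TRDD3
#' (full segments) and TRDJ1-TRDJ4 (segment 5' end through the conserved Phe
#' codon). TRDV2, TRDD1-3 and TRDJ1 follow the IMGT reference; the TRDJ2-4
#' excerpts are reconstructed from their canonical CDR3 tail motifs and are
#' used only where the exact sequence content does not matter (simulation,
#' which is self-consistent by construction).
#'
#' @return Path to the FASTA file shipped with the package.
#' @export
trd_germline_path <- function() {
  system.file("extdata", "trd_germline.fasta", package = "vd2rep", mustWork = TRUE)
}

#' Load a germline TRD segment reference from FASTA
#'
#' Headers must name the segment and its kind as `NAME|KIND` (e.g.
#' `TRDV2|V`); anything after whitespace is treated as free description.
#' V segments must begin with the conserved Cys codon `TGT` and J segments
#' must end with a Phe codon (`TTT`/`TTC`), since sequences are CDR3-proximal
#' regions delimited by those conserved anchors.
#'
#' @param path FASTA file; defaults to the packaged TRD reference.
#' @param required Segment names that must be present. Set to `NULL` to skip
#'   the completeness check.
#' @return A tibble with columns `name`, `kind` (one of V/D/J) and `seq`.
#' @export
load_germline_reference <- function(path = trd_germline_path(),
                                    required = c("TRDV2", "TRDD1", "TRDD2", "TRDD3",
                                                 "TRDJ1", "TRDJ2", "TRDJ3", "TRDJ4")) {
  fa <- Biostrings::readDNAStringSet(path)
  headers <- sub("\\s.*$", "", names(fa))
  parts <- strsplit(headers, "|", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("germline FASTA headers must be of the form NAME|KIND (e.g. TRDV2|V)")
  }
  ref <- tibble::tibble(
    name = vapply(parts, `[[`, "", 1L),
    kind = vapply(parts, `[[`, "", 2L),
    seq  = unname(toupper(as.character(fa)))
  )
  if (!all(ref$kind %in% c("V", "D", "J"))) {
    stop("segment kind must be one of V, D, J")
  }
  bad <- !grepl("^[ACGT]+$", ref$seq)
  if (any(bad)) {
    stop("non-ACGT characters in germline sequence(s): ",
         paste(ref$name[bad], collapse = ", "))
  }
  if (!is.null(required)) {
    missing <- setdiff(required, ref$name)
    if (length(missing)) {
      stop("germline reference is missing required segment(s): ",
           paste(missing, collapse = ", "))
    }
  }
  v_bad <- ref$kind == "V" & substr(ref$seq, 1L, 3L) != "TGT"
  if (any(v_bad)) {
    stop("V segment(s) must begin with the conserved Cys codon TGT: ",
         paste(ref$name[v_bad], collapse = ", "))
  }
  j_tail <- substr(ref$seq, nchar(ref$seq) - 2L, nchar(ref$seq))
  j_bad <- ref$kind == "J" & !j_tail %in% c("TTT", "TTC")
  if (any(j_bad)) {
    stop("J segment(s) must end with a Phe codon (TTT/TTC): ",
         paste(ref$name[j_bad], collapse = ", "))
  }
  ref
}

# Canonical clonotype-table column order (VDJtools-style dialect).
clonotype_columns <- function() {
  c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
    "vend", "dstart", "dend", "jstart")
}

#' Read a clonotype table
#'
#' Reads the tab-separated clonotype dialect used throughout the package:
#' columns `count`, `freq`, `cdr3nt`, `cdr3aa`, `v`, `d`, `j`, `VEnd`,
#' `DStart`, `DEnd`, `JStart` (case-insensitive). Junction positions are
#' 0-based inclusive indices into `cdr3nt` (`VEnd` = last V-templated base,
#' `JStart` = first J-templated base); that convention makes the N-insertion
#' formula `(JStart - DEnd - 1) + (DStart - VEnd - 1)` evaluate directly.
#' Files whose positions are 1-based can be converted at read time with
#' `positions_base = 1`. An absent D segment is encoded `"."` in the `d`
#' column and `-1` in `DStart`/`DEnd`.
#'
#' Each row is validated: `cdr3nt` must translate to `cdr3aa`, and the `freq`
#' column is renormalized (with a warning) if it deviates from
#' `count / sum(count)` by more than 1e-6.
#'
#' @param path TSV file.
#' @param individual_id,age_group Labels attached to every row (the table
#'   holds one individual's repertoire).
#' @param positions_base 0 (native) or 1 (convert 1-based positions).
#' @return A tibble with one row per clonotype, columns
#'   `individual_id`, `age_group`, then [clonotype_columns()].
#' @export
read_clonotype_table <- function(path, individual_id = "S1", age_group = "adult",
                                 positions_base = 0) {
  stopifnot(positions_base %in% c(0, 1))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  need <- clonotype_columns()
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("clonotype table is missing column(s): ", paste(missing, collapse = ", "))
  }
  rep <- tibble::as_tibble(raw[need])
  rep$count <- as.integer(rep$count)
  for (col in c("vend", "dstart", "dend", "jstart")) {
    val <- rep[[col]]
    if (any(is.na(suppressWarnings(as.numeric(val))) & !is.na(val))) {
      stop("malformed junction position in column ", col)
    }
    val <- as.integer(val)
    if (positions_base == 1) {
      val <- ifelse(val < 0, -1L, val - 1L)
    }
    rep[[col]] <- val
  }
  rep <- tibble::add_column(rep,
    individual_id = individual_id, age_group = age_group, .before = 1L)
  if (nrow(rep)) {
    validate_clonotypes(rep)
    expect_freq <- rep$count / sum(rep$count)
    if (any(abs(rep$freq - expect_freq) > 1e-6)) {
      warning("freq column deviates from count/total; renormalizing")
      rep$freq <- expect_freq
    }
  }
  rep
}

#' Write a clonotype table
#'
#' Inverse of [read_clonotype_table()]: writes the VDJtools-style TSV dialect
#' with 0-based inclusive positions and the `"."`/`-1` absent-D sentinels.
#'
#' @param rep Clonotype tibble (one individual).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  out <- rep[clonotype_columns()]
  names(out) <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                  "VEnd", "DStart", "DEnd", "JStart")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Row-level invariants shared by the reader and the simulator.
validate_clonotypes <- function(rep) {
  if (any(nchar(rep$cdr3nt) != 3L * nchar(rep$cdr3aa))) {
    stop("cdr3nt length must be 3x cdr3aa length")
  }
  aa <- translate_cdr3(rep$cdr3nt)
  bad <- is.na(aa) | aa != rep$cdr3aa
  if (any(bad)) {
    stop("cdr3nt does not encode cdr3aa in row(s): ",
         paste(which(bad), collapse = ", "))
  }
  d_absent <- rep$d == "."
  if (any(d_absent & (rep$dstart != -1L | rep$dend != -1L))) {
    stop("absent D ('.') requires DStart = DEnd = -1")
  }
  known <- rep$vend >= 0L & rep$jstart >= 0L
  ord <- !known | (rep$vend < rep$jstart & rep$jstart <= nchar(rep$cdr3nt) - 1L)
  if (!all(ord)) stop("junction positions out of order (need VEnd < JStart <= length-1)")
  with_d <- !d_absent & known
  ok_d <- !with_d | (rep$vend < rep$dstart & rep$dstart <= rep$dend &
                       rep$dend < rep$jstart)
  if (!all(ok_d)) stop("D positions must satisfy VEnd < DStart <= DEnd < JStart")
  invisible(rep)
}

#' Bind per-individual repertoires into a cohort
#'
#' @param reps A list of clonotype tibbles as returned by
#'   [read_clonotype_table()] or built by the simulator.
#' @return One tibble with all rows; `individual_id` must be unique per
#'   repertoire.
#' @export
cohort_bind <- function(reps) {
  ids <- vapply(reps, function(r) r$individual_id[1], "")
  if (anyDuplicated(ids)) stop("individual_id values must be unique across repertoires")
  dplyr::bind_rows(reps)
}
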