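# BLOSUM62 similarity restricted to the 20 standard residues.
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62[aa_alphabet(), aa_alphabet()]
}

#' CDR3 distance parameters
#'
#' Penalty scheme of the TCRdist family: after trimming the conserved
#' flanks, each aligned mismatch costs `min(mismatch_cap, mismatch_cap -
#' S(a,b))` (floored at 0) where `S` is the BLOSUM62 similarity, gaps cost
#' `gap_penalty` each, and the CDR3 total is weighted by `cdr3_weight`.
#' Because every record here carries the same TRDV2 chain, the CDR1/CDR2
#' contributions are constant across all pairs and cancel; only the CDR3
#' term is computed (see [build_distance_matrix()]).
#'
#' @param mismatch_cap Maximum per-position mismatch penalty (default 4).
#' @param gap_penalty Penalty per gap position (default 4).
#' @param cdr3_weight Weight multiplying the CDR3 penalty sum (default 3).
#' @param n_trim_start,n_trim_end Residues trimmed from the CDR3 start/end
#'   before comparison (defaults 3 and 2: the conserved C-flank and F-flank).
#' @param substitution 20x20 similarity matrix (default BLOSUM62).
#' @return A list of class `distance_params` carrying a precomputed
#'   per-position penalty table.
#' @export
distance_params <- function(mismatch_cap = 4L, gap_penalty = 4L,
                            cdr3_weight = 3L, n_trim_start = 3L,
                            n_trim_end = 2L, substitution = blosum62_matrix()) {
  stopifnot(mismatch_cap >= 0, gap_penalty >= 0, cdr3_weight >= 1,
            n_trim_start >= 0, n_trim_end >= 0)
  ab <- aa_alphabet()
  stopifnot(all(ab %in% rownames(substitution)),
            all(ab %in% colnames(substitution)))
  pen <- mismatch_cap - substitution[ab, ab]
  pen[pen > mismatch_cap] <- mismatch_cap
  pen[pen < 0] <- 0
  diag(pen) <- 0
  structure(list(mismatch_cap = mismatch_cap, gap_penalty = gap_penalty,
                 cdr3_weight = cdr3_weight, n_trim_start = as.integer(n_trim_start),
                 n_trim_end = as.integer(n_trim_end), penalty = pen),
            class = "distance_params")
}

# Encode a CDR3aa string as integer indices into the alphabet, trimmed.
encode_cdr3 <- function(x, params) {
  n <- nchar(x)
  min_len <- params$n_trim_start + params$n_trim_end + 1L
  if (n < min_len) stop("CDR3 too short after trimming: ", x)
  core <- substr(x, params$n_trim_start + 1L, n - params$n_trim_end)
  idx <- match(strsplit(core, "")[[1]], aa_alphabet())
  if (anyNA(idx)) stop("unknown residue in CDR3: ", x)
  idx
}

# Penalty between two encoded cores; shorter sequence padded with one
# contiguous gap block at the position minimizing the penalty (leftmost tie).
core_penalty <- function(a, b, params) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  la <- length(a); lb <- length(b)
  gap <- lb - la
  if (gap == 0L) {
    return(sum(params$penalty[cbind(a, b)]))
  }
  best <- Inf
  for (g in 0:la) {  # gap block after position g of the shorter sequence
    bb <- b[c(seq_len(g), if (g < la) (g + gap + 1L):lb)]
    cost <- sum(params$penalty[cbind(a, bb)]) + params$gap_penalty * gap
    if (cost < best) best <- cost
  }
  best
}

#' Distance between two CDR3 amino-acid sequences
#'
#' @param a,b CDR3aa strings over the 20-residue alphabet, each long enough
#'   to survive the flank trims.
#' @param params [distance_params()].
#' @return Non-negative numeric distance (0 for identical sequences).
#' @examples
#' p <- distance_params()
#' cdr3_pair_distance("CACDTLGDTDKLIF", "CACDTLGDTDKLIF", p)
#' @export
cdr3_pair_distance <- function(a, b, params = distance_params()) {
  stopifnot(inherits(params, "distance_params"))
  params$cdr3_weight * core_penalty(encode_cdr3(a, params),
                                    encode_cdr3(b, params), params)
}

#' Pairwise CDR3 distance matrix
#'
#' Computes all pairwise [cdr3_pair_distance()] values. When V calls are
#' supplied they must be uniform: with a single V gene the CDR1/CDR2/CDR2.5
#' penalty terms of the full TCRdist recipe are identical for every pair and
#' cancel out of all comparisons, which is what licenses the CDR3-only
#' computation.
#'
#' @param sequences Character vector of CDR3aa (length >= 2); names (or the
#'   sequences themselves) become matrix labels.
#' @param params [distance_params()].
#' @param v Optional vector of V calls; an error is raised if not uniform.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
build_distance_matrix <- function(sequences, params = distance_params(),
                                  v = NULL) {
  stopifnot(length(sequences) >= 2L)
  if (!is.null(v) && length(unique(v)) > 1L) {
    stop("CDR3-only distance requires a uniform V gene; got: ",
         paste(unique(v), collapse = ", "))
  }
  labels <- if (is.null(names(sequences))) sequences else names(sequences)
  cores <- lapply(sequences, encode_cdr3, params = params)
  n <- length(sequences)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      d <- params$cdr3_weight * core_penalty(cores[[i]], cores[[k]], params)
      m[i, k] <- d
      m[k, i] <- d
    }
  }
  m
}

#' Embed a distance matrix into two dimensions
#'
#' The embedding is a pluggable contract over a precomputed distance
#' matrix: the default backend is classical (metric) multidimensional
#' scaling via [stats::cmdscale()], which is fully deterministic; any other
#' backend (e.g. a UMAP implementation) can be supplied as a function
#' `f(matrix, seed, n_neighbors, min_dist)` returning an n x 2 coordinate
#' matrix. The embedding is visualization plumbing and carries no analysis
#' weight beyond preserving gross cluster separation.
#'
#' @param matrix Symmetric distance matrix (no `NA`/`NaN`).
#' @param seed Integer seed, set before the backend call.
#' @param n_neighbors,min_dist Knobs forwarded to non-default backends.
#' @param backend `"mds"` or a function as described above.
#' @return A tibble `label`, `x`, `y`.
#' @export
embed_2d <- function(matrix, seed = 1L, n_neighbors = 15L, min_dist = 0.1,
                     backend = "mds") {
  if (any(!is.finite(matrix))) stop("distance matrix contains NA/NaN values")
  set.seed(seed)
  coords <- if (is.function(backend)) {
    backend(matrix, seed = seed, n_neighbors = n_neighbors,
            min_dist = min_dist)
  } else if (identical(backend, "mds")) {
    co <- stats::cmdscale(stats::as.dist(matrix), k = min(2L, nrow(matrix) - 1L))
    # pad to 2 columns for tiny or degenerate inputs
    cbind(co, base::matrix(0, nrow(matrix),
                           max(0L, 2L - ncol(co))))[, 1:2, drop = FALSE]
  } else {
    stop("unknown embedding backend")
  }
  labels <- rownames(matrix)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(matrix)))
  tibble::tibble(label = labels, x = coords[, 1L], y = coords[, 2L])
}
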