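# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Hamming distance between equal-length sequences
#'
#' @param a,b Character vectors of equal-length sequences; `b` is recycled
#'   against `a` element-wise when lengths differ by recycling rules.
#' @return Integer vector of per-pair Hamming distances.
#' @keywords internal
hamming_pair <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
}

# Character matrix (one row per sequence) from equal-length sequences.
seq_char_matrix <- function(seqs, width = NULL) {
  if (length(seqs) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = width %||% 0L))
  }
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must have equal length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = w, byrow = TRUE)
}

# Hamming distances from every row of query matrix to every row of the
# universe matrix; returns length(query) x nrow(universe) integer matrix.
# Column-wise accumulation keeps this vectorised over reads.
hamming_to_universe <- function(qmat, umat) {
  stopifnot(ncol(qmat) == ncol(umat))
  d <- matrix(0L, nrow = nrow(qmat), ncol = nrow(umat))
  for (j in seq_len(ncol(qmat))) {
    d <- d + outer(qmat[, j], umat[, j], FUN = "!=")
  }
  d
}

# All-pairs Hamming distance matrix for a set of sequences (brute force;
# used for barcode design and small-universe verification).
hamming_all_pairs <- function(seqs) {
  m <- seq_char_matrix(seqs)
  hamming_to_universe(m, m)
}

# Random DNA sequences of fixed length under the current RNG state.
random_dna <- function(n, length) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    paste0(sample(bases, length, replace = TRUE), collapse = "")
  }, character(1))
}

# Dirichlet draw via independent gammas; alpha a positive vector.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))  # degenerate underflow guard
  g / sum(g)
}

# Scoped seeding: runs expr with a fixed RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}
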