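# 2-D discrete cosine transform descriptor.

# orthonormal DCT-II basis matrix: A[i+1, m+1] = alpha_i cos(pi (2m+1) i / 2M)
# with alpha_0 = sqrt(1/M), alpha_i = sqrt(2/M) otherwise; rows `idx` only
dct_basis <- function(M, idx = seq_len(M)) {
  i <- idx - 1L
  m <- seq_len(M) - 1L
  A <- cos(outer(i, 2 * m + 1) * pi / (2 * M))
  A * ifelse(i == 0, sqrt(1 / M), sqrt(2 / M))
}

# full orthonormal 2-D DCT-II of a matrix (used at full size in tests;
# feature extraction only materializes the retained rows/columns)
dct2 <- function(x) {
  dct_basis(nrow(x)) %*% x %*% t(dct_basis(ncol(x)))
}

#' Low-frequency 2-D DCT coefficients of a PSSM
#'
#' Applies the orthonormal 2-D DCT-II to the L x 20 score matrix and keeps
#' the top-left `keep_rows` x `keep_cols` block — the low-frequency corner
#' where the transform concentrates the profile's energy. When L <
#' `keep_rows` the missing coefficient rows are zero-filled so the
#' descriptor length is fixed.
#'
#' @param x a [pssm] object.
#' @param keep_rows,keep_cols size of the retained coefficient block
#'   (defaults 20 x 20 = 400 features).
#' @return numeric vector of length `keep_rows * keep_cols`, row-major.
#' @export
dct_features <- function(x, keep_rows = 20L, keep_cols = 20L) {
  stopifnot(inherits(x, "pssm"))
  keep_rows <- as.integer(keep_rows); keep_cols <- as.integer(keep_cols)
  if (keep_rows < 1L || keep_cols < 1L)
    stop("keep_rows and keep_cols must be >= 1")
  m <- x$scores
  L <- nrow(m)
  kr <- min(keep_rows, L)
  kc <- min(keep_cols, 20L)
  block <- dct_basis(L, seq_len(kr)) %*% m %*% t(dct_basis(20L, seq_len(kc)))
  out <- matrix(0, keep_rows, keep_cols)
  out[seq_len(kr), seq_len(kc)] <- block
  as.vector(t(out))
}
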