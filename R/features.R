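# Row standardization, Pse-PSSM and average-block descriptors.

#' Row-standardize a PSSM
#'
#' Each position (row) is centered and scaled across its 20 amino-acid
#' scores: `f(i,j) = (p(i,j) - mean_i) / sd_i`, with the population standard
#' deviation (divisor 20). Rows whose 20 scores are all equal have sd 0 and
#' map to all zeros by convention.
#'
#' @param x a [pssm] object.
#' @return object of class `"normalized_pssm"`: list with `values` (L x 20
#'   matrix, each non-constant row having mean 0 and population sd 1) and
#'   `source_id`.
#' @export
normalize_pssm <- function(x) {
  stopifnot(inherits(x, "pssm"))
  m <- x$scores
  mu <- rowMeans(m)
  cen <- m - mu
  sd_pop <- sqrt(rowMeans(cen^2))
  f <- cen / ifelse(sd_pop == 0, 1, sd_pop)
  f[sd_pop == 0, ] <- 0
  structure(list(values = f, source_id = x$id), class = "normalized_pssm")
}

#' Pse-PSSM descriptor
#'
#' Chou's pseudo-PSSM on the row-standardized profile: the 20 column means,
#' followed for each lag `xi = 1..lambda` by the 20 per-column mean squared
#' lag differences `(1/(L-xi)) * sum_i (f(i,j) - f(i+xi,j))^2`, which retain
#' a trace of sequence order that plain composition discards.
#'
#' @param norm a `"normalized_pssm"` (see [normalize_pssm()]).
#' @param lambda maximum lag, >= 0 (default 1). Requires `L > lambda`.
#' @return numeric vector of length `20 * (1 + lambda)`.
#' @export
pse_pssm_features <- function(norm, lambda = 1L) {
  stopifnot(inherits(norm, "normalized_pssm"))
  lambda <- as.integer(lambda)
  if (lambda < 0L) stop("lambda must be >= 0")
  f <- norm$values
  L <- nrow(f)
  if (L <= lambda)
    stop("sequence length (", L, ") must exceed the Pse-PSSM lag (", lambda,
         ")")
  out <- colMeans(f)
  for (xi in seq_len(lambda)) {
    d <- f[seq_len(L - xi), , drop = FALSE] -
      f[seq_len(L - xi) + xi, , drop = FALSE]
    out <- c(out, colMeans(d^2))  # mean over the L - xi differences
  }
  unname(out)
}

#' Average-block descriptor
#'
#' Partitions the PSSM rows into 20 consecutive blocks (each covering ~5% of
#' the sequence; boundaries at `round(i * L / 20)`, so block sizes differ by
#' at most one) and averages every column within every block. Blocks that
#' are empty (possible when L < 20) contribute zeros.
#'
#' @param x a [pssm] object.
#' @return numeric vector of length 400, ordered block-major: feature
#'   `j + 20 * (i - 1)` is the mean of amino-acid column `j` over block `i`.
#' @export
avblock_features <- function(x) {
  stopifnot(inherits(x, "pssm"))
  m <- x$scores
  L <- nrow(m)
  bnd <- round(seq_len(20L) * L / 20)
  lo <- c(0L, bnd[-20L]) + 1L
  out <- matrix(0, 20L, 20L)  # blocks x columns
  for (i in seq_len(20L)) {
    if (lo[i] > bnd[i]) next
    out[i, ] <- colMeans(m[lo[i]:bnd[i], , drop = FALSE])
  }
  as.vector(t(out))
}
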