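# Discrete wavelet transform descriptor.
#
# Each of the 20 amino-acid columns of the PSSM is treated as a 1-D discrete
# signal and pushed through a multi-level analysis cascade: at every level
# the current approximation is convolved with the low-pass filter g and the
# high-pass filter h and downsampled by two (y_low[n] = sum_k x[k] g[2n-k],
# y_high[n] = sum_k x[k] h[2n-k]); the low-pass output feeds the next level.
# Signal boundaries are extended by half-point symmetric reflection, the
# same extension the brute-force definition uses, so the cascade is exactly
# reproducible by direct convolution.

# Orthonormal decomposition filters. dbN = Daubechies with N vanishing
# moments (2N taps); db1 == haar. Coefficients are the standard published
# values of the scaling filter; the high-pass filter is its quadrature
# mirror.
wavelet_filters <- function(name) {
  sq2 <- sqrt(2)
  rec_lo <- switch(tolower(name),
    haar = , db1 = c(1, 1) / sq2,
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sq2),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stop("unknown wavelet '", name, "' (available: haar/db1, db2, db4)")
  )
  K <- length(rec_lo)
  dec_lo <- rev(rec_lo)
  dec_hi <- rec_lo * (-1)^seq_len(K)
  list(lo = dec_lo, hi = dec_hi)
}

# half-point symmetric extension by `k` samples on each side
sym_extend <- function(x, k) {
  n <- length(x)
  left <- x[pmin(k:1, n)]
  right <- x[pmax(n - seq_len(k) + 1L, 1L)]
  c(left, x, right)
}

# one analysis step: symmetric-extend, convolve with filter f, keep every
# second sample of the full (valid-over-extension) convolution;
# y[s] = sum_k f[k] * ext[s + K - k], computed via a lagged-embedding matmul
dwt_step <- function(x, f) {
  K <- length(f)
  ext <- sym_extend(x, K - 1L)
  y <- as.vector(stats::embed(ext, K) %*% f)
  y[seq(2L, length(y), by = 2L)]
}

# reflect-pad x on the right up to length n
pad_sym_to <- function(x, n) {
  while (length(x) < n) x <- c(x, rev(x))
  x[seq_len(n)]
}

#' Wavelet-cascade summary statistics of a PSSM
#'
#' Runs a `levels`-stage wavelet analysis cascade (default 4 levels — the
#' quadruple-layer decomposition) down every amino-acid column and
#' summarizes the detail and approximation coefficients of every level by
#' their mean, standard deviation, maximum and minimum. Columns shorter than
#' `2^levels` are symmetrically padded up to that length first.
#'
#' @param x a [pssm] object.
#' @param wavelet wavelet name: `"haar"`/`"db1"`, `"db2"` or `"db4"`
#'   (default `"db4"`).
#' @param levels number of cascade levels (default 4).
#' @return numeric vector of length `20 * levels * 2 * 4` (default 640),
#'   ordered column-major: for each amino-acid column, for each level 1 to
#'   `levels`, first the detail then the approximation statistics, each as
#'   (mean, sd, max, min). The standard deviation is the population sd
#'   (divisor n), so a single coefficient has sd 0.
#' @export
dwt_features <- function(x, wavelet = "db4", levels = 4L) {
  stopifnot(inherits(x, "pssm"))
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  filt <- wavelet_filters(wavelet)
  m <- x$scores
  if (nrow(m) < 2L^levels)
    m <- apply(m, 2L, pad_sym_to, n = 2L^levels)
  stats4m <- function(M) {  # 4 x ncol matrix of (mean, sd, max, min)
    mu <- colMeans(M)
    rbind(mu, sqrt(pmax(colMeans(M^2) - mu^2, 0)), apply(M, 2L, max),
          apply(M, 2L, min))
  }
  A <- m
  dstats <- vector("list", levels); astats <- vector("list", levels)
  for (lv in seq_len(levels)) {
    dstats[[lv]] <- stats4m(dwt_step_mat(A, filt$hi))
    A <- dwt_step_mat(A, filt$lo)
    astats[[lv]] <- stats4m(A)
  }
  out <- numeric(20L * levels * 8L)
  pos <- 0L
  for (j in seq_len(20L)) {
    for (lv in seq_len(levels)) {
      out[pos + 1:8] <- c(dstats[[lv]][, j], astats[[lv]][, j])
      pos <- pos + 8L
    }
  }
  out
}

# column-wise analysis step for a whole matrix; identical to applying
# dwt_step to every column
dwt_step_mat <- function(M, f) {
  K <- length(f)
  n <- nrow(M)
  E <- rbind(M[pmin((K - 1L):1L, n), , drop = FALSE], M,
             M[pmax(n - seq_len(K - 1L) + 1L, 1L), , drop = FALSE])
  Fm <- stats::filter(E, f, method = "convolution", sides = 1)
  y <- Fm[K:nrow(E), , drop = FALSE]
  matrix(y[seq(2L, nrow(y), by = 2L), ], ncol = ncol(M))
}
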