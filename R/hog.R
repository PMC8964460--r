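# Histogram-of-oriented-gradients descriptor.
#
# The PSSM is treated as a grey-level image: gradients are taken along the
# position axis (vertical) and the amino-acid axis (horizontal) by central
# differences (one-sided at the edges); each cell contributes its gradient
# magnitude to an unsigned-orientation histogram (theta folded into
# [0, pi)); the image is cut into a grid of sub-matrices whose histograms
# are concatenated.

#' HOG descriptor of a PSSM
#'
#' @param x a [pssm] object with at least 2 positions.
#' @param grid_rows,grid_cols number of row-strips along the sequence and
#'   column-strips along the amino-acid axis (defaults 5 x 5 = 25
#'   sub-matrices; strip boundaries at `round(i * L / grid_rows)` and
#'   `round(j * 20 / grid_cols)`).
#' @param bins number of orientation bins over `[0, pi)` (default 10, i.e.
#'   10 histogram channels per sub-matrix; 25 x 10 = 250 features).
#' @param normalize L2-normalize every sub-matrix histogram
#'   (`h / sqrt(sum(h^2) + eps^2)`, `eps = 1e-12`); default `TRUE`. With
#'   `normalize = FALSE` the sum of all histogram entries equals the sum of
#'   all gradient magnitudes.
#' @return numeric vector of length `grid_rows * grid_cols * bins`,
#'   concatenated row-strip-major.
#' @export
hog_features <- function(x, grid_rows = 5L, grid_cols = 5L, bins = 10L,
                         normalize = TRUE) {
  stopifnot(inherits(x, "pssm"))
  m <- x$scores
  L <- nrow(m)
  if (L < 2L) stop("HOG needs at least 2 positions")
  grid_rows <- as.integer(grid_rows); grid_cols <- as.integer(grid_cols)
  bins <- as.integer(bins)
  if (grid_rows < 1L || grid_cols < 1L || bins < 1L)
    stop("grid dimensions and bins must be >= 1")

  # central differences, one-sided at the borders
  gv <- (m[c(2:L, L), ] - m[c(1, 1:(L - 1)), ]) /
    c(1, rep(2, max(L - 2L, 0L)), 1)
  gh <- (m[, c(2:20, 20)] - m[, c(1, 1:19)]) /
    rep(c(1, rep(2, 18), 1), each = L)

  mag <- sqrt(gv^2 + gh^2)
  theta <- atan2(gv, gh) %% pi          # unsigned orientation in [0, pi)
  bin <- pmin(floor(theta / pi * bins), bins - 1L) + 1L

  rb <- round(seq_len(grid_rows) * L / grid_rows)
  cb <- round(seq_len(grid_cols) * 20 / grid_cols)
  strip_r <- findInterval(seq_len(L), c(0L, rb[-grid_rows]) + 0.5)
  strip_c <- findInterval(seq_len(20L), c(0L, cb[-grid_cols]) + 0.5)

  # accumulate magnitudes into (strip_r, strip_c, bin) cells
  cell <- (strip_r[row(m)] - 1L) * grid_cols * bins +
    (strip_c[col(m)] - 1L) * bins + bin
  h <- numeric(grid_rows * grid_cols * bins)
  acc <- rowsum(as.vector(mag), group = as.vector(cell))
  h[as.integer(rownames(acc))] <- acc[, 1L]

  if (normalize) {
    hm <- matrix(h, nrow = bins)  # one column per sub-matrix
    nrm <- sqrt(colSums(hm^2) + (1e-12)^2)
    h <- as.vector(hm / rep(nrm, each = bins))
  }
  h
}
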