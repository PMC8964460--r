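# Shared fixtures and independent brute-force oracles.

# a deterministic random integer PSSM in the ASCII log-odds range
random_pssm <- function(L, seed = 1, id = "rand") {
  set.seed(seed)
  pssm(matrix(sample(-15:15, L * 20, replace = TRUE), L, 20), id = id)
}

# brute-force single analysis step per the defining convolution:
# y[n] = sum_k f[k] * ext[n + K - k], downsampled to even indices, with
# half-point symmetric extension by K - 1 on both sides
oracle_dwt_step <- function(x, f) {
  K <- length(f)
  n <- length(x)
  left <- x[pmin((K - 1):1, n)]
  right <- x[pmax(n - seq_len(K - 1) + 1, 1)]
  ext <- c(left, x, right)
  y <- sapply(seq_len(length(ext) - K + 1), function(s)
    sum(f * ext[s + K - seq_len(K)]))
  y[seq(2, length(y), by = 2)]
}

# full orthonormal 2-D DCT-II by direct summation over the definition
oracle_dct2 <- function(x) {
  M <- nrow(x); N <- ncol(x)
  a <- function(i, n) if (i == 0) sqrt(1 / n) else sqrt(2 / n)
  out <- matrix(0, M, N)
  for (i in 0:(M - 1)) for (j in 0:(N - 1)) {
    s <- 0
    for (m in 0:(M - 1)) for (n in 0:(N - 1))
      s <- s + x[m + 1, n + 1] * cos(pi * (2 * m + 1) * i / (2 * M)) *
        cos(pi * (2 * n + 1) * j / (2 * N))
    out[i + 1, j + 1] <- a(i, M) * a(j, N) * s
  }
  out
}

# gradient magnitudes exactly as documented for the HOG descriptor
oracle_gradient_mass <- function(m) {
  L <- nrow(m)
  gv <- (m[c(2:L, L), ] - m[c(1, 1:(L - 1)), ]) /
    c(1, rep(2, max(L - 2, 0)), 1)
  gh <- (m[, c(2:20, 20)] - m[, c(1, 1:19)]) /
    rep(c(1, rep(2, 18), 1), each = L)
  sum(sqrt(gv^2 + gh^2))
}

# small, fast training configuration for unit tests of the model mechanics
test_dsn_config <- function(seed = 42L, epochs = 15L, ...) {
  dsn_config(hidden_sizes = c(16L, 8L), expand_units = 4L, epochs = epochs,
             batch_size = 16L, seed = seed, ...)
}

# extract features for every task of a stream (list of matrices)
stream_features <- function(stream, cfg = feature_config()) {
  lapply(stream, function(tk) extract_feature_matrix(tk$pssms, cfg))
}

# run the full synthetic pipeline once: returns test-set accuracy
pipeline_accuracy <- function(spec, model_cfg = dsn_config(seed = spec$seed)) {
  stream <- generate_task_stream(spec)
  test <- generate_labeled_set(spec)
  fx <- stream_features(stream)
  ft <- extract_feature_matrix(test$pssms)
  model <- dsn_init(ncol(ft), model_cfg)
  for (i in seq_along(stream))
    model <- train_task(model, fx[[i]], stream[[i]]$positive)
  list(model = model,
       accuracy = mean(predict(model, ft) == test$label),
       train_x = fx, train_stream = stream, test_x = ft,
       test_label = test$label)
}
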