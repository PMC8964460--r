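# Lifelong model mechanics on small synthetic tasks.

make_tasks <- function(n_classes = 3, n_per_class = 15, separation = 8,
                       seed = 5) {
  spec <- synthetic_spec(n_classes = n_classes, n_per_class = n_per_class,
                         separation = separation, seed = seed)
  stream <- generate_task_stream(spec)
  list(stream = stream, fx = stream_features(stream), spec = spec)
}

test_that("initialization is deterministic and shaped by the config", {
  cfg <- dsn_config(hidden_sizes = c(128L, 64L), seed = 1)
  m1 <- dsn_init(1730, cfg); m2 <- dsn_init(1730, cfg)
  expect_identical(m1$layers, m2$layers)
  expect_length(m1$heads, 0L)
  expect_equal(dim(m1$layers[[1]]$W), c(128L, 1730L))
  expect_equal(dim(m1$layers[[2]]$W), c(64L, 128L))
  expect_error(dsn_config(hidden_sizes = integer(0)), "hidden_sizes")
  expect_error(dsn_init(0, cfg), "input_dim")
})

test_that("earlier tasks' parameters and scores are bit-identical after
           further training", {
  tk <- make_tasks()
  m <- dsn_init(1730, test_dsn_config())
  m <- train_task(m, tk$fx[[1]], tk$stream[[1]]$positive)
  m <- train_task(m, tk$fx[[2]], tk$stream[[2]]$positive)
  snap <- m
  probe <- tk$fx[[1]][1:8, ]
  s_before <- predict(m, probe, type = "score")
  m <- train_task(m, tk$fx[[3]], tk$stream[[3]]$positive)

  expect_identical(m$heads[1:2], snap$heads[1:2])
  for (l in seq_along(m$layers)) {
    old <- which(m$layers[[l]]$ts <= 2)
    nc_old <- ncol(snap$layers[[l]]$W)
    expect_identical(m$layers[[l]]$W[old, seq_len(nc_old), drop = FALSE],
                     snap$layers[[l]]$W)
    expect_identical(m$layers[[l]]$b[old], snap$layers[[l]]$b)
    # any columns appended to frozen rows stay exactly zero
    if (ncol(m$layers[[l]]$W) > nc_old)
      expect_true(all(m$layers[[l]]$W[old, -seq_len(nc_old)] == 0))
  }
  s_after <- predict(m, probe, type = "score")
  expect_identical(s_before[, 1:2], s_after[, 1:2])
})

test_that("capacity grows monotonically and expansion follows the
           threshold rule", {
  tk <- make_tasks(n_classes = 4, n_per_class = 12, separation = 8, seed = 6)
  m <- dsn_init(1730, test_dsn_config())
  counts <- integer(0)
  for (i in seq_along(tk$stream)) {
    m <- train_task(m, tk$fx[[i]], tk$stream[[i]]$positive)
    counts <- c(counts, n_parameters(m))
    r <- m$history[[i]]
    expect_identical(r$expanded, r$units_added > 0L)
    expect_identical(r$expanded,
                     r$pre_expansion_loss > m$config$expand_threshold)
    widths <- sapply(m$layers, function(l) nrow(l$W))
    if (i > 1) expect_true(all(widths >= prev_widths))
    prev_widths <- widths
  }
  expect_true(all(diff(counts) > 0))  # heads alone grow the count
})

test_that("an unlearnable task triggers expansion; an easy one does not", {
  tk <- make_tasks(n_classes = 2, n_per_class = 20, separation = 8, seed = 7)
  m <- dsn_init(1730, dsn_config(seed = 42))
  m <- train_task(m, tk$fx[[1]], tk$stream[[1]]$positive)
  expect_false(m$history[[1]]$expanded)   # separable task, loss under tau

  # random labels cannot be fit by the frozen trunk's head alone
  hard <- make_tasks(n_classes = 2, n_per_class = 20, separation = 0,
                     seed = 8)
  set.seed(9)
  y_rand <- sample(hard$stream[[2]]$positive)
  m2 <- train_task(m, hard$fx[[2]], y_rand)
  expect_identical(m2$history[[2]]$expanded,
                   m2$history[[2]]$pre_expansion_loss > m2$config$expand_threshold)
  expect_true(m2$history[[2]]$expanded)
  expect_gt(n_parameters(m2), n_parameters(m) )
})

test_that("a separable task trains to high accuracy with reduced loss", {
  spec <- synthetic_spec(n_classes = 2, n_per_class = 40, separation = 8,
                         noise_sd = 1, seed = 10)
  stream <- generate_task_stream(spec)
  fx <- stream_features(stream)
  m <- dsn_init(1730, dsn_config(seed = 10))
  m <- train_task(m, fx[[1]], stream[[1]]$positive)
  top <- memdsn:::dsn_forward(m$layers,
                              memdsn:::apply_scaler(m, fx[[1]]))[[3]]
  p <- memdsn:::head_scores(m$heads[[1]], top)
  expect_gte(mean((p > 0.5) == stream[[1]]$positive), 0.95)
  expect_lt(m$history[[1]]$final_loss, log(2))  # better than an uninformed head
})

test_that("prediction takes the argmax head with ties toward the earliest
           class", {
  m <- dsn_init(4, test_dsn_config())
  tk <- list(x = rbind(diag(4), -diag(4), diag(4) * 2, -2 * diag(4)),
             y = rep(c(TRUE, FALSE), each = 4, times = 2))
  m <- train_task(m, tk$x, tk$y)
  expect_equal(unique(as.integer(predict(m, matrix(rnorm(40), 10, 4)))), 1L)

  # stubbed heads producing equal scores: lowest class index wins
  m$layers <- list(list(W = matrix(0, 2, 4), b = c(0, 0), ts = c(1L, 1L)))
  m$heads <- list(list(w = c(0, 0), b = -1, ts = 1L),
                  list(w = c(0, 0), b = 2, ts = 2L),
                  list(w = c(0, 0), b = 2, ts = 3L))
  m$n_tasks <- 3L
  m$scaler <- NULL
  pred <- predict(m, matrix(0, 3, 4))
  expect_equal(as.integer(pred), rep(2L, 3))
  expect_error(predict(dsn_init(4, test_dsn_config()), matrix(0, 1, 4)),
               "no trained heads")
})

test_that("task data are validated before training", {
  m <- dsn_init(10, test_dsn_config())
  expect_error(train_task(m, matrix(0, 4, 9), c(TRUE, TRUE, FALSE, FALSE)),
               "dimension")
  expect_error(train_task(m, matrix(0, 4, 10), c(TRUE, FALSE, FALSE, FALSE)),
               "positive")
})

test_that("model files round-trip bit-exactly and reject corruption", {
  tk <- make_tasks(n_classes = 2, n_per_class = 10, seed = 11)
  m <- dsn_init(1730, test_dsn_config())
  m <- train_task(m, tk$fx[[1]], tk$stream[[1]]$positive)
  f <- tempfile(fileext = ".bin")
  save_dsn(m, f)
  m2 <- load_dsn(f)
  expect_identical(unclass(m), unclass(m2))
  probe <- tk$fx[[1]][1:5, ]
  expect_identical(predict(m, probe, type = "score"),
                   predict(m2, probe, type = "score"))

  # truncation is a format error, not silent corruption
  raw <- readBin(f, "raw", file.size(f))
  f2 <- tempfile()
  writeBin(raw[1:(length(raw) %/% 3)], f2)
  expect_error(load_dsn(f2), "corrupt or truncated")
  f3 <- tempfile(); saveRDS(list(format = "other"), f3)
  expect_error(load_dsn(f3), "not a memdsn model")
})

test_that("training reports are reproducible for a fixed seed and data", {
  tk <- make_tasks(n_classes = 2, n_per_class = 10, seed = 12)
  run <- function() {
    m <- dsn_init(1730, test_dsn_config())
    for (i in 1:2) m <- train_task(m, tk$fx[[i]], tk$stream[[i]]$positive)
    m
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
})

test_that("the one-call fitting interface matches the sequential loop and
           reports through the S3 methods", {
  tk <- make_tasks(n_classes = 3, n_per_class = 10, seed = 13)
  x <- do.call(rbind, tk$fx)
  y <- unlist(lapply(tk$stream, `[[`, "label"))
  fit <- dsn_fit(x, y, config = test_dsn_config())
  expect_s3_class(fit, "dsn")
  expect_equal(fit$n_tasks, 3L)
  expect_equal(fit$classes, 1:3)
  expect_error(dsn_fit(x, y, task_order = c(1, 2), config = test_dsn_config()),
               "permutation")
  out <- capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("classes learned: 3", out)))
  expect_true(any(grepl("per-task training history", out)))
  cf <- coef(fit)
  expect_length(cf$trunk, 2L)
  expect_length(cf$heads, 3L)
})
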