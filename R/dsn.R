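# Lifelong one-vs-rest classifier with a dynamically scalable trunk.
#
# The model is a shared multi-layer ReLU trunk plus one binary (logistic)
# head per learned class. Classes arrive as a task stream; for each task the
# model (1) adds a head and trains it together with any still-trainable
# trunk units (selective retraining, elementwise l1 penalty), (2) if the
# held-out loss stays above a threshold, appends fresh units to every hidden
# layer and trains only those plus the head under a group-sparse penalty,
# pruning appended units whose incoming weights are driven to ~zero, and
# (3) freezes everything touched. Every unit carries the index of the task
# that owns it; a unit's incoming weights are trainable only during that
# task, and old units never receive connections from newer ones, so all
# earlier heads' scores are bit-for-bit reproducible after any amount of
# further training — catastrophic forgetting is excluded by construction,
# not merely discouraged.

#' Configuration of the dynamically scalable network
#'
#' @param hidden_sizes integer vector of initial hidden-layer widths
#'   (default `c(128, 64)`).
#' @param expand_units units appended to every hidden layer when a task
#'   triggers expansion (default 16).
#' @param expand_threshold held-out loss above which capacity is added
#'   (default 0.15, on the class-weighted binary cross-entropy scale).
#' @param reg_weight regularization weight `lambda` (default 1e-4).
#' @param reg_kind penalty used during selective retraining: `"l1"`
#'   (default, drives sparse reuse) or `"l2"`; expansion always uses a
#'   group-sparse (per-unit l2) penalty so that useless new units can be
#'   pruned exactly.
#' @param epochs,batch_size,learning_rate plain-SGD training schedule
#'   (defaults 40, 32, 0.05; fixed learning rate keeps runs deterministic).
#' @param val_fraction held-out fraction used for the expansion trigger
#'   (default 0.2, stratified by class).
#' @param class_weighting `"inverse-frequency"` (default; balances the
#'   heavily skewed membrane-protein classes) or `"none"`.
#' @param prune_tol incoming-weight norm below which an appended unit is
#'   removed after expansion training (default 1e-6).
#' @param seed integer; all randomness (initialization, shuffling, splits)
#'   derives from it and the task index.
#' @return object of class `"dsn_config"`.
#' @export
dsn_config <- function(hidden_sizes = c(128L, 64L), expand_units = 16L,
                       expand_threshold = 0.15, reg_weight = 1e-4,
                       reg_kind = c("l1", "l2"), epochs = 40L,
                       batch_size = 32L, learning_rate = 0.05,
                       val_fraction = 0.2,
                       class_weighting = c("inverse-frequency", "none"),
                       prune_tol = 1e-6, seed = 1L) {
  reg_kind <- match.arg(reg_kind)
  class_weighting <- match.arg(class_weighting)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) == 0L || any(hidden_sizes < 1L))
    stop("hidden_sizes must be a non-empty vector of positive integers")
  if (expand_units < 0L) stop("expand_units must be >= 0")
  if (expand_threshold < 0) stop("expand_threshold must be >= 0")
  if (reg_weight < 0) stop("reg_weight must be >= 0")
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0)
    stop("epochs, batch_size and learning_rate must be positive")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  structure(list(hidden_sizes = hidden_sizes,
                 expand_units = as.integer(expand_units),
                 expand_threshold = expand_threshold,
                 reg_weight = reg_weight, reg_kind = reg_kind,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction,
                 class_weighting = class_weighting,
                 prune_tol = prune_tol, seed = as.integer(seed)),
            class = "dsn_config")
}

relu <- function(z) z * (z > 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

he_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / max(nin, 1))), nout, nin)
}

#' Initialize an empty dynamically scalable network
#'
#' @param input_dim feature dimension (1730 under the default
#'   [feature_config()]).
#' @param config a [dsn_config()].
#' @return object of class `"dsn"` with the configured trunk, zero heads and
#'   per-unit task timestamps; initialization is deterministic in
#'   `config$seed`.
#' @export
dsn_init <- function(input_dim, config = dsn_config()) {
  input_dim <- as.integer(input_dim)
  if (input_dim < 1L) stop("input_dim must be >= 1")
  stopifnot(inherits(config, "dsn_config"))
  layers <- withr_seed(config$seed, {
    nin <- input_dim
    lapply(config$hidden_sizes, function(w) {
      l <- list(W = he_init(w, nin), b = numeric(w),
                ts = rep(1L, w))  # initial units belong to task 1
      nin <<- w
      l
    })
  })
  structure(list(input_dim = input_dim, config = config, layers = layers,
                 heads = list(), scaler = NULL, n_tasks = 0L,
                 history = list()),
            class = "dsn")
}

# ---- internal forward / backward machinery ---------------------------------

apply_scaler <- function(model, x) {
  if (is.null(model$scaler)) return(x)
  sweep(sweep(x, 2L, model$scaler$center), 2L, model$scaler$scale, `/`)
}

# activations of every trunk layer; x already standardized (n x d).
#
# The pass is blocked by unit generation ("era" = owning task): units added
# at task e read only units of era <= e, which form a column prefix, so each
# era's pre-activations are one matrix product over exactly the sub-matrices
# that existed when the era was trained. This keeps every earlier model's
# activations bit-identical inside a grown model — the same floating-point
# operations run in the same order, no matter how much capacity was added
# later.
dsn_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- x
  prev_ts <- rep(0L, ncol(x))
  for (l in seq_along(layers)) {
    W <- layers[[l]]$W; ts <- layers[[l]]$ts
    z <- matrix(0, nrow(x), nrow(W))
    for (e in unique(ts)) {          # ts is non-decreasing by construction
      rows <- which(ts == e)
      k <- sum(prev_ts <= e)         # visible input prefix for this era
      z[, rows] <- acts[[l]][, seq_len(k), drop = FALSE] %*%
        t(W[rows, seq_len(k), drop = FALSE])
    }
    acts[[l + 1L]] <- relu(sweep(z, 2L, layers[[l]]$b, `+`))
    prev_ts <- ts
  }
  acts
}

head_scores <- function(head, top) {
  as.vector(sigmoid(top[, seq_along(head$w), drop = FALSE] %*% head$w +
                      head$b))
}

# class-weighted binary cross-entropy, clipped for numerical safety
wbce <- function(p, y, sw) {
  eps <- 1e-12
  mean(sw * -(y * log(p + eps) + (1 - y) * log(1 - p + eps)))
}

sample_weights <- function(y, weighting) {
  if (weighting == "none") return(rep(1, length(y)))
  n <- length(y); np <- sum(y); nn <- n - np
  ifelse(y == 1, n / (2 * np), n / (2 * nn))
}

soft_threshold <- function(w, t) sign(w) * pmax(abs(w) - t, 0)

# SGD with backprop; only `trainable` rows of each layer (and the head) are
# updated. reg = "l1" (elementwise prox) or "group" (per-row l2 prox on
# trainable trunk rows, l1 on the head).
fit_network <- function(layers, head, x, y, sw, trainable, cfg, reg) {
  n <- nrow(x); lr <- cfg$learning_rate; lam <- cfg$reg_weight
  any_trunk <- any(vapply(trainable, any, logical(1)))
  if (!any_trunk) {
    # trunk fully frozen: cache top activations once, train head only
    top <- dsn_forward(layers, x)[[length(layers) + 1L]]
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        b <- idx[start:min(start + cfg$batch_size - 1L, n)]
        tb <- top[b, , drop = FALSE]
        p <- head_scores(head, tb)
        gs <- sw[b] * (p - y[b]) / length(b)
        head$w <- head$w - lr * as.vector(crossprod(tb, gs))
        head$b <- head$b - lr * sum(gs)
        if (lam > 0)
          head$w <- if (reg == "l2") head$w * (1 - lr * lam)
                    else soft_threshold(head$w, lr * lam)
      }
    }
    return(list(layers = layers, head = head))
  }
  nl <- length(layers)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      b <- idx[start:min(start + cfg$batch_size - 1L, n)]
      acts <- dsn_forward(layers, x[b, , drop = FALSE])
      top <- acts[[nl + 1L]]
      p <- head_scores(head, top)
      gs <- sw[b] * (p - y[b]) / length(b)
      # head gradient
      gw <- as.vector(crossprod(top[, seq_along(head$w), drop = FALSE], gs))
      delta <- matrix(0, length(b), ncol(top))
      delta[, seq_along(head$w)] <- outer(gs, head$w)
      delta <- delta * (top > 0)
      head$w <- head$w - lr * gw
      head$b <- head$b - lr * sum(gs)
      for (l in rev(seq_len(nl))) {
        tr <- trainable[[l]]
        if (any(tr)) {
          gW <- delta[, tr, drop = FALSE]
          layers[[l]]$W[tr, ] <- layers[[l]]$W[tr, , drop = FALSE] -
            lr * crossprod(gW, acts[[l]])
          layers[[l]]$b[tr] <- layers[[l]]$b[tr] - lr * colSums(gW)
        }
        if (l > 1L)
          delta <- (delta %*% layers[[l]]$W) * (acts[[l]] > 0)
      }
      if (lam > 0) {
        head$w <- if (reg == "l2") head$w * (1 - lr * lam)
                  else soft_threshold(head$w, lr * lam)
        for (l in seq_len(nl)) {
          tr <- trainable[[l]]
          if (!any(tr)) next
          Wt <- layers[[l]]$W[tr, , drop = FALSE]
          if (reg == "group") {
            nrm <- sqrt(rowSums(Wt^2))
            shrink <- pmax(0, 1 - lr * lam / pmax(nrm, 1e-300))
            layers[[l]]$W[tr, ] <- Wt * shrink
          } else if (reg == "l1") {
            layers[[l]]$W[tr, ] <- soft_threshold(Wt, lr * lam)
          } else {
            layers[[l]]$W[tr, ] <- Wt * (1 - lr * lam)
          }
        }
      }
    }
  }
  list(layers = layers, head = head)
}

# stratified train/validation split, deterministic under the current RNG
val_split <- function(y, frac) {
  pick <- function(i) if (length(i) > 1L)
    sample(i, max(1L, round(frac * length(i)))) else integer(0)
  val <- c(pick(which(y == 1)), pick(which(y == 0)))
  sort(val)
}

#' Train one lifelong task (one new class)
#'
#' Adds a binary head for the next class and trains it on the task's data.
#' If the held-out class-weighted loss after selective retraining exceeds
#' `config$expand_threshold`, every hidden layer is expanded by
#' `config$expand_units` fresh units which are trained (with the new head)
#' under a group-sparse penalty and pruned when their incoming weights
#' vanish. All parameters owned by earlier tasks are frozen throughout:
#' they are bit-identical before and after this call.
#'
#' @param model a `"dsn"` object.
#' @param x numeric matrix of feature vectors (rows = proteins), unscaled;
#'   the model standardizes internally with a scaler frozen at task 1.
#' @param y logical or 0/1 vector: `TRUE`/1 for members of the new class.
#' @return the updated model; the task's `train_report` (task index, losses,
#'   expansion flag, units added/pruned, seed) is appended to
#'   `model$history`.
#' @export
train_task <- function(model, x, y) {
  stopifnot(inherits(model, "dsn"))
  x <- as.matrix(x)
  y <- as.integer(as.logical(y))
  if (ncol(x) != model$input_dim)
    stop("feature dimension ", ncol(x), " does not match the model's ",
         model$input_dim)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (sum(y) < 2L) stop("a task needs at least 2 positive examples")
  if (sum(1 - y) < 2L) stop("a task needs at least 2 negative examples")
  cfg <- model$config
  t <- model$n_tasks + 1L
  task_seed <- cfg$seed + 7919L * t

  if (is.null(model$scaler)) {
    ctr <- colMeans(x); sc <- apply(x, 2L, stats::sd)
    sc[!is.finite(sc) | sc == 0] <- 1
    model$scaler <- list(center = ctr, scale = sc)
  }
  xs <- apply_scaler(model, x)
  sw <- sample_weights(y, cfg$class_weighting)

  old_layers <- model$layers
  res <- withr_seed(task_seed, {
    val <- val_split(y, cfg$val_fraction)
    tr <- setdiff(seq_along(y), val)
    top_w <- nrow(old_layers[[length(old_layers)]]$W)
    head <- list(w = stats::rnorm(top_w, sd = 0.01), b = 0, ts = t)
    trainable <- lapply(old_layers, function(l) l$ts == t)

    # Phase 1: selective retraining (new head + any units owned by task t)
    f1 <- fit_network(old_layers, head, xs[tr, , drop = FALSE], y[tr],
                      sw[tr], trainable, cfg, cfg$reg_kind)
    layers <- f1$layers; head <- f1$head
    vtop <- dsn_forward(layers, xs[val, , drop = FALSE])[[length(layers) + 1L]]
    pre_loss <- wbce(head_scores(head, vtop), y[val], sw[val])

    expanded <- pre_loss > cfg$expand_threshold && cfg$expand_units > 0L
    units_added <- 0L; pruned <- 0L
    if (expanded) {
      k <- cfg$expand_units
      units_added <- k * length(layers)
      # append k units to every hidden layer; old rows gain frozen zero
      # columns so earlier activations are untouched
      for (l in seq_along(layers)) {
        nin <- ncol(layers[[l]]$W)
        layers[[l]]$W <- rbind(layers[[l]]$W, he_init(k, nin))
        layers[[l]]$b <- c(layers[[l]]$b, numeric(k))
        layers[[l]]$ts <- c(layers[[l]]$ts, rep(t, k))
        if (l < length(layers)) {
          nxt <- layers[[l + 1L]]
          layers[[l + 1L]]$W <- cbind(nxt$W, matrix(0, nrow(nxt$W), k))
        }
      }
      head$w <- c(head$w, stats::rnorm(k, sd = 0.01))
      trainable <- lapply(layers, function(l) l$ts == t)
      f2 <- fit_network(layers, head, xs[tr, , drop = FALSE], y[tr], sw[tr],
                        trainable, cfg, "group")
      layers <- f2$layers; head <- f2$head
      # prune appended units whose incoming weights vanished
      for (l in rev(seq_along(layers))) {
        new_units <- which(layers[[l]]$ts == t)
        drop <- new_units[sqrt(rowSums(
          layers[[l]]$W[new_units, , drop = FALSE]^2)) < cfg$prune_tol]
        if (length(drop) == 0L) next
        pruned <- pruned + length(drop)
        keep <- setdiff(seq_len(nrow(layers[[l]]$W)), drop)
        layers[[l]]$W <- layers[[l]]$W[keep, , drop = FALSE]
        layers[[l]]$b <- layers[[l]]$b[keep]
        layers[[l]]$ts <- layers[[l]]$ts[keep]
        if (l < length(layers))
          layers[[l + 1L]]$W <- layers[[l + 1L]]$W[, keep, drop = FALSE]
        else
          head$w <- head$w[keep]
      }
      vtop <- dsn_forward(layers,
                          xs[val, , drop = FALSE])[[length(layers) + 1L]]
    }
    final_loss <- wbce(head_scores(head, vtop), y[val], sw[val])
    list(layers = layers, head = head,
         report = list(task_index = t, pre_expansion_loss = pre_loss,
                       expanded = expanded, units_added = units_added,
                       final_loss = final_loss, pruned_units = pruned,
                       seed_used = task_seed))
  })

  model$layers <- res$layers
  model$heads[[t]] <- res$head
  model$n_tasks <- t
  model$history[[t]] <- res$report
  model
}

#' Fit a DSN on a labeled feature matrix, class by class
#'
#' The classic one-call interface: classes are learned sequentially in
#' `task_order`, each as a one-vs-rest binary task built from the supplied
#' data.
#'
#' @param x numeric feature matrix (rows = proteins).
#' @param y integer class labels.
#' @param task_order order in which classes are learned (default ascending).
#' @param config a [dsn_config()].
#' @return a fitted `"dsn"` model whose head `i` scores class
#'   `task_order[i]`; the learned class of head `i` is kept in
#'   `model$classes`.
#' @export
dsn_fit <- function(x, y, task_order = sort(unique(y)),
                    config = dsn_config()) {
  x <- as.matrix(x); y <- as.integer(y)
  if (!setequal(task_order, unique(y)))
    stop("task_order must be a permutation of the observed classes")
  model <- dsn_init(ncol(x), config)
  for (cls in task_order)
    model <- train_task(model, x, y == cls)
  model$classes <- as.integer(task_order)
  model
}

#' Predict classes with a fitted DSN
#'
#' Evaluates every binary head and assigns the class of the highest-scoring
#' head; ties break toward the earliest-learned head (lowest class index
#' under the default ascending task order).
#'
#' @param object a `"dsn"` model with at least one head.
#' @param newdata feature matrix (rows = proteins), unscaled.
#' @param type `"class"` (default) for hard labels or `"score"` for the
#'   n x n_heads matrix of head probabilities.
#' @param ... unused.
#' @return integer class vector with the score matrix attached as attribute
#'   `"scores"`, or the score matrix itself for `type = "score"`.
#' @export
predict.dsn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (object$n_tasks == 0L) stop("model has no trained heads yet")
  x <- apply_scaler(object, as.matrix(newdata))
  if (ncol(x) != object$input_dim)
    stop("feature dimension ", ncol(x), " does not match the model's ",
         object$input_dim)
  top <- dsn_forward(object$layers, x)[[length(object$layers) + 1L]]
  scores <- vapply(object$heads, head_scores, numeric(nrow(x)), top = top)
  scores <- matrix(scores, nrow = nrow(x))
  classes <- if (is.null(object$classes)) seq_len(object$n_tasks)
             else object$classes
  colnames(scores) <- as.character(classes)
  if (type == "score") return(scores)
  pred <- classes[apply(scores, 1L, which.max)]  # which.max: ties -> first
  attr(pred, "scores") <- scores
  pred
}

#' Total number of parameters of a DSN
#'
#' @param model a `"dsn"` object.
#' @return integer count over trunk weights, biases and heads; it never
#'   decreases from one task to the next, and strictly increases exactly
#'   when a task expanded the trunk (or, trivially, added its head).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "dsn"))
  trunk <- sum(vapply(model$layers,
                      function(l) length(l$W) + length(l$b), numeric(1)))
  heads <- sum(vapply(model$heads,
                      function(h) length(h$w) + 1, numeric(1)))
  as.integer(trunk + heads)
}

#' @export
print.dsn <- function(x, ...) {
  widths <- vapply(x$layers, function(l) nrow(l$W), integer(1))
  cat("Dynamically scalable network\n")
  cat("  input dim: ", x$input_dim, "\n", sep = "")
  cat("  trunk widths: ", paste(widths, collapse = " -> "), "\n", sep = "")
  cat("  classes learned: ", x$n_tasks, "\n", sep = "")
  cat("  parameters: ", n_parameters(x), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dsn <- function(object, ...) {
  h <- object$history
  tab <- data.frame(
    task = vapply(h, `[[`, numeric(1), "task_index"),
    pre_loss = vapply(h, `[[`, numeric(1), "pre_expansion_loss"),
    expanded = vapply(h, `[[`, logical(1), "expanded"),
    units_added = vapply(h, `[[`, numeric(1), "units_added"),
    pruned = vapply(h, `[[`, numeric(1), "pruned_units"),
    final_loss = vapply(h, `[[`, numeric(1), "final_loss"))
  structure(list(model = object, tasks = tab), class = "summary.dsn")
}

#' @export
print.summary.dsn <- function(x, ...) {
  print(x$model)
  if (nrow(x$tasks) > 0L) {
    cat("per-task training history:\n")
    print(x$tasks, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.dsn <- function(object, ...) {
  list(trunk = lapply(object$layers, function(l) list(W = l$W, b = l$b)),
       heads = lapply(object$heads, function(h) list(w = h$w, b = h$b)))
}

#' Save / load a DSN model
#'
#' The on-disk form is a versioned container; loading verifies the format
#' tag and version and reproduces every parameter, unit timestamp and head
#' bit-exactly.
#'
#' @param model a `"dsn"` object.
#' @param path file path.
#' @return `save_dsn`: `path` invisibly; `load_dsn`: the restored model.
#' @export
save_dsn <- function(model, path) {
  stopifnot(inherits(model, "dsn"))
  saveRDS(list(format = "memdsn_dsn_model", version = 1L,
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_dsn
#' @export
load_dsn <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or truncated model file: ", path))
  if (!is.list(obj) || !identical(obj$format, "memdsn_dsn_model"))
    stop("not a memdsn model file: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported model file version: ", obj$version)
  structure(obj$model, class = "dsn")
}

#' Jointly trained one-vs-rest baseline
#'
#' Trains a single trunk of the given widths together with all class heads
#' simultaneously on the full dataset — the retrain-from-scratch
#' multi-task alternative the lifelong model avoids. Used as the reference
#' the sequentially trained model is compared against.
#'
#' @param x feature matrix; @param y integer class labels.
#' @param hidden_sizes trunk widths (match the lifelong model's final
#'   widths for a fair comparison).
#' @param config a [dsn_config()] (epochs, batch size, learning rate,
#'   weighting and seed are honored; expansion settings are irrelevant).
#' @return a `"dsn"` model with one head per class, usable with
#'   [predict.dsn()].
#' @export
dsn_joint_fit <- function(x, y, hidden_sizes = c(128L, 64L),
                          config = dsn_config()) {
  x <- as.matrix(x); y <- as.integer(y)
  classes <- sort(unique(y))
  cfg <- config
  ctr <- colMeans(x); sc <- apply(x, 2L, stats::sd)
  sc[!is.finite(sc) | sc == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, sc, `/`)
  n <- nrow(xs); nc <- length(classes)
  Y <- vapply(classes, function(c) as.numeric(y == c), numeric(n))
  SW <- vapply(classes, function(c)
    sample_weights(as.integer(y == c), cfg$class_weighting), numeric(n))
  withr_seed(cfg$seed, {
    nin <- ncol(xs)
    layers <- lapply(as.integer(hidden_sizes), function(w) {
      l <- list(W = he_init(w, nin), b = numeric(w), ts = rep(1L, w))
      nin <<- w
      l
    })
    top_w <- as.integer(hidden_sizes[length(hidden_sizes)])
    Wh <- matrix(stats::rnorm(nc * top_w, sd = 0.01), nc, top_w)
    bh <- numeric(nc)
    lr <- cfg$learning_rate; nl <- length(layers)
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        b <- idx[start:min(start + cfg$batch_size - 1L, n)]
        acts <- dsn_forward(layers, xs[b, , drop = FALSE])
        top <- acts[[nl + 1L]]
        P <- sigmoid(sweep(top %*% t(Wh), 2L, bh, `+`))
        G <- (P - Y[b, , drop = FALSE]) * SW[b, , drop = FALSE] /
          (length(b) * nc)
        delta <- (G %*% Wh) * (top > 0)
        Wh <- Wh - lr * crossprod(G, top)
        bh <- bh - lr * colSums(G)
        for (l in rev(seq_len(nl))) {
          layers[[l]]$W <- layers[[l]]$W - lr * crossprod(delta, acts[[l]])
          layers[[l]]$b <- layers[[l]]$b - lr * colSums(delta)
          if (l > 1L)
            delta <- (delta %*% layers[[l]]$W) * (acts[[l]] > 0)
        }
      }
    }
    heads <- lapply(seq_len(nc), function(i)
      list(w = Wh[i, ], b = bh[i], ts = 1L))
    structure(list(input_dim = ncol(xs), config = cfg, layers = layers,
                   heads = heads, scaler = list(center = ctr, scale = sc),
                   n_tasks = nc, history = list(),
                   classes = classes),
              class = "dsn")
  })
}
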