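# Synthetic labeled PSSM generation.
#
# The generator plants class signal in the column means of the profile:
# every class has a 20-vector template (a common base plus a class-specific
# scaled one-hot offset) and each sampled profile is template + iid Gaussian
# noise per entry, rounded to integers like real ASCII log-odds. Sequence
# lengths follow a log-normal law truncated from below, mimicking the
# heavy-tailed length spread of curated membrane-protein sets (most lengths
# between ~50 and ~3000).

#' Specification of a synthetic PSSM stream
#'
#' @param n_classes number of membrane-protein classes (2..20; default 8,
#'   the eight canonical types).
#' @param n_per_class profiles per class and per task (default 100).
#' @param separation template separation `Delta` >= 0: each class template is
#'   the common base plus `Delta` on one class-specific coordinate, so any
#'   two templates are `Delta * sqrt(2)` apart in Euclidean distance.
#'   `Delta = 0` makes the classes indistinguishable (chance-level control).
#' @param noise_sd standard deviation of the per-entry Gaussian noise
#'   (default 1, on the log-odds scale).
#' @param length_log_mean,length_log_sd parameters of the log-normal length
#'   law (defaults 5.5 and 0.8: median length ~245).
#' @param min_length lower truncation for lengths (default 16, so a 4-level
#'   wavelet cascade is always well defined).
#' @param seed integer seed; identical specs generate byte-identical data.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_classes = 8L, n_per_class = 100L,
                           separation = 8, noise_sd = 1,
                           length_log_mean = 5.5, length_log_sd = 0.8,
                           min_length = 16L, seed = 1L) {
  n_classes <- as.integer(n_classes); n_per_class <- as.integer(n_per_class)
  min_length <- as.integer(min_length)
  if (n_classes < 2L || n_classes > 20L)
    stop("n_classes must be in 2..20")
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (min_length < 16L) stop("min_length must be >= 16")
  structure(list(n_classes = n_classes, n_per_class = n_per_class,
                 separation = separation, noise_sd = noise_sd,
                 length_log_mean = length_log_mean,
                 length_log_sd = length_log_sd,
                 min_length = min_length, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic PSSM spec:", x$n_classes, "classes x", x$n_per_class,
      "profiles, separation", x$separation, ", noise sd", x$noise_sd, "\n")
  invisible(x)
}

#' Class template vectors
#'
#' Templates are `base + separation * e_c` where `base` is a common random
#' integer-ish log-odds baseline and `e_c` is the one-hot vector of
#' coordinate `c`; the pairwise Euclidean distance between any two templates
#' is exactly `separation * sqrt(2)`.
#'
#' @param n_classes number of classes (2..20).
#' @param separation offset scale `Delta` >= 0.
#' @param seed integer seed.
#' @return list of `n_classes` numeric 20-vectors.
#' @export
make_class_templates <- function(n_classes, separation, seed) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L || n_classes > 20L)
    stop("n_classes must be in 2..20")
  if (separation < 0) stop("separation must be >= 0")
  base <- withr_seed(seed, round(stats::rnorm(20, mean = -1, sd = 2)))
  lapply(seq_len(n_classes), function(c) {
    tpl <- base
    tpl[c] <- tpl[c] + separation
    tpl
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample one synthetic PSSM around a class template
#'
#' Each row is `template + N(0, noise_sd^2)` noise, rounded to integers
#' (ASCII PSSM log-odds are integers).
#'
#' @param template numeric 20-vector.
#' @param length number of positions L >= 1.
#' @param noise_sd noise standard deviation >= 0.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @param id protein id for the generated profile.
#' @return a [pssm] object of dimension `length` x 20.
#' @export
sample_pssm <- function(template, length, noise_sd, seed = NULL,
                        id = "synthetic") {
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1")
  if (length(template) != 20L) stop("template must have 20 entries")
  draw <- function() {
    noise <- matrix(stats::rnorm(length * 20L, sd = noise_sd), length, 20L)
    round(sweep(noise, 2L, template, `+`))
  }
  scores <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  pssm(scores, id = id)
}

# log-normal lengths truncated from below
sample_lengths <- function(n, spec) {
  l <- round(stats::rlnorm(n, spec$length_log_mean, spec$length_log_sd))
  pmax(as.integer(l), spec$min_length)
}

#' Generate a lifelong task stream of labeled synthetic PSSMs
#'
#' One task per class, in class order 1..n_classes. Task `t` carries
#' `n_per_class` positive profiles of class `t` plus `n_per_class` negative
#' profiles drawn round-robin from the other classes' templates — each task
#' ships its own negatives, because under the lifelong constraint earlier
#' tasks' training data are no longer available when a new class arrives.
#'
#' @param spec a [synthetic_spec].
#' @return list of `n_classes` tasks; each task is a list with elements
#'   `class` (the new class index), `pssms` (list of [pssm] objects),
#'   `label` (integer vector of true class ids) and `positive` (logical,
#'   `TRUE` for members of the task's class).
#' @export
generate_task_stream <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  templates <- make_class_templates(spec$n_classes, spec$separation,
                                    spec$seed)
  withr_seed(spec$seed + 1L, {
    lapply(seq_len(spec$n_classes), function(t) {
      others <- setdiff(seq_len(spec$n_classes), t)
      neg_cls <- rep_len(others, spec$n_per_class)
      cls <- c(rep(t, spec$n_per_class), neg_cls)
      lens <- sample_lengths(length(cls), spec)
      ps <- lapply(seq_along(cls), function(i) {
        sample_pssm(templates[[cls[i]]], lens[i], spec$noise_sd,
                    id = sprintf("task%02d_s%04d_c%d", t, i, cls[i]))
      })
      list(class = t, pssms = ps, label = cls,
           positive = cls == t)
    })
  })
}

#' Generate a balanced labeled evaluation set
#'
#' Draws `n_per_class` profiles from every class template using a RNG stream
#' disjoint from [generate_task_stream()]'s, so train and test sets from the
#' same spec do not share noise.
#'
#' @param spec a [synthetic_spec].
#' @return list with `pssms` (list of [pssm]) and `label` (integer vector).
#' @export
generate_labeled_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  templates <- make_class_templates(spec$n_classes, spec$separation,
                                    spec$seed)
  withr_seed(spec$seed + 2L, {
    cls <- rep(seq_len(spec$n_classes), each = spec$n_per_class)
    lens <- sample_lengths(length(cls), spec)
    ps <- lapply(seq_along(cls), function(i) {
      sample_pssm(templates[[cls[i]]], lens[i], spec$noise_sd,
                  id = sprintf("test_s%04d_c%d", i, cls[i]))
    })
    list(pssms = ps, label = cls)
  })
}

#' Write a synthetic dataset as ASCII PSSM files plus a label TSV
#'
#' Materializes [generate_labeled_set()] on disk so synthetic data flow
#' through the same file interfaces as real PSI-BLAST output.
#'
#' @param spec a [synthetic_spec].
#' @param dir output directory (created if needed); one `<id>.pssm` file per
#'   profile and a `labels.tsv` with `protein_id<TAB>class`.
#' @return invisibly, the label file path.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  set <- generate_labeled_set(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(set$pssms, `[[`, character(1), "id")
  for (p in set$pssms)
    write_ascii_pssm(p, file.path(dir, paste0(p$id, ".pssm")))
  labfile <- file.path(dir, "labels.tsv")
  utils::write.table(data.frame(ids, set$label), labfile, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(labfile)
}
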