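# One-vs-rest evaluation: confusion tallies, SN/SP/ACC/MCC, per-class
# accuracy tables and dataset summaries.

#' One-vs-rest confusion counts for a single class
#'
#' Treats `cls` as the positive class: TP are members of `cls` predicted as
#' `cls`, FP are non-members predicted as `cls`, TN are non-members
#' predicted as something else, FN are members predicted as something else.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param cls the class treated as positive.
#' @return object of class `"confusion_counts"`: list with integer `tp`,
#'   `fp`, `tn`, `fn` summing to `length(y_true)`.
#' @export
confusion_counts <- function(y_true, y_pred, cls) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (length(y_true) < 1L) stop("need at least one prediction")
  tpos <- y_true == cls; ppos <- y_pred == cls
  structure(list(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
                 tn = sum(!tpos & !ppos), fn = sum(tpos & !ppos)),
            class = "confusion_counts")
}

#' SN, SP, ACC and MCC from confusion counts
#'
#' Sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/total` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`. Any
#' degenerate denominator (a zero factor under the MCC root, no positives
#' for SN, no negatives for SP) defines the affected metric as 0, with a
#' warning, so batch reports never fail.
#'
#' @param c a [confusion_counts()] object or a list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return named numeric vector `c(sn, sp, acc, mcc)`.
#' @export
metrics_from_counts <- function(c) {
  # double precision: the MCC denominator overflows 32-bit integers for
  # realistic test-set sizes
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  tn <- as.numeric(c$tn); fn <- as.numeric(c$fn)
  total <- tp + fp + tn + fn
  if (total <= 0) stop("confusion counts sum to zero")
  degen <- character(0)
  if (tp + fn > 0) sn <- tp / (tp + fn) else { sn <- 0; degen <- c(degen, "SN") }
  if (tn + fp > 0) sp <- tn / (tn + fp) else { sp <- 0; degen <- c(degen, "SP") }
  acc <- (tp + tn) / total
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  if (denom > 0) mcc <- (tp * tn - fp * fn) / sqrt(denom)
  else { mcc <- 0; degen <- c(degen, "MCC") }
  if (length(degen) > 0)
    warning("degenerate denominator; ", paste(degen, collapse = ", "),
            " defined as 0", call. = FALSE)
  c(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

# round-half-up to `digits` decimals (round() rounds half to even, which is
# not how the benchmark tables are aggregated)
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-class and overall accuracy report
#'
#' The per-class accuracy follows the benchmark-table convention: for class
#' `c` it is the fraction of class-`c` test proteins predicted as `c`
#' (i.e. the class recall, printed as `x/y`), and the overall accuracy is
#' `sum(correct) / sum(total)`. SN/SP/ACC/MCC are also computed per class
#' from the one-vs-rest tallies.
#'
#' @param y_true,y_pred integer labels in `1..n_classes`.
#' @param n_classes number of classes (default: largest label seen).
#' @return object of class `"eval_report"`: list with `per_class` (data
#'   frame: class, correct, total, accuracy, sn, sp, acc, mcc),
#'   `overall_correct`, `overall_total`, `overall_acc`, `n_classes`,
#'   `n_samples`.
#' @export
eval_report <- function(y_true, y_pred, n_classes = max(y_true, y_pred)) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (any(y_true < 1L | y_true > n_classes) ||
      any(y_pred < 1L | y_pred > n_classes))
    stop("labels must lie in 1..", n_classes)
  per <- lapply(seq_len(n_classes), function(cls) {
    cc <- confusion_counts(y_true, y_pred, cls)
    m <- suppressWarnings(metrics_from_counts(cc))
    total <- sum(y_true == cls)
    correct <- cc$tp
    data.frame(class = cls, correct = correct, total = total,
               accuracy = if (total > 0) correct / total else NA_real_,
               sn = m["sn"], sp = m["sp"], acc = m["acc"], mcc = m["mcc"],
               row.names = NULL)
  })
  per <- do.call(rbind, per)
  structure(list(per_class = per,
                 overall_correct = sum(per$correct),
                 overall_total = length(y_true),
                 overall_acc = sum(per$correct) / length(y_true),
                 n_classes = as.integer(n_classes),
                 n_samples = length(y_true)),
            class = "eval_report")
}

#' Build a report directly from per-class correct/total counts
#'
#' Reconstructs label/prediction vectors consistent with printed per-class
#' `correct/total` pairs (misclassified members are assigned an arbitrary
#' other class, which affects neither per-class recall nor the overall
#' accuracy) and delegates to [eval_report()]. This is how published
#' accuracy tables are re-aggregated.
#'
#' @param correct,total integer vectors, one entry per class.
#' @return an `"eval_report"`.
#' @export
report_from_counts <- function(correct, total) {
  if (length(correct) != length(total))
    stop("correct and total must have one entry per class")
  if (any(correct > total) || any(correct < 0))
    stop("need 0 <= correct <= total for every class")
  nc <- length(correct)
  y_true <- rep(seq_len(nc), times = total)
  y_pred <- unlist(lapply(seq_len(nc), function(cls) {
    wrong <- total[cls] - correct[cls]
    other <- if (cls == 1L) 2L else 1L
    c(rep(cls, correct[cls]), rep(other, wrong))
  }))
  eval_report(y_true, y_pred, n_classes = nc)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("per-class accuracy (correct/total):\n")
  p <- x$per_class
  for (i in seq_len(nrow(p)))
    cat(sprintf("  class %d: %5.1f (%d/%d)\n", p$class[i],
                round_half_up(100 * p$accuracy[i]), p$correct[i],
                p$total[i]))
  cat(sprintf("  Overall: %5.1f (%d/%d)\n",
              round_half_up(100 * x$overall_acc), x$overall_correct,
              x$overall_total))
  invisible(x)
}

#' Percentages of an eval report, rendered like the benchmark tables
#'
#' @param x an `"eval_report"`.
#' @return list with `per_class` (numeric vector of per-class percentages,
#'   one decimal, round-half-up) and `overall` (the overall percentage,
#'   same rounding).
#' @export
report_percentages <- function(x) {
  stopifnot(inherits(x, "eval_report"))
  list(per_class = round_half_up(100 * x$per_class$accuracy),
       overall = round_half_up(100 * x$overall_acc))
}

#' Length and composition summary of a sequence set
#'
#' Per class: the five-number length summary and the 20-letter amino-acid
#' composition (frequencies over all residues of the class, summing to 1;
#' `X` residues are excluded from the composition).
#'
#' @param sequences data frame as returned by [read_fasta()], with `label`
#'   filled in (`NA` labels are grouped as class 0).
#' @return list with `lengths` (data frame class x min/q1/median/q3/max) and
#'   `composition` (matrix class x 20 amino acids).
#' @export
dataset_summary <- function(sequences) {
  if (NROW(sequences) == 0L) stop("empty sequence set")
  lab <- sequences$label
  lab[is.na(lab)] <- 0L
  lens <- nchar(sequences$residues)
  classes <- sort(unique(lab))
  qs <- t(vapply(classes, function(cl)
    stats::quantile(lens[lab == cl], c(0, .25, .5, .75, 1), names = FALSE),
    numeric(5)))
  lengths <- data.frame(class = classes, min = qs[, 1], q1 = qs[, 2],
                        median = qs[, 3], q3 = qs[, 4], max = qs[, 5])
  comp <- t(vapply(classes, function(cl) {
    chars <- unlist(strsplit(sequences$residues[lab == cl], ""))
    chars <- chars[chars != "X"]
    cnt <- table(factor(chars, levels = PSSM_ALPHABET))
    as.numeric(cnt) / sum(cnt)
  }, numeric(20)))
  colnames(comp) <- PSSM_ALPHABET
  rownames(comp) <- classes
  list(lengths = lengths, composition = comp)
}
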