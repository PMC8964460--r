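# Reading and writing protein sequences and PSI-BLAST ASCII PSSM profiles.
#
# Positions are 1-based in the ASCII file; matrices returned to R are ordinary
# 1-based matrices with one row per sequence position.

#: fixed PSI-BLAST amino-acid column order
PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a PSSM object
#'
#' A PSSM (position-specific scoring matrix) is an L x 20 matrix of
#' per-position amino-acid log-odds scores, usually produced by iterative
#' PSI-BLAST search (3 iterations, E-value 0.001 is the conventional setting
#' for membrane-protein profiles). Columns follow the fixed PSI-BLAST
#' amino-acid order `A R N D C Q E G H I L K M F P S T W Y V`.
#'
#' @param scores numeric matrix with exactly 20 columns and L >= 1 rows.
#' @param id protein identifier.
#' @param residues optional character vector of length L with the query
#'   residue letters (retained for provenance, not validated against any
#'   sequence; PSI-BLAST may emit `X`).
#' @return an object of class `"pssm"`: a list with elements `id`, `scores`
#'   (L x 20 numeric matrix with the alphabet as column names), `residues`
#'   and `length`.
#' @examples
#' p <- pssm(matrix(0, 4, 20), id = "toy")
#' dim(p$scores)
#' @export
pssm <- function(scores, id = "unknown", residues = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("a PSSM must have exactly 20 columns, got ", ncol(scores))
  if (nrow(scores) < 1L)
    stop("a PSSM must have at least one row")
  if (!is.numeric(scores))
    stop("PSSM scores must be numeric")
  if (is.null(residues)) residues <- rep("X", nrow(scores))
  if (length(residues) != nrow(scores))
    stop("residues must have one letter per PSSM row")
  colnames(scores) <- PSSM_ALPHABET
  rownames(scores) <- NULL
  structure(list(id = as.character(id), scores = scores,
                 residues = as.character(residues), length = nrow(scores)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM profile '", x$id, "': ", x$length, " positions x 20 amino acids\n",
      sep = "")
  cat("score range: [", min(x$scores), ", ", max(x$scores), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.pssm <- function(x) dim(x$scores)

#' Read protein sequences from a FASTA file
#'
#' Sequences are read with [Biostrings::readAAStringSet()] and validated
#' against the 20-letter amino-acid alphabet; `X` (unknown residue) is
#' accepted. The record identifier is the first whitespace-delimited token of
#' the header.
#'
#' @param path path to a FASTA file.
#' @return a data frame with columns `id`, `residues` and `label`
#'   (integer, `NA` until assigned from a label file), one row per record in
#'   file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read as raw strings so residue validation (with record names) is ours
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found in ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  res <- as.character(set)
  ok <- c(PSSM_ALPHABET, "X")
  for (i in seq_along(res)) {
    if (nchar(res[i]) == 0L)
      stop("empty sequence for record '", ids[i], "'")
    letters_i <- unique(strsplit(res[i], "")[[1]])
    bad <- setdiff(letters_i, ok)
    if (length(bad) > 0L)
      stop("record '", ids[i], "' contains illegal residue character(s): ",
           paste(bad, collapse = ", "))
  }
  data.frame(id = ids, residues = res, label = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Read a label file
#'
#' @param path tab-separated file with two columns: protein id and class
#'   index in 1..8 (no header).
#' @param n_classes upper bound for the class index (default 8, the eight
#'   membrane-protein types).
#' @return named integer vector of class labels, names are protein ids.
#' @export
read_labels <- function(path, n_classes = 8L) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label file must have two tab-separated columns")
  lab <- as.integer(tab[[2L]])
  if (anyNA(lab) || any(lab < 1L | lab > n_classes))
    stop("labels must be integers in 1..", n_classes)
  stats::setNames(lab, as.character(tab[[1L]]))
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, a column-label line,
#' then one data row per position consisting of the 1-based position index,
#' the query residue letter and the per-amino-acid scores. Only the first
#' 20-number block (the log-odds scores of the scoring matrix) is used; the
#' second 20-column block of weighted percentages and the trailing statistics
#' lines written by real PSI-BLAST are ignored. A data row must therefore
#' carry exactly 20 numbers (files written by [write_ascii_pssm()]) or the 40
#' or 42 numbers of genuine PSI-BLAST output; anything else is a format
#' error reported with its line number.
#'
#' @param path path to an ASCII PSSM file.
#' @param id protein id to attach; defaults to the file name without
#'   extension.
#' @return a [pssm] object.
#' @export
read_ascii_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rows <- list(); residues <- character(0)
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(tok) < 2L) next
    # data rows start with the integer position index followed by a letter
    if (!grepl("^[0-9]+$", tok[1]) || !grepl("^[A-Za-z]$", tok[2])) next
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(num))
      stop("non-numeric score on line ", ln, " of ", path)
    if (!(length(num) %in% c(20L, 40L, 42L)))
      stop("expected 20 log-odds values (or a 40/42-column PSI-BLAST row) ",
           "on line ", ln, " of ", path, ", got ", length(num))
    rows[[length(rows) + 1L]] <- num[1:20]
    residues <- c(residues, toupper(tok[2]))
  }
  if (length(rows) == 0L)
    stop("no PSSM data rows found in ", path)
  pssm(do.call(rbind, rows), id = id, residues = residues)
}

#' Write a PSSM as an ASCII profile file
#'
#' Emits the 20-column dialect accepted by [read_ascii_pssm()]: two header
#' lines, a column-label line, and one data row per position. The
#' round-trip `read_ascii_pssm(write_ascii_pssm(p))` reproduces `p$scores`
#' exactly (scores are written in full precision).
#'
#' @param x a [pssm] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  fmt_num <- function(v) {
    # integers (the usual log-odds case) print without decimals
    if (all(v == round(v))) format(v, scientific = FALSE, trim = TRUE)
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  body <- vapply(seq_len(x$length), function(i) {
    paste0(format(i, width = 5), " ", x$residues[i], "  ",
           paste(format(fmt_num(x$scores[i, ]), width = 4), collapse = " "))
  }, character(1))
  out <- c("",
           paste("Last position-specific scoring matrix computed for",
                 x$id),
           paste0("      ", paste(format(PSSM_ALPHABET, width = 4),
                                  collapse = " ")),
           body)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read every ASCII PSSM in a directory
#'
#' Files that fail to parse are skipped with a warning (real PSSM
#' directories are messy); the order of the returned list follows the sorted
#' file names.
#'
#' @param dir directory containing `.pssm` (or any extension) ASCII PSSM
#'   files.
#' @param pattern file-name regexp, default all files.
#' @return named list of [pssm] objects (may be empty).
#' @export
read_pssm_dir <- function(dir, pattern = NULL) {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  out <- list()
  for (f in files) {
    p <- tryCatch(read_ascii_pssm(f), error = function(e) {
      warning("skipping ", basename(f), ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(p)) out[[p$id]] <- p
  }
  out
}
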