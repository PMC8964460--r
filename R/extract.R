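# Feature configuration, end-to-end concatenation, batch extraction and the
# TSV feature-file interface.

#' Feature extraction configuration
#'
#' Controls the five descriptors. The defaults give the standard
#' 40 + 400 + 640 + 400 + 250 = 1730-dimensional vector:
#' Pse-PSSM (lag 1), 20x20 average blocks, a 4-level db4 wavelet cascade,
#' the 20x20 low-frequency DCT block and a 5x5x10 HOG.
#'
#' @param pse_lag Pse-PSSM maximum lag `lambda` (default 1).
#' @param wavelet wavelet family for the cascade (default `"db4"`).
#' @param dwt_levels cascade depth (default 4).
#' @param dct_keep_rows,dct_keep_cols retained DCT block (default 20, 20).
#' @param hog_grid_rows,hog_grid_cols,hog_bins HOG grid and orientation bins
#'   (defaults 5, 5, 10).
#' @return an object of class `"feature_config"`.
#' @export
feature_config <- function(pse_lag = 1L, wavelet = "db4", dwt_levels = 4L,
                           dct_keep_rows = 20L, dct_keep_cols = 20L,
                           hog_grid_rows = 5L, hog_grid_cols = 5L,
                           hog_bins = 10L) {
  cfg <- list(pse_lag = as.integer(pse_lag), wavelet = wavelet,
              dwt_levels = as.integer(dwt_levels),
              dct_keep_rows = as.integer(dct_keep_rows),
              dct_keep_cols = as.integer(dct_keep_cols),
              hog_grid_rows = as.integer(hog_grid_rows),
              hog_grid_cols = as.integer(hog_grid_cols),
              hog_bins = as.integer(hog_bins))
  if (cfg$pse_lag < 0L) stop("pse_lag must be >= 0")
  if (cfg$dwt_levels < 1L) stop("dwt_levels must be >= 1")
  wavelet_filters(cfg$wavelet)  # validates the name
  with(cfg, if (dct_keep_rows < 1L || dct_keep_cols < 1L ||
                hog_grid_rows < 1L || hog_grid_cols < 1L || hog_bins < 1L)
    stop("all feature-config dimensions must be >= 1"))
  structure(cfg, class = "feature_config")
}

# segment lengths implied by a config, in concatenation order
feature_layout <- function(cfg = feature_config()) {
  len <- c(pse_pssm = 20L * (1L + cfg$pse_lag),
           avblock = 400L,
           dwt = 20L * cfg$dwt_levels * 2L * 4L,
           dct = cfg$dct_keep_rows * cfg$dct_keep_cols,
           hog = cfg$hog_grid_rows * cfg$hog_grid_cols * cfg$hog_bins)
  data.frame(segment = names(len), start = cumsum(c(1L, unname(len[-5L]))),
             length = unname(len), stringsAsFactors = FALSE)
}

#' Extract the full concatenated feature vector of one PSSM
#'
#' Runs all five descriptors and stitches them end-to-end in the fixed
#' order `pse_pssm | avblock | dwt | dct | hog`. The output length depends
#' only on the configuration (1730 under defaults), never on the sequence
#' length.
#'
#' @param x a [pssm] object with `L >= max(2, pse_lag + 1)` positions.
#' @param cfg a [feature_config()].
#' @return named numeric vector (`segment.index` names) with attribute
#'   `"layout"`, the segment table from [feature_layout()].
#' @export
extract_features <- function(x, cfg = feature_config()) {
  stopifnot(inherits(x, "pssm"))
  v <- c(pse_pssm_features(normalize_pssm(x), cfg$pse_lag),
         avblock_features(x),
         dwt_features(x, cfg$wavelet, cfg$dwt_levels),
         dct_features(x, cfg$dct_keep_rows, cfg$dct_keep_cols),
         hog_features(x, cfg$hog_grid_rows, cfg$hog_grid_cols, cfg$hog_bins))
  lay <- feature_layout(cfg)
  names(v) <- unlist(lapply(seq_len(nrow(lay)), function(i)
    paste0(lay$segment[i], ".", seq_len(lay$length[i]))))
  attr(v, "layout") <- lay
  v
}

#' Extract features for a batch of PSSMs
#'
#' @param pssms list of [pssm] objects.
#' @param cfg a [feature_config()].
#' @return numeric matrix, one row per PSSM (row names are the protein
#'   ids), with the layout attached as attribute `"layout"`.
#' @export
extract_feature_matrix <- function(pssms, cfg = feature_config()) {
  if (length(pssms) == 0L) stop("no PSSMs to extract features from")
  rows <- lapply(pssms, extract_features, cfg = cfg)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(pssms, `[[`, character(1), "id")
  attr(m, "layout") <- feature_layout(cfg)
  m
}

#' Write / read a feature table as TSV
#'
#' The on-disk format is `protein_id` followed by one named column per
#' feature (`segment.index`), tab-separated with a header line.
#'
#' @param m feature matrix from [extract_feature_matrix()].
#' @param path TSV path.
#' @return `write_feature_tsv`: `path` invisibly; `read_feature_tsv`: a
#'   numeric matrix with protein ids as row names.
#' @export
write_feature_tsv <- function(m, path) {
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(df))
    stop("feature TSV lacks a protein_id column")
  m <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein_id
  m
}
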