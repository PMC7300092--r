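# Loading expression data and the min-max normalization expected by the
# Bernoulli decoder. Inputs are assumed log-normalized; each gene is scaled
# to [0, 1] across cells before modelling.

#' Load an expression matrix from disk
#'
#' CSV/TSV files carry a header row of gene names and a first column of cell
#' ids. MatrixMarket (`mtx`) files need sidecar files `genes.txt` and
#' `cells.txt` (one name per line) next to the matrix; the orientation is
#' auto-detected from the sidecar lengths and can be forced with `transpose`.
#'
#' @param path File path.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"` (default: from extension).
#' @param genes_path,cells_path Sidecar paths for `mtx` (default: `genes.txt`
#'   and `cells.txt` in the same directory).
#' @param transpose Force transposition of the stored matrix (mtx only);
#'   `NA` (default) auto-detects orientation from sidecar lengths.
#' @param log1p Apply `log1p` to the values (for raw-count inputs); by
#'   default values are taken as already log-normalized.
#' @return An [expression_matrix()] with `scale_state = "log_normalized"`.
#' @export
load_expression <- function(path, format = NULL, genes_path = NULL,
                            cells_path = NULL, transpose = NA, log1p = FALSE) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension; pass `format`"))
  }
  format <- match.arg(format, c("csv", "tsv", "mtx"))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    values <- as.matrix(df)
    .assert(is.numeric(values), "non-numeric entries in expression table")
    gene_names <- colnames(values)
    cell_ids <- rownames(values)
  } else {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.txt")
    if (is.null(cells_path)) cells_path <- file.path(dir, "cells.txt")
    .assert(file.exists(genes_path) && file.exists(cells_path),
            "mtx format needs genes.txt and cells.txt sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    gene_names <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    flip <- if (is.na(transpose)) {
      if (nrow(m) == length(cell_ids) && ncol(m) == length(gene_names)) {
        FALSE
      } else if (nrow(m) == length(gene_names) && ncol(m) == length(cell_ids)) {
        TRUE
      } else {
        stop("matrix dimensions match neither sidecar orientation", call. = FALSE)
      }
    } else {
      isTRUE(transpose)
    }
    values <- if (flip) t(m) else m
    .assert(nrow(values) == length(cell_ids) && ncol(values) == length(gene_names),
            "sidecar lengths do not match matrix dimensions")
  }
  if (anyNA(values)) stop("expression matrix contains NaN/NA entries", call. = FALSE)
  if (isTRUE(log1p)) values <- base::log1p(values)
  expression_matrix(values, gene_names = gene_names, cell_ids = cell_ids,
                    scale_state = "log_normalized")
}

#' Write an expression matrix to disk
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"mtx"` (mtx writes `genes.txt` and
#'   `cells.txt` sidecars next to the matrix).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = expr$cell_ids, expr$values, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(expr$gene_names, file.path(dir, "genes.txt"))
    writeLines(expr$cell_ids, file.path(dir, "cells.txt"))
  }
  invisible(path)
}

#' Per-gene min-max scaling to the unit interval
#'
#' Scales each gene to `[0, 1]` across cells via `(x - min) / (max - min)`,
#' matching the multivariate-Bernoulli modelling of the decoder. Constant
#' genes map to 0 and are reported; their indices stay in place so decoder
#' gene-weight analysis keeps a stable gene order. The per-gene minima and
#' ranges are retained for [inverse_minmax()].
#'
#' @param expr An [expression_matrix()] with `scale_state = "log_normalized"`.
#' @param verbose Emit a message when constant genes are encountered.
#' @return A unit-scaled [expression_matrix()] carrying a `scaling` attribute.
#' @export
minmax_scale <- function(expr, verbose = TRUE) {
  .assert(inherits(expr, "expression_matrix"), "expr must be an expression_matrix")
  .assert(expr$scale_state == "log_normalized",
          "minmax_scale expects log_normalized input")
  mins <- apply(expr$values, 2L, min)
  maxs <- apply(expr$values, 2L, max)
  rng <- maxs - mins
  constant <- rng == 0
  if (any(constant)) {
    .msg(sprintf("minmax_scale: %d constant gene(s) mapped to 0", sum(constant)),
         verbose = verbose)
  }
  denom <- ifelse(constant, 1, rng)
  scaled <- sweep(sweep(expr$values, 2L, mins, "-"), 2L, denom, "/")
  scaled[, constant] <- 0
  out <- expression_matrix(scaled, gene_names = expr$gene_names,
                           cell_ids = expr$cell_ids, labels = expr$labels,
                           scale_state = "unit_scaled")
  attr(out, "scaling") <- list(min = mins, range = rng, constant = constant)
  out
}

#' Invert a min-max scaling
#'
#' @param expr A unit-scaled [expression_matrix()] produced by [minmax_scale()].
#' @return An [expression_matrix()] on the original log-normalized scale.
#'   Constant genes are restored to their original constant value.
#' @export
inverse_minmax <- function(expr) {
  sc <- attr(expr, "scaling")
  .assert(!is.null(sc), "expr carries no scaling attribute")
  values <- sweep(sweep(expr$values, 2L, ifelse(sc$constant, 0, sc$range), "*"),
                  2L, sc$min, "+")
  expression_matrix(values, gene_names = expr$gene_names, cell_ids = expr$cell_ids,
                    labels = expr$labels, scale_state = "log_normalized")
}

#' Write per-cell labels as a two-column CSV
#' @param labels Vector of labels, one per cell.
#' @param cell_ids Cell identifiers.
#' @param path Output path.
#' @export
write_labels <- function(labels, cell_ids, path) {
  utils::write.csv(data.frame(cell_id = cell_ids, label = labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-cell labels written by [write_labels()]
#' @param path CSV path with columns `cell_id,label`.
#' @return Named vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$label, df$cell_id)
}
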