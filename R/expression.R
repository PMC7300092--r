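#' Expression matrix container
#'
#' Bundles a cells x genes matrix of expression values with gene names,
#' cell identifiers, optional cell labels and a record of its scale state.
#' The modelling functions expect `scale_state = "unit_scaled"`, produced by
#' [minmax_scale()] from log-normalized input.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param gene_names Character vector, one per column. Defaults to existing
#'   column names or `gene_1 ... gene_k`.
#' @param cell_ids Character vector, one per row. Defaults to existing row
#'   names or `cell_1 ... cell_N`.
#' @param labels Optional per-cell labels (factor or atomic vector).
#' @param scale_state Either `"log_normalized"` (raw input scale) or
#'   `"unit_scaled"` (per-gene min-max scaled to `[0, 1]`).
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_names = NULL, cell_ids = NULL,
                              labels = NULL,
                              scale_state = c("log_normalized", "unit_scaled")) {
  scale_state <- match.arg(scale_state)
  values <- as.matrix(values)
  .assert(is.numeric(values), "expression values must be numeric")
  .assert(!anyNA(values), "expression matrix contains missing values")
  if (is.null(gene_names)) {
    gene_names <- colnames(values)
    if (is.null(gene_names)) gene_names <- sprintf("gene_%d", seq_len(ncol(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(values)))
  }
  .assert(length(gene_names) == ncol(values),
          "gene_names length does not match number of columns")
  .assert(length(cell_ids) == nrow(values),
          "cell_ids length does not match number of rows")
  if (!is.null(labels)) {
    .assert(length(labels) == nrow(values),
            "labels length does not match number of cells")
  }
  if (scale_state == "unit_scaled") {
    .assert(min(values) >= 0 && max(values) <= 1,
            "unit_scaled expression must lie in [0, 1]")
  }
  dimnames(values) <- list(cell_ids, gene_names)
  structure(
    list(values = values, gene_names = gene_names, cell_ids = cell_ids,
         labels = labels, scale_state = scale_state),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values), x$scale_state))
  if (!is.null(x$labels)) {
    cat("labels:", paste(utils::head(names(table(x$labels)), 8), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
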