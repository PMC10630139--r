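#' Construct an expression dataset
#'
#' Bundles a cells x genes expression matrix with a binary treatment label and
#' optional per-cell annotations. This is the common input container for
#' [sccot()] and the simulation / evaluation helpers.
#'
#' @param values Numeric matrix, cells in rows and genes in columns. Raw counts
#'   or log1p-normalized values; state which via `counts`.
#' @param treatment Binary vector (0/1, logical, or a two-level factor) of
#'   length `nrow(values)`; 1 marks treated cells.
#' @param counts Logical; `TRUE` when `values` holds raw counts (the default
#'   auto-detects integer-valued matrices).
#' @param cell_labels Optional per-cell categorical annotation (e.g. cell type).
#' @param batch Optional per-cell batch label.
#' @param gene_ids Optional character vector of gene identifiers.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, treatment, counts = NULL,
                               cell_labels = NULL, batch = NULL,
                               gene_ids = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("expression values must be finite")
  z <- as_binary_treatment(treatment)
  if (length(z) != nrow(values))
    stop("treatment length must equal the number of cells (rows)")
  if (!any(z == 0) || !any(z == 1))
    stop("both treatment groups must be non-empty")
  if (is.null(counts)) {
    counts <- all(values >= 0) && all(values == round(values))
  }
  if (counts && (any(values < 0) || any(values != round(values))))
    stop("counts = TRUE but values are not nonnegative integers")
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  }
  colnames(values) <- gene_ids
  if (!is.null(cell_labels)) {
    cell_labels <- as.factor(cell_labels)
    stopifnot(length(cell_labels) == nrow(values))
  }
  if (!is.null(batch)) {
    batch <- as.factor(batch)
    stopifnot(length(batch) == nrow(values))
  }
  structure(list(values = values, treatment = z, counts = counts,
                 cell_labels = cell_labels, batch = batch,
                 gene_ids = gene_ids),
            class = "expression_dataset")
}

as_binary_treatment <- function(treatment) {
  if (is.factor(treatment) || is.character(treatment)) {
    lev <- sort(unique(as.character(treatment)))
    if (length(lev) != 2L)
      stop("treatment must have exactly two levels; found: ",
           paste(lev, collapse = ", "))
    z <- as.integer(as.character(treatment) == lev[2L])
    attr(z, "levels") <- lev
    return(z)
  }
  z <- as.integer(treatment)
  if (!all(z %in% c(0L, 1L))) stop("treatment must be binary {0,1}")
  z
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d cells x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$counts) "counts" else "log-normalized"))
  cat(sprintf("  treatment: %d control / %d treated\n",
              sum(x$treatment == 0), sum(x$treatment == 1)))
  if (!is.null(x$cell_labels))
    cat("  cell_labels:", nlevels(x$cell_labels), "levels\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# Subset cells, keeping annotations in step.
subset_cells <- function(ds, idx) {
  expression_dataset(ds$values[idx, , drop = FALSE], ds$treatment[idx],
                     counts = ds$counts,
                     cell_labels = if (!is.null(ds$cell_labels)) droplevels(ds$cell_labels[idx]),
                     batch = if (!is.null(ds$batch)) droplevels(ds$batch[idx]),
                     gene_ids = ds$gene_ids)
}
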