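#' Read an expression dataset from disk
#'
#' Supports a cells x genes CSV (numeric matrix with cell row names) or a
#' MatrixMarket directory (`matrix.mtx` + `barcodes.tsv` + `features.tsv`,
#' genes x cells as written by common pipelines, transposed on read). The
#' treatment label comes from a cell-metadata CSV (`obs`, first column = cell
#' barcode) via `treatment_key`; the level equal to `control_label` becomes
#' 0. With more than two levels, `treated_label` must pick the treated arm
#' and other cells are dropped. h5ad input is not supported by this package;
#' export to MTX or CSV first.
#'
#' @param path CSV file or MTX directory.
#' @param format `"csv"` or `"mtx_dir"` (`"h5ad"` errors with guidance).
#' @param obs Path to the cell-metadata CSV (optional for CSV input if
#'   `treatment_key` is a column of the expression file; required for MTX).
#' @param treatment_key Metadata column holding the condition label.
#' @param control_label Level treated as control.
#' @param treated_label Level treated as treated (required when the key has
#'   more than two levels).
#' @param genes_as_rows For CSV input, set `TRUE` when genes are rows.
#' @param normalize Apply library-size + log1p normalization on read.
#' @return An [expression_dataset()]. Remaining metadata columns are kept in
#'   attribute `"obs"`.
#' @export
read_expression <- function(path, format = c("csv", "mtx_dir", "h5ad"),
                            obs = NULL, treatment_key, control_label,
                            treated_label = NULL, genes_as_rows = FALSE,
                            normalize = FALSE) {
  format <- match.arg(format)
  if (format == "h5ad")
    stop("h5ad input is not supported; export to MTX or CSV first")
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (format == "csv") {
    raw <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    mat <- as.matrix(raw)
    if (genes_as_rows) mat <- t(mat)
    storage.mode(mat) <- "double"
    meta <- if (!is.null(obs))
      utils::read.csv(obs, row.names = 1L, check.names = FALSE) else NULL
  } else {
    mfile <- file.path(path, "matrix.mtx")
    bfile <- file.path(path, "barcodes.tsv")
    ffile <- file.path(path, "features.tsv")
    for (f in c(mfile, bfile, ffile))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mfile)
    barcodes <- readLines(bfile)
    features <- utils::read.delim(ffile, header = FALSE)[[1L]]
    mat <- t(as.matrix(m))
    dimnames(mat) <- list(barcodes, features)
    if (is.null(obs)) {
      ofile <- file.path(path, "obs.csv")
      if (!file.exists(ofile))
        stop("cell metadata required: pass obs= or provide obs.csv")
      obs <- ofile
    }
    meta <- utils::read.csv(obs, row.names = 1L, check.names = FALSE)
  }
  if (is.null(meta)) stop("cell metadata (obs) with the treatment column is required")
  meta <- meta[rownames(mat), , drop = FALSE]
  if (!treatment_key %in% colnames(meta))
    stop("treatment column '", treatment_key, "' not found in metadata")
  cond <- as.character(meta[[treatment_key]])
  lev <- sort(unique(cond))
  if (!control_label %in% lev)
    stop("control label '", control_label, "' not present; levels: ",
         paste(lev, collapse = ", "))
  other <- setdiff(lev, control_label)
  if (length(other) > 1L) {
    if (is.null(treated_label))
      stop("treatment column has levels {", paste(lev, collapse = ", "),
           "}; pass treated_label to disambiguate")
    if (!treated_label %in% other) stop("treated label not present")
    keep <- cond %in% c(control_label, treated_label)
    mat <- mat[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    cond <- cond[keep]
    other <- treated_label
  }
  z <- as.integer(cond == other)
  vals <- mat
  is_counts <- all(vals >= 0) && all(vals == round(vals))
  if (normalize) {
    if (!is_counts) warning("normalize requested on non-count input")
    vals <- lognormalize(vals)
    is_counts <- FALSE
  }
  ds <- expression_dataset(vals, z, counts = is_counts,
                           cell_labels = if ("cell_type" %in% colnames(meta))
                             factor(meta$cell_type),
                           batch = if ("batch" %in% colnames(meta))
                             factor(meta$batch))
  attr(ds, "obs") <- meta
  attr(ds, "normalized_on_read") <- normalize
  ds
}

#' Write an expression dataset as a MatrixMarket directory
#'
#' Writes `matrix.mtx` (genes x cells), `barcodes.tsv`, `features.tsv`, and
#' `obs.csv` (treatment plus any labels), the layout [read_expression()]
#' round-trips.
#'
#' @param ds An [expression_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_expression_mtx <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(ds$values), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  cells <- rownames(ds$values)
  if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(ds$values)))
  writeLines(cells, file.path(dir, "barcodes.tsv"))
  writeLines(ds$gene_ids, file.path(dir, "features.tsv"))
  obs <- data.frame(row.names = cells, treatment = ds$treatment)
  if (!is.null(ds$cell_labels)) obs$cell_type <- as.character(ds$cell_labels)
  if (!is.null(ds$batch)) obs$batch <- as.character(ds$batch)
  utils::write.csv(obs, file.path(dir, "obs.csv"))
  invisible(dir)
}

#' Write fit results to a directory
#'
#' Writes the confounder embedding, the ITE matrix, the per-component
#' dependence coefficients, the matching plan as explicit sparse triplets
#' (`control_index`, `treated_index`, `mass`; 0-based indices; masses sum to
#' 1), and a JSON run log with every resolved configuration field.
#'
#' @param fit A fitted `sccot` object.
#' @param dir Output directory.
#' @param plan_min_mass Triplets below this mass are omitted from the sparse
#'   plan file (default 0 keeps everything).
#' @export
write_results <- function(fit, dir, plan_min_mass = 0) {
  stopifnot(inherits(fit, "sccot"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$confounder,
                   file.path(dir, "confounder_embedding.csv"),
                   row.names = FALSE)
  utils::write.csv(as.matrix(fit$ite), file.path(dir, "ite.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(component = seq_along(fit$decomposition$coefficients),
               coefficient = fit$decomposition$coefficients,
               confounder = seq_along(fit$decomposition$coefficients) %in%
                 fit$decomposition$confounder_idx),
    file.path(dir, "component_coefficients.csv"), row.names = FALSE)
  M <- fit$plan$plan
  nz <- which(M > plan_min_mass, arr.ind = TRUE)
  utils::write.csv(
    data.frame(control_index = nz[, 1L] - 1L,
               treated_index = nz[, 2L] - 1L,
               mass = M[nz]),
    file.path(dir, "plan_triplets.csv"), row.names = FALSE)
  log <- c(fit$config,
           list(n_control = length(fit$control_index),
                n_treated = length(fit$treated_index),
                n_genes = ncol(fit$expr),
                plan_converged = fit$plan$converged,
                plan_iterations = fit$plan$iterations))
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back an ITE matrix written by [write_results()]
#' @param dir Results directory.
#' @return Numeric matrix.
#' @export
read_ite <- function(dir) {
  as.matrix(utils::read.csv(file.path(dir, "ite.csv"), check.names = FALSE))
}

#' Highly variable gene selection by mean/dispersion thresholds
#'
#' Standard mean-dispersion filtering on log1p-normalized input: gene means
#' and dispersions (variance/mean) are computed on the de-logged values, the
#' log dispersion is z-scored within 20 mean bins, and genes pass when
#' `min_mean < log1p(mean) < max_mean` and the normalized dispersion exceeds
#' `min_disp`. The default thresholds (0.0125, 3, 0.5) are the conventional
#' preprocessing choice for this kind of analysis.
#'
#' @param lognorm Log1p-normalized cells x genes matrix.
#' @param min_mean,max_mean,min_disp Threshold parameters.
#' @return Logical vector over genes (TRUE = highly variable).
#' @export
highly_variable_genes <- function(lognorm, min_mean = 0.0125, max_mean = 3,
                                  min_disp = 0.5) {
  x <- expm1(as.matrix(lognorm))
  mu <- colMeans(x)
  v <- apply(x, 2L, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  logmu <- log1p(mu)
  ldisp <- log(pmax(disp, 1e-12))
  n_bins <- max(1L, min(20L, length(mu) %/% 15L))
  bins <- cut(logmu,
              breaks = unique(quantile(logmu, probs = seq(0, 1, 1 / n_bins))),
              include.lowest = TRUE)
  global_sd <- sd(ldisp)
  norm_disp <- ldisp
  for (b in levels(bins)) {
    sel <- !is.na(bins) & bins == b
    if (sum(sel) < 2L) { norm_disp[sel] <- 0; next }
    mu_b <- stats::median(ldisp[sel]); sd_b <- sd(ldisp[sel])
    if (!is.finite(sd_b) || sd_b == 0) sd_b <- max(global_sd, 1e-8)
    norm_disp[sel] <- (ldisp[sel] - mu_b) / sd_b
  }
  logmu > min_mean & logmu < max_mean & norm_disp > min_disp
}
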