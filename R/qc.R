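#' Quality-control filtering of a methylation dataset
#'
#' Applies the standard array QC rules in order: (1) entries whose detection
#' P value exceeds `detection_threshold` are set missing; (2) probes listed
#' in `snp_probe_ids` are removed (SNP-harbouring probes); (3) probes listed
#' in `drop_probe_ids` are removed; (4) probes whose missing fraction
#' exceeds `max_missing` are removed. The operation is idempotent.
#'
#' @param dataset A [methylation_dataset()].
#' @param detection_threshold Detection-P cutoff in (0, 1); entries above it
#'   are treated as missing (default 0.01).
#' @param max_missing Maximum tolerated per-probe missing fraction
#'   (default 0.05).
#' @param snp_probe_ids Character vector of probes to exclude as
#'   SNP-harbouring (an explicit list: CpG-SNP annotation alone does not
#'   trigger removal).
#' @param drop_probe_ids Additional probes to exclude.
#' @return A list with `dataset` (filtered) and `report`, a `qc_report`
#'   with per-rule exclusion counts and the ids removed by each rule.
#' @export
apply_qc <- function(dataset, detection_threshold = 0.01, max_missing = 0.05,
                     snp_probe_ids = character(), drop_probe_ids = character()) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  if (detection_threshold <= 0 || detection_threshold >= 1)
    stop("detection_threshold must lie in (0, 1)")
  if (max_missing < 0 || max_missing > 1)
    stop("max_missing must lie in [0, 1]")

  vals <- dataset$values
  n_detp_masked <- 0L
  if (!is.null(dataset$detection_p)) {
    mask <- !is.na(dataset$detection_p) & dataset$detection_p > detection_threshold
    n_detp_masked <- sum(mask & !is.na(vals))
    vals[mask] <- NA_real_
  }

  snp_removed <- intersect(rownames(vals), snp_probe_ids)
  listed_removed <- setdiff(intersect(rownames(vals), drop_probe_ids),
                            snp_removed)
  keep <- setdiff(rownames(vals), c(snp_removed, listed_removed))
  vals <- vals[keep, , drop = FALSE]

  miss_frac <- rowMeans(is.na(vals))
  miss_removed <- rownames(vals)[miss_frac > max_missing]
  keep <- setdiff(rownames(vals), miss_removed)

  out <- dataset
  out$values <- vals[keep, , drop = FALSE]
  if (!is.null(out$detection_p))
    out$detection_p <- out$detection_p[keep, , drop = FALSE]
  if (!is.null(out$annotation))
    out$annotation <- out$annotation[match(keep, out$annotation$cpg_id), ,
                                     drop = FALSE]

  report <- structure(list(
    n_input = nrow(dataset$values),
    n_retained = length(keep),
    entries_masked_detection_p = n_detp_masked,
    excluded = list(snp = snp_removed, listed = listed_removed,
                    missingness = miss_removed),
    counts = c(snp = length(snp_removed), listed = length(listed_removed),
               missingness = length(miss_removed)),
    detection_threshold = detection_threshold,
    max_missing = max_missing), class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d probes in, %d retained\n", x$n_input, x$n_retained))
  cat(sprintf("  entries masked at detection P > %g: %d\n",
              x$detection_threshold, x$entries_masked_detection_p))
  cat(sprintf("  excluded: %d SNP-harbouring, %d listed, %d with > %g%% missing\n",
              x$counts[["snp"]], x$counts[["listed"]],
              x$counts[["missingness"]], 100 * x$max_missing))
  invisible(x)
}

#' Regional mean methylation phenotype
#'
#' Averages non-missing values over all probes annotated to the requested
#' gene group(s), producing one phenotype per sample. Presets: `"promoter"`
#' is TSS200 plus TSS1500; `"body"` is Body.
#'
#' @param dataset A [methylation_dataset()] with annotation (or pass
#'   `annotation`).
#' @param groups Character vector of gene groups, or the preset names
#'   `"promoter"` / `"body"`.
#' @param annotation Optional annotation overriding the dataset's.
#' @return Named numeric vector, one mean per sample.
#' @export
region_mean <- function(dataset, groups, annotation = dataset$annotation) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  if (is.null(annotation)) stop("probe annotation is required")
  groups <- switch(paste(groups, collapse = "+"),
                   promoter = c("TSS200", "TSS1500"),
                   body = "Body",
                   groups)
  ids <- annotation$cpg_id[annotation$gene_group %in% groups]
  ids <- intersect(rownames(dataset$values), ids)
  if (!length(ids)) stop("no probes annotated to group(s): ",
                         paste(groups, collapse = ", "))
  colMeans(dataset$values[ids, , drop = FALSE], na.rm = TRUE)
}

#' Residualise methylation on blood cell composition
#'
#' Per CpG, ordinary least squares of the M value on an intercept plus the
#' six blood cell-type proportions (CD8T, CD4T, Bcell, Mono, Gran, NK);
#' returns the residuals, preserving missing entries. If the proportion
#' columns are exactly collinear with the intercept (proportions summing to
#' one), trailing proportion columns are dropped until the design has full
#' rank, with a warning naming the dropped columns.
#'
#' @param m_matrix CpG x sample matrix of M values (or a
#'   [methylation_dataset()], returned as a dataset).
#' @param sheet Sample sheet containing the six proportion columns; rows
#'   matched to columns of `m_matrix` by `sample_id`.
#' @return Residual matrix (or dataset) of the same shape; per-CpG residual
#'   means over the samples used in each fit are zero.
#' @export
adjust_cell_composition <- function(m_matrix, sheet) {
  if (inherits(m_matrix, "MethylationDataset")) {
    out <- m_matrix
    if (out$scale != "M") stop("cell adjustment expects M-scale values")
    out$values <- adjust_cell_composition(out$values, sheet)
    return(out)
  }
  sheet <- validate_sample_sheet(sheet)
  miss_cells <- setdiff(.CELL_TYPES, names(sheet))
  if (length(miss_cells)) stop("sample sheet missing cell proportions: ",
                               paste(miss_cells, collapse = ", "))
  idx <- match(colnames(m_matrix), sheet$sample_id)
  if (anyNA(idx)) stop("samples absent from sheet: ",
                       paste(colnames(m_matrix)[is.na(idx)], collapse = ", "))
  props <- as.matrix(sheet[idx, .CELL_TYPES])
  if (anyNA(props)) stop("cell proportions must be complete for all samples")
  X <- cbind(intercept = 1, props)
  # drop trailing proportion columns until full column rank
  while (qr(X)$rank < ncol(X) && ncol(X) > 1) {
    warning("design rank-deficient; dropping cell column '",
            colnames(X)[ncol(X)], "'")
    X <- X[, -ncol(X), drop = FALSE]
  }
  res <- m_matrix
  complete_rows <- !apply(is.na(m_matrix), 1L, any)
  if (any(complete_rows)) {
    fit <- stats::lm.fit(X, t(m_matrix[complete_rows, , drop = FALSE]))
    res[complete_rows, ] <- t(fit$residuals)
  }
  for (i in which(!complete_rows)) {
    ok <- !is.na(m_matrix[i, ])
    if (sum(ok) > ncol(X))
      res[i, ok] <- stats::lm.fit(X[ok, , drop = FALSE],
                                  m_matrix[i, ok])$residuals
    # else: too few observations to adjust; left as-is (all downstream
    # stages re-check completeness per pair)
  }
  res
}
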