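# Full per-CpG scan over both waves: QC -> cell adjustment -> intraclass
# correlations -> univariate model selection per wave -> cross-wave
# significance overlap -> bivariate model on overlapping hits -> optional
# MZ-only replication ranking.

#' Run the per-CpG twin-model scan
#'
#' Executes the complete discovery pipeline on a methylation dataset and a
#' twin sample sheet: (1) detection-P / SNP-probe / missingness QC;
#' (2) optional residualisation on the six blood-cell proportions;
#' (3) per-CpG, per-wave MZ/DZ intraclass correlations with the Fisher z
#' zygosity test; (4) per-CpG, per-wave univariate model selection with
#' standardized components of the final model; (5) significance flags
#' (a quantity is significant when 0 is outside its 2.5-97.5% confidence
#' interval), recorded for a2, for heritability (h2; narrow or broad per
#' the final model's family) and for c2, with their cross-wave overlaps;
#' (6) the bivariate two-wave model on CpGs with significant heritability
#' at both waves (or all CpGs with `bivariate_all = TRUE`); (7) optional
#' MZ-only ICC replication ranking on
#' an independent cohort. A CpG whose model fit fails is reported with
#' missing values; it does not abort the scan. The scan is deterministic
#' given its inputs.
#'
#' @param dataset A [methylation_dataset()] (beta datasets are converted to
#'   M values).
#' @param sheet Sample sheet covering the dataset's samples.
#' @param detection_threshold,max_missing,snp_probe_ids,drop_probe_ids QC
#'   settings, see [apply_qc()].
#' @param adjust_cells Residualise on cell proportions when the sheet has
#'   them (default `TRUE`).
#' @param alpha LRT parsimony threshold for model selection.
#' @param min_pairs Minimum complete pairs per zygosity per fit.
#' @param bivariate_family Family for the bivariate stage (default `"AE"`).
#' @param bivariate_all Fit the bivariate model for every CpG instead of
#'   only the overlapping-significant ones.
#' @param replication Optional `list(dataset =, sheet =)` for the MZ-only
#'   replication ranking.
#' @param seed Recorded in the manifest (the scan itself draws no random
#'   numbers).
#' @return A `twin_scan` object with data.frame elements `icc`,
#'   `selection`, `heritability`, `flags`, `bivariate`, `replication`,
#'   plus `counts`, `qc_report` and `config`.
#' @export
run_scan <- function(dataset, sheet,
                     detection_threshold = 0.01, max_missing = 0.05,
                     snp_probe_ids = character(), drop_probe_ids = character(),
                     adjust_cells = TRUE, alpha = 0.05, min_pairs = 5,
                     bivariate_family = "AE", bivariate_all = FALSE,
                     replication = NULL, seed = NA_integer_) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  sheet <- validate_sample_sheet(sheet)
  dataset <- as_m_dataset(dataset)

  qc <- apply_qc(dataset, detection_threshold, max_missing,
                 snp_probe_ids, drop_probe_ids)
  ds <- qc$dataset
  if (nrow(ds$values) == 0) stop("no CpGs remain after QC")
  sheet <- sheet[sheet$sample_id %in% colnames(ds$values), ]

  vals <- ds$values
  if (adjust_cells && all(.CELL_TYPES %in% names(sheet)))
    vals <- adjust_cell_composition(vals, sheet)

  waves <- sort(unique(sheet$wave))
  adj <- methylation_dataset(vals, scale = "M", annotation = ds$annotation)

  icc_tab <- do.call(rbind, lapply(waves, function(w) {
    tab <- icc_by_zygosity(adj, sheet, wave = w)
    cbind(wave = w, tab)
  }))

  sel_rows <- list(); her_rows <- list()
  for (cg in rownames(vals)) {
    for (w in waves) {
      sel <- tryCatch(select_twin_model(vals[cg, ], sheet, wave = w,
                                        min_pairs = min_pairs, alpha = alpha),
                      error = function(e) NULL)
      if (is.null(sel)) {
        sel_rows[[length(sel_rows) + 1L]] <- data.frame(
          cpg_id = cg, wave = w, aic_ACE = NA_real_, aic_ADE = NA_real_,
          aic_AE = NA_real_, aic_CE = NA_real_, aic_DE = NA_real_,
          aic_E = NA_real_, bfm = NA_character_, bnm = NA_character_,
          lrt_stat = NA_real_, lrt_p = NA_real_, final = NA_character_,
          reason = NA_character_, stringsAsFactors = FALSE)
        her_rows[[length(her_rows) + 1L]] <- data.frame(
          cpg_id = cg, wave = w, model = NA_character_, a2 = NA_real_,
          a2_low = NA_real_, a2_high = NA_real_, c2 = NA_real_,
          c2_low = NA_real_, c2_high = NA_real_, d2 = NA_real_,
          d2_low = NA_real_, d2_high = NA_real_, e2 = NA_real_,
          e2_low = NA_real_, e2_high = NA_real_, h2 = NA_real_,
          h2_low = NA_real_, h2_high = NA_real_, sense = NA_character_,
          n_mz = NA_integer_, n_dz = NA_integer_, stringsAsFactors = FALSE)
        next
      }
      std <- standardize(sel$fits[[sel$final]])
      aic <- sel$aic
      sel_rows[[length(sel_rows) + 1L]] <- data.frame(
        cpg_id = cg, wave = w, aic_ACE = aic[["ACE"]], aic_ADE = aic[["ADE"]],
        aic_AE = aic[["AE"]], aic_CE = aic[["CE"]], aic_DE = aic[["DE"]],
        aic_E = aic[["E"]], bfm = sel$bfm, bnm = sel$bnm,
        lrt_stat = sel$lrt_stat, lrt_p = sel$lrt_p, final = sel$final,
        reason = sel$reason, stringsAsFactors = FALSE)
      fit <- sel$fits[[sel$final]]
      her_rows[[length(her_rows) + 1L]] <- data.frame(
        cpg_id = cg, wave = w, model = sel$final,
        a2 = std$estimates[["A"]], a2_low = std$ci["A", 1],
        a2_high = std$ci["A", 2],
        c2 = std$estimates[["C"]], c2_low = std$ci["C", 1],
        c2_high = std$ci["C", 2],
        d2 = std$estimates[["D"]], d2_low = std$ci["D", 1],
        d2_high = std$ci["D", 2],
        e2 = std$estimates[["E"]], e2_low = std$ci["E", 1],
        e2_high = std$ci["E", 2],
        h2 = std$h2, h2_low = std$h2_ci[1], h2_high = std$h2_ci[2],
        sense = std$sense, n_mz = fit$n_mz, n_dz = fit$n_dz,
        stringsAsFactors = FALSE)
    }
  }
  selection <- do.call(rbind, sel_rows)
  heritability <- do.call(rbind, her_rows)

  # significance: 0 excluded from the 2.5-97.5% CI of the standardized
  # component (estimates are non-negative, so this is lower bound > 0)
  sig <- function(lo) !is.na(lo) & is.finite(lo) & lo > 0
  her <- heritability
  flags <- data.frame(cpg_id = rownames(vals), stringsAsFactors = FALSE)
  for (w in waves) {
    hw <- her[her$wave == w, ]
    i <- match(flags$cpg_id, hw$cpg_id)
    flags[[paste0("sig_a2_w", w)]] <- sig(hw$a2_low[i])
    # heritability significance: narrow (a2) or broad (a2 + d2) per the
    # final model's family -- the discovery notion for "genetic" sites
    flags[[paste0("sig_h2_w", w)]] <- sig(hw$h2_low[i])
    flags[[paste0("sig_c2_w", w)]] <- sig(hw$c2_low[i])
  }
  if (length(waves) == 2) {
    flags$overlap_a2 <- flags$sig_a2_w1 & flags$sig_a2_w2
    flags$overlap_h2 <- flags$sig_h2_w1 & flags$sig_h2_w2
    flags$overlap_c2 <- flags$sig_c2_w1 & flags$sig_c2_w2
  }

  bivariate <- NULL
  if (length(waves) == 2) {
    biv_ids <- if (bivariate_all) flags$cpg_id
               else flags$cpg_id[which(flags$overlap_h2)]
    if (length(biv_ids)) {
      bivariate <- do.call(rbind, lapply(biv_ids, function(cg) {
        bf <- tryCatch(fit_bivariate(vals[cg, ], sheet,
                                     family = bivariate_family,
                                     min_pairs = min_pairs),
                       error = function(e) NULL)
        if (is.null(bf)) return(data.frame(
          cpg_id = cg, family = bivariate_family, r_g = NA_real_,
          r_g_low = NA_real_, r_g_high = NA_real_, r_e = NA_real_,
          r_e_low = NA_real_, r_e_high = NA_real_, a2_w1 = NA_real_,
          a2_w2 = NA_real_, e2_w1 = NA_real_, e2_w2 = NA_real_,
          loglik = NA_real_, converged = FALSE, stringsAsFactors = FALSE))
        data.frame(cpg_id = cg, family = bf$family,
                   r_g = bf$estimates[["r_g"]], r_g_low = bf$ci["r_g", 1],
                   r_g_high = bf$ci["r_g", 2],
                   r_e = bf$estimates[["r_e"]], r_e_low = bf$ci["r_e", 1],
                   r_e_high = bf$ci["r_e", 2],
                   a2_w1 = bf$estimates[["a2_w1"]],
                   a2_w2 = bf$estimates[["a2_w2"]],
                   e2_w1 = bf$estimates[["e2_w1"]],
                   e2_w2 = bf$estimates[["e2_w2"]],
                   loglik = bf$loglik, converged = bf$converged,
                   stringsAsFactors = FALSE)
      }))
    }
  }

  repl <- if (!is.null(replication))
    rank_mz_correlations(as_m_dataset(replication$dataset), replication$sheet)

  scan <- structure(list(icc = icc_tab, selection = selection,
                         heritability = heritability, flags = flags,
                         bivariate = bivariate, replication = repl,
                         annotation = ds$annotation, qc_report = qc$report,
                         config = list(detection_threshold = detection_threshold,
                                       max_missing = max_missing,
                                       alpha = alpha, min_pairs = min_pairs,
                                       bivariate_family = bivariate_family,
                                       bivariate_all = bivariate_all,
                                       adjust_cells = adjust_cells,
                                       seed = seed)),
                    class = "twin_scan")
  scan$counts <- summarize_counts(scan)
  scan
}

#' @export
print.twin_scan <- function(x, ...) {
  cat(sprintf("twin_scan: %d CpGs, waves %s\n",
              nrow(x$flags), paste(unique(x$heritability$wave), collapse = ",")))
  print(utils::head(as.data.frame(t(unlist(x$counts)))))
  invisible(x)
}

#' Significance counts from a scan
#'
#' Counts of CpGs with significant a2 / c2 per wave (0 outside the
#' 2.5-97.5% CI of the standardized component), their cross-wave overlaps,
#' and the number of bivariate fits whose a2 is significant at both waves.
#'
#' @param scan A `twin_scan` from [run_scan()].
#' @return A named list of counts.
#' @export
summarize_counts <- function(scan) {
  stopifnot(inherits(scan, "twin_scan"))
  fl <- scan$flags
  cnt <- function(col) if (col %in% names(fl)) sum(fl[[col]], na.rm = TRUE)
                       else NA_integer_
  out <- list(sig_a2_w1 = cnt("sig_a2_w1"), sig_a2_w2 = cnt("sig_a2_w2"),
              overlap_a2 = cnt("overlap_a2"),
              sig_h2_w1 = cnt("sig_h2_w1"), sig_h2_w2 = cnt("sig_h2_w2"),
              overlap_h2 = cnt("overlap_h2"),
              sig_c2_w1 = cnt("sig_c2_w1"), sig_c2_w2 = cnt("sig_c2_w2"),
              overlap_c2 = cnt("overlap_c2"))
  # bivariate-significant: the cross-wave genetic correlation's CI
  # excludes 0
  out$bivariate_significant <- if (is.null(scan$bivariate)) NA_integer_
  else sum(is.finite(scan$bivariate$r_g_low) & scan$bivariate$r_g_low > 0)
  out
}

#' Heritability heatmap matrix
#'
#' CpG x wave matrix of h2 estimates from the final models, rows ordered
#' by genomic position when the annotation provides one; missing fits stay
#' `NA`.
#'
#' @param scan A `twin_scan`.
#' @return Numeric matrix, rownames = CpG ids, colnames = `wave1`, ...
#' @export
heritability_heatmap_matrix <- function(scan) {
  stopifnot(inherits(scan, "twin_scan"))
  her <- scan$heritability
  waves <- sort(unique(her$wave))
  ids <- unique(her$cpg_id)
  ann <- scan$annotation
  if (!is.null(ann) && "position" %in% names(ann)) {
    ord <- order(ann$position[match(ids, ann$cpg_id)])
    ids <- ids[ord]
  }
  m <- matrix(NA_real_, length(ids), length(waves),
              dimnames = list(ids, paste0("wave", waves)))
  for (wi in seq_along(waves)) {
    hw <- her[her$wave == waves[wi], ]
    m[, wi] <- hw$h2[match(ids, hw$cpg_id)]
  }
  m
}

#' Write scan tables and a run manifest
#'
#' Writes `icc_table.csv`, `model_selection.csv`, `heritability.csv`,
#' `top_hits.csv` (rows significant for a2 or c2 in any wave),
#' `bivariate.csv`, `heatmap.csv`, `replication_rank.csv` (when present)
#' and `manifest.json` into `dir`. Output is byte-identical across re-runs
#' on identical inputs.
#'
#' @param scan A `twin_scan`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "twin_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) if (!is.null(df))
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(scan$icc, "icc_table.csv")
  wr(scan$selection, "model_selection.csv")
  wr(scan$heritability, "heritability.csv")
  fl <- scan$flags
  sig_any <- Reduce(`|`, lapply(grep("^sig_", names(fl), value = TRUE),
                                function(cn) fl[[cn]] %in% TRUE))
  top <- scan$heritability[scan$heritability$cpg_id %in% fl$cpg_id[sig_any], ]
  wr(top, "top_hits.csv")
  wr(fl, "flags.csv")
  wr(scan$bivariate, "bivariate.csv")
  hm <- heritability_heatmap_matrix(scan)
  wr(data.frame(cpg_id = rownames(hm), hm, check.names = FALSE), "heatmap.csv")
  wr(scan$replication, "replication_rank.csv")
  manifest <- list(package = "twinmeth",
                   version = as.character(utils::packageVersion("twinmeth")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = scan$config,
                   counts = scan$counts,
                   n_cpgs = nrow(scan$flags),
                   qc = list(n_input = scan$qc_report$n_input,
                             n_retained = scan$qc_report$n_retained,
                             excluded = as.list(scan$qc_report$counts)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
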