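#' Intraclass correlation for twin pairs
#'
#' One-way random-effects ANOVA intraclass correlation, ICC(1,1), for
#' groups of size 2: `r = (MSB - MSW) / (MSB + MSW)`, where MSB and MSW are
#' the between- and within-pair mean squares. Negative estimates are
#' reported as-is (not truncated at zero). The confidence interval uses the
#' Fisher z transform of r with standard error `1 / sqrt(n - 3/2)` (the
#' large-sample value for an intraclass correlation estimated from n pairs
#' of size 2).
#'
#' @param pairs Two-column numeric matrix or data.frame, one row per pair;
#'   rows with any missing value are dropped.
#' @param conf_level Confidence level (default 0.95).
#' @param zygosity Optional label stored in the result.
#' @param cpg_id Optional id stored in the result.
#' @return A list of class `icc_result`: `r`, `n_pairs`, `ci_low`,
#'   `ci_high`, `msb`, `msw`, `zygosity`, `cpg_id`.
#' @export
icc <- function(pairs, conf_level = 0.95, zygosity = NA_character_,
                cpg_id = NA_character_) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have exactly two columns")
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  n <- nrow(pairs)
  if (n < 3) stop("at least 3 complete pairs are required")
  gm <- mean(pairs)
  pm <- rowMeans(pairs)
  msb <- 2 * sum((pm - gm)^2) / (n - 1)
  msw <- sum((pairs - pm)^2) / n
  if (msb + msw <= 0) stop("zero total variance; ICC undefined")
  r <- (msb - msw) / (msb + msw)
  se_z <- 1 / sqrt(n - 1.5)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  # clamp before atanh only for the degenerate |r| = 1 case
  zr <- atanh(max(-1 + 1e-12, min(1 - 1e-12, r)))
  structure(list(r = r, n_pairs = n, ci_low = tanh(zr - q * se_z),
                 ci_high = tanh(zr + q * se_z), msb = msb, msw = msw,
                 zygosity = zygosity, cpg_id = cpg_id),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.4f (%.4f-%.4f), %d pairs%s\n", x$r, x$ci_low,
              x$ci_high, x$n_pairs,
              if (is.na(x$zygosity)) "" else paste0(" [", x$zygosity, "]")))
  invisible(x)
}

#' Fisher z test for the difference of two correlations
#'
#' Tests `r1 = r2` using the Fisher transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`, with a
#' two-sided p value from the standard normal. For twin-pair intraclass
#' correlations, `n` is the number of pairs (the pair is the sampling
#' unit).
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return A list of class `fisher_z_result`: `z`, `p`, `r1`, `r2`, `n1`,
#'   `n2`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must be strictly inside (-1, 1)")
  if (n1 < 4 || n2 < 4) stop("need at least 4 observations per group")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)),
                 r1 = r1, r2 = r2, n1 = n1, n2 = n2),
            class = "fisher_z_result")
}

#' @export
print.fisher_z_result <- function(x, ...) {
  cat(sprintf("Fisher z = %.4f, two-sided p = %.4g (r1 = %.3f, n1 = %d; r2 = %.3f, n2 = %d)\n",
              x$z, x$p, x$r1, x$n1, x$r2, x$n2))
  invisible(x)
}

# Complete within-pair duples for one CpG at one wave / one zygosity.
# Returns an n x 2 matrix (member 1, member 2).
.pair_duples <- function(y, sheet, zygosity, wave = NULL) {
  sel <- sheet$zygosity == zygosity
  if (!is.null(wave)) sel <- sel & sheet$wave == wave
  sub <- sheet[sel, ]
  y <- y[match(sub$sample_id, names(y))]
  m1 <- sub$member == 1
  i2 <- match(sub$pair_id[m1], sub$pair_id[sub$member == 2])
  out <- cbind(y[which(m1)], y[which(!m1)][i2])
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Per-CpG intraclass correlations by zygosity
#'
#' Computes MZ and DZ ICCs for each CpG at a given wave plus the Fisher z
#' test for the zygosity difference (the classical indication of genetic
#' influence: rMZ > rDZ).
#'
#' @param dataset A [methylation_dataset()] (M scale recommended).
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param wave Wave to analyse, or `NULL` for a single-wave sheet.
#' @return A `data.frame`: cpg_id, r_mz, mz_ci_low/high, n_mz, r_dz,
#'   dz_ci_low/high, n_dz, z, p.
#' @export
icc_by_zygosity <- function(dataset, sheet, wave = NULL) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  sheet <- validate_sample_sheet(sheet)
  rows <- lapply(rownames(dataset$values), function(cg) {
    y <- dataset$values[cg, ]
    res <- tryCatch({
      imz <- icc(.pair_duples(y, sheet, "MZ", wave), zygosity = "MZ",
                 cpg_id = cg)
      idz <- icc(.pair_duples(y, sheet, "DZ", wave), zygosity = "DZ",
                 cpg_id = cg)
      zt <- fisher_z_test(imz$r, imz$n_pairs, idz$r, idz$n_pairs)
      data.frame(cpg_id = cg, r_mz = imz$r, mz_ci_low = imz$ci_low,
                 mz_ci_high = imz$ci_high, n_mz = imz$n_pairs,
                 r_dz = idz$r, dz_ci_low = idz$ci_low,
                 dz_ci_high = idz$ci_high, n_dz = idz$n_pairs,
                 z = zt$z, p = zt$p, stringsAsFactors = FALSE)
    }, error = function(e) data.frame(cpg_id = cg, r_mz = NA_real_,
                                      mz_ci_low = NA_real_, mz_ci_high = NA_real_,
                                      n_mz = NA_integer_, r_dz = NA_real_,
                                      dz_ci_low = NA_real_, dz_ci_high = NA_real_,
                                      n_dz = NA_integer_, z = NA_real_,
                                      p = NA_real_, stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, rows)
}

#' Rank CpGs by monozygotic-pair intraclass correlation
#'
#' The replication device for an MZ-only cohort: sites under strong genetic
#' control must show high within-MZ-pair correlation even where
#' heritability itself cannot be estimated. Ties are broken by `cpg_id` so
#' the ordering is stable.
#'
#' @inheritParams icc_by_zygosity
#' @return A `data.frame` sorted by decreasing ICC: cpg_id, r, ci_low,
#'   ci_high, n_pairs, rank.
#' @export
rank_mz_correlations <- function(dataset, sheet, wave = NULL) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  sheet <- validate_sample_sheet(sheet)
  rows <- lapply(rownames(dataset$values), function(cg) {
    res <- tryCatch(icc(.pair_duples(dataset$values[cg, ], sheet, "MZ", wave),
                        zygosity = "MZ", cpg_id = cg),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(cpg_id = cg, r = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, n_pairs = NA_integer_,
                 stringsAsFactors = FALSE)
    else
      data.frame(cpg_id = cg, r = res$r, ci_low = res$ci_low,
                 ci_high = res$ci_high, n_pairs = res$n_pairs,
                 stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$r, tab$cpg_id, na.last = TRUE), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
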