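#' Per-CpG ground truth for the cohort simulator
#'
#' Builds the truth table consumed by [simulate_cohort()]. Variance
#' components are on the M-value-squared scale. C and D are confounded in
#' the twin design, so at most one of them may be nonzero per wave at a
#' site. Wave-2 components default to the wave-1 values; cross-wave factor
#' correlations default to 1 for A/C/D (stable influences) and 0 for E.
#'
#' @param cpg_id Character vector of CpG ids.
#' @param A,C,D,E Wave-1 variance components (recycled).
#' @param A2,C2,D2,E2 Optional wave-2 components (default: same as wave 1).
#' @param r_g,r_c,r_d,r_e Cross-wave factor correlations in `[-1, 1]`.
#' @param is_cpg_snp Logical; site has a SNP at the interrogated CpG.
#' @param maf Minor-allele frequency in `[0, 0.5]` for CpG-SNP sites.
#' @param gt_means Length-3 numeric (or 3-column matrix, one row per site):
#'   M-value mean per minor-allele count 0/1/2 at CpG-SNP sites.
#' @param baseline_mean Baseline M value added to every draw.
#' @return A `data.frame`, one row per CpG.
#' @export
cpg_truth <- function(cpg_id, A = 0, C = 0, D = 0, E = 1,
                      A2 = NULL, C2 = NULL, D2 = NULL, E2 = NULL,
                      r_g = 1, r_c = 1, r_d = 1, r_e = 0,
                      is_cpg_snp = FALSE, maf = 0,
                      gt_means = c(0, 0, 0), baseline_mean = 0) {
  n <- length(cpg_id)
  gt <- if (is.matrix(gt_means)) gt_means else
    matrix(gt_means, n, 3, byrow = TRUE)
  tr <- data.frame(cpg_id = as.character(cpg_id),
                   A = rep_len(A, n), C = rep_len(C, n),
                   D = rep_len(D, n), E = rep_len(E, n),
                   A2 = rep_len(if (is.null(A2)) A else A2, n),
                   C2 = rep_len(if (is.null(C2)) C else C2, n),
                   D2 = rep_len(if (is.null(D2)) D else D2, n),
                   E2 = rep_len(if (is.null(E2)) E else E2, n),
                   r_g = rep_len(r_g, n), r_c = rep_len(r_c, n),
                   r_d = rep_len(r_d, n), r_e = rep_len(r_e, n),
                   is_cpg_snp = rep_len(is_cpg_snp, n),
                   maf = rep_len(maf, n),
                   gt_mean0 = gt[, 1], gt_mean1 = gt[, 2], gt_mean2 = gt[, 3],
                   baseline_mean = rep_len(baseline_mean, n),
                   stringsAsFactors = FALSE)
  validate_cpg_truth(tr)
}

validate_cpg_truth <- function(truth) {
  comp <- as.matrix(truth[c("A", "C", "D", "E", "A2", "C2", "D2", "E2")])
  if (any(comp < 0)) stop("variance components must be non-negative")
  if (any(truth$C > 0 & truth$D > 0) || any(truth$C2 > 0 & truth$D2 > 0))
    stop("C and D are confounded in the twin design; at most one may be nonzero per site")
  cors <- as.matrix(truth[c("r_g", "r_c", "r_d", "r_e")])
  if (any(abs(cors) > 1)) stop("cross-wave correlations must lie in [-1, 1]")
  if (any(truth$maf < 0 | truth$maf > 0.5)) stop("maf must lie in [0, 0.5]")
  if (anyDuplicated(truth$cpg_id)) stop("cpg_id values must be unique")
  truth
}

#' Simulation configuration for a twin methylation cohort
#'
#' Defines the cohort design: pair counts per zygosity, one or two waves
#' (the second wave `wave_gap` years after the first), per-CpG ground truth,
#' demographic structure, blood-cell composition, covariate effects and
#' detection-P missingness. Defaults mirror an aging-twin design: first-wave
#' ages uniform on 73-82 years, a 10-year gap between waves, like-sex pairs
#' with an even sex ratio, and typical whole-blood mean cell fractions.
#'
#' @param n_mz_pairs,n_dz_pairs Pair counts (at least one pair in total).
#' @param truth Truth table from [cpg_truth()].
#' @param n_waves 1 or 2.
#' @param age_range Length-2 numeric, years; wave-1 age drawn uniformly,
#'   identical within a pair.
#' @param wave_gap Years between waves (added to age at wave 2).
#' @param sex_ratio Fraction of male pairs (pairs are like-sex).
#' @param age_effect,sex_effect Mean-model effects on the M scale
#'   (per year of age; male vs female shift).
#' @param cell_proportion_means Named length-6 non-negative fractions
#'   summing to 1 (CD8T, CD4T, Bcell, Mono, Gran, NK).
#' @param cell_concentration Dirichlet concentration for per-sample cell
#'   fractions (larger = tighter around the means).
#' @param cell_effect_sizes `NULL`, or an n_cpg x 6 matrix of per-CpG
#'   regression coefficients of M on the cell fractions.
#' @param missing_rate Expected fraction of entries given detection
#'   P > 0.01.
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_mz_pairs, n_dz_pairs, truth, n_waves = 2,
                              age_range = c(73, 82), wave_gap = 10,
                              sex_ratio = 0.5,
                              age_effect = 0.005, sex_effect = 0.05,
                              cell_proportion_means = c(
                                CD8T = 0.10, CD4T = 0.15, Bcell = 0.05,
                                Mono = 0.07, Gran = 0.60, NK = 0.03),
                              cell_concentration = 200,
                              cell_effect_sizes = NULL,
                              missing_rate = 0, seed = 1L) {
  if (n_mz_pairs < 0 || n_dz_pairs < 0 || n_mz_pairs + n_dz_pairs < 1)
    stop("need at least one twin pair")
  if (!n_waves %in% 1:2) stop("n_waves must be 1 or 2")
  truth <- validate_cpg_truth(truth)
  if (any(cell_proportion_means < 0) ||
      abs(sum(cell_proportion_means) - 1) > 1e-8)
    stop("cell_proportion_means must be non-negative and sum to 1")
  if (!is.null(cell_effect_sizes)) {
    cell_effect_sizes <- as.matrix(cell_effect_sizes)
    if (nrow(cell_effect_sizes) != nrow(truth) || ncol(cell_effect_sizes) != 6)
      stop("cell_effect_sizes must be n_cpg x 6")
  }
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]")
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs), truth = truth,
                 n_waves = as.integer(n_waves), age_range = age_range,
                 wave_gap = wave_gap, sex_ratio = sex_ratio,
                 age_effect = age_effect, sex_effect = sex_effect,
                 cell_proportion_means = cell_proportion_means,
                 cell_concentration = cell_concentration,
                 cell_effect_sizes = cell_effect_sizes,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

# Theoretical pair covariance implied by one truth row.
# Variable order: 1 wave -> (twin1, twin2); 2 waves ->
# (twin1.w1, twin1.w2, twin2.w1, twin2.w2).
.truth_pair_cov <- function(tr, zygosity, n_waves) {
  kA <- if (zygosity == "MZ") 1 else 0.5
  kD <- if (zygosity == "MZ") 1 else 0.25
  V1 <- tr$A + tr$C + tr$D + tr$E
  ct1 <- kA * tr$A + tr$C + kD * tr$D          # cross-twin, wave 1
  if (n_waves == 1) {
    sig <- matrix(c(V1, ct1, ct1, V1), 2, 2)
  } else {
    V2 <- tr$A2 + tr$C2 + tr$D2 + tr$E2
    ct2 <- kA * tr$A2 + tr$C2 + kD * tr$D2     # cross-twin, wave 2
    wt <- tr$r_g * sqrt(tr$A * tr$A2) + tr$r_c * sqrt(tr$C * tr$C2) +
      tr$r_d * sqrt(tr$D * tr$D2) + tr$r_e * sqrt(tr$E * tr$E2)
    xx <- kA * tr$r_g * sqrt(tr$A * tr$A2) + tr$r_c * sqrt(tr$C * tr$C2) +
      kD * tr$r_d * sqrt(tr$D * tr$D2)         # cross-twin cross-wave
    sig <- matrix(c(V1, wt, ct1, xx,
                    wt, V2, xx, ct2,
                    ct1, xx, V1, wt,
                    xx, ct2, wt, V2), 4, 4)
  }
  sig
}

# Sibling genotypes by explicit parental-allele transmission (exact IBD).
# Returns an n x 2 matrix of minor-allele counts (columns = co-twins).
.draw_pair_genotypes <- function(n, maf, zygosity) {
  if (n == 0) return(matrix(integer(), 0, 2))
  mother <- matrix(stats::rbinom(2 * n, 1, maf), n, 2)
  father <- matrix(stats::rbinom(2 * n, 1, maf), n, 2)
  pick <- function() cbind(mother[cbind(seq_len(n), sample(1:2, n, TRUE))],
                           father[cbind(seq_len(n), sample(1:2, n, TRUE))])
  g1 <- rowSums(pick())
  g2 <- if (zygosity == "MZ") g1 else rowSums(pick())
  cbind(g1, g2)
}

#' Simulate a twin methylation cohort with known ground truth
#'
#' Draws, for every CpG and twin pair, the 2-variable (one wave) or
#' 4-variable (two waves) methylation vector from a multivariate normal
#' whose covariance follows the classical twin model: total variance
#' A+C+D+E per wave; within-wave cross-twin covariance A+C+D (MZ) or
#' 0.5A+C+0.25D (DZ); cross-wave within-twin covariance
#' r_g sqrt(A1 A2) + r_c sqrt(C1 C2) + r_d sqrt(D1 D2) + r_e sqrt(E1 E2);
#' and cross-wave cross-twin covariance with the E term removed and the
#' A/D terms scaled by the zygosity coefficients. Age, sex and cell-
#' composition mean effects are added afterwards. CpG-SNP sites instead
#' receive a genotype-dependent mean: pair genotypes are drawn under
#' Hardy-Weinberg with explicit parental-allele transmission (MZ co-twins
#' share the genotype; DZ co-twins are full siblings), constant across
#' waves.
#'
#' @param config A [simulation_config()].
#' @return A list with `dataset` (M-scale [methylation_dataset()] with a
#'   detection-P matrix when `missing_rate > 0`, plus a generated probe
#'   annotation), `sheet` (sample sheet; one column/row per
#'   individual-wave), and `truth` (the truth table used).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tr <- config$truth
  n_cpg <- nrow(tr)
  nw <- config$n_waves
  d <- 2L * nw

  zyg <- c(rep("MZ", config$n_mz_pairs), rep("DZ", config$n_dz_pairs))
  n_pairs <- length(zyg)
  pair_id <- sprintf("%s%04d", zyg, c(seq_len(config$n_mz_pairs),
                                      seq_len(config$n_dz_pairs)))
  age1 <- stats::runif(n_pairs, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n_pairs, 1, config$sex_ratio)  # like-sex pairs

  # sample sheet: member varies fastest, then pair, then wave
  sheet <- do.call(rbind, lapply(seq_len(nw), function(w) {
    data.frame(sample_id = sprintf("%s_%d_w%d", rep(pair_id, each = 2),
                                   rep(1:2, n_pairs), w),
               pair_id = rep(pair_id, each = 2),
               member = rep(1:2, n_pairs),
               zygosity = rep(zyg, each = 2),
               wave = w,
               age = rep(age1, each = 2) + (w - 1) * config$wave_gap,
               sex = rep(sex, each = 2), stringsAsFactors = FALSE)
  }))
  n_samples <- nrow(sheet)

  # per-sample cell proportions: Dirichlet around the configured means
  alpha <- config$cell_proportion_means * config$cell_concentration
  gam <- matrix(stats::rgamma(n_samples * 6, shape = rep(alpha, each = n_samples)),
                n_samples, 6)
  props <- gam / rowSums(gam)
  colnames(props) <- .CELL_TYPES
  sheet <- cbind(sheet, as.data.frame(props))

  # column index of (pair p, member m, wave w) in the value matrix
  col_of <- function(m, w) (w - 1L) * 2L * n_pairs + 2L * (seq_len(n_pairs) - 1L) + m
  vals <- matrix(NA_real_, n_cpg, n_samples,
                 dimnames = list(tr$cpg_id, sheet$sample_id))
  is_mz <- zyg == "MZ"

  for (i in seq_len(n_cpg)) {
    row_i <- numeric(n_samples)
    for (z in c("MZ", "DZ")) {
      sel <- if (z == "MZ") is_mz else !is_mz
      nz <- sum(sel)
      if (nz == 0) next
      sig <- .truth_pair_cov(tr[i, ], z, nw)
      ch <- tryCatch(chol(sig), error = function(e)
        stop("implied ", z, " covariance for ", tr$cpg_id[i],
             " is not positive definite: ", conditionMessage(e)))
      draws <- matrix(stats::rnorm(nz * d), nz, d) %*% ch
      for (w in seq_len(nw)) for (m in 1:2) {
        # draw column order: (t1w1, t1w2, t2w1, t2w2) or (t1, t2)
        dc <- if (nw == 2) (m - 1L) * 2L + w else m
        row_i[col_of(m, w)[sel]] <- draws[, dc]
      }
    }
    row_i <- row_i + tr$baseline_mean[i]
    if (tr$is_cpg_snp[i]) {
      gt <- rbind(.draw_pair_genotypes(sum(is_mz), tr$maf[i], "MZ"),
                  .draw_pair_genotypes(sum(!is_mz), tr$maf[i], "DZ"))
      gt <- gt[order(c(which(is_mz), which(!is_mz))), , drop = FALSE]
      gmeans <- c(tr$gt_mean0[i], tr$gt_mean1[i], tr$gt_mean2[i])
      for (w in seq_len(nw)) for (m in 1:2)
        row_i[col_of(m, w)] <- row_i[col_of(m, w)] + gmeans[gt[, m] + 1L]
    }
    vals[i, ] <- row_i
  }

  # covariate mean effects, shared across CpGs for age/sex
  vals <- vals + matrix(config$age_effect * (sheet$age - mean(sheet$age)) +
                          config$sex_effect * sheet$sex,
                        n_cpg, n_samples, byrow = TRUE)
  if (!is.null(config$cell_effect_sizes))
    vals <- vals + config$cell_effect_sizes %*% t(props)

  ann <- data.frame(cpg_id = tr$cpg_id,
                    gene_group = "Body",
                    position = seq_len(n_cpg) * 1000L + 131e6,
                    is_cpg_snp = tr$is_cpg_snp, maf = tr$maf,
                    island_relation = "OpenSea",
                    stringsAsFactors = FALSE)
  ds <- methylation_dataset(vals, scale = "M", annotation = ann)
  if (config$missing_rate > 0)
    ds$detection_p <- simulate_detection_p(ds, config$missing_rate,
                                           seed = config$seed + 1L)
  list(dataset = ds, sheet = validate_sample_sheet(sheet), truth = tr)
}

#' Simulate a detection-P matrix
#'
#' Entries chosen uniformly at random with probability `missing_rate`
#' receive a detection P value above 0.01 (i.e. will be masked at the
#' default QC threshold); all other entries receive values at or below
#' 0.01.
#'
#' @param dataset A [methylation_dataset()] (only its dimensions are used).
#' @param missing_rate Fraction of entries to flag, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Numeric matrix of detection P values, same dimnames as the
#'   dataset values.
#' @export
simulate_detection_p <- function(dataset, missing_rate, seed = 1L) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  set.seed(seed)
  n <- length(dataset$values)
  flagged <- stats::runif(n) < missing_rate
  p <- numeric(n)
  p[flagged] <- 0.01 + stats::runif(sum(flagged)) * 0.99
  p[!flagged] <- stats::runif(sum(!flagged)) * 0.01
  matrix(p, nrow(dataset$values), ncol(dataset$values),
         dimnames = dimnames(dataset$values))
}

#' Write a simulated cohort to delimited text files
#'
#' Writes `methylation.csv` (CpGs x samples), `sample_sheet.csv`,
#' `truth.csv`, `annotation.csv`, optionally `detection_p.csv`, and
#' `config.yaml` into `dir`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param config Optional [simulation_config()] to record as YAML.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.csv(
    data.frame(cpg_id = rownames(m), m, check.names = FALSE),
    file.path(dir, f), row.names = FALSE)
  wm(cohort$dataset$values, "methylation.csv")
  if (!is.null(cohort$dataset$detection_p))
    wm(cohort$dataset$detection_p, "detection_p.csv")
  utils::write.csv(cohort$sheet, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$dataset$annotation, file.path(dir, "annotation.csv"),
                   row.names = FALSE)
  if (!is.null(config)) {
    cfg <- config
    cfg$truth <- NULL
    cfg$cell_effect_sizes <- NULL
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
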