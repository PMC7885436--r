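test_that("pure unique-environment truth gives uncorrelated co-twins", {
  s <- sim_one_cpg(10000, 10000, seed = 101, A = 0, C = 0, D = 0, E = 1)
  for (z in c("MZ", "DZ")) {
    d <- twinmeth:::.pair_duples(s$y, s$sheet, z, wave = 1)
    expect_lt(abs(cor(d[, 1], d[, 2])), 0.03)
  }
})

test_that("same config and seed reproduce the cohort bit-identically", {
  tr <- cpg_truth(c("a", "b"), A = c(0.5, 0), E = c(0.5, 1),
                  is_cpg_snp = c(FALSE, TRUE), maf = c(0, 0.3),
                  gt_means = c(-2, 0, 2))
  cfg <- simulation_config(50, 60, tr, n_waves = 2, missing_rate = 0.02,
                           seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$dataset$values, s2$dataset$values)
  expect_identical(s1$dataset$detection_p, s2$dataset$detection_p)
  expect_identical(s1$sheet, s2$sheet)
})

test_that("empirical pair covariance converges to the configured covariance", {
  tr <- cpg_truth("cg", A = 0.5, C = 0.2, E = 0.3, A2 = 0.4, C2 = 0.3,
                  E2 = 0.3, r_g = 0.8, r_c = 0.6, r_e = 0.1)
  cfg <- simulation_config(20000, 20000, tr, n_waves = 2, seed = 7,
                           age_effect = 0, sex_effect = 0)
  sim <- simulate_cohort(cfg)
  sh <- sim$sheet
  y <- sim$dataset$values[1, ]
  for (z in c("MZ", "DZ")) {
    pid <- unique(sh$pair_id[sh$zygosity == z])
    cols <- function(m, w) sprintf("%s_%d_w%d", pid, m, w)
    M <- cbind(y[cols(1, 1)], y[cols(1, 2)], y[cols(2, 1)], y[cols(2, 2)])
    emp <- cov(M)
    theo <- twinmeth:::.truth_pair_cov(tr[1, ], z, 2)
    # elementwise Monte-Carlo SE of a covariance is ~ sqrt((s_ii s_jj +
    # s_ij^2) / n); allow 3 SEs
    n <- length(pid)
    se <- sqrt((outer(diag(theo), diag(theo)) + theo^2) / n)
    expect_true(all(abs(emp - theo) < 3.5 * se))
  }
})

test_that("CpG-SNP sites obey Hardy-Weinberg and sibling genotype sharing", {
  maf <- 0.3
  tr <- cpg_truth("snp", A = 0, E = 0.05, is_cpg_snp = TRUE, maf = maf,
                  gt_means = c(-3, 0, 3))
  cfg <- simulation_config(8000, 8000, tr, n_waves = 1, seed = 5,
                           age_effect = 0, sex_effect = 0)
  sim <- simulate_cohort(cfg)
  y <- sim$dataset$values[1, ]
  # recover genotype from the well-separated means
  gt <- cut(y, c(-Inf, -1.5, 1.5, Inf), labels = FALSE) - 1L
  names(gt) <- names(y)
  freq <- tabulate(gt + 1L, 3) / length(gt)
  hw <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  expect_true(all(abs(freq - hw) < 0.02))
  sh <- sim$sheet
  for (z in c("MZ", "DZ")) {
    pid <- unique(sh$pair_id[sh$zygosity == z])
    g1 <- gt[sprintf("%s_1_w1", pid)]
    g2 <- gt[sprintf("%s_2_w1", pid)]
    if (z == "MZ") {
      expect_true(all(g1 == g2))
    } else {
      # full siblings: corr(g1, g2) = 1/2 under Mendelian transmission
      expect_equal(cor(g1, g2), 0.5, tolerance = 0.05)
      expect_true(any(g1 != g2))
    }
  }
})

test_that("beta values derived from simulated M stay strictly inside (0,1)", {
  tr <- cpg_truth(c("x", "y"), A = 0.8, E = 0.2, baseline_mean = c(-4, 4))
  sim <- simulate_cohort(simulation_config(200, 200, tr, seed = 3))
  b <- as_beta_dataset(sim$dataset)$values
  expect_true(all(b > 0 & b < 1))
})

test_that("detection-P generator hits the requested flag rate", {
  ds <- methylation_dataset(
    matrix(0, 100, 100, dimnames = list(sprintf("c%d", 1:100),
                                        sprintf("s%d", 1:100))), scale = "M")
  expect_true(all(simulate_detection_p(ds, 0, seed = 1) <= 0.01))
  expect_true(all(simulate_detection_p(ds, 1, seed = 1) > 0.01))
  p <- simulate_detection_p(ds, 0.05, seed = 8)
  n_flag <- sum(p > 0.01)
  # binomial: 500 +/- 3 * sqrt(10000 * .05 * .95) ~ 500 +/- 65
  expect_true(abs(n_flag - 500) < 66)
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(cpg_truth("x", C = 0.3, D = 0.3), "confounded")
  expect_error(cpg_truth("x", A = -0.1), "non-negative")
  expect_error(cpg_truth("x", r_g = 1.2), "\\[-1, 1\\]")
  tr <- cpg_truth("x", A = 0.5, E = 0.5)
  expect_error(simulation_config(0, 0, tr), "at least one")
  expect_error(simulation_config(10, 10, tr, missing_rate = 2), "missing_rate")
  expect_error(simulation_config(10, 10, tr,
                                 cell_proportion_means = rep(0.2, 6)),
               "sum to 1")
})

test_that("written cohort files round-trip through the readers", {
  tr <- cpg_truth(c("cg_a", "cg_b"), A = 0.5, E = 0.5)
  cfg <- simulation_config(10, 10, tr, seed = 2, missing_rate = 0.05)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir, config = cfg)
  ds <- read_methylation_matrix(file.path(dir, "methylation.csv"),
                                scale = "M",
                                detection_p_path = file.path(dir, "detection_p.csv"))
  expect_equal(ds$values, sim$dataset$values, tolerance = 1e-12)
  expect_equal(ds$detection_p, sim$dataset$detection_p, tolerance = 1e-12)
  sh <- read_sample_sheet(file.path(dir, "sample_sheet.csv"))
  expect_equal(sh$sample_id, sim$sheet$sample_id)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  ann <- read_probe_annotation(file.path(dir, "annotation.csv"))
  expect_equal(ann$cpg_id, c("cg_a", "cg_b"))
})
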