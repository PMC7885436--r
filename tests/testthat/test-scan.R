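# small planted-signal cohort reused across scan tests
scan_fixture <- function(seed = 301, n_mz = 120, n_dz = 180) {
  ids <- sprintf("cg%03d", 1:12)
  A <- c(rep(0.9, 2), rep(0, 10))
  C <- c(rep(0, 4), rep(0.65, 2), rep(0, 6))
  E <- 1 - A - C
  tr <- cpg_truth(ids, A = A, C = C, E = E)
  cfg <- simulation_config(n_mz, n_dz, tr, n_waves = 2, seed = seed)
  simulate_cohort(cfg)
}

test_that("the scan flags planted heritable and shared-environment sites", {
  sim <- scan_fixture()
  scan <- suppressWarnings(run_scan(sim$dataset, sim$sheet))
  fl <- scan$flags
  expect_true(all(fl$overlap_a2[1:2]))
  expect_true(all(fl$overlap_h2[1:2]))
  expect_true(all(fl$overlap_c2[5:6]))
  expect_false(any(fl$overlap_a2[5:12]))
  # bivariate stage ran on the overlapping-heritability sites only
  expect_setequal(scan$bivariate$cpg_id, fl$cpg_id[fl$overlap_h2])
  expect_true(all(scan$bivariate$r_g > 0.9))
})

test_that("summary counts are consistent with the per-CpG flag table", {
  sim <- scan_fixture(seed = 302)
  scan <- suppressWarnings(run_scan(sim$dataset, sim$sheet))
  fl <- scan$flags
  cnt <- summarize_counts(scan)
  expect_equal(cnt$sig_a2_w1, sum(fl$sig_a2_w1, na.rm = TRUE))
  expect_equal(cnt$sig_a2_w2, sum(fl$sig_a2_w2, na.rm = TRUE))
  expect_equal(cnt$overlap_a2, sum(fl$sig_a2_w1 & fl$sig_a2_w2, na.rm = TRUE))
  expect_equal(cnt$overlap_h2, sum(fl$sig_h2_w1 & fl$sig_h2_w2, na.rm = TRUE))
  expect_equal(cnt$overlap_c2, sum(fl$sig_c2_w1 & fl$sig_c2_w2, na.rm = TRUE))
  # overlap flag is exactly the conjunction of the per-wave flags
  expect_equal(fl$overlap_a2, fl$sig_a2_w1 & fl$sig_a2_w2)
})

test_that("heatmap matrix carries per-wave h2 ordered by position", {
  sim <- scan_fixture(seed = 303)
  scan <- suppressWarnings(run_scan(sim$dataset, sim$sheet))
  hm <- heritability_heatmap_matrix(scan)
  expect_equal(dim(hm), c(12, 2))
  expect_equal(colnames(hm), c("wave1", "wave2"))
  her <- scan$heritability
  for (w in 1:2) {
    hw <- her[her$wave == w, ]
    expect_equal(unname(hm[, w]), hw$h2[match(rownames(hm), hw$cpg_id)])
  }
  # planted heritable rows dominate, pure-noise rows sit near zero
  expect_true(all(hm[c("cg001", "cg002"), ] > 0.6))
  expect_true(all(hm[sprintf("cg%03d", 7:12), ] < 0.4, na.rm = TRUE))
})

test_that("scan outputs are byte-identical across re-runs", {
  sim <- scan_fixture(seed = 304, n_mz = 40, n_dz = 60)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scan(suppressWarnings(run_scan(sim$dataset, sim$sheet)), d1)
  write_scan(suppressWarnings(run_scan(sim$dataset, sim$sheet)), d2)
  for (f in list.files(d1)) {
    expect_true(file.exists(file.path(d2, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_true("manifest.json" %in% list.files(d1))
})

test_that("an empty post-QC dataset aborts with a message", {
  vals <- matrix(rnorm(40), 2, 20,
                 dimnames = list(c("cg1", "cg2"), flat_sheet(5, 5)$sample_id))
  dp <- matrix(1, 2, 20, dimnames = dimnames(vals))
  ds <- methylation_dataset(vals, scale = "M", detection_p = dp)
  expect_error(run_scan(ds, flat_sheet(5, 5)), "no CpGs remain")
})

test_that("one degenerate CpG does not abort the scan", {
  sim <- scan_fixture(seed = 305, n_mz = 40, n_dz = 60)
  vals <- sim$dataset$values[1:4, ]
  # constant row: no twin information; ICC is undefined for it
  vals[3, ] <- 5
  ds <- methylation_dataset(vals, scale = "M")
  scan <- suppressWarnings(run_scan(ds, sim$sheet))
  expect_equal(nrow(scan$flags), 4)
  # raw ICC on the unadjusted constant row is undefined
  expect_error(icc(cbind(rep(5, 40), rep(5, 40))), "zero total variance")
  # the degenerate row is reported as missing or as pure unique environment
  her3 <- scan$heritability[scan$heritability$cpg_id == "cg003", ]
  expect_true(all(is.na(her3$h2) | her3$h2 == 0))
  expect_false(any(scan$flags$overlap_a2[3], na.rm = TRUE))
  # the remaining CpGs are fitted normally
  her1 <- scan$heritability[scan$heritability$cpg_id == "cg001", ]
  expect_true(all(is.finite(her1$h2)))
})

test_that("replication ranking puts planted heritable sites on top", {
  sim <- scan_fixture(seed = 306)
  # MZ-only replication cohort with the same truth
  repl_cfg <- simulation_config(246, 0, sim$truth, n_waves = 1, seed = 999)
  repl <- simulate_cohort(repl_cfg)
  scan <- suppressWarnings(run_scan(sim$dataset, sim$sheet,
                                    replication = list(dataset = repl$dataset,
                                                       sheet = repl$sheet)))
  expect_setequal(scan$replication$cpg_id[1:2], c("cg001", "cg002"))
})
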