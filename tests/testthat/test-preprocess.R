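make_dataset <- function(n_cpg, n_samp, seed = 1, detection_p = NULL,
                         annotation = NULL) {
  set.seed(seed)
  vals <- matrix(rnorm(n_cpg * n_samp), n_cpg, n_samp,
                 dimnames = list(sprintf("cg%05d", seq_len(n_cpg)),
                                 sprintf("s%03d", seq_len(n_samp))))
  methylation_dataset(vals, scale = "M", detection_p = detection_p,
                      annotation = annotation)
}

test_that("detection-P masking and missingness exclusion follow the QC rules", {
  n_cpg <- 10; n_samp <- 40
  dp <- matrix(0.001, n_cpg, n_samp)
  # probes 1-2: 10% of entries above threshold -> excluded at max_missing 5%
  dp[1:2, 1:4] <- 0.5
  ds <- make_dataset(n_cpg, n_samp, detection_p = dp)
  out <- apply_qc(ds, detection_threshold = 0.01, max_missing = 0.05)
  expect_equal(nrow(out$dataset$values), 8)
  expect_equal(unname(out$report$counts[["missingness"]]), 2)
  expect_false(any(c("cg00001", "cg00002") %in% rownames(out$dataset$values)))

  # identity when nothing exceeds the threshold and no probe lists given
  clean <- make_dataset(5, 10, detection_p = matrix(0.005, 5, 10))
  out2 <- apply_qc(clean)
  expect_identical(out2$dataset$values, clean$values)
  expect_equal(out2$report$n_retained, 5)
})

test_that("SNP-probe and listed-probe exclusion are reported per rule", {
  ds <- make_dataset(12, 20)
  out <- apply_qc(ds, snp_probe_ids = c("cg00003", "cg00007", "not_present"),
                  drop_probe_ids = "cg00001")
  expect_equal(out$report$counts[["snp"]], 2)
  expect_equal(out$report$counts[["listed"]], 1)
  expect_equal(nrow(out$dataset$values), 9)
})

test_that("apply_qc is idempotent and a 176-probe fixture retains 170", {
  # fixture mirroring the array-QC setting: 176 probes, 6 with excessive
  # detection-P failures
  n_samp <- 50
  dp <- matrix(0.002, 176, n_samp)
  bad <- c(3, 40, 41, 100, 150, 176)
  dp[bad, 1:5] <- 0.9   # 10% missing > 5%
  ds <- make_dataset(176, n_samp, detection_p = dp)
  once <- apply_qc(ds)
  expect_equal(nrow(once$dataset$values), 170)
  twice <- apply_qc(once$dataset)
  expect_identical(twice$dataset$values, once$dataset$values)
  expect_equal(unname(twice$report$counts[["missingness"]]), 0)
  expect_error(apply_qc(ds, detection_threshold = 1.5), "detection_threshold")
})

test_that("region means average the requested annotation groups", {
  ann <- data.frame(
    cpg_id = sprintf("cg%05d", 1:170),
    gene_group = c(rep("TSS200", 11), rep("TSS1500", 12), "1stExon",
                   rep("Body", 144), rep("3'UTR", 2)),
    position = seq_len(170), stringsAsFactors = FALSE)
  ds <- make_dataset(170, 8, annotation = ann)
  body_ids <- ann$cpg_id[ann$gene_group == "Body"]
  expect_length(body_ids, 144)
  expect_equal(region_mean(ds, "body"),
               colMeans(ds$values[body_ids, ]))
  prom <- region_mean(ds, "promoter")
  prom_ids <- ann$cpg_id[ann$gene_group %in% c("TSS200", "TSS1500")]
  expect_length(prom_ids, 23)
  expect_equal(prom, colMeans(ds$values[prom_ids, ]))
  # single-probe group equals that probe's values
  one <- region_mean(ds, "1stExon")
  expect_equal(one, ds$values["cg00024", ])
  expect_error(region_mean(ds, "5'UTR"), "no probes")
})

test_that("cell-composition adjustment removes cell signal and centres residuals", {
  set.seed(42)
  n <- 120
  sheet <- flat_sheet(30, 30)
  props <- matrix(rgamma(n * 6, 5), n, 6)
  props <- props / rowSums(props)
  colnames(props) <- c("CD8T", "CD4T", "Bcell", "Mono", "Gran", "NK")
  sheet <- cbind(sheet, as.data.frame(props))
  m <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("cg", 1:5), sheet$sample_id))
  m[1, ] <- 2 * props[, "CD8T"] + rnorm(n, sd = 0.1)

  res <- suppressWarnings(adjust_cell_composition(m, sheet))
  expect_equal(dim(res), dim(m))
  # residuals orthogonal to the regressor and centred
  expect_lt(abs(cor(res[1, ], props[, "CD8T"])), 1e-8)
  expect_lt(var(res[1, ]), var(m[1, ]))
  expect_equal(unname(rowMeans(res)), rep(0, 5), tolerance = 1e-8)
  # proportions sum to 1 -> rank-deficient with intercept -> warned drop
  expect_warning(adjust_cell_composition(m, sheet), "rank-deficient")
  # missing entries preserved, fit uses remaining samples
  m2 <- m; m2[2, 1:3] <- NA
  res2 <- suppressWarnings(adjust_cell_composition(m2, sheet))
  expect_true(all(is.na(res2[2, 1:3])))
  expect_equal(mean(res2[2, -(1:3)]), 0, tolerance = 1e-8)
})
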