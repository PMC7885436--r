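test_that("twin_loglik matches a dense multivariate-normal oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(31)
  n <- 10
  mk <- function() data.frame(y1 = rnorm(n), y2 = rnorm(n),
                              age1 = runif(n, 70, 80), age2 = runif(n, 70, 80),
                              sex1 = rbinom(n, 1, 0.5), sex2 = rbinom(n, 1, 0.5))
  pmz <- mk(); pdz <- mk()
  cases <- list(
    list(model = "ACE", par = c(a = 0.6, c = 0.4, e = 0.5)),
    list(model = "ADE", par = c(a = 0.5, d = 0.45, e = 0.6)),
    list(model = "AE",  par = c(a = 0.9, e = 0.3)),
    list(model = "E",   par = c(e = 0.8)))
  for (cs in cases) {
    params <- c(cs$par, intercept = 0.2, age = 0.01, sex = -0.3)
    ll <- twin_loglik(params, pmz, pdz, model = cs$model)
    v <- twinmeth:::.uni_variances(cs$par, names(cs$par))
    oracle <- 0
    for (z in c("MZ", "DZ")) {
      pr <- if (z == "MZ") pmz else pdz
      sig <- twinmeth:::.uni_sigma(v, z)
      for (i in seq_len(n)) {
        mu <- params[["intercept"]] + params[["age"]] * c(pr$age1[i], pr$age2[i]) +
          params[["sex"]] * c(pr$sex1[i], pr$sex2[i])
        oracle <- oracle + mvtnorm::dmvnorm(c(pr$y1[i], pr$y2[i]), mu, sig,
                                            log = TRUE)
      }
    }
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("E-only model reduces to the iid normal log-likelihood", {
  set.seed(5)
  n <- 15
  pmz <- data.frame(y1 = rnorm(n), y2 = rnorm(n))
  pdz <- data.frame(y1 = rnorm(n), y2 = rnorm(n))
  e <- 0.7; mu <- 0.1
  ll <- twin_loglik(c(e = e, intercept = mu), pmz, pdz, model = "E")
  ys <- c(pmz$y1, pmz$y2, pdz$y1, pdz$y2)
  expect_equal(ll, sum(dnorm(ys, mu, e, log = TRUE)), tolerance = 1e-10)
})

test_that("profiled fit agrees with the explicit likelihood at its optimum", {
  s <- sim_one_cpg(200, 200, seed = 17, A = 0.6, E = 0.4)
  fit <- fit_twin_model(s$y, s$sheet, "AE", wave = 1)
  pr <- lapply(c("MZ", "DZ"), function(z) {
    d <- twinmeth:::.twin_pairs(s$y, s$sheet, wave = 1)[[z]]
    data.frame(y1 = d$Y[, 1], y2 = d$Y[, 2], age1 = d$ages[, 1],
               age2 = d$ages[, 2], sex1 = d$sexes[, 1], sex2 = d$sexes[, 2])
  })
  params <- c(fit$theta, intercept = unname(fit$beta[["intercept"]]),
              age = unname(fit$beta[["age"]]), sex = unname(fit$beta[["sex"]]))
  expect_equal(twin_loglik(params, pr[[1]], pr[[2]], model = "AE"),
               fit$loglik, tolerance = 1e-8)
})

test_that("log-likelihoods are monotone across nested models", {
  for (seed in c(2, 3, 4)) {
    s <- sim_one_cpg(150, 150, seed = seed, A = 0.4, C = 0.3, E = 0.3)
    sel <- select_twin_model(s$y, s$sheet, wave = 1)
    ll <- vapply(sel$fits, function(f) f$loglik, numeric(1))
    expect_gte(ll[["ACE"]] - ll[["AE"]], -1e-6)
    expect_gte(ll[["ACE"]] - ll[["CE"]], -1e-6)
    expect_gte(ll[["AE"]] - ll[["E"]], -1e-6)
    expect_gte(ll[["ADE"]] - ll[["AE"]], -1e-6)
    # AIC bookkeeping: AIC = -2 loglik + 2k
    for (f in sel$fits)
      expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
  }
})

test_that("standardized components follow the heritability formulas", {
  # ACE: h2 narrow = A / (A + C + E)
  s <- sim_one_cpg(400, 400, seed = 11, A = 0.6, C = 0.2, E = 0.2)
  fit <- fit_twin_model(s$y, s$sheet, "ACE", wave = 1)
  std <- standardize(fit)
  v <- fit$variances
  expect_equal(sum(std$estimates), 1, tolerance = 1e-8)
  expect_equal(std$h2, unname(v[["A"]] / sum(v)))
  expect_equal(std$sense, "narrow")
  expect_equal(std$h2, unname(std$estimates[["A"]]))

  # ADE: h2 broad = (A + D) / (A + D + E)
  s2 <- sim_one_cpg(400, 400, seed = 12, A = 0.4, D = 0.3, E = 0.3)
  fit2 <- fit_twin_model(s2$y, s2$sheet, "ADE", wave = 1)
  std2 <- standardize(fit2)
  v2 <- fit2$variances
  expect_equal(std2$sense, "broad")
  expect_equal(std2$h2, unname((v2[["A"]] + v2[["D"]]) / sum(v2)))

  # E-only: degenerate zero-width intervals
  s3 <- sim_one_cpg(100, 100, seed = 13, E = 1)
  std3 <- standardize(fit_twin_model(s3$y, s3$sheet, "E", wave = 1))
  expect_equal(unname(std3$estimates), c(0, 0, 0, 1))
  expect_equal(unname(std3$ci[, 1]), c(0, 0, 0, 1))
  expect_equal(unname(std3$ci[, 2]), c(0, 0, 0, 1))
})

test_that("null data is recovered as E and AE truth as AE", {
  s <- sim_one_cpg(1000, 1000, seed = 23, E = 1)
  fit <- fit_twin_model(s$y, s$sheet, "AE", wave = 1)
  expect_lt(fit$variances[["A"]] / sum(fit$variances), 0.05)

  s2 <- sim_one_cpg(1500, 1500, seed = 24, A = 0.7, E = 0.3)
  std <- standardize(fit_twin_model(s2$y, s2$sheet, "AE", wave = 1))
  expect_equal(unname(std$estimates[["A"]]), 0.7, tolerance = 0.05)
})

test_that("selection applies the parsimony and min-AIC rules", {
  # strong A and C: nested models fail the LRT -> min-AIC keeps the BFM
  s <- sim_one_cpg(3000, 3000, seed = 41, A = 0.4, C = 0.4, E = 0.2)
  sel <- select_twin_model(s$y, s$sheet, wave = 1)
  expect_equal(sel$bfm, "ACE")
  expect_lt(sel$lrt_p, 0.05)
  expect_equal(sel$reason, "min-AIC")
  expect_equal(sel$final, "ACE")

  # AE truth: the LRT of AE against the full model passes -> parsimony
  s2 <- sim_one_cpg(800, 800, seed = 42, A = 0.6, E = 0.4)
  sel2 <- select_twin_model(s2$y, s2$sheet, wave = 1)
  expect_gt(sel2$lrt_p, 0.05)
  expect_equal(sel2$reason, "parsimony")
  expect_equal(sel2$final, sel2$bnm)
  expect_true(sel2$final %in% twinmeth:::.NESTED[[sel2$bfm]])
})

test_that("standardized components are invariant to affine data transforms", {
  s <- sim_one_cpg(300, 300, seed = 51, A = 0.5, C = 0.3, E = 0.2)
  f1 <- fit_twin_model(s$y, s$sheet, "ACE", wave = 1)
  f2 <- fit_twin_model(3 * s$y + 7, s$sheet, "ACE", wave = 1)
  expect_equal(standardize(f1)$estimates, standardize(f2)$estimates,
               tolerance = 1e-8)
  expect_equal(f1$variances * 9, f2$variances, tolerance = 1e-6)
})

test_that("too few pairs are rejected per the minimum-data rule", {
  s <- sim_one_cpg(6, 4, seed = 61, A = 0.5, E = 0.5)
  expect_error(fit_twin_model(s$y, s$sheet, "AE", wave = 1),
               "at least 5 complete pairs")
})
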