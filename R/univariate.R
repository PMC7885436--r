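# Univariate ACE/ADE twin models: likelihood, ML fitting, AIC/LRT model
# selection and standardized variance components with delta-method CIs.

.UNI_MODELS <- list(ACE = c("a", "c", "e"), ADE = c("a", "d", "e"),
                    AE = c("a", "e"), CE = c("c", "e"), DE = c("d", "e"),
                    E = "e")
.MODEL_ORDER <- c("ACE", "ADE", "AE", "CE", "DE", "E")
.NESTED <- list(ACE = c("AE", "CE", "E"), ADE = c("AE", "DE", "E"))

# Path coefficients -> variance components (A, C, D, E); variances are the
# squares of unconstrained reals, so non-negativity is structural.
.uni_variances <- function(theta, free) {
  v <- c(A = 0, C = 0, D = 0, E = 0)
  v[toupper(free)] <- theta^2
  v
}

# Zygosity-specific 2x2 covariance implied by variance components.
.uni_sigma <- function(v, zygosity) {
  V <- sum(v)
  cv <- if (zygosity == "MZ") v[["A"]] + v[["C"]] + v[["D"]]
        else 0.5 * v[["A"]] + v[["C"]] + 0.25 * v[["D"]]
  matrix(c(V, cv, cv, V), 2, 2)
}

#' Univariate twin-model log-likelihood
#'
#' Sum over twin pairs of bivariate-normal log densities under the
#' classical twin model: each pair has covariance
#' `[[V, cov_z], [cov_z, V]]` with `V = A + C + D + E` and cross-twin
#' covariance `A + C + D` (MZ) or `0.5 A + C + 0.25 D` (DZ); the mean of
#' each member is `intercept + beta_age * age + beta_sex * sex`. Components
#' absent from `model` are fixed at zero. Variance components are
#' parameterized as squared path coefficients.
#'
#' @param params Named numeric vector: path coefficients among `a`, `c`,
#'   `d`, `e` (those free in `model`) plus mean coefficients `intercept`
#'   and, if the pair data include them, `age` and `sex`.
#' @param pairs_mz,pairs_dz Data frames of complete pairs with columns
#'   `y1`, `y2` and optionally `age1`, `age2`, `sex1`, `sex2`. Either may
#'   be empty/`NULL`.
#' @param model One of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"DE"`, `"E"`.
#' @return The log-likelihood (scalar).
#' @export
twin_loglik <- function(params, pairs_mz, pairs_dz, model = "ACE") {
  model <- match.arg(model, .MODEL_ORDER)
  free <- .UNI_MODELS[[model]]
  v <- .uni_variances(params[free], free)
  ll <- 0
  for (z in c("MZ", "DZ")) {
    pr <- if (z == "MZ") pairs_mz else pairs_dz
    if (is.null(pr) || nrow(pr) == 0) next
    sig <- .uni_sigma(v, z)
    V <- sig[1, 1]; cv <- sig[1, 2]
    det <- V^2 - cv^2
    if (det <= 0 || V <= 0) stop("implied pair covariance is singular")
    mu1 <- params[["intercept"]] +
      (if ("age1" %in% names(pr)) params[["age"]] * pr$age1 else 0) +
      (if ("sex1" %in% names(pr)) params[["sex"]] * pr$sex1 else 0)
    mu2 <- params[["intercept"]] +
      (if ("age2" %in% names(pr)) params[["age"]] * pr$age2 else 0) +
      (if ("sex2" %in% names(pr)) params[["sex"]] * pr$sex2 else 0)
    r1 <- pr$y1 - mu1; r2 <- pr$y2 - mu2
    quad <- (V * (r1^2 + r2^2) - 2 * cv * r1 * r2) / det
    ll <- ll + sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * quad)
  }
  ll
}

# Moment-informed and grid starting values (path scale) for `free`
# components, given pooled total variance vt and observed rmz/rdz.
.uni_starts <- function(free, vt, rmz, rdz) {
  nf <- length(free)
  sq <- function(x) sqrt(pmax(x, 1e-4 * vt))
  starts <- list(rep(sq(vt / nf), nf))                 # equal split
  if (nf > 1) {
    for (i in seq_len(nf)) {                           # each dominant
      x <- rep(0.2 * vt / max(nf - 1, 1), nf)
      x[i] <- 0.8 * vt
      starts <- c(starts, list(sq(x)))
    }
    # method of moments from observed twin correlations
    a2 <- min(max(2 * (rmz - rdz), 0.02), 0.95)
    c2 <- min(max(2 * rdz - rmz, 0.02), 0.95)
    mm <- c(a = a2, c = c2, d = 0.05, e = max(1 - a2 - c2, 0.05))
    starts <- c(starts, list(sq(vt * mm[free])))
  }
  lapply(starts, function(s) stats::setNames(as.numeric(s), free))
}

#' Fit one univariate twin model by maximum likelihood
#'
#' Variance components are parameterized as squares of unconstrained path
#' coefficients and the mean coefficients (intercept, age, sex; constant
#' covariates are dropped) are profiled out by generalised least squares,
#' so the optimiser works in at most three dimensions. Optimisation runs
#' Nelder-Mead from a documented grid of starts (equal split, each
#' component dominant, method of moments from the observed twin
#' correlations) followed by a quasi-Newton polish.
#'
#' @param y Named numeric vector of phenotype values (names = sample ids),
#'   or a single-CpG row of a methylation matrix.
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param model One of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"DE"`, `"E"`.
#' @param wave Wave to analyse, or `NULL` for a single-wave sheet.
#' @param min_pairs Minimum complete pairs required per zygosity.
#' @param extra_starts Optional list of additional named start vectors
#'   (path scale); used internally to seed full models from nested fits.
#' @return A `twin_fit` object: model, loglik, aic, number of free
#'   parameters `k`, path coefficients `theta`, variance components
#'   `variances`, mean coefficients `beta`, convergence flag, pair counts.
#' @export
fit_twin_model <- function(y, sheet, model = "ACE", wave = NULL,
                           min_pairs = 5, extra_starts = NULL) {
  model <- match.arg(model, .MODEL_ORDER)
  sheet <- validate_sample_sheet(sheet)
  pairs <- .twin_pairs(y, sheet, wave)
  .fit_twin_model_prepared(pairs, model, min_pairs, extra_starts)
}

# Collapse d = 2 pair moments to the symmetric-covariance form: with
# W = [[w1, w2], [w2, w1]], X'WX = w1 (T11 + T22) + w2 (T12 + T21), etc.
.uni_compact <- function(mo) {
  p <- mo$p
  list(P = matrix(mo$T[, 1] + mo$T[, 4], p, p),
       Q = matrix(mo$T[, 2] + mo$T[, 3], p, p),
       U1 = mo$U[, 1] + mo$U[, 4], U2 = mo$U[, 2] + mo$U[, 3],
       S1 = mo$S[1] + mo$S[4], S2 = mo$S[2] + mo$S[3], n = mo$n)
}

# Closed-form profile negative log-likelihood for the univariate model:
# O(p^2) per evaluation, no matrix decompositions beyond one p x p solve.
.uni_negll <- function(theta, iA, iC, iD, iE, mzc, dzc) {
  A <- if (iA) theta[iA]^2 else 0
  C <- if (iC) theta[iC]^2 else 0
  D <- if (iD) theta[iD]^2 else 0
  E <- if (iE) theta[iE]^2 else 0
  V <- A + C + D + E
  cm <- A + C + D
  cd <- 0.5 * A + C + 0.25 * D
  detm <- V * V - cm * cm
  detd <- V * V - cd * cd
  if (V <= 0 || detm <= 0 || detd <= 0) return(.PENALTY)
  w1m <- V / detm; w2m <- -cm / detm
  w1d <- V / detd; w2d <- -cd / detd
  Amat <- w1m * mzc$P + w2m * mzc$Q + w1d * dzc$P + w2d * dzc$Q
  b <- w1m * mzc$U1 + w2m * mzc$U2 + w1d * dzc$U1 + w2d * dzc$U2
  sw <- w1m * mzc$S1 + w2m * mzc$S2 + w1d * dzc$S1 + w2d * dzc$S2
  beta <- solve(Amat, b)  # X'WX is PD: design has full rank, W is PD
  quad <- sw - sum(beta * b)
  0.5 * (2 * (mzc$n + dzc$n) * log(2 * pi) +
           mzc$n * log(detm) + dzc$n * log(detd) + quad)
}

.fit_twin_model_prepared <- function(pairs, model, min_pairs = 5,
                                     extra_starts = NULL) {
  free <- .UNI_MODELS[[model]]
  n_mz <- nrow(pairs$MZ$Y); n_dz <- nrow(pairs$DZ$Y)
  if (n_mz < min_pairs || n_dz < min_pairs)
    stop(sprintf("need at least %d complete pairs per zygosity (have %d MZ, %d DZ)",
                 min_pairs, n_mz, n_dz))
  ages <- rbind(pairs$MZ$ages, pairs$DZ$ages)
  sexes <- rbind(pairs$MZ$sexes, pairs$DZ$sexes)
  des <- .build_design(ages, sexes)
  # fit on unit-variance data: the profile likelihood is then the same
  # function of theta for any affine transform of the input, so estimates
  # are exactly scale- and shift-invariant; results are mapped back below
  sc <- stats::sd(c(pairs$MZ$Y, pairs$DZ$Y))
  if (!is.finite(sc) || sc <= 0) stop("phenotype has zero variance")
  moments <- list(
    MZ = .pair_moments(pairs$MZ$Y / sc, des$X[seq_len(n_mz), , , drop = FALSE]),
    DZ = .pair_moments(pairs$DZ$Y / sc,
                       des$X[n_mz + seq_len(n_dz), , , drop = FALSE]))
  mzc <- .uni_compact(moments$MZ)
  dzc <- .uni_compact(moments$DZ)
  iA <- match("a", free, nomatch = 0L); iC <- match("c", free, nomatch = 0L)
  iD <- match("d", free, nomatch = 0L); iE <- match("e", free, nomatch = 0L)
  ld_shift <- 2 * (n_mz + n_dz) * log(sc)
  negll_std <- function(theta) .uni_negll(theta, iA, iC, iD, iE, mzc, dzc)
  negll <- function(theta) negll_std(theta / sc) + ld_shift

  vt <- stats::var(c(pairs$MZ$Y, pairs$DZ$Y) / sc)
  rq <- function(Y) tryCatch(stats::cor(Y[, 1], Y[, 2]), error = function(e) 0)
  starts <- .uni_starts(free, vt, rq(pairs$MZ$Y), rq(pairs$DZ$Y))
  if (!is.null(extra_starts))
    starts <- c(starts, lapply(extra_starts, function(s) {
      out <- stats::setNames(numeric(length(free)), free)
      common <- intersect(names(s), free)
      out[common] <- s[common] / sc
      out
    }))

  best <- NULL
  for (s in starts) {
    fit <- if (length(free) == 1L)
      stats::optim(s, negll_std, method = "Brent", lower = 1e-8,
                   upper = 10 * sqrt(max(vt, 1e-12)))
    else
      stats::optim(s, negll_std, method = "Nelder-Mead",
                   control = list(maxit = 250, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (length(free) > 1L) {
    pol <- tryCatch(stats::optim(best$par, negll_std, method = "BFGS",
                                 control = list(maxit = 200)),
                    error = function(e) NULL)
    if (!is.null(pol) && pol$value < best$value) best <- pol
  }

  theta_std <- stats::setNames(abs(best$par), free)  # sign fixed non-negative
  v_std <- .uni_variances(theta_std, free)
  pl <- .profile_loglik(list(.uni_sigma(v_std, "MZ"), .uni_sigma(v_std, "DZ")),
                        moments)
  converged <- best$convergence == 0 && !is.null(pl) &&
    best$value < .PENALTY / 2
  k <- length(free) + length(des$names)
  loglik <- if (is.null(pl)) -Inf else pl$loglik - ld_shift
  structure(list(model = model, loglik = loglik,
                 aic = -2 * loglik + 2 * k,
                 k = k, theta = theta_std * sc, variances = v_std * sc^2,
                 beta = if (is.null(pl)) NULL
                        else stats::setNames(pl$beta * sc, des$names),
                 converged = converged, n_mz = n_mz, n_dz = n_dz,
                 negll = negll), class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("%s twin model: loglik = %.4f, AIC = %.4f (%d MZ, %d DZ pairs)%s\n",
              x$model, x$loglik, x$aic, x$n_mz, x$n_dz,
              if (x$converged) "" else " [NOT CONVERGED]"))
  v <- x$variances
  cat(sprintf("  A = %.4g, C = %.4g, D = %.4g, E = %.4g\n",
              v[["A"]], v[["C"]], v[["D"]], v[["E"]]))
  invisible(x)
}

#' Fit and select among the six univariate twin models
#'
#' Fits ACE, ADE and the nested AE, CE, DE, E models, then applies the
#' two-step selection: the best full model (BFM) is the AIC-minimal of
#' {ACE, ADE}; the best nested model (BNM) is the AIC-minimal of the BFM's
#' nested set ({AE, CE, E} or {AE, DE, E}); a likelihood-ratio test
#' compares BNM to BFM (chi-squared, df = difference in free parameters).
#' If the LRT p value exceeds `alpha` the BNM is chosen by parsimony;
#' otherwise the AIC-minimal of {BFM, BNM} is chosen. AIC ties are broken
#' by the fixed order ACE, ADE, AE, CE, DE, E. Nested fits seed the starts
#' of the enclosing full models, which enforces likelihood monotonicity.
#'
#' @inheritParams fit_twin_model
#' @param alpha Parsimony threshold for the LRT p value (default 0.05).
#' @return A `twin_selection` object: `fits` (named list of `twin_fit`),
#'   `bfm`, `bnm`, `lrt_stat`, `lrt_df`, `lrt_p`, `final` (model name),
#'   `reason` (`"parsimony"` or `"min-AIC"`), `aic` (named vector).
#' @export
select_twin_model <- function(y, sheet, wave = NULL, min_pairs = 5,
                              alpha = 0.05) {
  sheet <- validate_sample_sheet(sheet)
  pairs <- .twin_pairs(y, sheet, wave)
  fits <- list()
  # nested models first; their solutions seed the full models
  for (m in c("E", "AE", "CE", "DE")) {
    seeds <- if (m != "E" && !is.null(fits$E)) list(fits$E$theta)
    fits[[m]] <- tryCatch(
      .fit_twin_model_prepared(pairs, m, min_pairs, extra_starts = seeds),
      error = function(e) NULL)
  }
  seed_of <- function(ms) Filter(Negate(is.null),
                                 lapply(fits[ms], function(f) f$theta))
  fits$ACE <- tryCatch(.fit_twin_model_prepared(
    pairs, "ACE", min_pairs, extra_starts = seed_of(c("AE", "CE", "E"))),
    error = function(e) NULL)
  fits$ADE <- tryCatch(.fit_twin_model_prepared(
    pairs, "ADE", min_pairs, extra_starts = seed_of(c("AE", "DE", "E"))),
    error = function(e) NULL)
  fits <- fits[.MODEL_ORDER]

  usable <- function(m) !is.null(fits[[m]]) && fits[[m]]$converged
  if (!usable("ACE") || !usable("ADE"))
    stop("both full models (ACE, ADE) must converge for selection")
  aic <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, numeric(1))

  pick_min <- function(models) {
    models <- models[vapply(models, usable, logical(1))]
    if (!length(models)) return(NA_character_)
    a <- aic[models]
    models[which(a <= min(a) + 1e-9)][1]  # fixed-order tie break
  }
  bfm <- pick_min(c("ACE", "ADE"))
  bnm <- pick_min(.NESTED[[bfm]])
  if (is.na(bnm)) {
    sel <- list(bfm = bfm, bnm = NA_character_, lrt_stat = NA_real_,
                lrt_df = NA_integer_, lrt_p = NA_real_, final = bfm,
                reason = "no-converged-nested", fits = fits, aic = aic)
    return(structure(sel, class = "twin_selection"))
  }
  lrt_stat <- max(0, 2 * (fits[[bfm]]$loglik - fits[[bnm]]$loglik))
  lrt_df <- fits[[bfm]]$k - fits[[bnm]]$k
  lrt_p <- stats::pchisq(lrt_stat, df = lrt_df, lower.tail = FALSE)
  if (lrt_p > alpha) {
    final <- bnm; reason <- "parsimony"
  } else {
    final <- pick_min(c(bfm, bnm)); reason <- "min-AIC"
  }
  structure(list(bfm = bfm, bnm = bnm, lrt_stat = lrt_stat,
                 lrt_df = lrt_df, lrt_p = lrt_p, final = final,
                 reason = reason, fits = fits, aic = aic),
            class = "twin_selection")
}

#' @export
print.twin_selection <- function(x, ...) {
  cat(sprintf("BFM = %s, BNM = %s; LRT chi2 = %.4f (df %d), p = %.4g\n",
              x$bfm, x$bnm, x$lrt_stat, x$lrt_df, x$lrt_p))
  cat(sprintf("final model: %s (%s)\n", x$final, x$reason))
  invisible(x)
}

#' Standardized variance components and heritability
#'
#' Converts a fitted twin model to proportions of total variance
#' (a2, c2, d2, e2, summing to 1) with 95% delta-method confidence
#' intervals on the proportion functions of the path coefficients,
#' untruncated (bounds may fall outside `[0, 1]`). Heritability is narrow
#' sense `A / (A + C + E)` for ACE-family models and broad sense
#' `(A + D) / (A + D + E)` for ADE-family models. When the observed
#' information is singular in a direction that the proportion gradients do
#' not touch (a component estimated at exactly zero), the corresponding
#' interval degenerates to zero width; when the information matrix is not
#' positive semi-definite the bounds are `NaN`.
#'
#' @param fit A `twin_fit` from [fit_twin_model()].
#' @param conf_level Confidence level (default 0.95 for 2.5-97.5% bounds).
#' @return A `std_components` object: `estimates` (a2, c2, d2, e2),
#'   `ci` (4 x 2 matrix), `h2`, `h2_ci`, `sense`, `model`.
#' @export
standardize <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "twin_fit"))
  free <- .UNI_MODELS[[fit$model]]
  broad <- fit$model %in% c("ADE", "DE")
  gfun <- function(theta) {
    v <- .uni_variances(theta, free)
    V <- sum(v)
    c(v / V, h2 = if (broad) (v[["A"]] + v[["D"]]) / V else v[["A"]] / V)
  }
  est <- gfun(fit$theta)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- rep(NaN, 5)
  H <- tryCatch(numDeriv::hessian(fit$negll, fit$theta), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    tol <- max(abs(ev$values)) * 1e-7
    if (all(ev$values > -tol)) {
      # pseudo-inverse: directions of zero information (components at the
      # zero boundary) get zero variance, matching the degenerate-interval
      # convention for null components
      pos <- ev$values > tol
      vcv <- ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
      J <- numDeriv::jacobian(gfun, fit$theta)
      vg <- rowSums((J %*% vcv) * J)
      se <- sqrt(pmax(vg, 0))
      se[vg < -1e-8] <- NaN
    }
  }
  ci <- cbind(lower = est - q * se, upper = est + q * se)
  structure(list(estimates = est[1:4], ci = ci[1:4, , drop = FALSE],
                 h2 = unname(est[5]), h2_ci = unname(ci[5, ]),
                 sense = if (broad) "broad" else "narrow",
                 model = fit$model), class = "std_components")
}

#' @export
print.std_components <- function(x, ...) {
  nm <- c("a2", "c2", "d2", "e2")
  for (i in 1:4)
    cat(sprintf("  %s = %.4f (%.4f-%.4f)\n", nm[i], x$estimates[i],
                x$ci[i, 1], x$ci[i, 2]))
  cat(sprintf("  h2 (%s) = %.4f (%.4f-%.4f) [%s model]\n", x$sense, x$h2,
              x$h2_ci[1], x$h2_ci[2], x$model))
  invisible(x)
}
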