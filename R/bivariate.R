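# Bivariate (two-wave) twin model in the correlated-factors
# parameterization: per-wave variance components plus cross-wave factor
# correlations r_g, r_c, r_d, r_e.

.BIV_FAMILIES <- list(AE = c("a", "e"), ACE = c("a", "c", "e"),
                      ADE = c("a", "d", "e"))
.BIV_COR_OF <- c(a = "r_g", c = "r_c", d = "r_d", e = "r_e")

#' Covariance matrix of the bivariate twin model
#'
#' Builds the 4 x 4 covariance of the vector (twin1-wave1, twin1-wave2,
#' twin2-wave1, twin2-wave2). Diagonals are the per-wave totals
#' `V_j = A_j + C_j + D_j + E_j`; within-twin cross-wave covariance is
#' `r_g sqrt(A1 A2) + r_c sqrt(C1 C2) + r_d sqrt(D1 D2) + r_e sqrt(E1 E2)`;
#' cross-twin same-wave covariance is the univariate twin covariance
#' (A and D scaled by 1/1 for MZ, 0.5/0.25 for DZ); cross-twin cross-wave
#' covariance drops the E term and scales the A and D terms by the same
#' zygosity coefficients.
#'
#' @param components Named list/vector with `A1`, `C1`, `D1`, `E1`, `A2`,
#'   `C2`, `D2`, `E2` (missing entries default to 0).
#' @param correlations Named list/vector with `r_g`, `r_c`, `r_d`, `r_e`
#'   (missing entries default to 0), each in `[-1, 1]`.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A 4 x 4 symmetric matrix.
#' @export
bivariate_cov <- function(components, correlations, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  gv <- function(x, nm) if (nm %in% names(x)) as.numeric(x[[nm]]) else 0
  A1 <- gv(components, "A1"); C1 <- gv(components, "C1")
  D1 <- gv(components, "D1"); E1 <- gv(components, "E1")
  A2 <- gv(components, "A2"); C2 <- gv(components, "C2")
  D2 <- gv(components, "D2"); E2 <- gv(components, "E2")
  if (min(A1, C1, D1, E1, A2, C2, D2, E2) < 0)
    stop("variance components must be non-negative")
  rg <- gv(correlations, "r_g"); rc <- gv(correlations, "r_c")
  rd <- gv(correlations, "r_d"); re <- gv(correlations, "r_e")
  if (max(abs(c(rg, rc, rd, re))) > 1)
    stop("factor correlations must lie in [-1, 1]")
  kA <- if (zygosity == "MZ") 1 else 0.5
  kD <- if (zygosity == "MZ") 1 else 0.25
  V1 <- A1 + C1 + D1 + E1
  V2 <- A2 + C2 + D2 + E2
  ct1 <- kA * A1 + C1 + kD * D1
  ct2 <- kA * A2 + C2 + kD * D2
  wt <- rg * sqrt(A1 * A2) + rc * sqrt(C1 * C2) + rd * sqrt(D1 * D2) +
    re * sqrt(E1 * E2)
  xx <- kA * rg * sqrt(A1 * A2) + rc * sqrt(C1 * C2) + kD * rd * sqrt(D1 * D2)
  matrix(c(V1, wt, ct1, xx,
           wt, V2, xx, ct2,
           ct1, xx, V1, wt,
           xx, ct2, wt, V2), 4, 4,
         dimnames = rep(list(c("t1w1", "t1w2", "t2w1", "t2w2")), 2))
}

# Complete quadruples (both twins at both waves) per zygosity.
.biv_quadruples <- function(y, sheet) {
  out <- list()
  for (z in c("MZ", "DZ")) {
    sub <- sheet[sheet$zygosity == z, ]
    pid <- unique(sub$pair_id)
    sid <- function(m, w) {
      idx <- match(paste(pid, m, w), paste(sub$pair_id, sub$member, sub$wave))
      sub$sample_id[idx]
    }
    ids <- cbind(sid(1, 1), sid(1, 2), sid(2, 1), sid(2, 2))
    Y <- matrix(y[match(ids, names(y))], ncol = 4)
    ages <- matrix(sub$age[match(ids, sub$sample_id)], ncol = 4)
    sexes <- matrix(sub$sex[match(ids, sub$sample_id)], ncol = 4)
    cc <- stats::complete.cases(Y) & stats::complete.cases(ages)
    out[[z]] <- list(Y = Y[cc, , drop = FALSE],
                     ages = ages[cc, , drop = FALSE],
                     sexes = sexes[cc, , drop = FALSE],
                     pair_id = pid[cc])
  }
  out
}

.biv_components <- function(theta, free) {
  comp <- c(A1 = 0, C1 = 0, D1 = 0, E1 = 0, A2 = 0, C2 = 0, D2 = 0, E2 = 0)
  for (f in free) {
    comp[[paste0(toupper(f), "1")]] <- theta[[paste0(f, "1")]]^2
    comp[[paste0(toupper(f), "2")]] <- theta[[paste0(f, "2")]]^2
  }
  comp
}

.biv_correlations <- function(theta, free, fixed) {
  cors <- c(r_g = 0, r_c = 0, r_d = 0, r_e = 0)
  for (f in free) {
    nm <- .BIV_COR_OF[[f]]
    cors[[nm]] <- if (nm %in% names(fixed)) fixed[[nm]]
                  else tanh(theta[[paste0("z_", substring(nm, 3))]])
  }
  cors
}

#' Fit the bivariate (two-wave) twin model
#'
#' Maximum likelihood over the quadrivariate-normal pair likelihood
#' (variables twin1-wave1, twin1-wave2, twin2-wave1, twin2-wave2; see
#' [bivariate_cov()]), with wave-specific mean models (intercept + age +
#' sex, constant covariates dropped) profiled out by generalised least
#' squares. Per-wave variance components are squared path coefficients;
#' cross-wave factor correlations are mapped through `tanh` of an
#' unconstrained real, so they stay inside `[-1, 1]`. Confidence intervals
#' are delta-method on the back-transformed quantities. Pairs missing any
#' of the four measurements are excluded.
#'
#' @param y Named numeric vector over all samples (both waves) for one CpG.
#' @param sheet Sample sheet with both waves.
#' @param family `"AE"` (default), `"ACE"` or `"ADE"`.
#' @param min_pairs Minimum complete quadruple count per zygosity.
#' @param fix_correlations Optional named numeric, e.g. `c(r_g = 0)`, to
#'   fix some factor correlations instead of estimating them.
#' @param conf_level Confidence level for the intervals.
#' @return A `bivariate_fit` object: family, per-wave components and
#'   standardized components, correlations with CIs, loglik, AIC,
#'   convergence flag, pair counts.
#' @export
fit_bivariate <- function(y, sheet, family = c("AE", "ACE", "ADE"),
                          min_pairs = 5, fix_correlations = NULL,
                          conf_level = 0.95) {
  family <- match.arg(family)
  sheet <- validate_sample_sheet(sheet)
  free <- .BIV_FAMILIES[[family]]
  quads <- .biv_quadruples(y, sheet)
  n_mz <- nrow(quads$MZ$Y); n_dz <- nrow(quads$DZ$Y)
  if (n_mz < min_pairs || n_dz < min_pairs)
    stop(sprintf("need at least %d complete-quadruple pairs per zygosity (have %d MZ, %d DZ)",
                 min_pairs, n_mz, n_dz))
  ages <- rbind(quads$MZ$ages, quads$DZ$ages)
  sexes <- rbind(quads$MZ$sexes, quads$DZ$sexes)
  des <- .build_design(ages, sexes, wave_of = c(1L, 2L, 1L, 2L))
  moments <- list(
    MZ = .pair_moments(quads$MZ$Y, des$X[seq_len(n_mz), , , drop = FALSE]),
    DZ = .pair_moments(quads$DZ$Y,
                       des$X[n_mz + seq_len(n_dz), , , drop = FALSE]))

  fixed <- fix_correlations
  par_names <- c(as.vector(rbind(paste0(free, "1"), paste0(free, "2"))),
                 paste0("z_", substring(.BIV_COR_OF[free], 3))[
                   !.BIV_COR_OF[free] %in% names(fixed)])
  negll <- function(theta) {
    theta <- stats::setNames(theta, par_names)
    comp <- .biv_components(theta, free)
    cors <- .biv_correlations(theta, free, fixed)
    sig <- list(bivariate_cov(comp, cors, "MZ"),
                bivariate_cov(comp, cors, "DZ"))
    pl <- .profile_loglik(sig, moments)
    if (is.null(pl)) return(.PENALTY)
    -pl$loglik
  }

  v1 <- stats::var(c(quads$MZ$Y[, c(1, 3)], quads$DZ$Y[, c(1, 3)]))
  v2 <- stats::var(c(quads$MZ$Y[, c(2, 4)], quads$DZ$Y[, c(2, 4)]))
  base <- stats::setNames(numeric(length(par_names)), par_names)
  nf <- length(free)
  for (f in free) {
    base[[paste0(f, "1")]] <- sqrt(v1 / nf)
    base[[paste0(f, "2")]] <- sqrt(v2 / nf)
  }
  starts <- lapply(c(0.5, 0.9, 0), function(r0) {
    s <- base
    s[grepl("^z_", par_names)] <- atanh(r0)
    s
  })

  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pol <- tryCatch(stats::optim(best$par, negll, method = "BFGS",
                               control = list(maxit = 300)),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) best <- pol

  theta <- stats::setNames(best$par, par_names)
  vcomp <- grepl("1$|2$", par_names) & !grepl("^z_", par_names)
  theta[vcomp] <- abs(theta[vcomp])
  comp <- .biv_components(theta, free)
  cors <- .biv_correlations(theta, free, fixed)
  converged <- best$convergence == 0 && best$value < .PENALTY / 2
  loglik <- -negll(theta)
  k <- length(par_names) + length(des$names)

  # delta-method CIs for correlations and per-wave standardized components
  gfun <- function(th) {
    th <- stats::setNames(th, par_names)
    cp <- .biv_components(th, free)
    cr <- .biv_correlations(th, free, fixed)
    V1 <- sum(cp[c("A1", "C1", "D1", "E1")])
    V2 <- sum(cp[c("A2", "C2", "D2", "E2")])
    c(cr, cp[c("A1", "C1", "D1", "E1")] / V1,
      cp[c("A2", "C2", "D2", "E2")] / V2)
  }
  est <- gfun(theta)
  names(est) <- c("r_g", "r_c", "r_d", "r_e",
                  "a2_w1", "c2_w1", "d2_w1", "e2_w1",
                  "a2_w2", "c2_w2", "d2_w2", "e2_w2")
  se <- rep(NaN, length(est))
  H <- tryCatch(numDeriv::hessian(negll, theta), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    tol <- max(abs(ev$values)) * 1e-7
    if (all(ev$values > -tol)) {
      pos <- ev$values > tol
      vcv <- ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
      J <- numDeriv::jacobian(gfun, as.numeric(theta))
      vg <- rowSums((J %*% vcv) * J)
      se <- sqrt(pmax(vg, 0))
      se[vg < -1e-8] <- NaN
    }
  }
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(lower = est - q * se, upper = est + q * se)
  structure(list(family = family, theta = theta, components = comp,
                 correlations = cors, estimates = est, ci = ci,
                 loglik = loglik, aic = -2 * loglik + 2 * k, k = k,
                 converged = converged, n_mz = n_mz, n_dz = n_dz,
                 negll = negll), class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("bivariate %s twin model: loglik = %.4f, AIC = %.4f (%d MZ, %d DZ pairs)%s\n",
              x$family, x$loglik, x$aic, x$n_mz, x$n_dz,
              if (x$converged) "" else " [NOT CONVERGED]"))
  for (nm in c("r_g", "r_c", "r_d", "r_e"))
    if (abs(x$correlations[[nm]]) > 0 || nm %in% c("r_g", "r_e"))
      cat(sprintf("  %s = %.3f (%.3f-%.3f)\n", nm, x$estimates[[nm]],
                  x$ci[nm, 1], x$ci[nm, 2]))
  cat(sprintf("  a2: wave1 %.3f, wave2 %.3f\n",
              x$estimates[["a2_w1"]], x$estimates[["a2_w2"]]))
  invisible(x)
}
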