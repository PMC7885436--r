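# Internal machinery shared by the univariate and bivariate twin models.
#
# Pairs are independent given their zygosity-specific covariance, so the
# Gaussian log-likelihood with a linear mean model can be evaluated from
# precomputed cross-moments: with d variables per pair and p mean
# coefficients, each evaluation only needs the d x d inverse covariance per
# zygosity and O(d^2 p^2) arithmetic, independent of the number of pairs.
# The mean coefficients are profiled out by generalised least squares at
# every variance-parameter point, which leaves the optimiser a 1-3 (or, in
# the bivariate model, up to 9) dimensional problem.

# Y: n x d matrix; X: n x d x p array (per-pair design, one row per
# variable). Returns flattened cross-moments.
.pair_moments <- function(Y, X) {
  n <- nrow(Y); d <- ncol(Y); p <- dim(X)[3]
  Tm <- matrix(0, p * p, d * d)
  Um <- matrix(0, p, d * d)
  for (j in seq_len(d)) {
    Xj <- matrix(X[, j, ], n, p)
    for (k in seq_len(d)) {
      col <- (k - 1L) * d + j
      Tm[, col] <- crossprod(Xj, matrix(X[, k, ], n, p))
      Um[, col] <- crossprod(Xj, Y[, k])
    }
  }
  list(T = Tm, U = Um, S = as.vector(crossprod(Y)), n = n, d = d, p = p)
}

# Profile log-likelihood over the mean coefficients. `sigmas` is a list of
# d x d covariance matrices parallel to `moments` (one per zygosity group;
# groups with n = 0 are skipped). Returns -Inf-like penalty info via NULL
# when a covariance is not positive definite or the GLS system is singular.
.profile_loglik <- function(sigmas, moments) {
  p <- NULL
  A <- NULL; b <- NULL; sw <- 0; logdet <- 0; N <- 0L; d <- NULL
  for (g in seq_along(moments)) {
    mo <- moments[[g]]
    if (is.null(mo) || mo$n == 0L) next
    ch <- tryCatch(chol(sigmas[[g]]), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    W <- chol2inv(ch)
    w <- as.vector(W)
    if (is.null(A)) {
      p <- mo$p; d <- mo$d
      A <- matrix(0, p, p); b <- numeric(p)
    }
    A <- A + matrix(mo$T %*% w, p, p)
    b <- b + as.vector(mo$U %*% w)
    sw <- sw + sum(mo$S * w)
    logdet <- logdet + mo$n * 2 * sum(log(diag(ch)))
    N <- N + mo$n
  }
  if (is.null(A)) return(NULL)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  quad <- sw - sum(beta * b)
  list(loglik = -0.5 * (N * d * log(2 * pi) + logdet + quad),
       beta = beta, n = N)
}

# Build per-pair design arrays. ages/sexes: n x d matrices aligned with Y.
# Covariate columns that are constant in the pooled data are dropped (they
# would be collinear with the intercept). For the bivariate model the
# design is wave-specific: `wave_of` gives the wave of each of the d
# variables and each wave gets its own intercept/age/sex columns.
.build_design <- function(ages, sexes, wave_of = NULL) {
  n <- nrow(ages); d <- ncol(ages)
  use_age <- stats::sd(as.vector(ages)) > 1e-12
  use_sex <- stats::sd(as.vector(sexes)) > 1e-12
  waves <- if (is.null(wave_of)) 1L else sort(unique(wave_of))
  if (is.null(wave_of)) wave_of <- rep(1L, d)
  per_wave <- 1L + use_age + use_sex
  p <- per_wave * length(waves)
  X <- array(0, dim = c(n, d, p))
  nm <- character(p)
  for (wi in seq_along(waves)) {
    off <- (wi - 1L) * per_wave
    sfx <- if (length(waves) > 1) paste0("_w", waves[wi]) else ""
    cols <- which(wave_of == waves[wi])
    X[, cols, off + 1L] <- 1
    nm[off + 1L] <- paste0("intercept", sfx)
    k <- 1L
    if (use_age) {
      k <- k + 1L
      X[, cols, off + k] <- ages[, cols]
      nm[off + k] <- paste0("age", sfx)
    }
    if (use_sex) {
      k <- k + 1L
      X[, cols, off + k] <- sexes[, cols]
      nm[off + k] <- paste0("sex", sfx)
    }
  }
  list(X = X, names = nm)
}

# Complete twin pairs for one CpG at one wave, split by zygosity.
# y: named numeric vector (by sample_id).
.twin_pairs <- function(y, sheet, wave = NULL) {
  if (!is.null(wave)) sheet <- sheet[sheet$wave == wave, ]
  out <- list()
  for (z in c("MZ", "DZ")) {
    sub <- sheet[sheet$zygosity == z, ]
    s1 <- sub[sub$member == 1, ]
    s2 <- sub[sub$member == 2, ]
    i2 <- match(s1$pair_id, s2$pair_id)
    ok <- !is.na(i2)
    s1 <- s1[ok, ]; s2 <- s2[i2[ok], ]
    Y <- cbind(y[match(s1$sample_id, names(y))],
               y[match(s2$sample_id, names(y))])
    cc <- stats::complete.cases(Y)
    out[[z]] <- list(Y = unname(Y[cc, , drop = FALSE]),
                     ages = cbind(s1$age, s2$age)[cc, , drop = FALSE],
                     sexes = cbind(s1$sex, s2$sex)[cc, , drop = FALSE],
                     pair_id = s1$pair_id[cc])
  }
  out
}

.PENALTY <- 1e10  # objective value returned for invalid covariance points
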