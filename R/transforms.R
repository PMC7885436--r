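#' Beta values from probe intensities
#'
#' Computes the methylation beta value from methylated and unmethylated
#' allele intensities as meth / (meth + unmeth + offset). The additive
#' offset (100 by default) regularises low-intensity probes and keeps the
#' result strictly below 1.
#'
#' @param meth Numeric vector/matrix of methylated-allele intensities (>= 0).
#' @param unmeth Numeric vector/matrix of unmethylated-allele intensities
#'   (>= 0), same shape as `meth`.
#' @param offset Non-negative regularising constant added to the denominator.
#' @return Beta values in `[0, 1)`, same shape as the inputs.
#' @examples
#' beta_from_intensities(100, 100)  # 1/3
#' beta_from_intensities(900, 0)    # 0.9
#' @export
beta_from_intensities <- function(meth, unmeth, offset = 100) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (offset < 0) stop("offset must be non-negative")
  denom <- meth + unmeth + offset
  beta <- meth / denom
  beta[denom == 0] <- 0  # meth = unmeth = offset = 0
  beta
}

#' Convert between beta and M values
#'
#' M is the base-2 logit of beta: `M = log2(beta / (1 - beta))`. M values
#' are the modelling scale (homoscedastic); beta values are the reporting
#' scale in `[0, 1]`. Beta values at or beyond the open interval (0, 1) are
#' clamped to `[eps, 1 - eps]` before the logit, with a warning, since an
#' exact 0 or 1 has infinite M.
#'
#' @param beta Numeric vector/matrix of beta values.
#' @param eps Clamping bound for beta values outside (0, 1).
#' @return M values (real line), same shape.
#' @examples
#' m_from_beta(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @export
m_from_beta <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  out_of_open <- !is.na(beta) & (beta <= 0 | beta >= 1)
  if (any(out_of_open)) {
    warning(sum(out_of_open), " beta value(s) at 0 or 1 clamped to [",
            format(eps), ", 1 - ", format(eps), "] before logit")
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log2(beta / (1 - beta))
}

#' @rdname m_from_beta
#' @param m Numeric vector/matrix of M values.
#' @export
beta_from_m <- function(m) {
  # inverse base-2 logit; written to avoid overflow for large |m|
  ifelse(m > 0, 1 / (1 + 2^(-m)), 2^m / (1 + 2^m))
}
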