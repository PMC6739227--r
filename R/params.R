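#' Random-effects covariance in modified Cholesky form
#'
#' The covariance of the random intercept and slope, `Sigma_b`, is
#' parameterized through the regression of the slope on the intercept:
#' `b1 = e1`, `b2 = delta * b1 + e2` with independent innovations
#' `e1 ~ N(0, sigma1^2)` and `e2 ~ N(0, sigma2^2)`.  Any finite `delta`
#' and positive `sigma1`, `sigma2` yield a positive-definite `Sigma_b`,
#' which makes unconstrained prior specification straightforward.
#'
#' @param delta Regression coefficient of the slope on the intercept.
#' @param sigma1,sigma2 Innovation standard deviations (positive).
#' @return An object of class `re_cov`.
#' @examples
#' sigma_b_from_cholesky(re_cov(delta = 0.5, sigma1 = 1, sigma2 = 1))
#' @export
re_cov <- function(delta, sigma1, sigma2) {
  if (!is.finite(delta)) abort("`delta` must be finite.")
  if (!isTRUE(sigma1 > 0) || !isTRUE(sigma2 > 0))
    abort("`sigma1` and `sigma2` must be positive.")
  structure(list(delta = delta, sigma1 = sigma1, sigma2 = sigma2),
            class = "re_cov")
}

#' @rdname re_cov
#' @param x An `re_cov` object.
#' @return `sigma_b_from_cholesky()`: the implied 2x2 covariance matrix
#'   `[[s1^2, d s1^2], [d s1^2, d^2 s1^2 + s2^2]]`.
#' @export
sigma_b_from_cholesky <- function(x) {
  stopifnot(inherits(x, "re_cov"))
  s1sq <- x$sigma1^2
  matrix(c(s1sq, x$delta * s1sq,
           x$delta * s1sq, x$delta^2 * s1sq + x$sigma2^2), 2, 2)
}

#' @rdname re_cov
#' @param Sigma A 2x2 symmetric positive-definite matrix.
#' @return `cholesky_from_sigma_b()`: the `re_cov` whose implied covariance
#'   is `Sigma` (the parameterization is a bijection).
#' @export
cholesky_from_sigma_b <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma))) || any(diag(Sigma) <= 0) ||
      det(Sigma) <= 0)
    abort("`Sigma` must be symmetric positive definite.")
  s1sq <- Sigma[1, 1]
  delta <- Sigma[1, 2] / s1sq
  s2sq <- Sigma[2, 2] - delta^2 * s1sq
  re_cov(delta = delta, sigma1 = sqrt(s1sq), sigma2 = sqrt(s2sq))
}

#' Shared parameter model parameters
#'
#' Bundles every parameter of the joint model: fixed effects `beta` of the
#' longitudinal linear mixed model, hazard coefficients `alpha` of the
#' probit discrete-hazard dropout model, the association vector `gamma`
#' linking the random effects to dropout (a length-2 vector shared across
#' visits, or an `(M-1) x 2` matrix for visit-specific association), the
#' random-effects covariance in modified Cholesky form, and the residual
#' standard deviation `sigma_eps`.
#'
#' @param beta Numeric fixed-effect vector (order must match the columns of
#'   the `fixed` design matrix; name the elements for readability).
#' @param alpha Numeric hazard coefficient vector (matching the `hazard`
#'   design matrix).
#' @param gamma Length-2 numeric vector `(gamma1, gamma2)` weighting the
#'   random intercept and slope in the hazard's linear predictor, or an
#'   `(M-1) x 2` matrix of visit-specific weights.
#' @param re_cov An [re_cov()] object.
#' @param sigma_eps Residual standard deviation (positive).
#' @return An object of class `spm_params`.
#' @export
spm_params <- function(beta, alpha, gamma, re_cov, sigma_eps) {
  stopifnot(inherits(re_cov, "re_cov"))
  if (!isTRUE(sigma_eps > 0)) abort("`sigma_eps` must be positive.")
  if (is.matrix(gamma)) {
    if (ncol(gamma) != 2L) abort("matrix `gamma` must have 2 columns.")
  } else if (length(gamma) != 2L) {
    abort("`gamma` must have length 2 (or be an (M-1) x 2 matrix).")
  }
  structure(list(beta = beta, alpha = alpha, gamma = gamma,
                 re_cov = re_cov, sigma_eps = sigma_eps),
            class = "spm_params")
}

#' @export
print.spm_params <- function(x, ...) {
  cat("<spm_params> p = ", length(x$beta), " fixed effects, p_S = ",
      length(x$alpha), " hazard terms\n", sep = "")
  cat("  gamma: ", if (is.matrix(x$gamma)) "visit-specific" else
    paste(signif(x$gamma, 3), collapse = ", "), "\n", sep = "")
  cat("  re_cov: delta=", signif(x$re_cov$delta, 3),
      " sigma1=", signif(x$re_cov$sigma1, 3),
      " sigma2=", signif(x$re_cov$sigma2, 3),
      "; sigma_eps=", signif(x$sigma_eps, 3), "\n", sep = "")
  invisible(x)
}

# gamma row for hazard/risk index l (1..M-1)
gamma_at <- function(params, l) {
  g <- params$gamma
  if (is.matrix(g)) g[l, ] else g
}

#' Parameter values emulating an HIV cohort CD4 analysis
#'
#' A complete `spm_params` set whose values mirror posterior means from a
#' published shared-parameter analysis of CD4 counts in a women's HIV
#' cohort (12 six-monthly visits; outcome square-root CD4, standardized).
#' Intended as a realistic default truth for the synthetic-data generator
#' and for examples; this is a convenience calibration, not a reproduction
#' of any data analysis.
#'
#' Fixed effects (in `fixed = ~ time * (vl + art + sympt)` column order
#' with viral-load reference level `>30k` copies/ml): intercept,
#' viral-load groups 0-500, 500-5k, 5k-30k, ART indicator, symptom score,
#' time, and the time interactions.  Hazard terms follow
#' `~ vl + art + sympt + time + I(time^2) + art:time`.
#'
#' @return An `spm_params` object.
#' @export
hers_params <- function() {
  beta <- c("(Intercept)" = -0.55,
            "vl0-500" = 1.52, "vl500-5k" = 1.02, "vl5k-30k" = 0.47,
            "art" = -0.65, "sympt" = -0.02,
            "time" = -1.21,
            "time:vl0-500" = 0.59, "time:vl500-5k" = 0.53,
            "time:vl5k-30k" = 0.37,
            "time:art" = 0.21, "time:sympt" = -0.06)
  alpha <- c("(Intercept)" = 1.11,
             "vl0-500" = 0.75, "vl500-5k" = 0.63, "vl5k-30k" = 0.26,
             "art" = -0.22, "sympt" = -0.01,
             "time" = 1.67, "I(time^2)" = -2.79, "art:time" = 0.37)
  # var(b1)=0.56, var(b2)=1.24, corr=-0.20 in modified Cholesky form
  Sigma <- matrix(c(0.56, -0.20 * sqrt(0.56 * 1.24),
                    -0.20 * sqrt(0.56 * 1.24), 1.24), 2, 2)
  spm_params(beta = beta, alpha = alpha, gamma = c(0.23, 0.28),
             re_cov = cholesky_from_sigma_b(Sigma),
             sigma_eps = sqrt(0.15))
}
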