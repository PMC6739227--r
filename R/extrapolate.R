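#' Sample missing post-dropout outcomes from the default extrapolation
#'
#' The default extrapolation distribution under the fitted shared
#' parameter model: draw `b` from the closed skew-normal conditional law
#' of the random effects given the subject's observed data, then
#' `Y_k = x_k' beta + z_k' b + eps_k` with independent
#' `eps_k ~ N(0, sigma_eps^2)`.  Draws are joint across the requested
#' visits (a common `b` per draw), which is what the additivity of the
#' skew-normal family licenses.
#'
#' @param subject A subject record with dropout visit `S < M`.
#' @param params An [spm_params()] object.
#' @param visits Visits to extrapolate (default all of `(S+1):M`).
#' @param n Number of draws.
#' @param seed Optional seed.
#' @param csn Optionally a precomputed [conditional_random_effects()]
#'   object for this subject.
#' @return An `n x length(visits)` matrix of outcome draws (columns named
#'   by visit), with the random-effect draws in attribute `"b"`.
#' @export
default_extrapolation_sample <- function(subject, params, visits = NULL,
                                         n = 1000L, seed = NULL, csn = NULL) {
  M <- length(subject$y)
  S <- subject$S
  if (S >= M) abort("Subject is a completer; nothing to extrapolate.")
  if (is.null(visits)) visits <- seq(S + 1L, M)
  if (any(visits < 2L | visits > M)) abort("`visits` out of range.")
  if (is.null(csn)) csn <- conditional_random_effects(subject, params)
  b <- sample_csn(csn, n, seed = seed)
  beta <- align_coef(params$beta, subject$X, "beta")
  fixed <- drop(subject$X[visits, , drop = FALSE] %*% beta)
  Zk <- subject$Z[visits, , drop = FALSE]
  draws <- b %*% t(Zk)
  draws <- sweep(draws, 2, fixed, "+") +
    matrix(rnorm(n * length(visits), 0, params$sigma_eps), n)
  colnames(draws) <- visits
  attr(draws, "b") <- b
  draws
}

#' Sample post-dropout outcomes under the sensitivity extrapolation
#'
#' The sensitivity model keeps the subject's closed skew-normal law for
#' `(b1, b2)` but lets the slope change after dropout: outcomes follow the
#' piecewise-linear model
#' `Y_k = x_k' beta + b1 + b2 t_k + Delta_i (t_k - t_S)_+ + eps_k`,
#' where the hinge `(x)_+` vanishes at and before the dropout visit and
#' `Delta_i = a (M - S) / (M - 1) * sigma_b2` ([delta_i()]).  With `a = 0`
#' the draws coincide, bitwise, with [default_extrapolation_sample()]
#' under the same seed: the deterministic hinge shift is added to shared
#' random draws.
#'
#' @inheritParams default_extrapolation_sample
#' @param a Sensitivity parameter (a fixed value; draw it from its prior
#'   with [sample_a()]).
#' @param sigma_b2 Standard deviation of the random slope given the
#'   subject's observed data; computed via [csn_moments()] when `NULL`.
#' @param times Visit-time vector of the study design; defaults to the
#'   subject's `Z` slope column.
#' @return As [default_extrapolation_sample()], plus attributes `"delta"`
#'   and `"shift"` (the per-visit mean shift).
#' @export
sensitivity_extrapolation_sample <- function(subject, params, a,
                                             sigma_b2 = NULL, visits = NULL,
                                             n = 1000L, seed = NULL,
                                             csn = NULL, times = NULL) {
  M <- length(subject$y)
  S <- subject$S
  if (ncol(subject$Z) != 2L)
    abort("Sensitivity extrapolation requires intercept+slope random effects (q = 2).")
  if (is.null(visits)) visits <- seq(S + 1L, M)
  if (is.null(csn)) csn <- conditional_random_effects(subject, params)
  if (is.null(sigma_b2)) sigma_b2 <- csn_moments(csn)$sigma_b2
  if (is.null(times)) times <- subject$Z[, 2]
  draws <- default_extrapolation_sample(subject, params, visits = visits,
                                        n = n, seed = seed, csn = csn)
  delta <- delta_i(a, S, M, sigma_b2)
  shift <- delta * pmax(times[visits] - times[S], 0)
  out <- sweep(draws, 2, shift, "+")
  colnames(out) <- colnames(draws)
  attr(out, "b") <- attr(draws, "b")
  attr(out, "delta") <- delta
  attr(out, "shift") <- shift
  out
}
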