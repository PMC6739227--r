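# Align a named coefficient vector with a design matrix's columns.  Keeps
# the likelihood code independent of the order covariates were written in.
align_coef <- function(coef, mat, what = "coefficient") {
  if (ncol(mat) != length(coef))
    abort(paste0("Length of ", what, " vector (", length(coef),
                 ") does not match design columns (", ncol(mat), ")."))
  cn <- colnames(mat)
  if (!is.null(names(coef)) && !is.null(cn) && setequal(names(coef), cn))
    coef <- coef[cn]
  unname(coef)
}

# Hazard linear predictor eta_l = x_{S,l}' alpha + gamma_l' (W_l b) for the
# requested risk indices l (default all 1..M-1).
hazard_eta <- function(subject, b, params, l = NULL) {
  Mm1 <- nrow(subject$Xs)
  if (is.null(l)) l <- seq_len(Mm1)
  alpha <- align_coef(params$alpha, subject$Xs, "alpha")
  base <- drop(subject$Xs[l, , drop = FALSE] %*% alpha)
  re <- vapply(l, function(li) {
    Wb <- if (!is.null(subject$W)) drop(subject$W[[li]] %*% b) else b
    sum(gamma_at(params, li) * Wb)
  }, numeric(1))
  base + re
}

#' Discrete hazard of dropout at a given visit
#'
#' Probability of dropping out at risk index `l` (i.e. the last attended
#' visit being `l`), given still under follow-up, the random effects and
#' covariates, under the probit model
#' `lambda_l = 1 - pnorm(x_l' alpha + gamma' (W_l b))`.  A positive
#' `gamma` component means subjects with larger random intercept/slope are
#' *less* likely to drop out.
#'
#' @param subject A subject record (see [spm_data()]).
#' @param l Risk index, an integer in `1..(M-1)`.
#' @param b Length-2 random-effect vector `(b1, b2)`.
#' @param params An [spm_params()] object.
#' @return The hazard probability, in `(0, 1)`.
#' @export
discrete_hazard <- function(subject, l, b, params) {
  Mm1 <- nrow(subject$Xs)
  if (!all(l >= 1L & l <= Mm1))
    abort(paste0("Risk index must lie in 1..", Mm1, "."))
  1 - pnorm(hazard_eta(subject, b, params, l = l))
}

#' Log-likelihood of the dropout visit given the random effects
#'
#' Discrete-time survival likelihood for the observed dropout visit `S`:
#' an event factor at visit 1 (`S = 1`); survival through `1..S-1` times
#' an event at `S` for interior dropout; and pure survival through all
#' `M - 1` at-risk visits for completers (`S = M`, administratively
#' censored).  Survival and event probabilities are accumulated on the
#' log scale via `pnorm(..., log.p = TRUE)`.
#'
#' @inheritParams discrete_hazard
#' @return Log-probability of the observed `S`.
#' @export
dropout_loglik <- function(subject, b, params) {
  S <- subject$S
  M <- length(subject$y)
  eta <- hazard_eta(subject, b, params)
  # survival factor at l: 1 - lambda_l = pnorm(eta_l); event: pnorm(-eta_l)
  if (S < M) {
    surv <- if (S > 1L) sum(pnorm(eta[seq_len(S - 1L)], log.p = TRUE)) else 0
    surv + pnorm(-eta[S], log.p = TRUE)
  } else {
    sum(pnorm(eta, log.p = TRUE))
  }
}

#' Log-density of the observed longitudinal outcomes given the random effects
#'
#' Gaussian log-density of the observed outcome entries under
#' `y_j = x_j' beta + z_j' b + eps_j`, `eps ~ N(0, sigma_eps^2 I)`.
#' Only rows with an observed outcome enter (intermittent gaps and
#' post-dropout visits are excluded), which is the row-deletion treatment
#' of latent-ignorable intermittent missingness.
#'
#' @inheritParams discrete_hazard
#' @return Log-density of the observed outcome vector.
#' @export
longitudinal_loglik <- function(subject, b, params) {
  obs <- subject$obs
  if (!any(obs)) abort("Subject has no observed outcomes.")
  beta <- align_coef(params$beta, subject$X, "beta")
  mu <- drop(subject$X[obs, , drop = FALSE] %*% beta) +
    drop(subject$Z[obs, , drop = FALSE] %*% b)
  sum(dnorm(subject$y[obs], mean = mu, sd = params$sigma_eps, log = TRUE))
}

#' Joint log-density of a subject's observed data and random effects
#'
#' The integrand of the observed-data likelihood: the sum of the
#' longitudinal log-density, the dropout log-likelihood, and the
#' `N(0, Sigma_b)` log-density of the random effects.  Integrating
#' `exp()` of this over `b` gives the subject's observed-data likelihood
#' contribution.
#'
#' @inheritParams discrete_hazard
#' @return Log-density value.
#' @export
joint_loglik_given_b <- function(subject, b, params) {
  Sigma <- sigma_b_from_cholesky(params$re_cov)
  longitudinal_loglik(subject, b, params) +
    dropout_loglik(subject, b, params) +
    dmvnorm2(b, c(0, 0), Sigma)
}

# bivariate normal log-density (2x2 case, closed form)
dmvnorm2 <- function(x, mean, Sigma) {
  d <- x - mean
  detS <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  q <- (Sigma[2, 2] * d[1]^2 - 2 * Sigma[1, 2] * d[1] * d[2] +
          Sigma[1, 1] * d[2]^2) / detS
  -log(2 * pi) - 0.5 * log(detS) - 0.5 * q
}
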