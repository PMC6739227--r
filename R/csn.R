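# Gaussian orthant probabilities ------------------------------------------
#
# Phi_m(upper; Sigma): P(X <= upper) for X ~ N(0, Sigma), via the
# Genz-Bretz quasi-Monte-Carlo algorithm in mvtnorm.  The absolute
# tolerance is config-exposed; dimensions here never exceed M - 1
# (11 in the motivating 12-visit design).
orthant_prob <- function(upper, Sigma, abseps = 1e-8) {
  m <- length(upper)
  if (m == 0L) return(1)
  if (m == 1L) return(pnorm(upper / sqrt(Sigma[1, 1])))
  if (m <= 6L) {
    # deterministic quadrature is fast and ~1e-8 accurate at low dimension
    p <- tryCatch(as.numeric(mvtnorm::pmvnorm(
      upper = upper, sigma = Sigma,
      algorithm = mvtnorm::Miwa(steps = 256))), error = function(e) NA_real_)
    if (is.finite(p) && p >= -1e-12) return(min(max(p, 0), 1))
  }
  as.numeric(mvtnorm::pmvnorm(
    upper = upper, sigma = Sigma,
    algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = 25000L * m)))
}

# Gradient of Phi_m(a; Sigma) w.r.t. a: the l-th element is
# phi(a_l; Sigma_ll) * Phi_{m-1}(conditional remainder).
orthant_grad <- function(a, Sigma, abseps = 1e-8) {
  m <- length(a)
  vapply(seq_len(m), function(l) {
    sll <- Sigma[l, l]
    dens <- dnorm(a[l], 0, sqrt(sll))
    if (m == 1L) return(dens)
    cm <- Sigma[-l, l] * a[l] / sll
    cv <- Sigma[-l, -l, drop = FALSE] -
      tcrossprod(Sigma[-l, l]) / sll
    dens * orthant_prob(a[-l] - cm, cv, abseps)
  }, numeric(1))
}

# Hessian of Phi_m(a; Sigma).  Off-diagonal entries use the bivariate
# density times an (m-2)-dimensional conditional orthant probability;
# diagonal entries follow from the Gaussian identity
#   d2Phi/da_l^2 = -(a_l/S_ll) dPhi/da_l - sum_{k!=l} (S_kl/S_ll) d2Phi/da_k da_l.
orthant_hess <- function(a, Sigma, grad = NULL, abseps = 1e-8) {
  m <- length(a)
  if (is.null(grad)) grad <- orthant_grad(a, Sigma, abseps)
  H <- matrix(0, m, m)
  if (m >= 2L) {
    for (k in seq_len(m - 1L)) {
      for (l in seq((k + 1L), m)) {
        idx <- c(k, l)
        S2 <- Sigma[idx, idx]
        d2 <- mvtnorm::dmvnorm(a[idx], sigma = S2)
        if (m == 2L) {
          tailp <- 1
        } else {
          S2inv <- solve(S2)
          cm <- Sigma[-idx, idx, drop = FALSE] %*% S2inv %*% a[idx]
          cv <- Sigma[-idx, -idx, drop = FALSE] -
            Sigma[-idx, idx, drop = FALSE] %*% S2inv %*%
            Sigma[idx, -idx, drop = FALSE]
          tailp <- orthant_prob(a[-idx] - drop(cm), cv, abseps)
        }
        H[k, l] <- H[l, k] <- d2 * tailp
      }
    }
  }
  for (l in seq_len(m)) {
    off <- if (m >= 2L) sum(Sigma[l, -l] * H[l, -l]) else 0
    H[l, l] <- -(a[l] / Sigma[l, l]) * grad[l] - off / Sigma[l, l]
  }
  H
}

# Closed skew-normal conditional law ---------------------------------------

#' Conditional distribution of the random effects given a subject's
#' observed data
#'
#' Under the shared parameter model, the density of `b` given a subject's
#' observed outcomes, dropout visit and covariate history is proportional
#' to `phi(b; mu, Omega) * prod_l Phi(c_l + d_l' b)`: the Gaussian factor
#' is the usual mixed-model conjugate update of the `N(0, Sigma_b)` prior
#' by the observed outcome rows, and each probit survival/event factor of
#' the dropout likelihood contributes one skew factor.  A dropout at visit
#' `S < M` contributes `S` factors (`S - 1` survival factors plus the
#' event factor, whose argument enters with flipped sign since
#' `lambda = Phi(-eta)`); a completer contributes `M - 1` survival
#' factors.  This is a closed skew-normal (CSN) distribution; its
#' normalizing constant is an `m`-dimensional Gaussian orthant
#' probability.
#'
#' @param subject A subject record (see [spm_data()]).
#' @param params An [spm_params()] object.
#' @param orthant_tol Absolute tolerance for orthant probabilities.
#' @return An object of class `spm_csn` with fields `mu`, `Omega` (the
#'   base Gaussian), `c`, `D` (skew offsets/slopes, one row per probit
#'   factor), and `log_norm` (log normalizing constant).
#' @export
conditional_random_effects <- function(subject, params, orthant_tol = 1e-8) {
  obs <- subject$obs
  if (!any(obs)) abort("Subject has no observed outcomes.")
  M <- length(subject$y)
  S <- subject$S
  Sigma_b <- sigma_b_from_cholesky(params$re_cov)

  Zo <- subject$Z[obs, , drop = FALSE]
  Xo <- subject$X[obs, , drop = FALSE]
  beta <- align_coef(params$beta, subject$X, "beta")
  resid <- subject$y[obs] - drop(Xo %*% beta)
  prec <- solve(Sigma_b) + crossprod(Zo) / params$sigma_eps^2
  Omega <- solve(prec)
  Omega <- (Omega + t(Omega)) / 2
  mu <- drop(Omega %*% crossprod(Zo, resid)) / params$sigma_eps^2

  m <- if (S < M) S else M - 1L
  alpha <- align_coef(params$alpha, subject$Xs, "alpha")
  cvec <- drop(subject$Xs[seq_len(m), , drop = FALSE] %*% alpha)
  D <- t(vapply(seq_len(m), function(l) {
    g <- gamma_at(params, l)
    if (!is.null(subject$W)) drop(crossprod(subject$W[[l]], g)) else g
  }, numeric(2)))
  if (S < M) {             # event factor: lambda_S = Phi(-eta_S)
    cvec[S] <- -cvec[S]
    D[S, ] <- -D[S, ]
  }
  Sigma_star <- diag(m) + D %*% Omega %*% t(D)
  log_norm <- log(orthant_prob(cvec + drop(D %*% mu), Sigma_star,
                               orthant_tol))
  structure(list(mu = mu, Omega = Omega, c = cvec, D = D,
                 log_norm = log_norm, orthant_tol = orthant_tol),
            class = "spm_csn")
}

#' @export
print.spm_csn <- function(x, ...) {
  cat("<spm_csn> q = ", length(x$mu), ", m = ", length(x$c),
      " skew factors, log-normalizer ", signif(x$log_norm, 4), "\n", sep = "")
  invisible(x)
}

#' Density of a closed skew-normal distribution
#'
#' @param b Numeric matrix (`n x q`) or vector of evaluation points.
#' @param csn An `spm_csn` object from [conditional_random_effects()].
#' @param log Return the log-density?
#' @return Numeric vector of (log-)density values.
#' @export
dcsn <- function(b, csn, log = FALSE) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  base <- mvtnorm::dmvnorm(b, mean = csn$mu, sigma = csn$Omega, log = TRUE)
  arg <- sweep(b %*% t(csn$D), 2, csn$c, "+")
  skew <- rowSums(matrix(pnorm(arg, log.p = TRUE), nrow = nrow(b)))
  out <- base + skew - csn$log_norm
  if (log) out else exp(out)
}

#' Exact mean and covariance of a closed skew-normal
#'
#' Obtained from first and second derivatives of the log of the Gaussian
#' orthant normalizing constant: with `a* = c + D mu` and
#' `Sigma* = I + D Omega D'`, the mean is
#' `mu + Omega D' grad log Phi_m(a*; Sigma*)` and the covariance is
#' `Omega + Omega D' (hess log Phi_m) D Omega`.  Each evaluation needs
#' `m`- and `(m-1)`/`(m-2)`-dimensional orthant probabilities.
#'
#' @param csn An `spm_csn` object.
#' @return A list with `mean` (length `q`), `cov` (`q x q`), and
#'   `sigma_b2` (the standard deviation of the random slope, the driver of
#'   the sensitivity adjustment).
#' @export
csn_moments <- function(csn) {
  m <- length(csn$c)
  if (m == 0L || all(csn$D == 0)) {
    q <- nrow(csn$Omega)
    return(list(mean = csn$mu, cov = csn$Omega,
                sigma_b2 = sqrt(csn$Omega[q, q])))
  }
  a <- csn$c + drop(csn$D %*% csn$mu)
  Sigma_star <- diag(m) + csn$D %*% csn$Omega %*% t(csn$D)
  K <- orthant_prob(a, Sigma_star, csn$orthant_tol)
  if (!is.finite(K) || K <= 0)
    abort("Orthant normalizing constant is numerically singular.")
  g <- orthant_grad(a, Sigma_star, csn$orthant_tol)
  H <- orthant_hess(a, Sigma_star, grad = g, csn$orthant_tol)
  u <- g / K
  Hlog <- H / K - tcrossprod(u)
  OD <- csn$Omega %*% t(csn$D)
  mean <- csn$mu + drop(OD %*% u)
  cov <- csn$Omega + OD %*% Hlog %*% t(OD)
  cov <- (cov + t(cov)) / 2
  list(mean = mean, cov = cov,
       sigma_b2 = sqrt(max(cov[nrow(cov), ncol(cov)], 0)))
}

#' Exact sampling from a closed skew-normal by rejection
#'
#' Proposes from the base Gaussian `N(mu, Omega)` and accepts with
#' probability `prod_l Phi(c_l + d_l' b)` (each factor is at most 1, so
#' this is a valid acceptance probability and the accepted draws are
#' exact).  The expected acceptance rate equals the normalizing constant
#' `exp(log_norm)`.
#'
#' @param csn An `spm_csn` object.
#' @param n Number of draws.
#' @param seed Optional seed (set just before sampling).
#' @param accept_floor Error if the estimated acceptance rate falls below
#'   this floor; such subjects need a sequential one-factor-at-a-time
#'   scheme instead.
#' @return An `n x q` matrix of draws, with attribute `acceptance_rate`.
#' @export
sample_csn <- function(csn, n, seed = NULL, accept_floor = 1e-4) {
  if (n < 1) abort("`n` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  # constant factors (zero skew slope) cancel against the normalizer and
  # need not enter the acceptance probability
  live <- rowSums(csn$D != 0) > 0
  D <- csn$D[live, , drop = FALSE]
  cvec <- csn$c[live]
  lconst <- sum(pnorm(csn$c[!live], log.p = TRUE))
  rate <- exp(csn$log_norm - lconst)
  if (rate < accept_floor)
    abort(paste0("Rejection acceptance rate ", signif(rate, 3),
                 " is below the floor ", accept_floor,
                 "; use a sequential one-factor-at-a-time sampler."))
  q <- length(csn$mu)
  L <- chol(csn$Omega)
  out <- matrix(NA_real_, n, q)
  got <- 0L
  tried <- 0L
  accepted <- 0L
  while (got < n) {
    batch <- max(1000L, ceiling((n - got) / max(rate, 1e-3)))
    batch <- min(batch, 500000L)
    prop <- matrix(rnorm(batch * q), batch, q) %*% L
    prop <- sweep(prop, 2, csn$mu, "+")
    if (nrow(D)) {
      arg <- sweep(prop %*% t(D), 2, cvec, "+")
      lacc <- rowSums(matrix(pnorm(arg, log.p = TRUE), nrow = batch))
      keep <- log(runif(batch)) < lacc
    } else {
      keep <- rep(TRUE, batch)
    }
    tried <- tried + batch
    nk <- sum(keep)
    accepted <- accepted + nk
    if (nk) {
      take <- min(nk, n - got)
      out[got + seq_len(take), ] <- prop[keep, , drop = FALSE][seq_len(take), ,
                                                               drop = FALSE]
      got <- got + take
    }
    if (tried > 1e7 && accepted / tried < accept_floor)
      abort("Rejection sampler acceptance rate below floor; use the sequential fallback.")
  }
  attr(out, "acceptance_rate") <- accepted / tried
  out
}
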