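# Shared builders, oracles and a small cached fit for the test suite.

# --- compact designs -------------------------------------------------------

spec_m8 <- function() {
  spm_spec(study_design(8), fixed = ~ time * trt, hazard = ~ trt + time)
}

trt_sampler <- function(p = 0.5) function(n) tibble::tibble(trt = rbinom(n, 1, p))

truth_m8 <- function(gamma = c(0.23, 0.28)) {
  spm_params(
    beta = c("(Intercept)" = -0.5, "trt" = 0.6, "time" = -1.2,
             "time:trt" = 0.3),
    alpha = c("(Intercept)" = 1.0, "trt" = -0.2, "time" = 0.8),
    gamma = gamma,
    re_cov = re_cov(-0.3, 0.75, 1.1),
    sigma_eps = 0.4)
}

# a bare-bones subject record with full control over the pieces
toy_record <- function(S, y, X = NULL, Z = NULL, Xs = NULL, obs = NULL,
                       p = 1L) {
  M <- length(y)
  if (is.null(X)) X <- matrix(0, M, p)
  if (is.null(Z)) Z <- cbind(1, seq(0, 1, length.out = M))
  if (is.null(Xs)) Xs <- matrix(1, M - 1L, 1L)
  if (is.null(obs)) {
    obs <- !is.na(y)
    obs[seq_len(M) > S] <- FALSE
  }
  structure(list(id = "toy", S = as.integer(S), y = y, obs = obs,
                 X = X, Z = Z, Xs = Xs,
                 covariates = tibble::tibble(.dummy = 1)),
            class = "subject_record")
}

toy_params <- function(alpha = 0, gamma = c(0, 0), delta = 0,
                       sigma1 = 1, sigma2 = 1, sigma_eps = 1, beta = 0) {
  spm_params(beta = beta, alpha = alpha, gamma = gamma,
             re_cov = re_cov(delta, sigma1, sigma2), sigma_eps = sigma_eps)
}

# --- quadrature oracle for 2-D CSN densities ------------------------------

quad_csn <- function(csn, half_width = 10, n_grid = 601) {
  sx <- sqrt(csn$Omega[1, 1])
  sy <- sqrt(csn$Omega[2, 2])
  gx <- seq(csn$mu[1] - half_width * sx, csn$mu[1] + half_width * sx,
            length.out = n_grid)
  gy <- seq(csn$mu[2] - half_width * sy, csn$mu[2] + half_width * sy,
            length.out = n_grid)
  gr <- as.matrix(expand.grid(b1 = gx, b2 = gy))
  dens <- dcsn(gr, csn)
  w <- diff(gx)[1] * diff(gy)[1]
  Z <- sum(dens) * w
  mean <- colSums(gr * dens) * w / Z
  cov <- crossprod(gr, gr * dens) * w / Z - tcrossprod(mean)
  list(integral = Z, mean = unname(mean), cov = unname(cov))
}

# --- one small fitted model, shared across test files ---------------------

.spmsens_test_cache <- new.env(parent = emptyenv())

cached_small_fit <- function() {
  if (is.null(.spmsens_test_cache$fit)) {
    sim <- simulate_spm(spm_generator(60, spec_m8(), truth_m8(),
                                      trt_sampler(), seed = 402))
    .spmsens_test_cache$sim <- sim
    .spmsens_test_cache$fit <- fit_spm(
      sim, mcmc = mcmc_config(chains = 2, burn_in = 150, draws = 250,
                              thin = 1, adapt = 100, seed = 12))
  }
  .spmsens_test_cache$fit
}

cached_small_sim <- function() {
  invisible(cached_small_fit())
  .spmsens_test_cache$sim
}
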