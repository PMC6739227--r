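test_that("modified Cholesky parameterization reproduces the covariance", {
  expect_equal(sigma_b_from_cholesky(re_cov(0, 1, 1)), diag(2))
  expect_equal(sigma_b_from_cholesky(re_cov(0.5, 1, 1)),
               matrix(c(1, 0.5, 0.5, 1.25), 2, 2))
  # oracle: L diag(s1^2, s2^2) L' with unit-lower-triangular L
  d <- 0.7; s1 <- 1.3; s2 <- 0.4
  L <- matrix(c(1, d, 0, 1), 2, 2)
  expect_equal(sigma_b_from_cholesky(re_cov(d, s1, s2)),
               L %*% diag(c(s1^2, s2^2)) %*% t(L))
  # decompose-then-reconstruct is the identity on SPD matrices
  set.seed(71)
  for (i in 1:20) {
    A <- matrix(rnorm(4), 2, 2)
    Sigma <- crossprod(A) + diag(0.1, 2)
    rc <- cholesky_from_sigma_b(Sigma)
    expect_equal(sigma_b_from_cholesky(rc), Sigma, tolerance = 1e-12)
  }
  expect_error(re_cov(0, -1, 1), "positive")
  expect_error(re_cov(0, 1, 0), "positive")
})

test_that("probit discrete hazard matches the normal-CDF formula", {
  rec <- toy_record(S = 3, y = c(0, 0, NA, NA) + 0, Xs = matrix(1, 3, 1))
  # linear predictor 0 -> hazard one half
  expect_equal(discrete_hazard(rec, 1, c(0, 0), toy_params(alpha = 0)), 0.5)
  # x'alpha = 1.645, gamma = 0 -> 1 - Phi(1.645) ~ 0.05
  lam <- discrete_hazard(rec, 1, c(2, -3), toy_params(alpha = 1.645))
  expect_equal(lam, 1 - pnorm(1.645), tolerance = 1e-12)
  expect_equal(lam, 0.05, tolerance = 1e-3)
  # posterior-mean-scale smoke value: x'alpha = 1.11, gamma = (.23, .28),
  # b = (1,1) -> 1 - Phi(1.62)
  lam2 <- discrete_hazard(rec, 2, c(1, 1),
                          toy_params(alpha = 1.11, gamma = c(0.23, 0.28)))
  expect_equal(lam2, 1 - pnorm(1.62), tolerance = 1e-12)
  expect_equal(lam2, 0.0526, tolerance = 1e-3)
  expect_error(discrete_hazard(rec, 4, c(0, 0), toy_params()), "Risk index")
  expect_error(discrete_hazard(rec, 0, c(0, 0), toy_params()), "Risk index")
})

test_that("dropout likelihood enumerates the sequential-Bernoulli law", {
  # all hazards one half at M = 3: P(S) = 1/2, 1/4, 1/4
  p <- toy_params(alpha = 0)
  probs <- vapply(1:3, function(S) {
    rec <- toy_record(S = S, y = rep(0, 3), Xs = matrix(0, 2, 1))
    exp(dropout_loglik(rec, c(0.3, -0.1), p))
  }, numeric(1))
  expect_equal(probs, c(0.5, 0.25, 0.25), tolerance = 1e-12)
  # gamma = 0 makes the dropout law free of the random effects
  rec <- toy_record(S = 2, y = rep(0, 4), Xs = matrix(c(1, -1, 2), 3, 1))
  p2 <- toy_params(alpha = 0.4)
  expect_equal(dropout_loglik(rec, c(5, -7), p2),
               dropout_loglik(rec, c(0, 0), p2))
  # completers: M - 1 survival factors, no event factor
  recM <- toy_record(S = 4, y = rep(0, 4), Xs = matrix(c(1, -1, 2), 3, 1))
  b <- c(0.2, 0.1)
  p3 <- toy_params(alpha = 0.4, gamma = c(0.3, -0.2))
  eta <- drop(recM$Xs %*% p3$alpha) + 0.3 * b[1] - 0.2 * b[2]
  expect_equal(dropout_loglik(recM, b, p3),
               sum(pnorm(eta, log.p = TRUE)), tolerance = 1e-12)
})

test_that("dropout probabilities over all possible S sum to one", {
  set.seed(90)
  M <- 5
  for (i in 1:200) {
    Xs <- matrix(rnorm(2 * (M - 1)), M - 1, 2)
    p <- toy_params(alpha = rnorm(2), gamma = rnorm(2, 0, 0.6),
                    delta = rnorm(1), sigma1 = runif(1, 0.3, 2),
                    sigma2 = runif(1, 0.3, 2))
    b <- rnorm(2, 0, 2)
    tot <- sum(vapply(seq_len(M), function(S) {
      rec <- toy_record(S = S, y = rep(0, M), Xs = Xs)
      exp(dropout_loglik(rec, b, p))
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("longitudinal log-density handles observed rows only", {
  # one observation with zero residual, unit sigma: -log(2*pi)/2
  rec <- toy_record(S = 1, y = c(0, NA, NA))
  expect_equal(longitudinal_loglik(rec, c(0, 0), toy_params()),
               -0.5 * log(2 * pi))
  # residuals (1, -1): sum of two univariate normal log-densities
  rec2 <- toy_record(S = 2, y = c(1, -1, NA))
  b0 <- c(0, 0)
  expect_equal(longitudinal_loglik(rec2, b0, toy_params()),
               -log(2 * pi) - 1)
  # unobserved visits' design rows are irrelevant
  rec3 <- rec2
  rec3$X[3, ] <- 99
  rec3$y[3] <- 123  # ignored: obs flag is FALSE
  rec3$obs[3] <- FALSE
  expect_equal(longitudinal_loglik(rec3, b0, toy_params()),
               longitudinal_loglik(rec2, b0, toy_params()))
  # intermittent gap: middle visit missing
  rec4 <- toy_record(S = 3, y = c(1, NA, -1))
  expect_equal(longitudinal_loglik(rec4, b0, toy_params()),
               -log(2 * pi) - 1)
})

test_that("joint log-density is the sum of its three parts and separates
          when dropout is ignorable", {
  rec <- toy_record(S = 2, y = c(0.4, -0.2, NA), Xs = matrix(c(1, 0.5), 2, 1))
  p <- toy_params(alpha = 0.3, gamma = c(0.2, -0.1), delta = 0.4,
                  sigma1 = 0.8, sigma2 = 1.2, sigma_eps = 0.5)
  b <- c(0.3, -0.6)
  Sigma <- sigma_b_from_cholesky(p$re_cov)
  expect_equal(joint_loglik_given_b(rec, b, p),
               longitudinal_loglik(rec, b, p) + dropout_loglik(rec, b, p) +
                 mvtnorm::dmvnorm(b, sigma = Sigma, log = TRUE),
               tolerance = 1e-10)

  # gamma = 0: integrating exp(joint) over b factorizes into the dropout
  # mass times the longitudinal-marginal integral (quadrature oracle)
  p0 <- toy_params(alpha = 0.3, gamma = c(0, 0), delta = 0.4,
                   sigma1 = 0.8, sigma2 = 1.2, sigma_eps = 0.5)
  g <- seq(-6, 6, length.out = 161)
  gr <- as.matrix(expand.grid(g, g))
  w <- diff(g)[1]^2
  joint_int <- sum(exp(apply(gr, 1, function(b)
    joint_loglik_given_b(rec, b, p0)))) * w
  long_int <- sum(exp(apply(gr, 1, function(b)
    longitudinal_loglik(rec, b, p0) +
      mvtnorm::dmvnorm(b, sigma = sigma_b_from_cholesky(p0$re_cov),
                       log = TRUE)))) * w
  drop_mass <- exp(dropout_loglik(rec, c(0, 0), p0))
  expect_equal(joint_int, long_int * drop_mass, tolerance = 1e-6)
})

test_that("with ignorable dropout and zero residuals the prior mode
          maximizes the joint density over b", {
  rec <- toy_record(S = 3, y = c(0, 0, 0), Xs = matrix(1, 2, 1))
  p <- toy_params(alpha = 0.5, gamma = c(0, 0))
  f <- function(b) joint_loglik_given_b(rec, b, p)
  eps <- 1e-5
  g1 <- (f(c(eps, 0)) - f(c(-eps, 0))) / (2 * eps)
  g2 <- (f(c(0, eps)) - f(c(0, -eps))) / (2 * eps)
  expect_lt(abs(g1), 1e-6)
  expect_lt(abs(g2), 1e-6)
  expect_gt(f(c(0, 0)), f(c(0.3, -0.2)))
})

test_that("long-format tables round-trip into subject records", {
  sim <- simulate_spm(spm_generator(12, spec_m8(), truth_m8(),
                                    trt_sampler(), intermittent_rate = 0.1,
                                    seed = 31))
  long <- as_tibble(sim$data)
  long_obs <- dplyr::filter(long, visit <= S)
  dat <- spm_data(dplyr::select(long_obs, -"observed"), spec_m8(),
                  s_col = "S")
  expect_length(dat$subjects, 12)
  for (i in seq_along(dat$subjects)) {
    a <- dat$subjects[[i]]
    b <- sim$data$subjects[[i]]
    expect_equal(a$S, b$S)
    expect_equal(a$y, b$y)
    expect_equal(a$obs, b$obs)
    expect_equal(unname(a$X), unname(b$X))
  }
  # derived S (last observed visit) agrees when no trailing gap exists
  dat2 <- spm_data(dplyr::select(long_obs, -"observed", -"S"), spec_m8())
  S2 <- vapply(dat2$subjects, `[[`, integer(1), "S")
  last_obs <- vapply(sim$data$subjects,
                     function(s) max(which(s$obs)), integer(1))
  expect_equal(S2, last_obs)
  # visit-1 outcome is required
  bad <- dplyr::mutate(long_obs,
                       y = ifelse(visit == 1, NA_real_, y))
  expect_error(spm_data(dplyr::select(bad, -"observed"), spec_m8(),
                        s_col = "S"), "visit 1")
})
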