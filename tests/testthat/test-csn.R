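# make an spm_csn by hand (the class is just a parameter bundle)
manual_csn <- function(mu, Omega, cvec, D, orthant_tol = 1e-8) {
  mu <- as.numeric(mu)
  Omega <- as.matrix(Omega)
  D <- matrix(D, ncol = length(mu))
  Sigma_star <- diag(length(cvec)) + D %*% Omega %*% t(D)
  ln <- log(spmsens:::orthant_prob(cvec + drop(D %*% mu), Sigma_star,
                                   orthant_tol))
  structure(list(mu = mu, Omega = Omega, c = cvec, D = D, log_norm = ln,
                 orthant_tol = orthant_tol), class = "spm_csn")
}

test_that("ignorable dropout reduces the conditional law to the conjugate
          Gaussian update", {
  # prior I2, one observation with z = (1, 0), sigma_eps = 1, residual 2:
  # posterior mean (1, 0), variance diag(1/2, 1)
  spec <- spm_spec(study_design(2), fixed = ~ 1, hazard = ~ 1)
  rec <- toy_record(S = 2, y = c(2, NA), Z = cbind(1, c(0, 1)),
                    Xs = matrix(1, 1, 1))
  rec$obs <- c(TRUE, FALSE)  # dropout right after baseline
  rec$S <- 1L
  p <- toy_params(alpha = 0.3, gamma = c(0, 0))
  csn <- conditional_random_effects(rec, p)
  expect_equal(csn$mu, c(1, 0), tolerance = 1e-12)
  expect_equal(csn$Omega, diag(c(0.5, 1)), tolerance = 1e-12)
  expect_true(all(csn$D == 0))
  mo <- csn_moments(csn)
  expect_equal(mo$mean, csn$mu)
  expect_equal(mo$cov, csn$Omega)
  expect_equal(mo$sigma_b2, 1)
  # density equals the bivariate normal
  pts <- rbind(c(0, 0), c(1, -1), c(2, 0.5))
  expect_equal(dcsn(pts, csn),
               mvtnorm::dmvnorm(pts, mean = csn$mu, sigma = csn$Omega),
               tolerance = 1e-10)
})

test_that("the one-dimensional half-normal-skew case has known constants", {
  # density proportional to phi(b) * Phi(b): normalizer 1/2, mean 1/sqrt(pi)
  csn <- manual_csn(0, matrix(1), 0, 1)
  expect_equal(csn$log_norm, log(0.5), tolerance = 1e-9)
  mo <- csn_moments(csn)
  expect_equal(mo$mean, 1 / sqrt(pi), tolerance = 1e-7)
  # skew-normal variance 1 - 2/(pi * 2) = 1 - 1/pi for delta = 1/sqrt(2)
  expect_equal(drop(mo$cov), 1 - 1 / pi, tolerance = 1e-7)
  dr <- sample_csn(csn, 40000, seed = 1)
  expect_lt(abs(mean(dr) - 1 / sqrt(pi)), 3 * sd(dr) / sqrt(40000))
})

test_that("orthant-probability derivatives match finite differences", {
  set.seed(7)
  A <- matrix(rnorm(9, sd = 0.4), 3, 3)
  Sigma <- crossprod(A) + diag(3)
  a <- c(0.3, -0.2, 0.8)
  # deterministic quadrature reference (the randomized QMC routine is too
  # noisy to difference at h^2 scale)
  miwa <- function(upper)
    as.numeric(mvtnorm::pmvnorm(upper = upper, sigma = Sigma,
                                algorithm = mvtnorm::Miwa(steps = 512)))
  g <- spmsens:::orthant_grad(a, Sigma)
  H <- spmsens:::orthant_hess(a, Sigma, grad = g)
  h <- 1e-3
  for (l in 1:3) {
    e <- replace(numeric(3), l, h)
    fd <- (miwa(a + e) - miwa(a - e)) / (2 * h)
    expect_equal(g[l], fd, tolerance = 1e-5)
  }
  for (k in 1:3) for (l in 1:3) {
    ek <- replace(numeric(3), k, h)
    el <- replace(numeric(3), l, h)
    fd2 <- (miwa(a + ek + el) - miwa(a + ek - el) -
              miwa(a - ek + el) + miwa(a - ek - el)) / (4 * h^2)
    expect_equal(H[k, l], fd2, tolerance = 1e-4)
  }
})

test_that("closed-form moments agree with quadrature and with rejection
          sampling on a dropout subject", {
  sim <- simulate_spm(spm_generator(30, spec_m8(), truth_m8(), trt_sampler(),
                                    seed = 4))
  S <- vapply(sim$data$subjects, `[[`, integer(1), "S")
  idx <- which(S >= 3 & S <= 6)[1:3]
  for (i in idx) {
    csn <- conditional_random_effects(sim$data$subjects[[i]], truth_m8())
    q <- quad_csn(csn)
    expect_equal(q$integral, 1, tolerance = 1e-6)
    mo <- csn_moments(csn)
    expect_equal(mo$mean, q$mean, tolerance = 1e-4)
    expect_equal(mo$cov, q$cov, tolerance = 1e-4)
    # sampling check pooled over independent streams: each stream's
    # Mahalanobis mean-error statistic is chi-square(2), so the sum over
    # four streams is chi-square(8); a biased sampler inflates every term
    maha <- sum(vapply(0:3, function(k) {
      dr <- sample_csn(csn, 30000, seed = i + 1000 * k)
      err <- colMeans(dr) - mo$mean
      drop(t(err) %*% solve(mo$cov / nrow(dr)) %*% err)
    }, numeric(1)))
    expect_lt(maha, qchisq(0.999, df = 8))
  }
})

test_that("an unnormalized density renormalized by quadrature matches dcsn", {
  sim <- simulate_spm(spm_generator(30, spec_m8(), truth_m8(), trt_sampler(),
                                    seed = 4))
  s <- sim$data$subjects[[which(vapply(sim$data$subjects, `[[`, integer(1),
                                       "S") < 8)[1]]]
  csn <- conditional_random_effects(s, truth_m8())
  q <- quad_csn(csn)
  pts <- rbind(csn$mu, csn$mu + c(0.3, -0.4), csn$mu - c(0.5, 0.1))
  unnorm <- function(b) {
    mvtnorm::dmvnorm(b, mean = csn$mu, sigma = csn$Omega) *
      apply(pnorm(sweep(b %*% t(csn$D), 2, csn$c, "+")), 1, prod)
  }
  # quadrature renormalization of the unnormalized density
  expect_equal(unnorm(pts) / exp(csn$log_norm) / q$integral, dcsn(pts, csn),
               tolerance = 1e-6)
})

test_that("rejection sampling is exact, seeded, and accepts everything in
          the Gaussian case", {
  csn0 <- manual_csn(c(0.5, -0.5), diag(c(1, 0.5)), c(2, 1),
                     matrix(0, 2, 2))
  dr <- sample_csn(csn0, 5000, seed = 8)
  expect_equal(attr(dr, "acceptance_rate"), 1)
  d1 <- sample_csn(csn0, 100, seed = 11)
  d2 <- sample_csn(csn0, 100, seed = 11)
  expect_identical(d1, d2)
  # an impossible acceptance rate triggers the fallback advice
  csn_bad <- manual_csn(0, matrix(1), -15, 1)
  expect_error(sample_csn(csn_bad, 10, seed = 1), "floor")
})

test_that("hazard factor counts follow the dropout pattern", {
  sim <- simulate_spm(spm_generator(40, spec_m8(), truth_m8(), trt_sampler(),
                                    seed = 13))
  for (s in sim$data$subjects[1:20]) {
    csn <- conditional_random_effects(s, truth_m8())
    m_expect <- if (s$S < 8) s$S else 7L
    expect_length(csn$c, m_expect)
    if (s$S < 8) {
      # event factor enters with flipped sign
      expect_equal(csn$D[s$S, ], -truth_m8()$gamma)
      if (s$S > 1) expect_equal(csn$D[1, ], truth_m8()$gamma)
    }
  }
})
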