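test_that("the generator is deterministic and grows without reshuffling", {
  gen <- spm_generator(15, spec_m8(), truth_m8(), trt_sampler(), seed = 5)
  s1 <- simulate_spm(gen)
  s2 <- simulate_spm(gen)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as_tibble(s1$data), as_tibble(s2$data))
  # enlarging N leaves earlier subjects untouched
  s3 <- simulate_spm(spm_generator(30, spec_m8(), truth_m8(),
                                   trt_sampler(), seed = 5))
  expect_identical(s1$truth$y_complete, s3$truth$y_complete[1:15, ])
  expect_identical(s1$truth$S, s3$truth$S[1:15])
  # and the written files are byte-identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_spm_sim(s1, d1)
  write_spm_sim(s2, d2)
  for (f in c("dataset.csv", "truth_params.yaml", "truth_subjects.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("observed records respect the missingness conventions", {
  sim <- simulate_spm(spm_generator(80, spec_m8(), truth_m8(), trt_sampler(),
                                    intermittent_rate = 0.3, seed = 9))
  for (s in sim$data$subjects) {
    expect_true(s$obs[1])                        # baseline always observed
    if (s$S < 8) expect_false(any(s$obs[(s$S + 1):8]))
    expect_true(all(is.na(s$y[!s$obs])))
  }
  # written dataset has at most N * M outcome rows and no truth columns
  d <- withr::local_tempdir()
  write_spm_sim(sim, d)
  ds <- readr::read_csv(file.path(d, "dataset.csv"), show_col_types = FALSE)
  expect_lte(sum(!is.na(ds$y)), 80 * 8)
  expect_false(any(grepl("complete|^b[12]$", names(ds))))
})

test_that("intermittent masking hits its target rate", {
  # masking applies to in-follow-up visits after baseline
  rate <- 0.076
  sim <- simulate_spm(spm_generator(1500, spec_m8(), truth_m8(),
                                    trt_sampler(), intermittent_rate = rate,
                                    seed = 17))
  eligible <- sum(pmax(sim$truth$S - 1L, 0L))
  masked <- sum(vapply(sim$data$subjects, function(s)
    sum(!s$obs[seq_len(s$S)]), integer(1)))
  se <- sqrt(rate * (1 - rate) / eligible)
  expect_lt(abs(masked / eligible - rate), 3 * se)
})

test_that("with ignorable dropout the empirical dropout law matches the
          closed-form sequential-Bernoulli pmf", {
  M <- 4
  spec <- spm_spec(study_design(M), fixed = ~ time, hazard = ~ time)
  truth <- spm_params(beta = c("(Intercept)" = 0, "time" = -1),
                      alpha = c("(Intercept)" = 0.9, "time" = -0.4),
                      gamma = c(0, 0), re_cov = re_cov(-0.3, 0.8, 1),
                      sigma_eps = 0.4)
  n <- 6000
  sim <- simulate_spm(spm_generator(n, spec, truth,
                                    function(k) tibble::tibble(.x = rep(1, k)),
                                    seed = 23))
  # closed form: hazard free of b
  tt <- spec$design$times[1:(M - 1)]
  lam <- 1 - pnorm(0.9 - 0.4 * tt)
  pmf <- c(lam[1], (1 - lam[1]) * lam[2], (1 - lam[1]) * (1 - lam[2]) * lam[3],
           prod(1 - lam))
  obs <- tabulate(sim$truth$S, nbins = M)
  gof <- suppressWarnings(stats::chisq.test(obs, p = pmf))
  expect_gt(gof$p.value, 0.001)
})

test_that("complete outcomes recover the marginal fixed-effect mean and
          degenerate noise collapses to it", {
  sim <- simulate_spm(spm_generator(4000, spec_m8(), truth_m8(),
                                    trt_sampler(), seed = 41))
  fixed <- t(vapply(sim$data$subjects, function(s) {
    beta <- spmsens:::align_coef(truth_m8()$beta, s$X)
    drop(s$X %*% beta)
  }, numeric(8)))
  resid <- sim$truth$y_complete - fixed
  se <- apply(resid, 2, sd) / sqrt(nrow(resid))
  expect_true(all(abs(colMeans(resid)) < 3 * se))

  # sigma1 = sigma2 = sigma_eps -> 0: Y equals the fixed part exactly
  tr0 <- spm_params(beta = truth_m8()$beta, alpha = truth_m8()$alpha,
                    gamma = c(0.23, 0.28),
                    re_cov = re_cov(-0.3, 1e-10, 1e-10), sigma_eps = 1e-10)
  sim0 <- simulate_spm(spm_generator(20, spec_m8(), tr0, trt_sampler(),
                                     seed = 3))
  fixed0 <- t(vapply(sim0$data$subjects, function(s) {
    beta <- spmsens:::align_coef(tr0$beta, s$X)
    drop(s$X %*% beta)
  }, numeric(8)))
  expect_equal(sim0$truth$y_complete, fixed0, tolerance = 1e-7)
})

test_that("positive association produces steeper observed decline among
          early dropouts than among completers", {
  # gamma2 > 0: higher slope protects against dropout, so dropouts decline
  # faster on average
  sim <- simulate_spm(spm_generator(3000, spec_m8(), truth_m8(),
                                    trt_sampler(), seed = 59))
  ols_slope <- function(s) {
    t <- s$Z[s$obs, 2]
    y <- s$y[s$obs]
    if (length(y) < 3) return(NA_real_)
    stats::cov(t, y) / stats::var(t)
  }
  slopes <- vapply(sim$data$subjects, ols_slope, numeric(1))
  S <- sim$truth$S
  early <- slopes[S < 8 & !is.na(slopes)]
  completers <- slopes[S == 8]
  expect_lt(mean(early), mean(completers))
})
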