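test_that("G-computation at one draw is reproducible and anchored at
          a = 0", {
  p <- truth_m8()
  prof <- gcomp_profiles(trt = c(0, 1))
  g1 <- gcomp_one_draw(p, prof, spec_m8(), a = 0, n_mc = 2000, seed = 3)
  g2 <- gcomp_one_draw(p, prof, spec_m8(), a = 0, n_mc = 2000, seed = 3)
  expect_identical(g1, g2)
  expect_identical(g1$sensitivity, g1$default)
  # the default column ignores the sensitivity configuration entirely
  g3 <- gcomp_one_draw(p, prof, spec_m8(), a = -1.7,
                       sens = sensitivity_config(sigma_group_cap = 8L),
                       n_mc = 2000, seed = 3)
  expect_identical(g3$default, g1$default)
  expect_true(all(g3$sensitivity <= g3$default))
  # exact per-replicate slope SDs follow the same contract at small n
  g5 <- gcomp_one_draw(p, prof, spec_m8(), a = 0, n_mc = 250, seed = 9)
  g6 <- gcomp_one_draw(p, prof, spec_m8(), a = -0.4,
                       sens = sensitivity_config(sigma_mode = "exact"),
                       n_mc = 250, seed = 9)
  expect_identical(g6$default, g5$default)
  expect_true(all(g6$sensitivity <= g6$default))
})

test_that("post-dropout predicted means are monotone in the sensitivity
          parameter", {
  p <- truth_m8()
  prof <- gcomp_profiles(trt = 0)
  runs <- lapply(c(-2, -1, 0), function(a)
    gcomp_one_draw(p, prof, spec_m8(), a = a,
                   sens = sensitivity_config(sigma_group_cap = 12L),
                   n_mc = 4000, seed = 11))
  for (i in 1:2) {
    lo <- dplyr::filter(runs[[i]], stat == "mean")$sensitivity
    hi <- dplyr::filter(runs[[i + 1]], stat == "mean")$sensitivity
    expect_true(all(lo <= hi))
    expect_lt(lo[8], hi[8])   # strictly below at the final visit
  }
})

test_that("a covariate with no model coefficients cannot move contrasts", {
  spec <- spm_spec(study_design(6), fixed = ~ time * (trt + inert),
                   hazard = ~ trt + inert + time)
  p <- spm_params(
    beta = c("(Intercept)" = -0.5, "trt" = 0.6, "inert" = 0, "time" = -1.2,
             "time:trt" = 0.3, "time:inert" = 0),
    alpha = c("(Intercept)" = 1.0, "trt" = -0.2, "inert" = 0, "time" = 0.8),
    gamma = c(0.23, 0.28), re_cov = re_cov(-0.3, 0.75, 1.1),
    sigma_eps = 0.4)
  prof <- gcomp_profiles(trt = 0, inert = c(0, 1))
  g <- gcomp_one_draw(p, prof, spec, a = NULL, n_mc = 20000, seed = 7)
  g$draw <- 1L
  g$a <- NA_real_
  ct <- gcomp_contrasts(g, data.frame(profile = prof$label[2],
                                      reference = prof$label[1]))
  sd_y <- 1.6
  expect_true(all(abs(ct$default) < 4 * sqrt(2) * sd_y / sqrt(20000)))
})

test_that("contrast algebra behaves like differences", {
  fit <- cached_small_fit()
  prof <- gcomp_profiles(trt = c(0, 1))
  gc <- spm_gcompute(fit, prof, a_fixed = 0, n_draws = 3, n_mc = 1500,
                     seed = 2)
  self <- gcomp_contrasts(gc, data.frame(profile = prof$label[1],
                                         reference = prof$label[1]))
  expect_true(all(self$default == 0))
  expect_true(all(self$sensitivity == 0))
  ab <- gcomp_contrasts(gc, data.frame(profile = prof$label[1],
                                       reference = prof$label[2]))
  ba <- gcomp_contrasts(gc, data.frame(profile = prof$label[2],
                                       reference = prof$label[1]))
  expect_equal(ab$default, -ba$default)
  expect_equal(ab$sensitivity, -ba$sensitivity)
  expect_error(gcomp_contrasts(gc, data.frame(profile = "nope",
                                              reference = prof$label[1])),
               "Unknown profile")
})

test_that("posterior summarization reduces draws to calibrated cells", {
  fit <- cached_small_fit()
  prof <- gcomp_profiles(trt = 0)
  gc <- spm_gcompute(fit, prof, a_fixed = 0, n_draws = 4, n_mc = 1000,
                     seed = 5)
  sm <- summarize_posterior(gc)
  expect_true(all(sm$conf.low <= sm$estimate & sm$estimate <= sm$conf.high))
  # a single draw yields degenerate intervals at that draw
  one <- gc[gc$draw == 1, ]
  sm1 <- summarize_posterior(one)
  expect_equal(sm1$conf.low, sm1$estimate)
  expect_equal(sm1$conf.high, sm1$estimate)
  # constant input: zero-width intervals at the constant
  const <- gc
  const$default <- 1.5
  const$sensitivity <- 1.5
  smc <- summarize_posterior(const)
  expect_true(all(smc$estimate == 1.5 & smc$conf.low == 1.5 &
                    smc$conf.high == 1.5))
  expect_true(all(smc$excludes_zero))
  # the full posterior pipeline is reproducible
  gc2 <- spm_gcompute(fit, prof, a_fixed = 0, n_draws = 4, n_mc = 1000,
                      seed = 5)
  expect_identical(tibble::as_tibble(gc), tibble::as_tibble(gc2))
  # plotting returns a ggplot without error
  expect_s3_class(autoplot(sm), "ggplot")
})
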