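#' Prior specification for the shared parameter model
#'
#' Defaults: diffuse `N(0, 100)` priors on the fixed effects and on the
#' Cholesky regression coefficient `delta`; weakly informative `N(0, 4)`
#' priors on the hazard coefficients and the association parameters
#' (probit-scale coefficients much beyond 2 are implausible);
#' `sigma_eps^2 ~ Inverse-Gamma(0.001, 0.001)` (shape/rate); and
#' `sigma_k ~ Uniform(0, 5)` on the innovation SDs.
#'
#' @param beta_sd,delta_sd,alpha_gamma_sd Normal prior SDs.
#' @param sigma_eps_shape,sigma_eps_rate Inverse-gamma hyperparameters for
#'   the residual variance.
#' @param sigma_upper Upper bound of the uniform priors on `sigma1`,
#'   `sigma2`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_sd = 10, delta_sd = 10, alpha_gamma_sd = 2,
                       sigma_eps_shape = 0.001, sigma_eps_rate = 0.001,
                       sigma_upper = 5) {
  vals <- c(beta_sd, delta_sd, alpha_gamma_sd, sigma_eps_shape,
            sigma_eps_rate, sigma_upper)
  if (any(vals <= 0)) abort("All prior scales must be positive.")
  structure(list(beta_sd = beta_sd, delta_sd = delta_sd,
                 alpha_gamma_sd = alpha_gamma_sd,
                 sigma_eps_shape = sigma_eps_shape,
                 sigma_eps_rate = sigma_eps_rate,
                 sigma_upper = sigma_upper),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' @param chains Number of chains (default 3).
#' @param burn_in Burn-in iterations per chain (default 5000).
#' @param draws Kept (post-thinning) draws per chain (default 3000, i.e.
#'   9000 pooled with three chains).
#' @param thin Thinning interval (default 5).
#' @param adapt Adaptation iterations (default 1000).
#' @param seed Master seed; chain RNG seeds are derived from it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, burn_in = 5000L, draws = 3000L,
                        thin = 5L, adapt = 1000L, seed = 1L) {
  v <- c(chains, burn_in, draws, thin, adapt)
  if (any(v < 1) || any(v != round(v)))
    abort("MCMC settings must be positive integers.")
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 draws = as.integer(draws), thin = as.integer(thin),
                 adapt = as.integer(adapt), seed = as.integer(seed)),
            class = "mcmc_config")
}

# Flatten an spm_data object into the arrays the JAGS model consumes.
jags_data_from_spm <- function(data) {
  subjects <- data$subjects
  N <- length(subjects)
  M <- data$spec$design$M
  ylist <- vector("list", N)
  rlist <- vector("list", N)
  for (i in seq_len(N)) {
    s <- subjects[[i]]
    obs <- which(s$obs)
    ylist[[i]] <- list(y = s$y[obs], X = s$X[obs, , drop = FALSE],
                       tz = s$Z[obs, 2], sub = rep(i, length(obs)))
    nrisk <- if (s$S < M) s$S else M - 1L
    r <- rep(0L, nrisk)
    if (s$S < M) r[nrisk] <- 1L
    rlist[[i]] <- list(r = r, Xs = s$Xs[seq_len(nrisk), , drop = FALSE],
                       sub = rep(i, nrisk))
  }
  list(
    N = N,
    n_y = sum(lengths(lapply(ylist, `[[`, "y"))),
    y = unlist(lapply(ylist, `[[`, "y")),
    Xy = do.call(rbind, lapply(ylist, `[[`, "X")),
    tz = unlist(lapply(ylist, `[[`, "tz")),
    suby = unlist(lapply(ylist, `[[`, "sub")),
    n_r = sum(lengths(lapply(rlist, `[[`, "r"))),
    r = unlist(lapply(rlist, `[[`, "r")),
    Xr = do.call(rbind, lapply(rlist, `[[`, "Xs")),
    subr = unlist(lapply(rlist, `[[`, "sub"))
  )
}

# Detect the [A, time * A] structure of the fixed-effects design that
# permits hierarchical centering (subject-level means absorbed into the
# random-effect distributions, which decouples the fixed effects from
# the latent effects and mixes far better).  Returns NULL when the
# structure does not hold.
centering_plan <- function(data) {
  rec1 <- data$subjects[[1]]
  cn <- colnames(rec1$X)
  is_time <- cn == "time" | grepl("^time:", cn) | grepl(":time$", cn)
  bcols <- cn[!is_time]
  tcols <- cn[is_time]
  partner <- function(tc) {
    if (tc == "time") return("(Intercept)")
    sub("^time:", "", sub(":time$", "", tc))
  }
  tpart <- vapply(tcols, partner, character(1))
  if (!setequal(tpart, bcols) || length(tcols) != length(bcols)) return(NULL)
  tcols <- tcols[match(bcols, tpart)]   # align pairs
  times <- data$spec$design$times
  for (s in data$subjects) {
    base <- s$X[, bcols, drop = FALSE]
    if (max(abs(sweep(base, 2, base[1, ]))) > 1e-10) return(NULL)
    tv <- s$X[, tcols, drop = FALSE]
    if (max(abs(tv - times %o% base[1, ])) > 1e-10) return(NULL)
  }
  A <- do.call(rbind, lapply(data$subjects,
                             function(s) s$X[1, bcols, drop = TRUE]))
  A <- matrix(A, nrow = length(data$subjects))
  colnames(A) <- bcols
  list(A = A, bcols = bcols, tcols = tcols)
}

spm_jags_model_centered <- function(pb, ps, priors, gamma_zero) {
  gterm <- if (gamma_zero) "0"
  else "gamma[1] * b1[subr[k]] + gamma[2] * b2[subr[k]]"
  gprior <- if (gamma_zero) ""
  else sprintf("  gamma[1] ~ dnorm(0, %.8g)\n  gamma[2] ~ dnorm(0, %.8g)\n",
               1 / priors$alpha_gamma_sd^2, 1 / priors$alpha_gamma_sd^2)
  sprintf("
model {
  for (k in 1:n_y) {
    y[k] ~ dnorm(u[suby[k], 1] + tz[k] * u[suby[k], 2], tau_eps)
  }
  eta_r <- Xr %%*%% alpha
  for (k in 1:n_r) {
    p_r[k] <- max(1e-12, min(1 - 1e-12, phi(-(eta_r[k] + %s))))
    r[k] ~ dbern(p_r[k])
  }
  mu1v <- A %%*%% beta_b
  mu2v <- A %%*%% beta_t
  for (i in 1:N) {
    u[i, 1] ~ dnorm(mu1v[i], tau1)
    u[i, 2] ~ dnorm(mu2v[i] + delta * (u[i, 1] - mu1v[i]), tau2)
    b1[i] <- u[i, 1] - mu1v[i]
    b2[i] <- u[i, 2] - mu2v[i]
  }
  for (j in 1:%d) {
    beta_b[j] ~ dnorm(0, %.8g)
    beta_t[j] ~ dnorm(0, %.8g)
  }
  for (j in 1:%d) { alpha[j] ~ dnorm(0, %.8g) }
%s  delta ~ dnorm(0, %.8g)
  tau_eps ~ dgamma(%.8g, %.8g)
  sigma_eps <- 1 / sqrt(tau_eps)
  sigma1 ~ dunif(0, %.8g)
  sigma2 ~ dunif(0, %.8g)
  tau1 <- 1 / (sigma1 * sigma1)
  tau2 <- 1 / (sigma2 * sigma2)
}", gterm, pb, 1 / priors$beta_sd^2, 1 / priors$beta_sd^2,
    ps, 1 / priors$alpha_gamma_sd^2, gprior, 1 / priors$delta_sd^2,
    priors$sigma_eps_shape, priors$sigma_eps_rate,
    priors$sigma_upper, priors$sigma_upper)
}

spm_jags_model_plain <- function(p, ps, priors, gamma_zero) {
  gterm <- if (gamma_zero) "0"
  else "gamma[1] * b[subr[k], 1] + gamma[2] * b[subr[k], 2]"
  gprior <- if (gamma_zero) ""
  else sprintf("  gamma[1] ~ dnorm(0, %.8g)\n  gamma[2] ~ dnorm(0, %.8g)\n",
               1 / priors$alpha_gamma_sd^2, 1 / priors$alpha_gamma_sd^2)
  sprintf("
model {
  mu_fix <- Xy %%*%% beta
  for (k in 1:n_y) {
    y[k] ~ dnorm(mu_fix[k] + b[suby[k], 1] + tz[k] * b[suby[k], 2], tau_eps)
  }
  eta_r <- Xr %%*%% alpha
  for (k in 1:n_r) {
    p_r[k] <- max(1e-12, min(1 - 1e-12, phi(-(eta_r[k] + %s))))
    r[k] ~ dbern(p_r[k])
  }
  for (i in 1:N) {
    b[i, 1] ~ dnorm(0, tau1)
    b[i, 2] ~ dnorm(delta * b[i, 1], tau2)
  }
  for (j in 1:%d) { beta[j] ~ dnorm(0, %.8g) }
  for (j in 1:%d) { alpha[j] ~ dnorm(0, %.8g) }
%s  delta ~ dnorm(0, %.8g)
  tau_eps ~ dgamma(%.8g, %.8g)
  sigma_eps <- 1 / sqrt(tau_eps)
  sigma1 ~ dunif(0, %.8g)
  sigma2 ~ dunif(0, %.8g)
  tau1 <- 1 / (sigma1 * sigma1)
  tau2 <- 1 / (sigma2 * sigma2)
}", gterm, p, 1 / priors$beta_sd^2, ps, 1 / priors$alpha_gamma_sd^2,
    gprior, 1 / priors$delta_sd^2,
    priors$sigma_eps_shape, priors$sigma_eps_rate,
    priors$sigma_upper, priors$sigma_upper)
}

#' Fit the shared parameter model by MCMC
#'
#' Samples the joint posterior of all model parameters with the
#' per-subject random effects treated as latent variables (data
#' augmentation of the observed-data likelihood), using JAGS.  The probit
#' hazard enters as a direct Bernoulli-probit likelihood on the
#' at-risk/event indicators.  When the fixed-effects design has the
#' `covariates + time:covariates` structure, the sampler uses a
#' hierarchically centered parameterization (subject-level means absorbed
#' into the random-intercept/slope distributions), which decorrelates the
#' fixed effects from the latent effects and mixes much faster; results
#' are reported on the usual uncentered scale either way.
#'
#' @param data An [spm_data()] object (or an `spm_sim`, whose observed
#'   data are used).
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param gamma_zero Fix the association parameters at zero?  This is the
#'   ignorable-dropout comparator: the longitudinal posterior then
#'   coincides with a standard linear mixed model on the observed data.
#' @param save_b Keep the per-subject random-effect draws (needed by
#'   posterior predictive checks)?
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `spm_fit`.
#' @export
fit_spm <- function(data, priors = prior_spec(), mcmc = mcmc_config(),
                    gamma_zero = FALSE, save_b = TRUE, quiet = TRUE) {
  if (inherits(data, "spm_sim")) data <- data$data
  stopifnot(inherits(data, "spm_data"), inherits(priors, "prior_spec"),
            inherits(mcmc, "mcmc_config"))
  if (any(vapply(data$subjects, function(s) !any(s$obs), logical(1))))
    abort("Every subject must have at least one observed outcome.")
  jd <- jags_data_from_spm(data)
  p <- ncol(jd$Xy)
  ps <- ncol(jd$Xr)
  plan <- centering_plan(data)
  centered <- !is.null(plan)

  if (centered) {
    model_str <- spm_jags_model_centered(length(plan$bcols), ps, priors,
                                         gamma_zero)
    jdata <- list(y = jd$y, suby = jd$suby, tz = jd$tz, n_y = jd$n_y,
                  r = jd$r, subr = jd$subr, Xr = jd$Xr, n_r = jd$n_r,
                  N = jd$N, A = plan$A)
    if (gamma_zero) jdata$subr <- NULL   # unused once gamma terms drop out
    base_inits <- function(ch) {
      ini <- list(beta_b = rep(0, length(plan$bcols)),
                  beta_t = rep(0, length(plan$tcols)),
                  alpha = rep(0, ps), delta = 0,
                  sigma1 = 0.5 + 0.5 * ch, sigma2 = 0.5 + 0.5 * ch,
                  tau_eps = 1, u = matrix(0, jd$N, 2))
      if (!gamma_zero) ini$gamma <- c(0, 0)
      ini
    }
    monitors <- c("beta_b", "beta_t", "alpha", if (!gamma_zero) "gamma",
                  "delta", "sigma1", "sigma2", "sigma_eps")
    b_monitors <- c("b1", "b2")
  } else {
    model_str <- spm_jags_model_plain(p, ps, priors, gamma_zero)
    jdata <- jd
    if (gamma_zero) jdata$subr <- NULL
    base_inits <- function(ch) {
      ini <- list(beta = rep(0, p), alpha = rep(0, ps), delta = 0,
                  sigma1 = 0.5 + 0.5 * ch, sigma2 = 0.5 + 0.5 * ch,
                  tau_eps = 1, b = matrix(0, jd$N, 2))
      if (!gamma_zero) ini$gamma <- c(0, 0)
      ini
    }
    monitors <- c("beta", "alpha", if (!gamma_zero) "gamma",
                  "delta", "sigma1", "sigma2", "sigma_eps")
    b_monitors <- "b"
  }

  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    c(base_inits(ch),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = subject_seed(mcmc$seed, 7919L + ch)))
  })

  t0 <- Sys.time()
  jm <- rjags::jags.model(textConnection(model_str), data = jdata,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = mcmc$adapt, quiet = quiet)
  update(jm, mcmc$burn_in, progress.bar = "none")
  monitors_all <- c(monitors, if (save_b) b_monitors)
  sam <- rjags::coda.samples(jm, monitors_all,
                             n.iter = mcmc$draws * mcmc$thin,
                             thin = mcmc$thin, progress.bar = "none")
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  vn <- colnames(sam[[1]])
  b_cols <- grep("^b\\[|^b1\\[|^b2\\[", vn, value = TRUE)
  par_cols <- setdiff(vn, b_cols)
  par_mat <- do.call(rbind, lapply(sam, function(ch)
    as.matrix(ch)[, par_cols, drop = FALSE]))
  n_per <- nrow(sam[[1]])
  draws <- tibble::as_tibble(par_mat)
  names(draws) <- rename_terms(names(draws), colnames(jd$Xy),
                               colnames(jd$Xr), plan)
  if (gamma_zero) draws$gamma1 <- draws$gamma2 <- 0
  draws <- dplyr::bind_cols(
    tibble::tibble(.chain = rep(seq_len(mcmc$chains), each = n_per),
                   .iteration = rep(seq_len(n_per), mcmc$chains)),
    draws)

  b_draws <- NULL
  if (save_b && length(b_cols)) {
    bm <- do.call(rbind, lapply(sam, function(ch)
      as.matrix(ch)[, b_cols, drop = FALSE]))
    b_draws <- array(NA_real_, c(nrow(bm), jd$N, 2))
    for (i in seq_len(jd$N)) {
      if (centered) {
        b_draws[, i, 1] <- bm[, paste0("b1[", i, "]")]
        b_draws[, i, 2] <- bm[, paste0("b2[", i, "]")]
      } else {
        b_draws[, i, 1] <- bm[, paste0("b[", i, ",1]")]
        b_draws[, i, 2] <- bm[, paste0("b[", i, ",2]")]
      }
    }
  }
  coda_params <- coda::as.mcmc.list(lapply(sam, function(ch) {
    m <- as.matrix(ch)[, par_cols, drop = FALSE]
    colnames(m) <- rename_terms(colnames(m), colnames(jd$Xy),
                                colnames(jd$Xr), plan)
    coda::mcmc(m, thin = mcmc$thin)
  }))

  structure(list(draws = draws, b_draws = b_draws, coda = coda_params,
                 data = data, priors = priors, mcmc = mcmc,
                 gamma_zero = gamma_zero, centered = centered,
                 terms = list(fixed = colnames(jd$Xy),
                              hazard = colnames(jd$Xr)),
                 runtime = runtime),
            class = "spm_fit")
}

rename_terms <- function(nm, fixed_terms, hazard_terms, plan = NULL) {
  out <- nm
  if (!is.null(plan)) {
    for (j in seq_along(plan$bcols))
      out[out == paste0("beta_b[", j, "]")] <- paste0("beta_", plan$bcols[j])
    for (j in seq_along(plan$tcols))
      out[out == paste0("beta_t[", j, "]")] <- paste0("beta_", plan$tcols[j])
    if (length(plan$bcols) == 1L) {
      out[out == "beta_b"] <- paste0("beta_", plan$bcols[1])
      out[out == "beta_t"] <- paste0("beta_", plan$tcols[1])
    }
  }
  for (j in seq_along(fixed_terms))
    out[out == paste0("beta[", j, "]")] <- paste0("beta_", fixed_terms[j])
  if (length(fixed_terms) == 1L)
    out[out == "beta"] <- paste0("beta_", fixed_terms[1])
  for (j in seq_along(hazard_terms))
    out[out == paste0("alpha[", j, "]")] <- paste0("alpha_", hazard_terms[j])
  if (length(hazard_terms) == 1L)
    out[out == "alpha"] <- paste0("alpha_", hazard_terms[1])
  out[out == "gamma[1]"] <- "gamma1"
  out[out == "gamma[2]"] <- "gamma2"
  out
}

#' @export
print.spm_fit <- function(x, ...) {
  cat("<spm_fit> ", nrow(x$draws), " pooled draws (", x$mcmc$chains,
      " chains), ", length(x$data$subjects), " subjects",
      if (x$gamma_zero) ", gamma fixed at 0",
      if (isTRUE(x$centered)) ", centered parameterization", "\n", sep = "")
  invisible(x)
}

# Rebuild an spm_params object from row `i` of the pooled draws.
params_from_draw <- function(fit, i) {
  d <- fit$draws[i, ]
  beta <- unlist(d[paste0("beta_", fit$terms$fixed)])
  names(beta) <- fit$terms$fixed
  alpha <- unlist(d[paste0("alpha_", fit$terms$hazard)])
  names(alpha) <- fit$terms$hazard
  spm_params(beta = beta, alpha = alpha,
             gamma = c(d$gamma1, d$gamma2),
             re_cov = re_cov(d$delta, d$sigma1, d$sigma2),
             sigma_eps = d$sigma_eps)
}

#' Tidy posterior summaries of a fitted shared parameter model
#'
#' @param x An `spm_fit` object.
#' @param conf_level Credible-interval level (central; default 0.95).
#' @param derived Also report the derived random-effects covariance
#'   summaries `var(b1)`, `var(b2)`, `corr(b1,b2)`?
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior mean),
#'   `std.error` (posterior SD), `conf.low`, `conf.high`.
#' @export
tidy.spm_fit <- function(x, conf_level = 0.95, derived = TRUE, ...) {
  d <- dplyr::select(x$draws, -".chain", -".iteration")
  if (x$gamma_zero) d <- dplyr::select(d, -"gamma1", -"gamma2")
  if (derived) {
    d$`var_b1` <- d$sigma1^2
    d$`var_b2` <- d$delta^2 * d$sigma1^2 + d$sigma2^2
    d$`corr_b` <- d$delta * d$sigma1^2 / sqrt(d$var_b1 * d$var_b2)
  }
  a <- (1 - conf_level) / 2
  purrr::map_dfr(names(d), function(nm) {
    v <- d[[nm]]
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
}

#' One-line summary of a fitted shared parameter model
#'
#' @param x An `spm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: subjects, pooled draws, chains, max Rhat,
#'   min effective sample size, convergence flag, runtime (seconds).
#' @export
glance.spm_fit <- function(x, ...) {
  cv <- check_convergence(x)
  tibble::tibble(n_subjects = length(x$data$subjects),
                 n_draws = nrow(x$draws), chains = x$mcmc$chains,
                 max_rhat = max(cv$rhat, na.rm = TRUE),
                 min_ess = min(cv$ess, na.rm = TRUE),
                 converged = all(cv$pass, na.rm = TRUE),
                 runtime = x$runtime)
}

#' Convergence diagnostics for posterior draws
#'
#' Per-parameter Gelman-Rubin potential scale reduction factor and
#' effective sample size, with a pass flag at `Rhat < 1.1`.
#'
#' @param x An `spm_fit` or a [coda::mcmc.list] with at least two chains.
#' @param rhat_limit Pass threshold (default 1.1).
#' @return A tibble with columns `term`, `rhat`, `ess`, `pass`.
#' @export
check_convergence <- function(x, rhat_limit = 1.1) {
  UseMethod("check_convergence")
}

#' @export
check_convergence.spm_fit <- function(x, rhat_limit = 1.1) {
  check_convergence(x$coda, rhat_limit = rhat_limit)
}

#' @export
check_convergence.mcmc.list <- function(x, rhat_limit = 1.1) {
  m <- coda::nchain(x)
  if (m < 2L) abort("Convergence diagnostics need at least 2 chains.")
  n <- coda::niter(x)
  terms <- coda::varnames(x)
  # classic Gelman-Rubin PSRF: sqrt(((n-1)/n W + (1 + 1/m) B/n) / W)
  rhat <- vapply(terms, function(v) {
    ch <- vapply(seq_len(m), function(j) as.matrix(x[[j]])[, v], numeric(n))
    W <- mean(apply(ch, 2, var))
    B_over_n <- var(colMeans(ch))
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + (1 + 1 / m) * B_over_n) / W)
  }, numeric(1))
  ess <- coda::effectiveSize(x)
  tibble::tibble(term = terms, rhat = unname(rhat),
                 ess = as.numeric(ess[terms]),
                 pass = unname(rhat) < rhat_limit)
}
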