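#' Chi-square discrepancy between outcomes and the model's conditional fit
#'
#' Sum over all observed outcome entries of the squared standardized
#' residual given the parameters and each subject's random effects:
#' `sum_ij (y_ij - x_ij' beta - z_ij' b_i)^2 / sigma_eps^2`.  Under the
#' model this is a chi-square variable with one degree of freedom per
#' observed entry.
#'
#' @param data An [spm_data()] object.
#' @param params An [spm_params()] object.
#' @param b `N x 2` matrix of random effects (one row per subject, in the
#'   order of `data$subjects`).
#' @return The scalar discrepancy.
#' @export
chi2_discrepancy <- function(data, params, b) {
  subjects <- data$subjects
  stopifnot(nrow(b) == length(subjects))
  tot <- 0
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    obs <- s$obs
    beta <- align_coef(params$beta, s$X, "beta")
    mu <- drop(s$X[obs, , drop = FALSE] %*% beta) +
      drop(s$Z[obs, , drop = FALSE] %*% b[i, ])
    tot <- tot + sum((s$y[obs] - mu)^2)
  }
  tot / params$sigma_eps^2
}

#' Posterior predictive check via the chi-square discrepancy
#'
#' For each selected posterior draw: compute the observed-data
#' discrepancy using that draw's parameters and augmented random effects;
#' then replicate a full dataset from the model (new random effects, new
#' outcomes, new dropout times, same covariates and sample size),
#' truncate it at the replicated dropout visits to form replicated
#' *observed* data, and compute the replicated discrepancy.  The reported
#' p-value is the posterior probability that the replicated discrepancy
#' exceeds the observed one; values near 0 or 1 signal lack of fit.
#'
#' @param fit An [fit_spm()] result with saved random-effect draws
#'   (`save_b = TRUE`).
#' @param n_draws Number of posterior draws to use (evenly spaced).
#' @param seed Seed for the replication streams.
#' @return An object of class `spm_ppc`: list with `draws` (tibble of
#'   per-draw observed and replicated discrepancies) and `p_value`.
#' @export
ppc_pvalue <- function(fit, n_draws = 200L, seed = 1L) {
  stopifnot(inherits(fit, "spm_fit"))
  if (is.null(fit$b_draws))
    abort("Posterior predictive checks need `fit_spm(..., save_b = TRUE)`.")
  data <- fit$data
  subjects <- data$subjects
  N <- length(subjects)
  M <- data$spec$design$M
  total <- nrow(fit$draws)
  pick <- unique(round(seq(1, total, length.out = min(n_draws, total))))
  set.seed(subject_seed(seed, 31L))

  # stack the per-subject design matrices once
  Xall <- do.call(rbind, lapply(subjects, `[[`, "X"))
  Z2 <- subjects[[1]]$Z[, 2]
  Xsall <- do.call(rbind, lapply(subjects, `[[`, "Xs"))
  obs_mask <- unlist(lapply(subjects, `[[`, "obs"))
  yobs <- unlist(lapply(subjects, `[[`, "y"))[obs_mask]
  sub_of_row <- rep(seq_len(N), each = M)

  out <- purrr::map_dfr(seq_along(pick), function(j) {
    params <- params_from_draw(fit, pick[j])
    beta <- align_coef(params$beta, subjects[[1]]$X, "beta")
    mu_fix <- drop(Xall %*% beta)           # N*M vector
    b_obs <- fit$b_draws[pick[j], , , drop = FALSE]
    dim(b_obs) <- c(N, 2)
    mu_obs <- mu_fix + b_obs[sub_of_row, 1] + rep(Z2, N) * b_obs[sub_of_row, 2]
    T_obs <- sum((yobs - mu_obs[obs_mask])^2) / params$sigma_eps^2

    # replicate outcomes and dropout with fresh random effects
    rc <- params$re_cov
    b1 <- rnorm(N, 0, rc$sigma1)
    b2 <- rc$delta * b1 + rnorm(N, 0, rc$sigma2)
    mu_rep <- mu_fix + b1[sub_of_row] + rep(Z2, N) * b2[sub_of_row]
    y_rep <- mu_rep + rnorm(N * M, 0, params$sigma_eps)
    alpha <- align_coef(params$alpha, subjects[[1]]$Xs, "alpha")
    eta <- matrix(drop(Xsall %*% alpha), nrow = N, byrow = TRUE)
    for (l in seq_len(M - 1L)) {
      g <- gamma_at(params, l)
      eta[, l] <- eta[, l] + b1 * g[1] + b2 * g[2]
    }
    S_rep <- rep(M, N)
    alive <- rep(TRUE, N)
    U <- matrix(runif(N * (M - 1L)), N)
    for (l in seq_len(M - 1L)) {
      drop_now <- alive & (U[, l] < 1 - pnorm(eta[, l]))
      S_rep[drop_now] <- l
      alive <- alive & !drop_now
    }
    rep_mask <- rep(seq_len(M), N) <= S_rep[sub_of_row]
    T_rep <- sum((y_rep[rep_mask] - mu_rep[rep_mask])^2) / params$sigma_eps^2
    tibble::tibble(draw = j, T_obs = T_obs, T_rep = T_rep,
                   n_obs = sum(obs_mask), n_rep = sum(rep_mask))
  })
  structure(list(draws = out, p_value = mean(out$T_rep > out$T_obs)),
            class = "spm_ppc")
}

#' @export
print.spm_ppc <- function(x, ...) {
  cat("<spm_ppc> posterior P(T_rep > T_obs) = ",
      format(x$p_value, digits = 3), " over ", nrow(x$draws),
      " draws\n", sep = "")
  invisible(x)
}
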