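# G-computation: Monte-Carlo prediction of longitudinal summaries per
# covariate profile under the default (closed skew-normal) and
# sensitivity extrapolations, then contrasts between profiles and
# posterior summarization over parameter draws.

#' Covariate profiles for G-computation
#'
#' A profile is a full set of baseline covariate values, labelled.  Any
#' tibble with a `label` column plus the covariate columns used by the
#' model spec works; this helper builds the cross of supplied values.
#'
#' @param ... Named covariate values (vectors are crossed).
#' @param label Optional labels; default pastes the covariate values.
#' @return A tibble of profiles with a `label` column.
#' @examples
#' gcomp_profiles(vl = factor(c(">30k", "0-500"),
#'                            levels = c(">30k", "0-500", "500-5k", "5k-30k")),
#'                art = c(0, 1), sympt = 0)
#' @export
gcomp_profiles <- function(..., label = NULL) {
  prof <- tidyr::expand_grid(...)
  if (is.null(label)) {
    label <- apply(prof, 1, function(r)
      paste(paste0(names(prof), "=", trimws(as.character(r))), collapse = ","))
  }
  dplyr::bind_cols(tibble::tibble(label = label), prof)
}

#' The eight covariate profiles of the motivating analysis
#'
#' Viral-load group crossed with ART status, symptom score fixed at zero.
#' @return A tibble of 8 profiles.
#' @export
hers_profiles <- function() {
  lv <- c(">30k", "0-500", "500-5k", "5k-30k")
  gcomp_profiles(vl = factor(lv, levels = lv), art = c(0L, 1L), sympt = 0L)
}

# Precompute everything about one profile that does not depend on the
# replicate draws: design rows, fixed-effect means, hazard offsets.
profile_machine <- function(profile_row, spec, params) {
  M <- spec$design$M
  covs <- profile_row[setdiff(names(profile_row), "label")]
  rec <- new_subject_record(profile_row$label, M, rep(NA_real_, M),
                            rep(FALSE, M), covs, spec)
  beta <- align_coef(params$beta, rec$X, "beta")
  alpha <- align_coef(params$alpha, rec$Xs, "alpha")
  list(rec = rec, M = M, times = spec$design$times,
       mu_fix = drop(rec$X %*% beta),
       eta_base = drop(rec$Xs %*% alpha))
}

# Simulate n complete replicates (Y, b, S) at one profile and parameter
# draw.  Fully vectorized.
simulate_replicates <- function(pm, params, n) {
  M <- pm$M
  rc <- params$re_cov
  b1 <- rnorm(n, 0, rc$sigma1)
  b2 <- rc$delta * b1 + rnorm(n, 0, rc$sigma2)
  b <- cbind(b1, b2)
  Y <- matrix(pm$mu_fix, n, M, byrow = TRUE) +
    b %*% t(pm$rec$Z) + matrix(rnorm(n * M, 0, params$sigma_eps), n, M)
  S <- rep(M, n)
  alive <- rep(TRUE, n)
  for (l in seq_len(M - 1L)) {
    g <- gamma_at(params, l)
    lam <- 1 - pnorm(pm$eta_base[l] + b[, 1] * g[1] + b[, 2] * g[2])
    drop_now <- alive & (runif(n) < lam)
    S[drop_now] <- l
    alive <- alive & !drop_now
  }
  list(Y = Y, b = b, S = S)
}

# The closed skew-normal machinery shared by all replicates in an
# S-group at a profile: common Omega, c, D; only mu varies with y.
csn_group <- function(pm, params, s) {
  M <- pm$M
  Sigma_b <- sigma_b_from_cholesky(params$re_cov)
  Zo <- pm$rec$Z[seq_len(s), , drop = FALSE]
  prec <- solve(Sigma_b) + crossprod(Zo) / params$sigma_eps^2
  Omega <- solve(prec)
  Omega <- (Omega + t(Omega)) / 2
  cvec <- pm$eta_base[seq_len(s)]
  D <- t(vapply(seq_len(s), function(l) gamma_at(params, l), numeric(2)))
  cvec[s] <- -cvec[s]
  D[s, ] <- -D[s, ]
  list(Omega = Omega, c = cvec, D = D, Zo = Zo, s = s)
}

# Conditional means mu_i for all members of an S-group (rows of Yobs are
# the replicates' observed outcomes at visits 1..s).
csn_group_mu <- function(cg, pm, params, Yobs) {
  resid <- sweep(Yobs, 2, pm$mu_fix[seq_len(cg$s)], "-")
  t(cg$Omega %*% t(resid %*% cg$Zo) / params$sigma_eps^2)
}

# Vectorized rejection sampling: one CSN draw per row of mu_mat.
csn_sample_group <- function(cg, mu_mat, max_rounds = 20000L) {
  n <- nrow(mu_mat)
  L <- chol(cg$Omega)
  live <- rowSums(cg$D != 0) > 0
  D <- cg$D[live, , drop = FALSE]
  cvec <- cg$c[live]
  out <- matrix(NA_real_, n, 2)
  pending <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    k <- length(pending)
    if (!k) break
    # propose several candidates per pending replicate once few remain
    reps <- max(1L, min(200L, 2000L %/% k))
    rows <- rep(pending, each = reps)
    prop <- mu_mat[rows, , drop = FALSE] +
      matrix(rnorm(2 * length(rows)), ncol = 2) %*% L
    if (nrow(D)) {
      arg <- sweep(prop %*% t(D), 2, cvec, "+")
      lacc <- rowSums(matrix(pnorm(arg, log.p = TRUE), nrow = length(rows)))
      ok <- log(runif(length(rows))) < lacc
    } else {
      ok <- rep(TRUE, length(rows))
    }
    acc <- which(ok)
    if (length(acc)) {
      firsts <- acc[!duplicated(rows[acc])]  # first acceptance per replicate
      out[rows[firsts], ] <- prop[firsts, , drop = FALSE]
      pending <- setdiff(pending, rows[firsts])
    }
  }
  if (length(pending))
    abort("CSN rejection sampling failed to accept for some replicates.")
  out
}

# sigma_b2 for selected members of an S-group (exact closed-form moments).
csn_group_sigma_b2 <- function(cg, mu_mat, idx, orthant_tol = 1e-7) {
  vapply(idx, function(i) {
    csn <- structure(list(mu = mu_mat[i, ], Omega = cg$Omega, c = cg$c,
                          D = cg$D, log_norm = NA_real_,
                          orthant_tol = orthant_tol),
                     class = "spm_csn")
    csn_moments(csn)$sigma_b2
  }, numeric(1))
}

#' G-computation at a single parameter draw
#'
#' Simulates `n_mc` replicate subjects from the shared parameter model at
#' one covariate profile and one parameter draw, truncates each replicate
#' at its dropout visit, fills the missing outcomes from the default
#' (closed skew-normal) extrapolation, and adds the sensitivity
#' piecewise-linear slope adjustment for sensitivity parameter `a`.  The
#' sensitivity outcomes are the default outcomes plus the deterministic
#' hinge shift `Delta_i (t_k - t_S)_+`, so `a = 0` reproduces the default
#' results exactly.
#'
#' @param params An [spm_params()] draw.
#' @param profiles Profile tibble (see [gcomp_profiles()]).
#' @param spec An [spm_spec()].
#' @param a Sensitivity-parameter value for this draw (`NULL` to skip the
#'   sensitivity extrapolation entirely).
#' @param sens A [sensitivity_config()] (controls the `sigma_b2` mode).
#' @param n_mc Monte-Carlo replicates per profile.  The methodology wants
#'   this large relative to the study size (100 times N is the
#'   recommendation).
#' @param summary_visits Visits for the change-from-baseline summaries.
#' @param seed Seed for this draw's replicate streams.
#' @return A tibble with columns `profile`, `stat` (`"mean"` for
#'   per-visit predicted means, `"change"` for change from baseline),
#'   `visit`, `default`, and (unless `a` is `NULL`) `sensitivity`.
#' @export
gcomp_one_draw <- function(params, profiles, spec, a = NULL,
                           sens = sensitivity_config(), n_mc = 10000L,
                           summary_visits = NULL, seed = 1L) {
  M <- spec$design$M
  times <- spec$design$times
  if (is.null(summary_visits)) summary_visits <- unique(pmin(c(6L, M), M))
  with_sens <- !is.null(a)
  purrr::map_dfr(seq_len(nrow(profiles)), function(pi) {
    set.seed(subject_seed(seed, pi))
    pm <- profile_machine(profiles[pi, ], spec, params)
    rep <- simulate_replicates(pm, params, n_mc)
    Ydef <- rep$Y
    shift <- matrix(0, n_mc, M)
    csn_cache <- list()
    # default imputation: replace post-dropout outcomes by CSN-based draws
    for (s in sort(unique(rep$S[rep$S < M]))) {
      idx <- which(rep$S == s)
      cg <- csn_group(pm, params, s)
      mu_mat <- csn_group_mu(cg, pm, params,
                             rep$Y[idx, seq_len(s), drop = FALSE])
      bdraw <- csn_sample_group(cg, mu_mat)
      k <- seq(s + 1L, M)
      Ydef[idx, k] <- matrix(pm$mu_fix[k], length(idx), length(k),
                             byrow = TRUE) +
        bdraw %*% t(pm$rec$Z[k, , drop = FALSE]) +
        matrix(rnorm(length(idx) * length(k), 0, params$sigma_eps),
               length(idx))
      csn_cache[[as.character(s)]] <- list(cg = cg, mu_mat = mu_mat,
                                           idx = idx)
    }
    # sensitivity shift (separate RNG substream so the default results
    # are bit-identical whatever the sensitivity configuration)
    if (with_sens && a != 0 && length(csn_cache)) {
      set.seed(subject_seed(seed, 100000L + pi))
      sig_of <- sigma_b2_for_groups(csn_cache, pm, params, sens)
      for (s in names(csn_cache)) {
        sv <- as.integer(s)
        idx <- csn_cache[[s]]$idx
        delta <- delta_i(a, sv, M, sig_of[[s]])
        if (length(delta) == 1L) delta <- rep(delta, length(idx))
        k <- seq(sv + 1L, M)
        shift[idx, k] <- delta %o% pmax(times[k] - times[sv], 0)
      }
    }
    Ysens <- Ydef + shift
    means_def <- colMeans(Ydef)
    means_sens <- colMeans(Ysens)
    out <- tibble::tibble(
      profile = profiles$label[pi],
      stat = c(rep("mean", M), rep("change", length(summary_visits))),
      visit = c(seq_len(M), summary_visits),
      default = c(means_def,
                  means_def[summary_visits] - means_def[1]),
      n_mc = n_mc)
    if (with_sens) {
      out$sensitivity <- c(means_sens,
                           means_sens[summary_visits] - means_sens[1])
      out <- dplyr::relocate(out, "sensitivity", .after = "default")
    }
    out
  })
}

# sigma_b2 per S-group: exact per replicate, or the profile-wide average
# of exact values over a capped subsample of dropouts (grouping key = the
# profile, since all replicates share its covariates).
sigma_b2_for_groups <- function(csn_cache, pm, params, sens) {
  if (sens$sigma_mode == "exact") {
    lapply(csn_cache, function(e)
      csn_group_sigma_b2(e$cg, e$mu_mat, seq_len(nrow(e$mu_mat))))
  } else {
    n_per <- vapply(csn_cache, function(e) nrow(e$mu_mat), numeric(1))
    total <- sum(n_per)
    take <- pmax(1L, pmin(n_per, ceiling(sens$sigma_group_cap *
                                           n_per / total)))
    vals <- unlist(lapply(seq_along(csn_cache), function(j) {
      e <- csn_cache[[j]]
      pick <- sample.int(nrow(e$mu_mat), take[j])
      csn_group_sigma_b2(e$cg, e$mu_mat, pick)
    }))
    wts <- unlist(lapply(seq_along(csn_cache), function(j)
      rep(n_per[j] / take[j], take[j])))
    gbar <- sum(vals * wts) / sum(wts)
    stats::setNames(rep(list(gbar), length(csn_cache)), names(csn_cache))
  }
}

#' Monte-Carlo G-computation over posterior draws
#'
#' Runs [gcomp_one_draw()] for a subset of posterior parameter draws
#' (evenly spaced thinning of the pooled draws), drawing the sensitivity
#' parameter `a` once per parameter draw from its triangular prior
#' (or holding it at `a_fixed`), and stacks the results.
#'
#' @param fit An [fit_spm()] result.
#' @param profiles Profile tibble (see [gcomp_profiles()]).
#' @param sens A [sensitivity_config()], or `NULL` to skip the
#'   sensitivity extrapolation.
#' @param n_draws Number of posterior draws to process.
#' @param n_mc Monte-Carlo replicates per (draw, profile).
#' @param summary_visits Visits for change-from-baseline summaries.
#' @param a_fixed Optional fixed value of the sensitivity parameter
#'   (overrides the prior draw; used for anchoring and tipping checks).
#' @param seed Master seed; per-(draw, profile) streams are derived.
#' @return An object of class `spm_gcomp`: a tibble with columns `draw`,
#'   `a`, `profile`, `stat`, `visit`, `default`, `sensitivity`, plus the
#'   configuration as attributes.
#' @export
spm_gcompute <- function(fit, profiles, sens = sensitivity_config(),
                         n_draws = 20L, n_mc = NULL, summary_visits = NULL,
                         a_fixed = NULL, seed = 1L) {
  stopifnot(inherits(fit, "spm_fit"))
  spec <- fit$data$spec
  if (is.null(n_mc)) n_mc <- 100L * length(fit$data$subjects)
  total <- nrow(fit$draws)
  pick <- unique(round(seq(1, total, length.out = min(n_draws, total))))
  with_sens <- !is.null(sens)
  if (with_sens) {
    set.seed(subject_seed(seed, 424243L))
    a_draws <- if (is.null(a_fixed)) sample_a(sens, length(pick))
    else rep(a_fixed, length(pick))
  }
  res <- purrr::map_dfr(seq_along(pick), function(j) {
    params <- params_from_draw(fit, pick[j])
    a <- if (with_sens) a_draws[j] else NULL
    out <- gcomp_one_draw(params, profiles, spec, a = a, sens = sens,
                          n_mc = n_mc, summary_visits = summary_visits,
                          seed = subject_seed(seed, j))
    out$draw <- j
    out$a <- if (with_sens) a else NA_real_
    dplyr::relocate(out, "draw", "a")
  })
  structure(res, class = c("spm_gcomp", class(res)),
            sens = sens, seed = seed)
}

#' Contrasts between covariate profiles
#'
#' Differences of G-computation summaries between named profile pairs,
#' per posterior draw (e.g. each viral-load group versus the reference
#' group within an ART stratum).
#'
#' @param gc An `spm_gcomp` tibble (or the result of [gcomp_one_draw()]
#'   with a `draw` column added).
#' @param pairs A data frame with columns `profile` and `reference` (and
#'   optionally `label`), naming the profile pairs to difference.
#' @return A tibble like `gc` but with a `contrast` column and values
#'   `profile - reference`.
#' @export
gcomp_contrasts <- function(gc, pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("profile", "reference") %in% names(pairs)))
    abort("`pairs` needs columns `profile` and `reference`.")
  known <- unique(gc$profile)
  bad <- setdiff(unique(c(pairs$profile, pairs$reference)), known)
  if (length(bad))
    abort(paste0("Unknown profile label(s): ", paste(bad, collapse = ", ")))
  if (!"label" %in% names(pairs))
    pairs$label <- paste0(pairs$profile, " - ", pairs$reference)
  has_draw <- "draw" %in% names(gc)
  keys <- c(if (has_draw) c("draw", "a"), "stat", "visit", "n_mc")
  vals <- intersect(c("default", "sensitivity"), names(gc))
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    x <- dplyr::filter(gc, .data$profile == pairs$profile[i])
    r <- dplyr::filter(gc, .data$profile == pairs$reference[i])
    j <- dplyr::inner_join(x, r, by = keys, suffix = c("", ".ref"))
    for (v in vals) j[[v]] <- j[[v]] - j[[paste0(v, ".ref")]]
    j$contrast <- pairs$label[i]
    dplyr::select(j, "contrast", dplyr::all_of(keys), dplyr::all_of(vals))
  })
}

#' Posterior summaries of G-computation results
#'
#' Posterior mean and central credible interval of every cell
#' (profile/contrast by statistic by visit by extrapolation), flagging
#' intervals that exclude zero.
#'
#' @param gc An `spm_gcomp` or [gcomp_contrasts()] tibble with a `draw`
#'   column.
#' @param conf_level Credible level (default 0.95).
#' @return A tibble with columns `profile` (or `contrast`), `stat`,
#'   `visit`, `extrapolation`, `estimate`, `conf.low`, `conf.high`,
#'   `excludes_zero`.
#' @export
summarize_posterior <- function(gc, conf_level = 0.95) {
  key <- if ("contrast" %in% names(gc)) "contrast" else "profile"
  vals <- intersect(c("default", "sensitivity"), names(gc))
  long <- tidyr::pivot_longer(gc, dplyr::all_of(vals),
                              names_to = "extrapolation",
                              values_to = "value")
  alpha <- (1 - conf_level) / 2
  out <- dplyr::summarise(
    dplyr::group_by(long, .data[[key]], .data$stat, .data$visit,
                    .data$extrapolation),
    estimate = mean(.data$value),
    conf.low = unname(quantile(.data$value, alpha)),
    conf.high = unname(quantile(.data$value, 1 - alpha)),
    .groups = "drop")
  out$excludes_zero <- out$conf.low > 0 | out$conf.high < 0
  structure(out, class = c("spm_gcomp_summary", class(out)))
}

#' Plot G-computation posterior summaries
#'
#' Point estimates with credible-interval bars per profile or contrast,
#' default versus sensitivity extrapolation side by side, facetted by
#' summary statistic and visit.
#'
#' @param object A [summarize_posterior()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spm_gcomp_summary <- function(object, ...) {
  key <- if ("contrast" %in% names(object)) "contrast" else "profile"
  dat <- dplyr::mutate(object,
                       cell = paste0(.data$stat, " @ visit ", .data$visit))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$estimate, y = .data[[key]],
    xmin = .data$conf.low, xmax = .data$conf.high,
    colour = .data$extrapolation)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~cell, scales = "free_x") +
    ggplot2::labs(x = "posterior mean (95% CrI)", y = NULL,
                  colour = "extrapolation") +
    ggplot2::theme_minimal()
}
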