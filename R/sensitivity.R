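#' Sensitivity-analysis configuration
#'
#' The global sensitivity parameter `a` scales the post-dropout slope
#' change and is assigned an informative triangular prior; the default
#' support `[-2, 0]` with mode `-1` encodes the belief that subjects who
#' drop out decline faster than the model predicts, by at most two
#' conditional standard deviations of the random slope for the earliest
#' dropouts, centred at one.  `sigma_mode` selects how the per-subject
#' conditional slope SD is obtained during G-computation: `"exact"`
#' computes [csn_moments()] per subject; `"group"` averages exact values
#' within covariate groups and assigns the group mean (a speed-up, since
#' exact moments need many multivariate normal probabilities).
#'
#' @param prior_low,prior_mode,prior_high Triangular prior support/mode.
#' @param sigma_mode `"group"` (default) or `"exact"`.
#' @param sigma_group_cap In `"group"` mode, the maximum number of
#'   dropout subjects per group used to estimate the group-average slope
#'   SD (an averaging subsample size, not a statistical threshold).
#' @return An object of class `sensitivity_config`.
#' @export
sensitivity_config <- function(prior_low = -2, prior_mode = -1,
                               prior_high = 0, sigma_mode = c("group", "exact"),
                               sigma_group_cap = 64L) {
  if (!(prior_low <= prior_mode && prior_mode <= prior_high))
    abort("Need prior_low <= prior_mode <= prior_high.")
  if (prior_low >= prior_high)
    abort("Triangular prior support is degenerate (low >= high).")
  structure(list(prior_low = prior_low, prior_mode = prior_mode,
                 prior_high = prior_high,
                 sigma_mode = match.arg(sigma_mode),
                 sigma_group_cap = as.integer(sigma_group_cap)),
            class = "sensitivity_config")
}

#' @export
print.sensitivity_config <- function(x, ...) {
  cat("<sensitivity_config> a ~ Triangular(", x$prior_low, ", mode ",
      x$prior_mode, ", ", x$prior_high, "); sigma_b2 mode: ",
      x$sigma_mode, "\n", sep = "")
  invisible(x)
}

#' Draw the global sensitivity parameter from its triangular prior
#'
#' @param config A [sensitivity_config()].
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Numeric vector of draws in `[prior_low, prior_high]`.
#' @export
sample_a <- function(config, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rtriangular(n, config$prior_low, config$prior_mode, config$prior_high)
}

#' Triangular distribution
#'
#' @param n Number of draws.
#' @param low,mode,high Support endpoints and mode.
#' @return `rtriangular()`: draws (inverse-CDF method);
#'   `dtriangular()`: density values.
#' @export
rtriangular <- function(n, low, mode, high) {
  u <- runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

#' @rdname rtriangular
#' @param x Evaluation points.
#' @export
dtriangular <- function(x, low, mode, high) {
  out <- numeric(length(x))
  up <- x >= low & x <= mode
  dn <- x > mode & x <= high
  if (mode > low)
    out[up] <- 2 * (x[up] - low) / ((high - low) * (mode - low))
  else
    out[x == low] <- 2 / (high - low)
  if (high > mode)
    out[dn] <- 2 * (high - x[dn]) / ((high - low) * (high - mode))
  out
}

#' Per-subject post-dropout slope change
#'
#' `Delta_i = a * (M - S_i) / (M - 1) * sigma_b2`: zero for completers
#' (`S = M`); the full `a * sigma_b2` for a subject dropping out right
#' after baseline (`S = 1`); `a / (M - 1) * sigma_b2` for a subject
#' missing only the final visit.  Scaling by the conditional slope SD
#' calibrates the adjustment to each subject's own observed-data
#' uncertainty; scaling by `(M - S)/(M - 1)` adjusts earlier dropouts
#' more.
#'
#' @param a Sensitivity parameter value.
#' @param S Dropout visit (in `1..M`); vectorized.
#' @param M Number of scheduled visits.
#' @param sigma_b2 Conditional standard deviation(s) of the random slope.
#' @return `Delta_i` value(s), in random-slope units per unit standardized
#'   time.
#' @export
delta_i <- function(a, S, M, sigma_b2) {
  if (any(S < 1L | S > M)) abort("`S` must lie in 1..M.")
  if (any(sigma_b2 < 0)) abort("`sigma_b2` must be nonnegative.")
  a * (M - S) / (M - 1) * sigma_b2
}

#' Conditional slope standard deviations for a set of subjects
#'
#' Computes `sigma_b2 = SD(b2 | observed data)` for every subject at one
#' parameter draw.  In `"exact"` mode each subject gets their own
#' [csn_moments()] value.  In `"group"` mode exact values are computed for
#' (a capped subsample of) the dropouts within each covariate group and
#' the group average is assigned to all subjects in the group; empty
#' groups fall back to the exact per-subject value with a warning.
#'
#' @param data An [spm_data()] object.
#' @param params An [spm_params()] object (one posterior draw).
#' @param config A [sensitivity_config()].
#' @param groups Factor/character vector of group labels (length = number
#'   of subjects); default groups by the combination of baseline
#'   covariates.
#' @return A tibble with columns `id`, `S`, `group`, `sigma_b2`.
#' @export
sigma_b2_lookup <- function(data, params, config = sensitivity_config(),
                            groups = NULL) {
  subjects <- data$subjects
  n <- length(subjects)
  if (is.null(groups)) {
    groups <- vapply(subjects, function(s)
      paste(vapply(s$covariates, as.character, character(1)),
            collapse = "|"), character(1))
  }
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  S <- vapply(subjects, `[[`, integer(1), "S")
  exact_one <- function(i)
    csn_moments(conditional_random_effects(subjects[[i]], params))$sigma_b2
  if (config$sigma_mode == "exact") {
    sig <- vapply(seq_len(n), exact_one, numeric(1))
  } else {
    sig <- numeric(n)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      if (!length(idx)) next
      pick <- idx
      if (length(pick) > config$sigma_group_cap)
        pick <- pick[round(seq(1, length(pick),
                               length.out = config$sigma_group_cap))]
      sig[idx] <- mean(vapply(pick, exact_one, numeric(1)))
    }
  }
  tibble::tibble(id = ids, S = S, group = groups, sigma_b2 = sig)
}
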