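#' Default model specification emulating an HIV-cohort CD4 analysis
#'
#' Twelve six-monthly visits on the standardized scale `t = (j-1)/11`;
#' fixed effects: baseline viral-load group (4 levels, reference the
#' highest, `>30k` copies/ml), antiretroviral-therapy indicator, symptom
#' score (0-5), time, and all time interactions; hazard: the baseline
#' covariates plus linear and quadratic time and an ART-by-time term.
#'
#' @param M Number of scheduled visits.
#' @return An [spm_spec()].
#' @export
hers_spec <- function(M = 12L) {
  spm_spec(study_design(M),
           fixed  = ~ time * (vl + art + sympt),
           hazard = ~ vl + art + sympt + time + I(time^2) + art:time)
}

#' Baseline covariate sampler for the HIV-cohort emulation
#'
#' Independent sampling of the three baseline covariates: viral-load group
#' (factor with reference `>30k`), ART indicator, and integer symptom score
#' 0-5.  Joint dependence between the covariates is deliberately not
#' emulated.
#'
#' @param prob_vl Sampling probabilities for viral-load levels
#'   `>30k, 0-500, 500-5k, 5k-30k`.
#' @param prob_art Probability of ART at baseline.
#' @param sympt_size,sympt_prob Binomial parameters for the symptom score.
#' @return A function of `n` returning an `n`-row tibble.
#' @export
hers_covariate_sampler <- function(prob_vl = c(0.25, 0.3, 0.25, 0.2),
                                   prob_art = 0.4,
                                   sympt_size = 5, sympt_prob = 0.2) {
  lv <- c(">30k", "0-500", "500-5k", "5k-30k")
  stopifnot(length(prob_vl) == 4, all(prob_vl >= 0))
  function(n) {
    tibble::tibble(
      vl = factor(sample(lv, n, replace = TRUE, prob = prob_vl), levels = lv),
      art = rbinom(n, 1, prob_art),
      sympt = rbinom(n, sympt_size, sympt_prob)
    )
  }
}

#' Synthetic-data generator configuration
#'
#' @param N Number of subjects.
#' @param spec An [spm_spec()] (design + formulas).
#' @param params True [spm_params()] used to generate the data.
#' @param covariate_sampler Function of `n` returning an `n`-row tibble of
#'   baseline covariates matching the formulas in `spec`.
#' @param intermittent_rate Probability that an in-follow-up outcome at
#'   visits `2..S` is intermittently missing (the baseline outcome is never
#'   masked).  Default 0; around 0.076 mimics the motivating cohort.
#' @param seed Master seed.  Per-subject random streams are derived from it
#'   deterministically, so enlarging `N` never reshuffles earlier subjects.
#' @return An object of class `spm_generator`.
#' @export
spm_generator <- function(N, spec = hers_spec(), params = hers_params(),
                          covariate_sampler = hers_covariate_sampler(),
                          intermittent_rate = 0, seed = 1L) {
  stopifnot(inherits(spec, "spm_spec"), inherits(params, "spm_params"))
  if (N < 1) abort("`N` must be >= 1.")
  if (intermittent_rate < 0 || intermittent_rate > 1)
    abort("`intermittent_rate` must be in [0, 1].")
  structure(list(N = as.integer(N), spec = spec, params = params,
                 covariate_sampler = covariate_sampler,
                 intermittent_rate = intermittent_rate,
                 seed = as.integer(seed)),
            class = "spm_generator")
}

# Deterministic per-subject substream: a distinct, reproducible seed per
# (master seed, subject id) pair, kept inside 32-bit integer range.
subject_seed <- function(seed, id) {
  as.integer((as.double(seed) * 48271 + as.double(id) * 69621) %% 2147483587)
}

#' Simulate one subject from the shared parameter model
#'
#' Draws baseline covariates, random effects `b ~ N(0, Sigma_b)`, the
#' complete outcome vector `Y_j = x_j' beta + z_j' b + eps_j` at all `M`
#' visits, and the dropout visit `S` by sequential Bernoulli trials with
#' the probit discrete hazard; then truncates at `S` and applies
#' intermittent masking (never at visit 1).
#'
#' @param config An [spm_generator()].
#' @param id Subject id (integer; also selects the subject's random
#'   substream).
#' @return A list with `record` (the observed [spm_data()]-style subject
#'   record), `y_complete` (length-`M` complete outcome), and `b`.
#' @export
simulate_subject <- function(config, id) {
  set.seed(subject_seed(config$seed, id))
  spec <- config$spec
  params <- config$params
  des <- spec$design
  M <- des$M
  covs <- config$covariate_sampler(1L)

  rc <- params$re_cov
  b1 <- rnorm(1, 0, rc$sigma1)
  b2 <- rc$delta * b1 + rnorm(1, 0, rc$sigma2)
  b <- c(b1, b2)

  # a skeleton record gives us the design matrices for this profile
  rec <- new_subject_record(id, M, rep(NA_real_, M), rep(FALSE, M), covs, spec)

  beta <- align_coef(params$beta, rec$X, "beta")
  y_complete <- drop(rec$X %*% beta) + drop(rec$Z %*% b) +
    rnorm(M, 0, params$sigma_eps)

  lambda <- discrete_hazard(rec, seq_len(M - 1L), b, params)
  u <- runif(M - 1L)
  drop_at <- which(u < lambda)
  S <- if (length(drop_at)) min(drop_at) else M

  obs <- seq_len(M) <= S
  if (config$intermittent_rate > 0 && S > 1L) {
    mask <- runif(S - 1L) < config$intermittent_rate
    obs[1L + which(mask)] <- FALSE
  }
  y <- ifelse(obs, y_complete, NA_real_)
  rec$S <- as.integer(S)
  rec$y <- y
  rec$obs <- obs
  list(record = rec, y_complete = y_complete, b = b)
}

#' Simulate a full dataset from the shared parameter model
#'
#' @param config An [spm_generator()].
#' @return An object of class `spm_sim`: a list with `data` (an
#'   [spm_data()] object of the observed records), and `truth` (the
#'   generating `params`, the `N x 2` matrix of random effects, the
#'   `N x M` complete outcome matrix, and the dropout visits `S`) kept
#'   separate so observed-data code cannot leak complete-data information.
#' @examples
#' sim <- simulate_spm(spm_generator(25, seed = 7))
#' sim$data
#' @export
simulate_spm <- function(config) {
  stopifnot(inherits(config, "spm_generator"))
  subs <- lapply(seq_len(config$N), function(i) simulate_subject(config, i))
  records <- lapply(subs, `[[`, "record")
  dat <- structure(list(subjects = records, spec = config$spec,
                        mapping = list(id = "id", visit = "visit", y = "y",
                                       s_col = "S")),
                   class = "spm_data")
  truth <- list(
    params = config$params,
    b = do.call(rbind, lapply(subs, `[[`, "b")),
    y_complete = do.call(rbind, lapply(subs, `[[`, "y_complete")),
    S = vapply(records, `[[`, integer(1), "S")
  )
  structure(list(data = dat, truth = truth, config = config),
            class = "spm_sim")
}

#' @export
print.spm_sim <- function(x, ...) {
  cat("<spm_sim> N =", x$config$N, "subjects (seed", x$config$seed, ")\n")
  print(x$data)
  invisible(x)
}

#' Write a simulated dataset and its truth bundle to disk
#'
#' Writes `dataset.csv` (long format, attended visits only, empty cells
#' for intermittently missing outcomes, plus the dropout visit column `S`)
#' and a truth bundle (`truth_params.yaml`, `truth_subjects.csv` with the
#' per-subject random effects and complete outcomes).  Byte-identical
#' output for identical generator configs.
#'
#' @param sim An [simulate_spm()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_spm_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "spm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  des <- sim$config$spec$design
  long <- as_tibble.spm_data(sim$data)
  long <- dplyr::filter(long, .data$visit <= .data$S)
  long <- dplyr::select(long, -"observed")
  f_data <- file.path(dir, "dataset.csv")
  readr::write_csv(long, f_data, na = "")

  p <- sim$truth$params
  f_par <- file.path(dir, "truth_params.yaml")
  yaml::write_yaml(list(
    beta = as.list(p$beta), alpha = as.list(p$alpha),
    gamma = as.numeric(p$gamma),
    delta = p$re_cov$delta, sigma1 = p$re_cov$sigma1,
    sigma2 = p$re_cov$sigma2, sigma_eps = p$sigma_eps
  ), f_par)

  yc <- sim$truth$y_complete
  colnames(yc) <- paste0("y_complete_", seq_len(des$M))
  truth_tbl <- dplyr::bind_cols(
    tibble::tibble(id = vapply(sim$data$subjects, function(s) as.character(s$id),
                               character(1)),
                   b1 = sim$truth$b[, 1], b2 = sim$truth$b[, 2],
                   S = sim$truth$S),
    tibble::as_tibble(yc)
  )
  f_truth <- file.path(dir, "truth_subjects.csv")
  readr::write_csv(truth_tbl, f_truth)
  invisible(c(f_data, f_par, f_truth))
}
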