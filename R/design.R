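#' Study design: scheduled visits on a standardized time scale
#'
#' Describes the visit schedule shared by all subjects: `M` scheduled visits
#' at times in `[0, 1]`.  The default schedule is equally spaced,
#' `t_j = (j - 1) / (M - 1)`, i.e. visit numbers standardized so that
#' baseline is 0 and the final scheduled visit is 1.
#'
#' @param M Number of scheduled visits (integer, at least 2).
#' @param times Optional numeric vector of length `M` of visit times;
#'   must start at 0 and be strictly increasing.
#'
#' @return An object of class `study_design`: a list with elements `M`
#'   and `times`.
#' @examples
#' study_design(12)
#' @export
study_design <- function(M = 12L, times = NULL) {
  M <- as.integer(M)
  if (is.na(M) || M < 2L) abort("`M` must be an integer >= 2.")
  if (is.null(times)) times <- (seq_len(M) - 1) / (M - 1)
  times <- as.numeric(times)
  if (length(times) != M) abort("`times` must have length `M`.")
  if (times[1] != 0) abort("`times[1]` must be 0 (baseline).")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  structure(list(M = M, times = times), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> ", x$M, " visits at t = ",
      paste(signif(x$times, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Model specification: formulas mapping covariates to design matrices
#'
#' Binds the study design to two one-sided formulas evaluated on the
#' long-format data: `fixed` builds the fixed-effects rows `x_ij` of the
#' longitudinal model and `hazard` builds the rows `x_{S,ij}` of the
#' discrete-hazard probit model.  Both formulas may use the column `time`
#' (the standardized visit time); the hazard formula is evaluated at the
#' at-risk visits `1, ..., M - 1`, where the `time` value of risk index
#' `l` is the design time `t_l`.  Random effects are the intercept and
#' slope, `z_ij = (1, t_j)`.
#'
#' @param design A [study_design()].
#' @param fixed One-sided formula for the longitudinal fixed effects.
#' @param hazard One-sided formula for the dropout hazard covariates.
#'
#' @return An object of class `spm_spec`.
#' @examples
#' spm_spec(study_design(12),
#'          fixed  = ~ time * (vl + art + sympt),
#'          hazard = ~ vl + art + sympt + time + I(time^2) + art:time)
#' @export
spm_spec <- function(design, fixed, hazard) {
  stopifnot(inherits(design, "study_design"))
  if (!inherits(fixed, "formula") || !inherits(hazard, "formula"))
    abort("`fixed` and `hazard` must be formulas.")
  structure(list(design = design, fixed = fixed, hazard = hazard),
            class = "spm_spec")
}

#' @export
print.spm_spec <- function(x, ...) {
  cat("<spm_spec>\n  fixed:  ", deparse(x$fixed),
      "\n  hazard: ", deparse(x$hazard),
      "\n  visits: ", x$design$M, "\n", sep = "")
  invisible(x)
}

# Baseline covariate columns = everything named in the formulas except time.
spec_covariates <- function(spec) {
  v <- union(all.vars(spec$fixed), all.vars(spec$hazard))
  setdiff(v, "time")
}

#' Assemble per-subject records from a long-format table
#'
#' Converts a long table (one row per subject-visit; missing outcome values
#' recorded as `NA`) into the per-subject records used by the likelihood,
#' extrapolation and G-computation machinery.  Each subject is completed to
#' the full visit grid `1..M` (baseline covariates are carried to unattended
#' visits, so design rows exist for extrapolation), the dropout visit `S` is
#' taken from `s_col` if given or derived as the last visit with an observed
#' outcome, and the fixed-effects and hazard design matrices are built from
#' the formulas in `spec`.
#'
#' Missingness convention: the outcome at visit 1 must be observed; `NA`
#' outcomes at visits `<= S` are intermittent gaps (handled by row deletion
#' in the likelihood); all visits `> S` are unobserved by definition.
#'
#' @param data Long-format data frame with at least id, visit and outcome
#'   columns plus the covariates named in `spec`.
#' @param spec An [spm_spec()].
#' @param id,visit,y Names of the subject-id, visit-number and outcome
#'   columns (defaults `"id"`, `"visit"`, `"y"`).
#' @param s_col Optional name of a column giving the dropout visit `S`
#'   (last attended visit, `M` for completers); constant within subject.
#'
#' @return An object of class `spm_data`: a list with `subjects` (list of
#'   per-subject records), `spec`, and the column mapping.  Each record has
#'   elements `id`, `S`, `y` (length `M`, `NA` where unobserved), `obs`
#'   (logical length `M`), `X` (`M x p`), `Z` (`M x 2`), `Xs`
#'   (`(M-1) x p_S`), and `covariates` (one-row tibble of baseline values).
#' @export
spm_data <- function(data, spec, id = "id", visit = "visit", y = "y",
                     s_col = NULL) {
  stopifnot(inherits(spec, "spm_spec"))
  data <- tibble::as_tibble(data)
  need <- c(id, visit, y, spec_covariates(spec))
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort(paste0("Missing columns in `data`: ", paste(miss, collapse = ", ")))
  des <- spec$design
  M <- des$M

  split_rows <- split(seq_len(nrow(data)), data[[id]])
  # preserve first-appearance order of subjects
  split_rows <- split_rows[unique(as.character(data[[id]]))]

  subjects <- lapply(names(split_rows), function(sid) {
    rows <- data[split_rows[[sid]], , drop = FALSE]
    vis <- as.integer(rows[[visit]])
    if (anyDuplicated(vis)) abort(paste0("Duplicate visits for subject ", sid))
    if (any(vis < 1L | vis > M))
      abort(paste0("Visit out of 1..M range for subject ", sid))
    yfull <- rep(NA_real_, M)
    yfull[vis] <- as.numeric(rows[[y]])
    if (is.na(yfull[1]))
      abort(paste0("Baseline outcome missing for subject ", sid,
                   " (visit 1 must be observed)."))
    if (!is.null(s_col)) {
      S <- as.integer(rows[[s_col]][1])
    } else {
      S <- max(which(!is.na(yfull)))
    }
    if (S < 1L || S > M) abort(paste0("Dropout visit out of range for ", sid))
    obs <- !is.na(yfull)
    obs[seq_len(M) > S] <- FALSE
    yfull[!obs] <- NA_real_
    cov1 <- rows[1, spec_covariates(spec), drop = FALSE]
    new_subject_record(sid, S, yfull, obs, cov1, spec)
  })
  structure(list(subjects = subjects, spec = spec,
                 mapping = list(id = id, visit = visit, y = y, s_col = s_col)),
            class = "spm_data")
}

# Build one subject record from baseline covariates (design rows for all M
# visits).  Used by spm_data() and by the simulator/G-computation, which
# construct records directly from covariate profiles.
new_subject_record <- function(id, S, y, obs, covariates, spec) {
  des <- spec$design
  M <- des$M
  grid <- tibble::as_tibble(covariates)[rep(1L, M), , drop = FALSE]
  grid$time <- des$times
  X <- model.matrix(spec$fixed, grid)
  Z <- cbind(1, des$times)
  Xs <- model.matrix(spec$hazard, grid[seq_len(M - 1L), , drop = FALSE])
  structure(list(id = id, S = as.integer(S), y = y, obs = obs,
                 X = X, Z = Z, Xs = Xs,
                 covariates = tibble::as_tibble(covariates)),
            class = "subject_record")
}

#' @export
print.spm_data <- function(x, ...) {
  S <- vapply(x$subjects, `[[`, integer(1), "S")
  M <- x$spec$design$M
  cat("<spm_data> ", length(x$subjects), " subjects, M = ", M,
      "; completers: ", sum(S == M),
      " (", round(100 * mean(S == M)), "%)\n", sep = "")
  invisible(x)
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record> id=", x$id, " S=", x$S, " observed ",
      sum(x$obs), "/", length(x$y), " outcomes\n", sep = "")
  invisible(x)
}

#' Long-format view of an spm_data object
#'
#' @param x An [spm_data()] object.
#' @param ... Unused.
#' @return A tibble with one row per subject-visit: id, visit, time, y,
#'   observed flag, dropout visit S, and baseline covariates.
#' @export
as_tibble.spm_data <- function(x, ...) {
  des <- x$spec$design
  purrr::map_dfr(x$subjects, function(s) {
    dplyr::bind_cols(
      tibble::tibble(id = s$id, visit = seq_len(des$M), time = des$times,
                     y = s$y, observed = s$obs, S = s$S),
      s$covariates[rep(1L, des$M), , drop = FALSE]
    )
  })
}
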