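#' @importFrom stats runif rnorm
NULL

#' Configuration for the synthetic feeding-trial generator
#'
#' Defines a multi-study treatment-mean database with the statistical
#' structure the mixed-model development assumes: a fixed dietary response
#' (the `true_model` equation), one random level shift per study, and a
#' within-experiment residual whose SD scales with 1/sqrt(n_obs) so that
#' weighting by the number of observations is exact inverse-variance
#' weighting. Predictors are drawn uniformly within their ranges with a
#' study-level mean shift, so studies differ in mean DMI and diet as real
#' feeding experiments do.
#'
#' Default predictor ranges span the published database: DMI 8-26 kg/day,
#' FA 10-60 g/kg DM, NDF 250-550 g/kg DM, forage proportion 45-100%.
#'
#' @param n_studies Number of studies.
#' @param n_records Total number of treatment means, distributed as evenly
#'   as possible across studies.
#' @param true_model Basic-model id or spec generating the mean response.
#' @param sigma_study SD of the random study intercept, MJ/day.
#' @param sigma_resid Within-experiment residual SD, MJ/day, for a record
#'   with one observation (scaled by 1/sqrt(n_obs) per record).
#' @param predictor_ranges Named list of `c(min, max)` for `dmi`, `fa`,
#'   `ndf`, `forage_prop`.
#' @param n_obs_range Integer `c(min, max)` animals per treatment mean.
#' @param technique_probs Named probabilities over the four measurement
#'   techniques; techniques are assigned per study.
#' @param technique_effects Named per-technique CH4 offsets, MJ/day
#'   (default all 0).
#' @param within_study_frac Fraction of each predictor range used as the
#'   within-study spread (controls the study-level correlation of
#'   predictors).
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return List of class `trial_gen_config`.
#' @export
trial_gen_config <- function(n_studies = 19,
                             n_records = 63,
                             true_model = "model3",
                             sigma_study = 1.5,
                             sigma_resid = 1.0,
                             predictor_ranges = list(
                               dmi = c(8, 26), fa = c(10, 60),
                               ndf = c(250, 550), forage_prop = c(45, 100)),
                             n_obs_range = c(2L, 6L),
                             technique_probs = c(tracer = 0.48,
                                                 chamber = 0.45,
                                                 headhood = 0.035,
                                                 greenfeed = 0.035),
                             technique_effects = c(tracer = 0, chamber = 0,
                                                   headhood = 0,
                                                   greenfeed = 0),
                             within_study_frac = 0.3,
                             seed = 1L) {
  stopifnot(n_studies >= 1, n_records >= n_studies,
            sigma_study >= 0, sigma_resid >= 0,
            within_study_frac > 0, within_study_frac <= 1)
  for (rg in predictor_ranges) {
    if (length(rg) != 2 || rg[1] > rg[2]) stop("predictor range not ordered")
  }
  if (abs(sum(technique_probs) - 1) > 1e-8) {
    stop("technique_probs must sum to 1")
  }
  structure(list(
    n_studies = as.integer(n_studies), n_records = as.integer(n_records),
    true_model = basic_model(true_model), sigma_study = sigma_study,
    sigma_resid = sigma_resid, predictor_ranges = predictor_ranges,
    n_obs_range = as.integer(n_obs_range),
    technique_probs = technique_probs,
    technique_effects = technique_effects,
    within_study_frac = within_study_frac, seed = as.integer(seed)
  ), class = "trial_gen_config")
}

#' Generate a synthetic feeding-trial database
#'
#' Draws a treatment-mean database per the configured study structure:
#' `ch4_mj = true_model(predictors) + study_effect + residual + technique
#' offset`, with one study effect per study (SD `sigma_study`), residual SD
#' `sigma_resid / sqrt(n_obs)` and the study's technique offset. All latent
#' draws are returned in the `truth` element so parameter-recovery tests
#' can compare against the generating values.
#'
#' @param config A [trial_gen_config()].
#' @return List with `records` (a validated trial table) and `truth`
#'   (list: `config`, `study_effects`, `residuals`, `true_coefficients`).
#' @examples
#' db <- generate_trial_database(trial_gen_config(seed = 42))
#' nrow(db$records) # 63
#' @export
generate_trial_database <- function(config) {
  stopifnot(inherits(config, "trial_gen_config"))
  set.seed(config$seed)
  ns <- config$n_studies
  sizes <- rep(config$n_records %/% ns, ns)
  extra <- config$n_records %% ns
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

  study_effects <- rnorm(ns, 0, config$sigma_study)
  study_technique <- sample(names(config$technique_probs), ns,
                            replace = TRUE, prob = config$technique_probs)

  draw_pred <- function(range, size) {
    half <- config$within_study_frac * diff(range) / 2
    center <- runif(1, range[1] + half, range[2] - half)
    runif(size, center - half, center + half)
  }

  rows <- vector("list", ns)
  resids <- vector("list", ns)
  for (j in seq_len(ns)) {
    sz <- sizes[j]
    dmi <- draw_pred(config$predictor_ranges$dmi, sz)
    fa  <- draw_pred(config$predictor_ranges$fa, sz)
    ndf <- draw_pred(config$predictor_ranges$ndf, sz)
    forage <- draw_pred(config$predictor_ranges$forage_prop, sz)
    n_obs <- sample(seq(config$n_obs_range[1], config$n_obs_range[2]),
                    sz, replace = TRUE)
    eps <- rnorm(sz, 0, config$sigma_resid / sqrt(n_obs))
    mu <- predict_ch4(config$true_model, dmi = dmi, fa = fa, ndf = ndf,
                      ee = fa / 0.8)
    rows[[j]] <- data.frame(
      study_id = sprintf("S%02d", j), n_obs = n_obs, stage = "lactating",
      forage_prop = forage, dmi = dmi, fa = fa, ee = fa / 0.8, ndf = ndf,
      ch4_mj = mu + study_effects[j] + eps +
        config$technique_effects[[study_technique[j]]],
      technique = study_technique[j], subset = "development")
    resids[[j]] <- eps
  }
  records <- validate_trial_records(do.call(rbind, rows))
  list(records = records,
       truth = list(config = config,
                    study_effects = setNames(study_effects,
                                             sprintf("S%02d", seq_len(ns))),
                    residuals = unlist(resids),
                    true_coefficients = config$true_model))
}

#' Split a trial database into development and evaluation subsets
#'
#' Splits by whole studies, never within a study: studies are shuffled and
#' assigned to the evaluation subset until its record count best
#' approximates `frac_eval` of the total.
#'
#' @param records Validated trial-record data frame (>= 2 studies).
#' @param frac_eval Target evaluation fraction, strictly between 0 and 1.
#' @param seed Integer seed for the study shuffle.
#' @return List with `development` and `evaluation` data frames; the
#'   `subset` column is set accordingly. No study appears in both.
#' @export
generate_eval_split <- function(records, frac_eval, seed = 1L) {
  if (!is.numeric(frac_eval) || frac_eval <= 0 || frac_eval >= 1) {
    stop("frac_eval must lie strictly between 0 and 1")
  }
  studies <- unique(records$study_id)
  if (length(studies) < 2) stop("too few studies to split")
  set.seed(seed)
  studies <- sample(studies)
  counts <- table(records$study_id)[studies]
  target <- frac_eval * nrow(records)
  cum <- cumsum(as.numeric(counts))
  # take the prefix whose record count is closest to the target,
  # keeping at least one study on each side
  k <- which.min(abs(cum - target))
  k <- min(max(k, 1L), length(studies) - 1L)
  eval_studies <- studies[seq_len(k)]
  ev <- records[records$study_id %in% eval_studies, ]
  dev <- records[!records$study_id %in% eval_studies, ]
  ev$subset <- "evaluation"
  dev$subset <- "development"
  list(development = dev, evaluation = ev)
}
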