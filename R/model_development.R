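#' @importFrom lme4 lmer fixef VarCorr lmerControl
#' @importFrom stats as.formula anova pt lm coef setNames
NULL

fit_lmer_quiet <- function(formula, data, weights, REML = TRUE) {
  msgs <- character()
  # lmer assigns helper objects into the formula environment; give it this
  # frame so the caller's locals are never clobbered (all model variables
  # live in `data`)
  environment(formula) <- environment()
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, weights = weights, REML = REML,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(fit = fit, messages = msgs)
}

#' Refit a basic CH4 equation by weighted linear mixed-effects
#'
#' Fits CH4 production (MJ/day) on a subset of \{dmi, fa, ndf, ee\} with a
#' single random intercept grouped by study, the structure appropriate for
#' treatment means pooled across feeding experiments: fixed slopes capture
#' the dietary response while the random study intercept absorbs
#' between-experiment level differences. Estimation is REML; records are
#' weighted by their number of contributing observations (case weights
#' proportional to `n_obs`, normalised to mean 1 so variance components are
#' scale-stable) or uniformly. The intercept can be suppressed to force
#' zero CH4 at zero intake.
#'
#' Wald t statistics with residual degrees of freedom (n - p) provide the
#' fixed-effect p-values.
#'
#' @param records Validated trial-record data frame (>= 2 distinct studies).
#' @param predictors Character subset of `c("dmi","fa","ndf","ee")`.
#' @param include_intercept Keep the fixed intercept? `FALSE` forces the
#'   equation through the origin.
#' @param weights `"n_obs"` (default) or `"uniform"`.
#' @return Object of class `ch4_fit`: list with `coefficients`,
#'   `std_errors`, `p_values` (named per predictor, plus `(Intercept)`
#'   unless suppressed), `sigma_study`, `sigma_resid`, `converged`,
#'   `messages`, `n_studies`, `n_records`, `predictors`, `vif` and the
#'   underlying `merMod` object as `fit`.
#' @examples
#' cfg <- trial_gen_config(n_studies = 10, n_records = 40, seed = 7)
#' db <- generate_trial_database(cfg)
#' fit_basic_model(db$records, c("dmi", "fa", "ndf"),
#'                 include_intercept = FALSE)
#' @export
fit_basic_model <- function(records,
                            predictors = c("dmi", "fa", "ndf"),
                            include_intercept = TRUE,
                            weights = c("n_obs", "uniform")) {
  weights <- match.arg(weights)
  predictors <- match.arg(predictors, c("dmi", "fa", "ndf", "ee"),
                          several.ok = TRUE)
  n_studies <- length(unique(records$study_id))
  if (n_studies < 2) {
    stop("at least 2 distinct studies are required to estimate the ",
         "random study intercept")
  }
  if (nrow(records) < length(predictors) + 2) {
    stop("too few records for ", length(predictors), " predictor(s)")
  }
  for (p in predictors) {
    if (any(is.na(records[[p]]))) {
      stop("missing values in requested predictor '", p, "'")
    }
  }
  X <- as.matrix(records[predictors])
  if (qr(cbind(if (include_intercept) 1, X))$rank <
      ncol(X) + include_intercept) {
    stop("rank-deficient design: collinear columns among ",
         paste(predictors, collapse = ", "))
  }

  w <- if (weights == "n_obs") records$n_obs / mean(records$n_obs)
       else rep(1, nrow(records))
  d <- data.frame(ch4_mj = records$ch4_mj, X,
                  study_id = factor(records$study_id), .w = w)
  rhs <- paste(c(if (!include_intercept) "0", predictors, "(1 | study_id)"),
               collapse = " + ")
  fq <- fit_lmer_quiet(as.formula(paste("ch4_mj ~", rhs)), d, d$.w)

  est <- lme4::fixef(fq$fit)
  se <- sqrt(diag(as.matrix(vcov(fq$fit))))
  df_resid <- nrow(d) - length(est)
  pv <- 2 * stats::pt(-abs(est / se), df = df_resid)
  vc <- as.data.frame(lme4::VarCorr(fq$fit))

  structure(list(
    coefficients = est,
    std_errors = setNames(se, names(est)),
    p_values = setNames(pv, names(est)),
    sigma_study = vc$sdcor[vc$grp == "study_id"],
    sigma_resid = vc$sdcor[vc$grp == "Residual"],
    converged = !any(grepl("failed to converge", fq$messages)),
    messages = fq$messages,
    n_studies = n_studies, n_records = nrow(records),
    predictors = predictors, include_intercept = include_intercept,
    weights = weights,
    vif = if (length(predictors) >= 2) vif(records, predictors),
    fit = fq$fit
  ), class = "ch4_fit")
}

#' @export
print.ch4_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted mixed-effects CH4 model (%d records, %d studies, weights %s)\n",
    x$n_records, x$n_studies, x$weights))
  tab <- data.frame(estimate = x$coefficients, std_error = x$std_errors,
                    p_value = signif(x$p_values, 3))
  print(tab, digits = 4)
  cat(sprintf("sigma_study %.3f  sigma_resid %.3f  converged: %s\n",
              x$sigma_study, x$sigma_resid, x$converged))
  invisible(x)
}

#' Variance inflation factors for a candidate predictor set
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j comes from the ordinary regression of
#' predictor j on the remaining predictors (with intercept). Computed on
#' the fixed-effects design only. Values exceeding 5 flag multicollinearity
#' in this workflow; perfectly collinear predictors are reported as `Inf`,
#' not as an error.
#'
#' @param records Trial-record data frame (or any data frame containing the
#'   predictor columns).
#' @param predictors Character vector of >= 2 column names.
#' @return Named numeric vector of VIFs (>= 1).
#' @export
vif <- function(records, predictors) {
  if (length(predictors) < 2) stop("vif() needs at least 2 predictors")
  if (nrow(records) < length(predictors) + 1) {
    stop("too few records to compute VIF")
  }
  X <- as.data.frame(records[predictors])
  out <- vapply(predictors, function(p) {
    f <- as.formula(paste(p, "~", paste(setdiff(predictors, p),
                                        collapse = " + ")))
    r2 <- summary(stats::lm(f, data = X))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(pmax(out, 1), predictors)
}

#' Screen for a measurement-technique effect
#'
#' Adds the categorical CH4 measurement technique (tracer, chamber,
#' headhood, greenfeed) as a fixed factor to the mixed model and tests it
#' jointly by a likelihood-ratio test (ML refits of the models with and
#' without the factor). Techniques not significant at the screening
#' threshold (p > 0.1) are recommended for exclusion from final models.
#'
#' @inheritParams fit_basic_model
#' @param threshold Screening significance level (default 0.1).
#' @return List with `p_value`, `df` (numerator degrees of freedom),
#'   `keep_technique` (logical, `p < threshold`) and `n_levels`.
#' @export
screen_technique_effect <- function(records,
                                    predictors = c("dmi", "fa", "ndf"),
                                    include_intercept = TRUE,
                                    weights = c("n_obs", "uniform"),
                                    threshold = 0.1) {
  weights <- match.arg(weights)
  lev <- unique(records$technique)
  if (length(lev) < 2) {
    stop("technique screening requires at least 2 technique levels")
  }
  w <- if (weights == "n_obs") records$n_obs / mean(records$n_obs)
       else rep(1, nrow(records))
  d <- data.frame(ch4_mj = records$ch4_mj,
                  as.data.frame(records[predictors]),
                  technique = factor(records$technique),
                  study_id = factor(records$study_id), .w = w)
  base_rhs <- paste(c(if (!include_intercept) "0", predictors,
                      "(1 | study_id)"), collapse = " + ")
  f0 <- fit_lmer_quiet(as.formula(paste("ch4_mj ~", base_rhs)),
                       d, d$.w, REML = FALSE)
  f1 <- fit_lmer_quiet(
    as.formula(paste("ch4_mj ~", base_rhs, "+ technique")),
    d, d$.w, REML = FALSE)
  lrt <- suppressMessages(anova(f0$fit, f1$fit))
  p <- lrt[["Pr(>Chisq)"]][2]
  list(p_value = p, df = lrt$Df[2], keep_technique = p < threshold,
       n_levels = length(lev))
}

#' Check that every retained predictor is significant
#'
#' Final reported models keep only predictors significant at p < 0.05;
#' this helper applies that rule to a fitted model.
#'
#' @param fit A `ch4_fit` from [fit_basic_model()].
#' @param alpha Significance threshold (default 0.05).
#' @return List with `valid` (all predictor p-values below `alpha`) and
#'   `failing` (names of predictors that are not).
#' @export
validate_final_model <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "ch4_fit"))
  pv <- fit$p_values[setdiff(names(fit$p_values), "(Intercept)")]
  failing <- names(pv)[pv >= alpha]
  list(valid = length(failing) == 0, failing = failing)
}
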