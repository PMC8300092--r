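operational_model_table <- list(
  ym_s = list(b0 = 7.11, b_ecm = -7e-5,   b_conc = -4.1e-3,
              response = "ym",
              label = "Ym from CH4 predicted with the Storlien equation"),
  ym_m = list(b0 = 7.65, b_ecm = -1.1e-4, b_conc = -5.4e-3,
              response = "ym",
              label = "Ym from CH4 predicted with the developed zero-intercept model"),
  ym_n = list(b0 = 7.71, b_ecm = -1e-4,   b_conc = -4.4e-3,
              response = "ym",
              label = "Ym from CH4 predicted with the Nielsen (NorFor) equation"),
  gei  = list(b0 = 159,  b_ecm = 0.02,    b_conc = 1.39,
              response = "gei",
              label = "Gross energy intake from ECM and concentrate share")
)

#' Retrieve a published operational model
#'
#' The operational tier predicts the methane conversion factor Ym (% of
#' GEI) or gross energy intake (MJ/cow/day) linearly from annual
#' energy-corrected milk yield (kg) and dietary concentrate share
#' (percentage points of DM). Coefficients are frozen to the published
#' values; the three Ym variants differ in which basic model generated the
#' CH4 input. Both Ym slopes are negative and both GEI slopes positive.
#'
#' @param model_id One of `"ym_s"`, `"ym_m"`, `"ym_n"`, `"gei"`.
#' @return List with `model_id`, `b0`, `b_ecm`, `b_conc`, `response`,
#'   `label`.
#' @export
operational_model <- function(model_id) {
  if (!is.character(model_id) || length(model_id) != 1 ||
      !model_id %in% names(operational_model_table)) {
    stop("unknown operational model id; use one of: ",
         paste(names(operational_model_table), collapse = ", "))
  }
  c(list(model_id = model_id), operational_model_table[[model_id]])
}

check_op_inputs <- function(ecm_annual, conc_share) {
  if (any(ecm_annual < 0)) stop("ecm_annual must be >= 0")
  if (any(conc_share < 0 | conc_share > 100)) {
    stop("conc_share must lie in [0, 100] (percentage points)")
  }
}

#' Predict the methane conversion factor Ym
#'
#' Exact, unrounded evaluation of the published linear Ym equation
#' (round only for display, e.g. `round(ym, 2)`).
#'
#' @param model_id `"ym_s"`, `"ym_m"` or `"ym_n"`.
#' @param ecm_annual Annual (305-day) ECM, kg.
#' @param conc_share Concentrate share, % of DM.
#' @return Ym, % of GEI.
#' @examples
#' round(predict_ym("ym_s", 6000, 38), 2) # 6.53
#' @export
predict_ym <- function(model_id, ecm_annual, conc_share) {
  m <- operational_model(model_id)
  if (m$response != "ym") stop("'", model_id, "' is not a Ym model")
  check_op_inputs(ecm_annual, conc_share)
  m$b0 + m$b_ecm * ecm_annual + m$b_conc * conc_share
}

#' Predict gross energy intake from ECM and concentrate share
#'
#' @inheritParams predict_ym
#' @return GEI, MJ/cow/day.
#' @examples
#' predict_gei(0, 0) # 159 (intercept)
#' @export
predict_gei <- function(ecm_annual, conc_share) {
  m <- operational_model("gei")
  check_op_inputs(ecm_annual, conc_share)
  m$b0 + m$b_ecm * ecm_annual + m$b_conc * conc_share
}

#' Annual enteric CH4 emission factor
#'
#' Tier-2 style emission factor
#' `EF = GEI x (Ym / 100) x 365 / 55.65` (kg CH4/head/year), with 55.65
#' MJ/kg the energy content of methane. Bilinear in GEI and Ym; round to
#' one decimal for display.
#'
#' @param gei Gross energy intake, MJ/cow/day (>= 0).
#' @param ym Methane conversion factor, % of GEI (>= 0).
#' @return EF, kg CH4/head/year.
#' @examples
#' round(emission_factor(298, 6.66), 1) # 130.2
#' @export
emission_factor <- function(gei, ym) {
  if (any(gei < 0) || any(ym < 0)) {
    stop("gei and ym must be non-negative")
  }
  gei * (ym / 100) * 365 / ch4_units$mj_per_kg_ch4
}

#' Compose an emission scenario from the operational models
#'
#' Evaluates the chosen Ym equation (unrounded), takes GEI either from the
#' published GEI equation (default) or from a supplied table value, and
#' composes the annual emission factor.
#'
#' @param ecm_annual Annual ECM, kg.
#' @param conc_share Concentrate share, % of DM.
#' @param ym_model `"ym_s"`, `"ym_m"` or `"ym_n"`.
#' @param gei `NULL` to use the published GEI equation, or a numeric GEI
#'   (MJ/cow/day) table value.
#' @return List of class `emission_scenario`: `ecm_annual`, `conc_share`,
#'   `ym_model`, `ym` (%), `gei_source`, `gei` (MJ/cow/day), `ef`
#'   (kg CH4/head/year).
#' @examples
#' s <- scenario_report(6000, 38, "ym_s", gei = 298)
#' round(s$ef, 1) # 127.7
#' @export
scenario_report <- function(ecm_annual, conc_share, ym_model = "ym_s",
                            gei = NULL) {
  ym <- predict_ym(ym_model, ecm_annual, conc_share)
  gei_source <- if (is.null(gei)) "printed_equation" else "table_value"
  if (is.null(gei)) gei <- predict_gei(ecm_annual, conc_share)
  if (any(gei < 0)) stop("gei must be non-negative")
  structure(list(ecm_annual = ecm_annual, conc_share = conc_share,
                 ym_model = ym_model, ym = ym, gei_source = gei_source,
                 gei = gei, ef = emission_factor(gei, ym)),
            class = "emission_scenario")
}

#' @export
print.emission_scenario <- function(x, ...) {
  cat(sprintf(
    "Emission scenario: %g kg ECM/yr, %.1f%% concentrate [%s, GEI %s]\n",
    x$ecm_annual, x$conc_share, x$ym_model, x$gei_source))
  cat(sprintf("  Ym %.2f%% of GEI   GEI %.0f MJ/cow/day   EF %.1f kg CH4/head/yr\n",
              x$ym, x$gei, x$ef))
  invisible(x)
}

#' Refit an operational model on a simulated feeding database
#'
#' Linear mixed-effects fit of Ym or GEI on annual ECM and concentrate
#' share over the lactating records. The repeated structure treats each
#' ECM production level as the subject observed repeatedly over days
#' after calving: a random intercept grouped by ECM level (default). The
#' finer day-within-ECM-level interaction grouping is available as an
#' alternative; it additionally absorbs the lactation time course, which
#' on this grid is the main source of within-level concentrate-share
#' variation. VIF of the two fixed predictors is reported alongside.
#'
#' @param records Operational database with `ym` attached (for
#'   `response = "ym"`); dry-period records are excluded.
#' @param response `"ym"` or `"gei"`.
#' @param grouping `"ecm_level"` (default) or `"day_within_ecm"`.
#' @return Object of class `ch4_opfit`: `coefficients` (named `b0`,
#'   `b_ecm`, `b_conc`), `std_errors`, `p_values`, `sigma_group`,
#'   `sigma_resid`, `vif`, `converged`, `messages`, `n`, `response`, and
#'   the underlying `merMod` as `fit`.
#' @export
fit_operational <- function(records, response = c("ym", "gei"),
                            grouping = c("ecm_level", "day_within_ecm")) {
  response <- match.arg(response)
  grouping <- match.arg(grouping)
  d <- records[records$period == "lactation", ]
  if (!response %in% names(d)) {
    stop("response '", response, "' not present; run attach_ch4_ym() first")
  }
  if (length(unique(d$ecm_annual)) < 3) {
    stop("records must span at least 3 ECM levels")
  }
  if (length(unique(d$day_in_milk)) < 5) {
    stop("records must span at least 5 timepoints")
  }
  d$grp <- if (grouping == "ecm_level") factor(d$ecm_annual)
           else interaction(d$ecm_annual, d$day_in_milk, drop = TRUE)
  if (nlevels(d$grp) < 2) stop("degenerate grouping: a single group")
  d$y <- d[[response]]
  fq <- fit_lmer_quiet(y ~ ecm_annual + conc_share + (1 | grp),
                       d, rep(1, nrow(d)))
  est <- lme4::fixef(fq$fit)
  se <- sqrt(diag(as.matrix(vcov(fq$fit))))
  pv <- 2 * stats::pt(-abs(est / se), df = nrow(d) - length(est))
  vc <- as.data.frame(lme4::VarCorr(fq$fit))
  nm <- c("b0", "b_ecm", "b_conc")
  structure(list(
    coefficients = setNames(as.numeric(est), nm),
    std_errors = setNames(as.numeric(se), nm),
    p_values = setNames(as.numeric(pv), nm),
    sigma_group = vc$sdcor[vc$grp == "grp"],
    sigma_resid = vc$sdcor[vc$grp == "Residual"],
    vif = vif(d, c("ecm_annual", "conc_share")),
    converged = !any(grepl("failed to converge", fq$messages)),
    messages = fq$messages, n = nrow(d), response = response,
    grouping = grouping, fit = fq$fit
  ), class = "ch4_opfit")
}

#' @export
print.ch4_opfit <- function(x, ...) {
  cat(sprintf("Operational %s model (n = %d lactating records, grouping %s)\n",
              x$response, x$n, x$grouping))
  print(data.frame(estimate = x$coefficients, std_error = x$std_errors,
                   p_value = signif(x$p_values, 3)), digits = 4)
  cat(sprintf("sigma_group %.4g  sigma_resid %.4g  VIF %.2f\n",
              x$sigma_group, x$sigma_resid, max(x$vif)))
  invisible(x)
}
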