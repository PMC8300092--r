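#' @importFrom jsonlite write_json
NULL

# Registry of published fixed-coefficient CH4 prediction equations.
# Coefficients are frozen to the printed values; comparator equations whose
# native output is g/day or L/day carry the unit wrapper in `output_scale`
# (g: x 0.05565 MJ/g; L: x 0.716 g/L then x 0.05565).
basic_model_table <- list(
  model1 = list(
    intercept = 4.92, coef_dmi = 1.13, coef_fa = -0.118, coef_ndf = 0,
    coef_ee = 0, coef_dmi2 = 0, output_scale = "MJ",
    requires = c("dmi", "fa"),
    label = "DMI + FA, with intercept (developed)"),
  model2 = list(
    intercept = -3.01, coef_dmi = 1.19, coef_fa = -0.103, coef_ndf = 0.017,
    coef_ee = 0, coef_dmi2 = 0, output_scale = "MJ",
    requires = c("dmi", "fa", "ndf"),
    label = "DMI + FA + NDF, with intercept (developed)"),
  model3 = list(
    intercept = 0, coef_dmi = 1.13, coef_fa = -0.114, coef_ndf = 0.012,
    coef_ee = 0, coef_dmi2 = 0, output_scale = "MJ",
    requires = c("dmi", "fa", "ndf"),
    label = "DMI + FA + NDF, zero intercept (developed, recommended)"),
  nielsen = list(
    intercept = 0, coef_dmi = 1.23, coef_fa = -0.145, coef_ndf = 0.012,
    coef_ee = 0, coef_dmi2 = 0, output_scale = "MJ",
    requires = c("dmi", "fa", "ndf"),
    label = "Nielsen et al. (NorFor) DMI + FA + NDF"),
  storlien = list(
    intercept = 6.80, coef_dmi = 1.09, coef_fa = -0.15, coef_ndf = 0,
    coef_ee = 0, coef_dmi2 = 0, output_scale = "MJ",
    requires = c("dmi", "fa"),
    label = "Storlien et al. DMI + FA"),
  niu_ndf = list(
    # printed as 3.42 x NDF/10 with NDF in g/kg DM; implemented literally
    intercept = 26.0, coef_dmi = 15.3, coef_fa = 0, coef_ndf = 3.42 / 10,
    coef_ee = 0, coef_dmi2 = 0, output_scale = "g",
    requires = c("dmi", "ndf"),
    label = "Niu et al. DMI + NDF (g/day)"),
  ramin = list(
    intercept = 38.0, coef_dmi = 19.22, coef_fa = 0, coef_ndf = 0,
    coef_ee = 0, coef_dmi2 = 0, output_scale = "g",
    requires = "dmi",
    label = "Ramin & Huhtanen DMI only (g/day)"),
  niu_ee = list(
    intercept = 160, coef_dmi = 14.2, coef_fa = 0, coef_ndf = 0,
    coef_ee = -13.5 / 10, coef_dmi2 = 0, output_scale = "g",
    requires = c("dmi", "ee"),
    label = "Niu et al. DMI + EE (g/day)"),
  niu_dmi = list(
    intercept = 107, coef_dmi = 14.5, coef_fa = 0, coef_ndf = 0,
    coef_ee = 0, coef_dmi2 = 0, output_scale = "g",
    requires = "dmi",
    label = "Niu et al. DMI only (g/day)"),
  mills_nonlinear = list(
    intercept = 20, coef_dmi = 35.8, coef_fa = 0, coef_ndf = 0,
    coef_ee = 0, coef_dmi2 = -0.5, output_scale = "L",
    requires = "dmi",
    label = "Mills et al. quadratic in DMI (L/day)")
)

#' Names of the registered basic CH4 prediction models
#'
#' @return Character vector of model ids accepted by [basic_model()] and
#'   [predict_ch4()].
#' @export
basic_model_ids <- function() names(basic_model_table)

#' Retrieve a basic-model specification from the registry
#'
#' The registry holds the ten fixed-coefficient equations predicting daily
#' enteric CH4 production (MJ/day): three developed models on DMI, dietary
#' fatty acids (FA) and NDF, and seven published comparators, including one
#' quadratic in DMI. Coefficients are frozen to their published values;
#' equations published on the g/day or L/day scale are converted to MJ/day
#' via 0.716 g/L and 0.05565 MJ/g at prediction time.
#'
#' @param model_id One of [basic_model_ids()].
#' @return A list with elements `model_id`, `intercept`, `coef_dmi`,
#'   `coef_fa`, `coef_ndf`, `coef_ee`, `coef_dmi2`, `output_scale`
#'   (`"MJ"`, `"g"` or `"L"`), `requires` and `label`.
#' @examples
#' basic_model("model3")$coef_dmi # 1.13
#' @export
basic_model <- function(model_id) {
  if (is.list(model_id) && !is.null(model_id$coef_dmi)) return(model_id)
  if (!is.character(model_id) || length(model_id) != 1 ||
      !model_id %in% names(basic_model_table)) {
    stop("unknown basic model id; see basic_model_ids()")
  }
  c(list(model_id = model_id), basic_model_table[[model_id]])
}

#' Predict daily CH4 production (MJ/day) with a basic model
#'
#' Evaluates the model's printed equation exactly, including the g-to-MJ
#' (x 0.05565) and L-to-g (x 0.716) wrappers for comparator models whose
#' native output is mass or volume. No domain clamping is applied;
#' out-of-range inputs are the caller's concern.
#'
#' @param model Model id (see [basic_model_ids()]) or a spec from
#'   [basic_model()].
#' @param dmi Dry matter intake, kg/day (> 0). Vectorised.
#' @param fa Dietary fatty acids, g/kg DM (required by models containing FA).
#' @param ndf Dietary NDF, g/kg DM.
#' @param ee Dietary ether extract, g/kg DM.
#' @return CH4 production in MJ/day.
#' @examples
#' predict_ch4("model3", dmi = 20, fa = 30, ndf = 350) # 23.38
#' @export
predict_ch4 <- function(model, dmi, fa = NULL, ndf = NULL, ee = NULL) {
  m <- basic_model(model)
  if (any(!is.finite(dmi)) || any(dmi < 0)) {
    stop("predict_ch4(): dmi must be finite and non-negative")
  }
  supplied <- list(dmi = dmi, fa = fa, ndf = ndf, ee = ee)
  for (p in m$requires) {
    if (is.null(supplied[[p]]) || any(is.na(supplied[[p]]))) {
      stop("model '", m$model_id %||% "?", "' requires predictor '", p, "'")
    }
  }
  z <- function(x) if (is.null(x)) 0 else x
  native <- m$intercept + m$coef_dmi * dmi + m$coef_dmi2 * dmi^2 +
    m$coef_fa * z(fa) + m$coef_ndf * z(ndf) + m$coef_ee * z(ee)
  switch(m$output_scale,
    MJ = native,
    g  = native * ch4_units$gram_to_mj,
    L  = native * ch4_units$litre_to_gram * ch4_units$gram_to_mj,
    stop("unknown output_scale: ", m$output_scale)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict CH4 for every record of a trial table
#'
#' Order-preserving wrapper around [predict_ch4()] returning paired
#' observed/predicted vectors ready for [evaluate_predictions()].
#'
#' @param model Model id or spec.
#' @param records Validated trial-record data frame.
#' @return Data frame with columns `observed` and `predicted` (MJ/day),
#'   one row per input record.
#' @export
predict_table <- function(model, records) {
  m <- basic_model(model)
  if (nrow(records) == 0) {
    return(data.frame(observed = numeric(0), predicted = numeric(0)))
  }
  pred <- vapply(seq_len(nrow(records)), function(i) {
    tryCatch(
      predict_ch4(m,
        dmi = records$dmi[i],
        fa  = if (!is.na(records$fa[i])) records$fa[i],
        ndf = records$ndf[i],
        ee  = if (!is.na(records$ee[i])) records$ee[i]),
      error = function(e) stop("record ", i, ": ", conditionMessage(e))
    )
  }, numeric(1))
  data.frame(observed = records$ch4_mj, predicted = pred)
}

#' Dump the basic-model registry as a machine-readable table
#'
#' @param path Optional path; when given, the registry is written there as
#'   JSON for audit.
#' @return Data frame with one row per model and the printed coefficients.
#' @export
basic_model_registry <- function(path = NULL) {
  reg <- do.call(rbind, lapply(names(basic_model_table), function(id) {
    m <- basic_model_table[[id]]
    data.frame(model_id = id, intercept = m$intercept, coef_dmi = m$coef_dmi,
               coef_fa = m$coef_fa, coef_ndf = m$coef_ndf, coef_ee = m$coef_ee,
               coef_dmi2 = m$coef_dmi2, output_scale = m$output_scale,
               requires = paste(m$requires, collapse = "+"), label = m$label)
  }))
  if (!is.null(path)) {
    jsonlite::write_json(reg, path, digits = NA, pretty = TRUE)
  }
  reg
}
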