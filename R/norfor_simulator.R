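#' Load the silage and concentrate composition table
#'
#' Chemical composition (per kg DM) of the three silage qualities (codes
#' 1-3; NEL 7.0, 6.1, 5.7 MJ/kg DM) and three complementary concentrate
#' mixtures (codes I-III; NEL 8.0, 7.7, 7.5) used by the operational
#' feeding simulator. Gross energy (GE, MJ/kg DM) is computed from the
#' composition as
#' `0.0242 CP + 0.0366 crude fat + 0.0170 (1000 - ash - CP - crude fat)`
#' (g/kg DM) and is later rescaled by a single calibration factor anchored
#' to the published mean GEI (see [build_operational_database()]).
#'
#' @param path Optional CSV path; defaults to the packaged table.
#' @return Data frame with one row per feed, including `ge_raw`.
#' @export
load_feed_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "norfor_feeds.csv", package = "metanor")
  }
  if (!nzchar(path) || !file.exists(path)) stop("feed table not found: ", path)
  feeds <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(code = "character"))
  needed <- c("type", "code", "ash", "crude_protein", "crude_fat", "ndf",
              "nel")
  miss <- setdiff(needed, names(feeds))
  if (length(miss)) stop("feed table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(feeds$nel <= 0)) stop("feed NEL must be positive")
  comp_sum <- feeds$ash + feeds$crude_protein + feeds$crude_fat + feeds$ndf
  if (any(comp_sum > 1000)) stop("feed component sums exceed 1000 g/kg DM")
  feeds$ge_raw <- 0.0242 * feeds$crude_protein + 0.0366 * feeds$crude_fat +
    0.0170 * (1000 - feeds$ash - feeds$crude_protein - feeds$crude_fat)
  feeds
}

get_feed <- function(feeds, type, code) {
  i <- which(feeds$type == type & feeds$code == as.character(code))
  if (length(i) != 1) stop("unknown ", type, " code: ", code)
  feeds[i, ]
}

#' Default energy and simulation parameters for the feeding simulator
#'
#' All constants are exposed so they can be recalibrated: maintenance NEL
#' is `maint_coef x bw^0.75 x activity_factor` (defaults 0.33 MJ/kg^0.75,
#' 600 kg, 1.125 -> 45.0 MJ/day), lactation adds `nel_per_kg_ecm` (3.45 MJ
#' NEL per kg ECM; both calibrated once against the published grid's
#' energy balance), silage intake is capped at a fixed fill capacity
#' (`silage_dmi_cap`, kg DM/day) with concentrate filling the remaining
#' energy gap up to `conc_share_cap` % of total DM. Dietary fatty acids
#' for the basic model are taken as `fa_of_crude_fat` x dietary crude fat.
#' The lactation curve is a Wood gamma with shape `wood_b`, decay `wood_c`
#' (peak at day b/c = 62.5). The GE scale is anchored so the mean
#' simulated lactation GEI at `gei_anchor$ecm` kg ECM on silage
#' `gei_anchor$silage` equals `gei_anchor$gei` MJ/day.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
norfor_params <- function(...) {
  p <- list(
    bw = 600, maint_coef = 0.33, activity_factor = 1.125,
    nel_per_kg_ecm = 3.45,
    silage_dmi_cap = 14, conc_share_cap = 65,
    fa_of_crude_fat = 0.80,
    wood_b = 0.25, wood_c = 0.004,
    lactation_days = 305L, dry_days = 60L,
    weeks = seq(2L, 44L, by = 2L),
    gei_anchor = list(ecm = 6000, silage = "1", gei = 300)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Daily energy-corrected milk yield over a standardized lactation
#'
#' Wood gamma curve `y(t) = a t^b exp(-c t)` with the scale `a` chosen so
#' the day-1..305 sum equals the annual (305-day) ECM; the curve therefore
#' scales linearly in `ecm_annual` and its sum reproduces it exactly.
#'
#' @param ecm_annual 305-day lactation ECM, kg (> 0).
#' @param day_in_milk Day(s) in 1..305.
#' @param params [norfor_params()] list (uses `wood_b`, `wood_c`).
#' @return Daily ECM, kg/day.
#' @export
lactation_curve <- function(ecm_annual, day_in_milk, params = norfor_params()) {
  if (ecm_annual <= 0) stop("ecm_annual must be positive")
  if (any(day_in_milk < 1 | day_in_milk > params$lactation_days)) {
    stop("day_in_milk outside lactation (1..", params$lactation_days, ")")
  }
  shape <- function(t) t^params$wood_b * exp(-params$wood_c * t)
  a <- ecm_annual / sum(shape(seq_len(params$lactation_days)))
  a * shape(day_in_milk)
}

#' NEL requirement of a cow at a given milk yield
#'
#' @param daily_ecm Daily ECM, kg/day (0 for a dry cow).
#' @param params [norfor_params()] list.
#' @return Requirement, MJ NEL/day.
#' @export
energy_requirement <- function(daily_ecm, params = norfor_params()) {
  stopifnot(daily_ecm >= 0)
  params$maint_coef * params$bw^0.75 * params$activity_factor +
    params$nel_per_kg_ecm * daily_ecm
}

#' Formulate a silage + concentrate ration meeting the NEL requirement
#'
#' Silage is fed up to the fill capacity; when its NEL does not cover the
#' requirement, concentrate supplies the gap. The concentrate share of DM
#' is capped (default 65%); rations that cannot meet the requirement under
#' the cap are returned flagged (`feasible = FALSE`), not as an error.
#' For feasible rations the NEL supply matches the requirement exactly
#' (well within 0.1 MJ).
#'
#' @param daily_ecm Daily ECM, kg/day (0 = dry cow, silage only).
#' @param silage Feed row (from [load_feed_table()]) for the silage.
#' @param concentrate Feed row for the concentrate, or `NULL` for a
#'   silage-only ration.
#' @param params [norfor_params()] list.
#' @return List: `conc_share` (% of DM), `silage_dmi`, `conc_dmi`, `dmi`
#'   (kg/day), `nel_requirement`, `nel_supply` (MJ/day), `gei_raw`
#'   (MJ/day, uncalibrated GE scale), `feasible`.
#' @export
formulate_ration <- function(daily_ecm, silage, concentrate = NULL,
                             params = norfor_params()) {
  req <- energy_requirement(daily_ecm, params)
  cap <- params$silage_dmi_cap
  if (req <= cap * silage$nel) {
    s_dmi <- req / silage$nel
    c_dmi <- 0
    feasible <- TRUE
  } else if (is.null(concentrate)) {
    s_dmi <- cap
    c_dmi <- 0
    feasible <- FALSE
  } else {
    s_dmi <- cap
    c_dmi <- (req - cap * silage$nel) / concentrate$nel
    share <- 100 * c_dmi / (s_dmi + c_dmi)
    if (share > params$conc_share_cap) {
      # cap the share; the requirement is then not met
      c_dmi <- s_dmi * params$conc_share_cap / (100 - params$conc_share_cap)
      feasible <- FALSE
    } else {
      feasible <- TRUE
    }
  }
  dmi <- s_dmi + c_dmi
  supply <- s_dmi * silage$nel + c_dmi *
    (if (is.null(concentrate)) 0 else concentrate$nel)
  gei_raw <- s_dmi * silage$ge_raw + c_dmi *
    (if (is.null(concentrate)) 0 else concentrate$ge_raw)
  list(conc_share = 100 * c_dmi / dmi, silage_dmi = s_dmi, conc_dmi = c_dmi,
       dmi = dmi, nel_requirement = req, nel_supply = supply,
       gei_raw = gei_raw, feasible = feasible)
}

#' Default configuration of the operational simulation grid
#'
#' Fifteen annual-ECM levels (5000 to 12000 kg in 500-kg steps), each
#' paired with the three silage qualities and the published
#' silage-concentrate pairings, simulated at every second lactation week
#' (22 timepoints) plus a 60-day dry period on silage alone.
#'
#' @param params [norfor_params()] list.
#' @param feeds Feed table from [load_feed_table()].
#' @param pairings Data frame `ecm, silage, concentrate`; defaults to the
#'   packaged reference pairings.
#' @return List of class `norfor_config`.
#' @export
norfor_config <- function(params = norfor_params(),
                          feeds = load_feed_table(),
                          pairings = NULL) {
  if (is.null(pairings)) {
    ref <- utils::read.csv(
      system.file("extdata", "norfor_reference_grid.csv",
                  package = "metanor"),
      colClasses = c(silage = "character", concentrate = "character"))
    pairings <- ref[c("ecm", "silage", "concentrate")]
  }
  for (i in seq_len(nrow(pairings))) {
    get_feed(feeds, "silage", pairings$silage[i])
    get_feed(feeds, "concentrate", pairings$concentrate[i])
  }
  structure(list(params = params, feeds = feeds, pairings = pairings),
            class = "norfor_config")
}

#' Published reference grid for the operational database
#'
#' Mean and min-max concentrate share, DMI and GEI per ECM level and
#' silage series over a 305-day lactation, as published; used to anchor
#' and sanity-check the simulator.
#'
#' @return Data frame with one row per ECM level x silage.
#' @export
load_reference_grid <- function() {
  utils::read.csv(
    system.file("extdata", "norfor_reference_grid.csv", package = "metanor"),
    colClasses = c(silage = "character", concentrate = "character"))
}

#' Build the simulated operational feeding database
#'
#' For every ECM level x silage pairing, simulates rations at lactation
#' weeks 2, 4, ..., 44 (day in milk 7w - 3, i.e. days 11..305) and one
#' aggregated 60-day dry period on silage alone. Feed GE is calibrated by
#' a single multiplicative factor so the mean lactation GEI of the anchor
#' series (6000 kg ECM, silage 1 by default) matches the published 300
#' MJ/day exactly; since DMI depends only on NEL, the calibration is
#' linear and deterministic. The whole database is deterministic given the
#' config.
#'
#' @param config A [norfor_config()].
#' @return Data frame of operational records: `ecm_annual`, `silage_code`,
#'   `conc_code`, `period` ("lactation"/"dry"), `week`, `day_in_milk`,
#'   `days_weight` (days represented by the record), `daily_ecm`,
#'   `conc_share` (% of DM), `silage_dmi`, `conc_dmi`, `dmi` (kg/day),
#'   `nel_requirement`, `nel_supply`, `gei` (MJ/day), `feasible`, and the
#'   DMI-weighted diet composition `diet_fa`, `diet_ee`, `diet_ndf`
#'   (g/kg DM). The GE calibration factor is attached as attribute
#'   `ge_scale`.
#' @export
build_operational_database <- function(config = norfor_config()) {
  stopifnot(inherits(config, "norfor_config"))
  p <- config$params
  days <- 7L * p$weeks - 3L
  if (any(days > p$lactation_days)) stop("week grid exceeds lactation length")

  rows <- vector("list", nrow(config$pairings) * (length(days) + 1L))
  k <- 0L
  for (i in seq_len(nrow(config$pairings))) {
    ecm <- config$pairings$ecm[i]
    sil <- get_feed(config$feeds, "silage", config$pairings$silage[i])
    con <- get_feed(config$feeds, "concentrate",
                    config$pairings$concentrate[i])
    one <- function(day, week, daily_ecm, period, days_weight, conc) {
      r <- formulate_ration(daily_ecm, sil, conc, p)
      w_s <- r$silage_dmi / r$dmi
      w_c <- r$conc_dmi / r$dmi
      fat <- w_s * sil$crude_fat + w_c *
        (if (is.null(conc)) 0 else conc$crude_fat)
      data.frame(
        ecm_annual = ecm, silage_code = sil$code,
        conc_code = if (is.null(conc)) NA_character_ else conc$code,
        period = period, week = week, day_in_milk = day,
        days_weight = days_weight, daily_ecm = daily_ecm,
        conc_share = r$conc_share, silage_dmi = r$silage_dmi,
        conc_dmi = r$conc_dmi, dmi = r$dmi,
        nel_requirement = r$nel_requirement, nel_supply = r$nel_supply,
        gei = r$gei_raw, feasible = r$feasible,
        diet_fa = p$fa_of_crude_fat * fat, diet_ee = fat,
        diet_ndf = w_s * sil$ndf + w_c *
          (if (is.null(conc)) 0 else conc$ndf))
    }
    for (d in seq_along(days)) {
      k <- k + 1L
      rows[[k]] <- one(days[d], p$weeks[d],
                       lactation_curve(ecm, days[d], p), "lactation",
                       p$lactation_days / length(days), con)
    }
    k <- k + 1L
    rows[[k]] <- one(NA_integer_, NA_integer_, 0, "dry", p$dry_days, NULL)
  }
  db <- do.call(rbind, rows)

  # exact GE calibration against the anchor row of the published grid
  a <- p$gei_anchor
  anchor <- db$period == "lactation" & db$ecm_annual == a$ecm &
    db$silage_code == as.character(a$silage)
  if (!any(anchor)) stop("GE anchor series not present in the grid")
  ge_scale <- a$gei / mean(db$gei[anchor])
  db$gei <- db$gei * ge_scale
  attr(db, "ge_scale") <- ge_scale
  db
}

#' Attach basic-model CH4 predictions and Ym to operational records
#'
#' Predicts daily CH4 production (MJ/day) from each record's DMI and
#' DMI-weighted diet composition with the chosen basic model, and derives
#' the methane conversion factor `ym = 100 x ch4_pred / gei` (% of GEI).
#'
#' @param records Operational database from [build_operational_database()].
#' @param model Basic-model id or spec (default `"model3"`).
#' @return `records` with `ch4_pred` (MJ/day) and `ym` (%) columns added.
#' @export
attach_ch4_ym <- function(records, model = "model3") {
  if (any(!is.finite(records$gei)) || any(records$gei <= 0)) {
    stop("gei must be positive for every record")
  }
  records$ch4_pred <- predict_ch4(model, dmi = records$dmi,
                                  fa = records$diet_fa,
                                  ndf = records$diet_ndf,
                                  ee = records$diet_ee)
  records$ym <- 100 * records$ch4_pred / records$gei
  records
}
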