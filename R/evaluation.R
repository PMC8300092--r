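#' Mean squared prediction error decomposition and concordance
#'
#' Computes the model-performance statistics used to compare CH4 prediction
#' equations: MSPE and its exact decomposition into error in central
#' tendency (mean bias), error due to regression (slope bias) and error due
#' to disturbance (random scatter); RMSPE as a percentage of the observed
#' mean; and Lin's concordance correlation coefficient
#' CCC = r x Cb with Cb = 2 / (v + 1/v + mu^2), v = So/Sp,
#' mu = (Pbar - Obar) / sqrt(So Sp).
#'
#' All moments use the population (divide-by-n) convention: only then does
#' ECT + ED + ER reproduce the MSPE identically, and CCC equals the usual
#' 2 s_op / (So^2 + Sp^2 + (Pbar - Obar)^2).
#'
#' @param observed,predicted Equal-length numeric vectors (MJ/day),
#'   length >= 3, finite; `observed` must not be constant (its SD enters
#'   denominators), nor `predicted` (Pearson r undefined).
#' @return Object of class `ch4_eval`: a list with `n`, `mspe`,
#'   `rmspe_pct`, `ect`, `ed`, `er` (and `ect_pct`, `ed_pct`, `er_pct`, as
#'   % of MSPE; `NA` when MSPE is 0), `ccc`, `r`, `cb`, `v`, `mu`,
#'   `obs_mean`, `pred_mean`, `so`, `sp`.
#' @examples
#' ev <- evaluate_predictions(c(20, 25, 30), c(22, 24, 31))
#' round(ev$ccc, 4) # 0.9375
#' @export
evaluate_predictions <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  n <- length(observed)
  if (n < 3) stop("at least 3 paired values are required")
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("observed and predicted must be finite")
  }
  obar <- mean(observed)
  pbar <- mean(predicted)
  so2 <- mean((observed - obar)^2)
  sp2 <- mean((predicted - pbar)^2)
  if (so2 == 0) stop("observed vector is constant; statistics undefined")
  if (sp2 == 0) stop("predicted vector is constant; correlation undefined")
  so <- sqrt(so2); sp <- sqrt(sp2)
  cov_op <- mean((observed - obar) * (predicted - pbar))
  r <- cov_op / (so * sp)

  mspe <- mean((observed - predicted)^2)
  ect <- (pbar - obar)^2
  ed  <- (1 - r^2) * so2
  er  <- (sp - r * so)^2

  v  <- so / sp
  mu <- (pbar - obar) / sqrt(so * sp)
  cb <- 2 / (v + 1 / v + mu^2)

  pct <- function(x) if (mspe > 0) 100 * x / mspe else NA_real_
  structure(list(
    n = n, mspe = mspe, rmspe_pct = 100 * sqrt(mspe) / obar,
    ect = ect, ed = ed, er = er,
    ect_pct = pct(ect), ed_pct = pct(ed), er_pct = pct(er),
    ccc = r * cb, r = r, cb = cb, v = v, mu = mu,
    obs_mean = obar, pred_mean = pbar, so = so, sp = sp
  ), class = "ch4_eval")
}

#' @export
print.ch4_eval <- function(x, ...) {
  cat(sprintf("CH4 prediction evaluation (n = %d)\n", x$n))
  cat(sprintf("  MSPE %.4f (MJ/day)^2   RMSPE %.1f%% of observed mean\n",
              x$mspe, x$rmspe_pct))
  if (!is.na(x$ect_pct)) {
    cat(sprintf("  ECT %.1f%%  ER %.1f%%  ED %.1f%% of MSPE\n",
                x$ect_pct, x$er_pct, x$ed_pct))
  }
  cat(sprintf("  CCC %.3f  (r %.3f x Cb %.3f)\n", x$ccc, x$r, x$cb))
  invisible(x)
}

#' Evaluate and rank basic models on a trial table
#'
#' Predicts CH4 for every model on the given records and orders the
#' resulting evaluation table by decreasing concordance correlation
#' coefficient, ties broken by lower RMSPE%. Models whose required
#' predictors are unavailable in the data are skipped with a warning.
#'
#' @param models Character vector of model ids (or list of specs); default
#'   all registered models.
#' @param records Validated trial-record data frame.
#' @return Data frame with one row per evaluable model: `model_id`, `n`,
#'   `rmspe_pct`, `ect_pct`, `ed_pct`, `er_pct`, `ccc`, `r`, `cb`.
#' @export
rank_models <- function(models = basic_model_ids(), records) {
  rows <- list()
  for (mid in models) {
    m <- basic_model(mid)
    res <- tryCatch({
      op <- predict_table(m, records)
      ev <- evaluate_predictions(op$observed, op$predicted)
      data.frame(model_id = m$model_id %||% "<anonymous>", n = ev$n,
                 rmspe_pct = ev$rmspe_pct, ect_pct = ev$ect_pct,
                 ed_pct = ev$ed_pct, er_pct = ev$er_pct,
                 ccc = ev$ccc, r = ev$r, cb = ev$cb)
    }, error = function(e) {
      warning("model '", if (is.character(mid)) mid else "<spec>",
              "' skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) {
    return(data.frame(model_id = character(0), n = integer(0),
                      rmspe_pct = numeric(0), ect_pct = numeric(0),
                      ed_pct = numeric(0), er_pct = numeric(0),
                      ccc = numeric(0), r = numeric(0), cb = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$ccc, out$rmspe_pct), ]
  rownames(out) <- NULL
  out
}
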