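test_that("noiseless data are interpolated exactly", {
  db <- generate_trial_database(trial_gen_config(
    n_studies = 8, n_records = 32, sigma_study = 0, sigma_resid = 0,
    seed = 11))
  fit <- fit_basic_model(db$records, c("dmi", "fa", "ndf"),
                         include_intercept = FALSE)
  expect_equal(unname(fit$coefficients[c("dmi", "fa", "ndf")]),
               c(1.13, -0.114, 0.012), tolerance = 1e-8)
  expect_gte(fit$sigma_study, 0)
})

test_that("coefficients are invariant to rescaling the weights", {
  db <- generate_trial_database(trial_gen_config(seed = 21))
  f1 <- fit_basic_model(db$records, c("dmi", "fa", "ndf"),
                        include_intercept = FALSE, weights = "n_obs")
  rec10 <- db$records
  rec10$n_obs <- rec10$n_obs * 10L
  f2 <- fit_basic_model(rec10, c("dmi", "fa", "ndf"),
                        include_intercept = FALSE, weights = "n_obs")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("with no study variance and uniform weights the fit matches OLS", {
  db <- generate_trial_database(trial_gen_config(
    n_studies = 10, n_records = 50, sigma_study = 0, sigma_resid = 0.8,
    seed = 31))
  fit <- fit_basic_model(db$records, c("dmi", "fa", "ndf"),
                         include_intercept = TRUE, weights = "uniform")
  ols <- lm(ch4_mj ~ dmi + fa + ndf, data = db$records)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-4)
})

test_that("seeded parameter recovery lands within three standard errors", {
  db <- generate_trial_database(trial_gen_config(
    n_studies = 19, n_records = 63, sigma_study = 1.5, sigma_resid = 1.0,
    seed = 42))
  fit <- fit_basic_model(db$records, c("dmi", "fa", "ndf"),
                         include_intercept = FALSE, weights = "n_obs")
  truth <- c(dmi = 1.13, fa = -0.114, ndf = 0.012)
  for (p in names(truth)) {
    expect_lt(abs(fit$coefficients[[p]] - truth[[p]]),
              3 * fit$std_errors[[p]])
  }
  expect_gt(fit$sigma_study, 0)
  expect_gt(fit$sigma_resid, 0)
})

test_that("preconditions are enforced", {
  db <- generate_trial_database(trial_gen_config(seed = 5))
  one_study <- db$records[db$records$study_id == db$records$study_id[1], ]
  expect_error(fit_basic_model(one_study), "2 distinct studies")
  rec <- db$records
  rec$fa[3] <- NA
  expect_error(fit_basic_model(rec, c("dmi", "fa")), "missing values.*fa")
  rec <- db$records
  rec$ee <- 2 * rec$fa # exactly collinear with fa
  expect_error(fit_basic_model(rec, c("dmi", "fa", "ee")),
               "rank-deficient")
  expect_error(fit_basic_model(db$records[1:3, ], c("dmi", "fa", "ndf")))
})

test_that("VIF matches its closed form", {
  # exactly orthogonal predictors
  d <- data.frame(x1 = c(-1, -1, 1, 1), x2 = c(-1, 1, -1, 1))
  expect_equal(unname(vif(d, c("x1", "x2"))), c(1, 1), tolerance = 1e-12)

  # a pair with sample correlation 0.9 -> VIF = 1 / (1 - 0.81)
  set.seed(9)
  n <- 60
  x <- rnorm(n); z <- residuals(lm(rnorm(n) ~ x))
  xs <- (x - mean(x)) / sd(x); zs <- (z - mean(z)) / sd(z)
  y <- 0.9 * xs + sqrt(1 - 0.81) * zs
  d <- data.frame(x = xs, y = y)
  expect_equal(cor(d$x, d$y), 0.9, tolerance = 1e-10)
  expect_equal(unname(vif(d, c("x", "y"))), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-8)

  # duplicated predictor flagged infinite, not an exception (the perfect
  # auxiliary fit makes lm's summary warn; that warning is the point here)
  d$w <- d$x
  expect_equal(suppressWarnings(unname(vif(d, c("x", "w")))), c(Inf, Inf))
})

test_that("technique screening detects an offset and passes a null", {
  n_rep <- 30
  null_p <- effect_p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    db0 <- generate_trial_database(trial_gen_config(seed = 1000 + i))
    null_p[i] <- screen_technique_effect(db0$records)$p_value
    db1 <- generate_trial_database(trial_gen_config(
      technique_effects = c(tracer = 0, chamber = 5, headhood = 0,
                            greenfeed = 0),
      seed = 2000 + i))
    effect_p[i] <- screen_technique_effect(db1$records)$p_value
  }
  expect_gte(mean(null_p > 0.1), 0.8)
  expect_gte(mean(effect_p < 0.05), 0.8)

  one_level <- generate_trial_database(trial_gen_config(
    technique_probs = c(tracer = 1, chamber = 0, headhood = 0,
                        greenfeed = 0), seed = 3))$records
  expect_error(screen_technique_effect(one_level), "2 technique levels")
})

test_that("validate_final_model flags non-significant predictors", {
  db <- generate_trial_database(trial_gen_config(seed = 77))
  fit <- fit_basic_model(db$records, c("dmi", "fa", "ndf"),
                         include_intercept = FALSE)
  chk <- validate_final_model(fit)
  expect_true(chk$valid) # strong signal at this noise level
  # a pure-noise predictor should fail the p < 0.05 rule
  rec <- db$records
  set.seed(1)
  rec$ee <- runif(nrow(rec), 20, 60)
  fit2 <- fit_basic_model(rec, c("dmi", "fa", "ndf", "ee"),
                          include_intercept = FALSE)
  chk2 <- validate_final_model(fit2)
  expect_true("ee" %in% chk2$failing)
})
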