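# Probe points are hand evaluations of the printed coefficient sets,
# computed independently of predict_ch4()'s evaluation path.

test_that("every registry model reproduces hand-computed probe outputs", {
  g <- 0.05565; l <- 0.716
  probes <- list(
    # model, dmi, fa, ndf, ee, expected (exact arithmetic)
    list("model1", 20, 30, NA, NA, 4.92 + 1.13 * 20 - 0.118 * 30),
    list("model1", 12, 45, NA, NA, 4.92 + 1.13 * 12 - 0.118 * 45),
    list("model2", 20, 30, 350, NA, -3.01 + 1.19 * 20 - 0.103 * 30 + 0.017 * 350),
    list("model2", 15, 22, 480, NA, -3.01 + 1.19 * 15 - 0.103 * 22 + 0.017 * 480),
    list("model3", 20, 30, 350, NA, 23.38),
    list("model3", 10, 55, 520, NA, 1.13 * 10 - 0.114 * 55 + 0.012 * 520),
    list("nielsen", 20, 30, 350, NA, 1.23 * 20 - 0.145 * 30 + 0.012 * 350),
    list("storlien", 20, 30, NA, NA, 6.80 + 1.09 * 20 - 0.15 * 30),
    list("niu_ndf", 20, NA, 350, NA, (26.0 + 15.3 * 20 + 3.42 * 350 / 10) * g),
    list("ramin", 20, NA, NA, NA, 23.50656),
    list("ramin", 8, NA, NA, NA, (38.0 + 19.22 * 8) * g),
    list("niu_ee", 20, NA, NA, 40, (160 + 14.2 * 20 - 13.5 * 40 / 10) * g),
    list("niu_dmi", 20, NA, NA, NA, (107 + 14.5 * 20) * g),
    list("mills_nonlinear", 10, NA, NA, NA, 13.0692912),
    list("mills_nonlinear", 26, NA, NA, NA, (20 + 35.8 * 26 - 0.5 * 26^2) * l * g)
  )
  for (p in probes) {
    got <- predict_ch4(p[[1]], dmi = p[[2]],
                       fa = if (!is.na(p[[3]])) p[[3]],
                       ndf = if (!is.na(p[[4]])) p[[4]],
                       ee = if (!is.na(p[[5]])) p[[5]])
    expect_equal(got, p[[6]], tolerance = 1e-9,
                 label = sprintf("%s probe", p[[1]]))
  }
})

test_that("the zero-intercept model passes through the origin and is linear in DMI", {
  expect_identical(predict_ch4("model3", 0, 0, 0), 0)
  # doubling DMI with FA, NDF fixed raises the output by exactly 1.13 * dmi
  for (dmi in c(8, 15, 26)) {
    expect_equal(predict_ch4("model3", 2 * dmi, 30, 400) -
                   predict_ch4("model3", dmi, 30, 400),
                 1.13 * dmi, tolerance = 1e-12)
  }
})

test_that("predictions respond to diet in the expected directions", {
  dmi <- seq(8, 26, length.out = 10)
  fa <- 30; ndf <- 400; ee <- 38; h <- 1e-6
  for (id in basic_model_ids()) {
    m <- basic_model(id)
    args0 <- list(m, dmi = dmi, fa = fa, ndf = ndf, ee = ee)
    f0 <- do.call(predict_ch4, args0)
    expect_true(all(f0 > 0), label = paste(id, "positive on admissible range"))
    d_dmi <- (do.call(predict_ch4, modifyList(args0, list(dmi = dmi + h))) - f0) / h
    expect_true(all(d_dmi > 0), label = paste(id, "dCH4/dDMI > 0"))
    if ("fa" %in% m$requires) {
      d_fa <- (do.call(predict_ch4, modifyList(args0, list(fa = fa + h))) - f0) / h
      expect_true(all(d_fa < 0), label = paste(id, "dCH4/dFA < 0"))
    }
    if ("ndf" %in% m$requires) {
      d_ndf <- (do.call(predict_ch4, modifyList(args0, list(ndf = ndf + h))) - f0) / h
      expect_true(all(d_ndf > 0), label = paste(id, "dCH4/dNDF > 0"))
    }
  }
})

test_that("missing required predictors raise a named error", {
  expect_error(predict_ch4("model3", dmi = 20, ndf = 350), "'fa'")
  expect_error(predict_ch4("niu_ee", dmi = 20), "'ee'")
  expect_error(basic_model("no_such_model"), "unknown basic model")
})

test_that("predict_table is pointwise-consistent and order-preserving", {
  tab <- tiny_trial_table()
  op <- predict_table("storlien", tab)
  expect_equal(nrow(op), nrow(tab))
  expect_equal(op$observed, tab$ch4_mj)
  for (i in seq_len(nrow(tab))) {
    expect_equal(op$predicted[i],
                 predict_ch4("storlien", tab$dmi[i], fa = tab$fa[i]))
  }
  empty <- predict_table("model3", tab[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("model2 and model3 predictions differ by the printed coefficient gap", {
  db <- read_trial_table(packaged_fixture_path())
  p2 <- predict_table("model2", db)$predicted
  p3 <- predict_table("model3", db)$predicted
  gap <- -3.01 + 0.06 * db$dmi + 0.011 * db$fa + 0.005 * db$ndf
  expect_equal(p2 - p3, gap, tolerance = 1e-10)
})

test_that("the registry dump lists all ten printed coefficient sets", {
  reg <- basic_model_registry()
  expect_equal(nrow(reg), 10)
  expect_setequal(reg$model_id, basic_model_ids())
  path <- withr::local_tempfile(fileext = ".json")
  basic_model_registry(path)
  audit <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(audit$coef_dmi[audit$model_id == "model3"], 1.13)
})
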