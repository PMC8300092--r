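feeds <- load_feed_table()
params <- norfor_params()

test_that("feed table carries the published compositions and a GE above NEL", {
  expect_equal(nrow(feeds), 6)
  sil2 <- feeds[feeds$type == "silage" & feeds$code == "2", ]
  expect_equal(sil2$nel, 6.1)
  expect_equal(sil2$ndf, 511)
  expect_true(all(feeds$ge_raw > feeds$nel))
  expect_true(all(feeds$ash + feeds$crude_protein + feeds$crude_fat +
                    feeds$ndf <= 1000))
})

test_that("the lactation curve integrates to the annual yield and scales linearly", {
  days <- 1:305
  for (ecm in c(5000, 6000, 12000)) {
    y <- lactation_curve(ecm, days)
    expect_true(all(y >= 0))
    expect_lt(abs(sum(y) - ecm) / ecm, 0.001)
    peak <- days[which.max(y)]
    expect_gte(peak, 30); expect_lte(peak, 90)
  }
  expect_equal(lactation_curve(12000, days), 2 * lactation_curve(6000, days),
               tolerance = 1e-12)
  expect_error(lactation_curve(6000, 0), "outside lactation")
  expect_error(lactation_curve(6000, 306), "outside lactation")
  expect_error(lactation_curve(0, 10), "positive")
})

test_that("ration formulation meets the energy requirement", {
  sil <- feeds[feeds$type == "silage" & feeds$code == "2", ]
  con <- feeds[feeds$type == "concentrate" & feeds$code == "II", ]
  # dry cow: silage only at exactly maintenance
  dry <- formulate_ration(0, sil, con, params)
  expect_equal(dry$conc_share, 0)
  expect_equal(dry$nel_supply, energy_requirement(0, params),
               tolerance = 1e-10)
  # solver contract over a yield sweep
  for (ecm_d in c(5, 15, 25, 40)) {
    r <- formulate_ration(ecm_d, sil, con, params)
    expect_true(r$feasible)
    expect_lt(abs(r$nel_supply - r$nel_requirement), 0.1)
    expect_equal(r$conc_share, 100 * r$conc_dmi / r$dmi, tolerance = 1e-12)
    expect_true(r$conc_share >= 0 && r$conc_share <= params$conc_share_cap)
  }
})

test_that("better silage needs less concentrate at the same yield", {
  s1 <- feeds[feeds$type == "silage" & feeds$code == "1", ]
  s3 <- feeds[feeds$type == "silage" & feeds$code == "3", ]
  con <- feeds[feeds$type == "concentrate" & feeds$code == "II", ]
  for (ecm_d in c(20, 30, 40)) {
    r1 <- formulate_ration(ecm_d, s1, con, params)
    r3 <- formulate_ration(ecm_d, s3, con, params)
    expect_lt(r1$conc_share, r3$conc_share)
  }
})

test_that("an unattainable requirement is flagged, not thrown", {
  sil <- feeds[feeds$type == "silage" & feeds$code == "3", ]
  con <- feeds[feeds$type == "concentrate" & feeds$code == "III", ]
  r <- formulate_ration(80, sil, con, params) # absurd yield
  expect_false(r$feasible)
  expect_equal(r$conc_share, params$conc_share_cap, tolerance = 1e-10)
  expect_lt(r$nel_supply, r$nel_requirement)
  # silage-only ration that cannot cover the requirement
  r2 <- formulate_ration(30, sil, NULL, params)
  expect_false(r2$feasible)
})

test_that("the default operational grid has the expected shape and is deterministic", {
  db1 <- build_operational_database()
  db2 <- build_operational_database()
  expect_identical(db1, db2)
  lact <- db1[db1$period == "lactation", ]
  expect_equal(nrow(lact), 15 * 3 * 22)
  expect_equal(sum(db1$period == "dry"), 45)
  expect_true(all(db1$gei > 0))
  expect_true(all(abs(db1$nel_supply[db1$feasible] -
                        db1$nel_requirement[db1$feasible]) < 0.1))
  expect_true(all(db1$period != "dry" | db1$conc_share == 0))
  # GE anchor reproduced exactly
  a <- norfor_params()$gei_anchor
  anchor <- lact$ecm_annual == a$ecm & lact$silage_code == a$silage
  expect_equal(mean(lact$gei[anchor]), a$gei, tolerance = 1e-10)
  expect_error(norfor_config(pairings = data.frame(
    ecm = 6000, silage = "9", concentrate = "I")), "unknown silage")
})

test_that("diet composition is the DMI-weighted mean of the feeds", {
  # 50:50 silage 2 and concentrate II -> NDF (511 + 208) / 2
  sil <- feeds[feeds$type == "silage" & feeds$code == "2", ]
  con <- feeds[feeds$type == "concentrate" & feeds$code == "II", ]
  expect_equal(0.5 * sil$ndf + 0.5 * con$ndf, 359.5)
  db <- build_operational_database()
  i <- which(db$period == "lactation")[1]
  w_s <- db$silage_dmi[i] / db$dmi[i]
  sil_i <- feeds[feeds$type == "silage" & feeds$code == db$silage_code[i], ]
  con_i <- feeds[feeds$type == "concentrate" &
                   feeds$code == db$conc_code[i], ]
  expect_equal(db$diet_ndf[i],
               w_s * sil_i$ndf + (1 - w_s) * con_i$ndf, tolerance = 1e-10)
  expect_equal(db$diet_fa[i], 0.8 * db$diet_ee[i], tolerance = 1e-10)
})

test_that("attach_ch4_ym fills Ym as the CH4 share of GEI", {
  db <- attach_ch4_ym(build_operational_database(), "model3")
  expect_equal(db$ym, 100 * db$ch4_pred / db$gei, tolerance = 1e-12)
  expect_equal(100 * 19.85 / 298, 6.6611, tolerance = 1e-4)
  # doubling CH4 doubles Ym
  db2 <- db
  db2$ch4_pred <- 2 * db2$ch4_pred
  db2$ym <- 100 * db2$ch4_pred / db2$gei
  expect_equal(db2$ym, 2 * db$ym, tolerance = 1e-12)
  bad <- db
  bad$gei[1] <- 0
  expect_error(attach_ch4_ym(bad, "model3"), "gei")
})
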