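adult <- exposure_parameters("adult")

test_that("dietary average daily intake follows the intake formula", {
  p <- exposure_parameters("adult", IR = 0.3, EF = 350, ED = 24, BW = 60,
                           AT_nc = 8760)
  # oracle: hand arithmetic 0.5*0.3*350*24/(60*8760)
  expect_equal(adi_food(0.5, p, "nc"), 2.39726e-3, tolerance = 1e-5)
  expect_equal(adi_food(0, p, "nc"), 0)
  p2 <- exposure_parameters("adult", IR = 0.3, EF = 350, ED = 24, BW = 120,
                            AT_nc = 8760)
  expect_equal(adi_food(0.5, p2, "nc"), adi_food(0.5, p, "nc") / 2)
})

test_that("soil-pathway intakes carry the mg-to-kg factor and PEF", {
  p <- exposure_parameters("adult", IngR = 100, EF = 350, ED = 24, BW = 60,
                           AT_nc = 8760)
  # oracle: hand arithmetic 652.34*100*350*24/(60*8760)*1e-6
  expect_equal(adi_soil(652.34, p, "ing", "nc"), 1.042553e-3,
               tolerance = 1e-5)
  for (pw in c("ing", "inh", "der")) {
    expect_equal(adi_soil(0, p, pw, "nc"), 0)
  }
  # inhalation = ingestion x (InhR/IngR)/PEF
  expect_equal(adi_soil(100, p, "inh", "nc"),
               adi_soil(100, p, "ing", "nc") * (p$InhR / p$IngR) / p$PEF,
               tolerance = 1e-12)
  expect_error(adi_soil(1, p, "food"), "adi_food")
})

test_that("hazard quotient and carcinogenic risk are the defining ratios", {
  expect_equal(hazard_quotient(1e-3, 1e-3), 1)
  expect_equal(hazard_quotient(0, 0.5), 0)
  expect_equal(hazard_quotient(2e-3, 1e-3), 2)
  expect_error(hazard_quotient(1, 0), "> 0")
  expect_equal(carcinogenic_risk(1e-3, 1.5), 1.5e-3)
  expect_equal(carcinogenic_risk(0, 1.5), 0)
  expect_true(is.na(carcinogenic_risk(1e-3, NA)))  # e.g. Pb dermal
})

test_that("aggregation reproduces the published risk-table margins", {
  rt <- aggregate_risk(table3_cells())
  grand <- rt$grand
  hi_ad <- grand$hi[grand$population == "adult"]
  hi_ch <- grand$hi[grand$population == "child"]
  tcr_ad <- grand$tcr[grand$population == "adult"]
  expect_lt(abs(hi_ad - 49.41), 0.011)
  expect_lt(abs(hi_ch - 104.83), 0.011)
  expect_equal(signif(tcr_ad, 3), 4.23e-2)
  expect_equal(signif(grand$tcr[grand$population == "child"], 3), 8.92e-2)
  pt <- rt$pathway_totals
  # published margins agree with the cell sums to last-digit rounding
  expect_lt(abs(pt$hq_total[pt$population == "adult" &
                              pt$pathway == "food"] - 48.95), 0.011)
  expect_lt(abs(pt$hq_total[pt$population == "child" &
                              pt$pathway == "food"] - 102.62), 0.011)
  expect_lt(abs(pt$hq_total[pt$population == "child" &
                              pt$pathway == "ing"] - 1.39), 0.011)
  # metals with no slope factor at all have absent CR totals, not zero
  mt <- rt$metal_totals
  expect_true(is.na(mt$cr_total[mt$population == "adult" & mt$metal == "Cu"]))
  expect_false(is.na(mt$cr_total[mt$population == "adult" & mt$metal == "Pb"]))
  # all-zero cells give zero margins
  zero <- table3_cells()
  zero$hq <- 0; zero$cr <- ifelse(is.na(zero$cr), NA, 0)
  z <- aggregate_risk(zero)$grand
  expect_equal(z$hi, c(0, 0))
  expect_equal(z$tcr, c(0, 0))
})

test_that("risk scales linearly in concentration and sums commute", {
  c_rice <- c(Cu = 0.5, Cr = 0.3, Zn = 4, Cd = 0.2, Pb = 0.4, As = 0.15)
  c_soil <- c(Cu = 65.18, Cr = 69.75, Zn = 490.87, Cd = 2.01, Pb = 652.34,
              As = 148.11)
  rt1 <- aggregate_risk(risk_cells(c_rice, c_soil))
  # doubling every concentration doubles HI and TCR bit-for-bit
  rt2 <- aggregate_risk(risk_cells(c_rice * 2, c_soil * 2))
  expect_identical(rt2$grand$hi, rt1$grand$hi * 2)
  expect_identical(rt2$grand$tcr, rt1$grand$tcr * 2)
  k <- 1.7
  rt3 <- aggregate_risk(risk_cells(c_rice * k, c_soil * k))
  expect_equal(rt3$grand$hi, rt1$grand$hi * k, tolerance = 1e-12)
  expect_equal(rt3$grand$tcr, rt1$grand$tcr * k, tolerance = 1e-12)
  # HI via metal totals equals HI via pathway totals
  expect_equal(
    tapply(rt1$metal_totals$hq_total, rt1$metal_totals$population, sum),
    tapply(rt1$pathway_totals$hq_total, rt1$pathway_totals$population, sum),
    tolerance = 1e-12)
})

test_that("risk classification thresholds are strict", {
  expect_equal(classify_risk(49.41, "HQ_HI"), "risk")
  expect_equal(classify_risk(1, "HQ_HI"), "no potential risk")
  expect_equal(classify_risk(5e-5, "CR_TCR"), "acceptable")
  expect_equal(classify_risk(1e-4, "CR_TCR"), "acceptable")
  expect_equal(classify_risk(2e-4, "CR_TCR"), "unacceptable")
  expect_equal(classify_risk(1e-7, "CR_TCR"), "no obvious risk")
})

test_that("the wide layout mirrors the published table structure", {
  rt <- aggregate_risk(table3_cells())
  wide <- risk_table_wide(rt)
  expect_named(wide, c("population", "metal", "HQ_food", "HQ_ing", "HQ_inh",
                       "HQ_der", "HQ_total", "CR_food", "CR_ing", "CR_inh",
                       "CR_der", "CR_total"))
  expect_equal(nrow(wide), 14)  # 6 metals x 2 populations + 2 margin rows
  margin <- wide[wide$metal == "HI/TCR" & wide$population == "adult", ]
  expect_lt(abs(margin$HQ_total - 49.41), 0.011)
})
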