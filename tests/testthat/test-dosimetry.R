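test_that("ICRP 103 weights are complete and normalised", {
  w <- icrp103_weights()
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unname(w["breast"]), 0.12)
  expect_equal(unname(w["thyroid"]), 0.04)
  expect_equal(unname(w["remainder"]), 0.12)
})

test_that("effective dose obeys the trivial identities", {
  w <- icrp103_weights()
  zero <- data.frame(organ = names(w), dose_uGy = 0, stderr_uGy = 0)
  expect_equal(effective_dose(zero)$effective_uSv, 0)
  unif <- data.frame(organ = names(w), dose_uGy = 1000, stderr_uGy = 0)
  expect_equal(effective_dose(unif)$effective_uSv, 1000, tolerance = 1e-9)
  # breast-only dose of 1.783 mSv weights down to ~214 uSv effective
  bo <- data.frame(organ = names(w),
                   dose_uGy = ifelse(names(w) == "breast", 1783, 0),
                   stderr_uGy = 0)
  ed <- effective_dose(bo)
  expect_equal(ed$effective_uSv, 214, tolerance = 0.01)
  expect_equal(unname(ed$contributions_percent[["breast"]]), 100)
  neg <- zero; neg$dose_uGy[1] <- -1
  expect_error(effective_dose(neg), "negative")
  part <- data.frame(organ = "breast", dose_uGy = 1000, stderr_uGy = 0)
  expect_warning(effective_dose(part), "zero-filled")
})

test_that("normalisation is linear in the entrance dose and empty protocols vanish", {
  tl <- test_tally_cc()
  sc <- test_scene_cc()
  mk <- function(entr) exposure_protocol(
    views = data.frame(view = "CC", side = "left", entrance_mGy = entr))
  t1 <- normalize_tallies(list(CC = tl), mk(3.6), sc)
  t2 <- normalize_tallies(list(CC = tl), mk(7.2), sc)
  expect_equal(t2$dose_uGy, 2 * t1$dose_uGy, tolerance = 1e-9)
  expect_equal(attr(t2, "surface_air_kerma_uGy"),
               2 * attr(t1, "surface_air_kerma_uGy"), tolerance = 1e-9)
  empty <- exposure_protocol(views = data.frame(view = character(),
                                                side = character(),
                                                entrance_mGy = numeric()))
  t0 <- normalize_tallies(list(CC = tl), empty, sc)
  expect_true(all(t0$dose_uGy == 0))
})

test_that("contribution percentages are scale-invariant and sum to 100", {
  tab <- test_protocol_table()
  ed <- effective_dose(tab)
  expect_equal(sum(ed$contributions_percent), 100, tolerance = 0.1)
  tab2 <- tab; tab2$dose_uGy <- tab2$dose_uGy * 5
  ed2 <- effective_dose(tab2)
  expect_equal(ed$contributions_percent, ed2$contributions_percent,
               tolerance = 1e-9)
  # breast field dominates the effective dose
  expect_gt(ed$contributions_percent[["breast"]], 90)
})

test_that("the MGD estimate is linear and in the DgN plausibility band", {
  tl <- test_tally_cc()
  m1 <- mgd_estimate(tl, 3.6)
  expect_equal(mgd_estimate(tl, 7.2), 2 * m1, tolerance = 1e-12)
  # MGD/entrance for a 5.6 cm 3:2 breast at 28 kVp W/Rh
  expect_gt(m1 / 3.6, 0.15); expect_lt(m1 / 3.6, 0.35)
})

test_that("conversion factors reproduce the worked arithmetic", {
  cf <- conversion_factor(374, 158)
  expect_equal(cf$factor, 2.367, tolerance = 0.001)
  expect_equal(conversion_factor(5, 5)$factor, 1)
  sd_ <- scaled_thyroid_dose(4.3, cf)
  expect_gt(sd_$dose_uGy, 8); expect_lt(sd_$dose_uGy, 12)
  expect_error(conversion_factor(-1, 3), "positive")
  expect_error(scaled_thyroid_dose(0, 2), "positive")
})

test_that("the non-breast scaling increase matches its closed form", {
  tab <- test_protocol_table()
  expect_equal(scaled_effective_dose_increase(tab, 1), 0, tolerance = 1e-9)
  inc <- scaled_effective_dose_increase(tab, 2.3)
  fb <- effective_dose(tab)$contributions_percent[["breast"]] / 100
  expect_equal(inc, (2.3 - 1) * (1 - fb) * 100, tolerance = 1e-6)
  expect_error(scaled_effective_dose_increase(tab, -1), "positive")
})
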