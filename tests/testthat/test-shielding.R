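test_that("monoenergetic transmission follows Beer-Lambert", {
  pb <- shield_spec("head_wall", thickness_mm = 1)
  expect_lte(transmission(pb, 35), 1e-9)
  thin <- shield_spec("collar", thickness_mm = 1e-12)
  expect_equal(transmission(thin, 30), 1, tolerance = 1e-9)
  # independent hand computation from the embedded table (log-log interp)
  collar <- shield_spec("collar", thickness_mm = 0.25)
  tb <- get_material("lead")$table
  i <- max(which(tb$energy_keV <= 30)); j <- i + 1
  f <- (log(30) - log(tb$energy_keV[i])) /
    (log(tb$energy_keV[j]) - log(tb$energy_keV[i]))
  mu <- exp((1 - f) * log(tb$total[i]) + f * log(tb$total[j])) * 11.35
  expect_equal(transmission(collar, 30), exp(-mu * 0.025), tolerance = 1e-9)
  # stacking multiplies
  t1 <- transmission(shield_spec("collar", thickness_mm = 0.1), 30)
  t2 <- transmission(shield_spec("collar", thickness_mm = 0.15), 30)
  expect_equal(t1 * t2, transmission(collar, 30), tolerance = 1e-12)
  # strictly decreasing in thickness
  expect_lt(transmission(collar, 30),
            transmission(shield_spec("collar", thickness_mm = 0.2), 30))
})

test_that("spectrum-weighted transmission is consistent and bounded", {
  collar <- shield_spec("collar", thickness_mm = 0.25)
  s <- test_spectrum(30)
  tw <- spectrum_transmission(collar, s)
  mono_t <- transmission(collar, s$energy_bins[s$fluence_weights > 0])
  expect_gte(tw, min(mono_t)); expect_lte(tw, max(mono_t))
  # monoenergetic pseudo-spectrum equals the monoenergetic value
  expect_equal(spectrum_transmission(collar, mono_spectrum(25)),
               transmission(collar, 25), tolerance = 1e-9)
  expect_equal(spectrum_transmission(shield_spec("collar",
                                                 thickness_mm = 1e-12), s),
               1, tolerance = 1e-9)
  # the 0.25 mm collar at 30 kVp W/Rh transmits below 1.5e-4 (kerma-weighted)
  expect_lte(tw, 1.5e-4)
})
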