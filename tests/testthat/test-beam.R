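test_that("spectrum generation honours the endpoint and normalisation", {
  s <- generate_spectrum(tube_setting(kvp = 30, filtration = list(),
                                      anode_self_filtration_um = 0))
  expect_equal(sum(s$fluence_weights), 1, tolerance = 1e-12)
  expect_true(all(s$fluence_weights >= 0))
  populated <- s$energy_bins[s$fluence_weights > 0]
  # endpoint: the last populated bin reaches the kVp
  expect_equal(max(populated) + s$bin_width[length(s$bin_width)] / 2, 30,
               tolerance = 0.26)
  expect_true(all(s$energy_bins <= 30))
  expect_true(all(s$energy_bins >= 8))
})

test_that("the rhodium K-edge cuts the filtered spectrum", {
  s <- generate_spectrum(tube_setting(kvp = 30))
  kedge <- 23.2199
  below <- which.min(abs(s$energy_bins - (kedge - 0.3)))
  above <- which.min(abs(s$energy_bins - (kedge + 0.3)))
  # oracle: the drop must match the rhodium transmission ratio applied to
  # the smooth Kramers form; the edge must cut the fluence by more than half
  expect_lt(s$fluence_weights[above] / s$fluence_weights[below], 0.5)
  rh <- get_material("rhodium")
  t_ratio <- exp(-lookup_mu(rh, kedge + 0.3) * 0.005) /
    exp(-lookup_mu(rh, kedge - 0.3) * 0.005)
  expect_lt(t_ratio, 0.5)
})

test_that("mean energy increases with kVp and filtration composes", {
  e28 <- mean_energy(test_spectrum(28))
  e35 <- mean_energy(test_spectrum(35))
  expect_gt(e35, e28)
  rh <- get_material("rhodium")
  one <- generate_spectrum(tube_setting(kvp = 30,
                                        filtration = list(list(rh, 0.050))))
  two <- generate_spectrum(tube_setting(kvp = 30,
                                        filtration = list(list(rh, 0.020),
                                                          list(rh, 0.030))))
  expect_equal(one$fluence_weights, two$fluence_weights, tolerance = 1e-12)
})

test_that("half-value layer matches the closed form and the W/Rh band", {
  al <- get_material("aluminium")
  mono <- mono_spectrum(20)
  expect_equal(half_value_layer(mono, al), 10 * log(2) / lookup_mu(al, 20),
               tolerance = 1e-3)
  hvl <- half_value_layer(generate_spectrum(tube_setting(kvp = 30)), al)
  expect_gt(hvl, 0.45); expect_lt(hvl, 0.65)
  # scale invariance of the transmission integral
  s <- test_spectrum(28)
  s2 <- s; s2$fluence_weights <- 2 * s$fluence_weights
  expect_equal(half_value_layer(s2, al), half_value_layer(s, al),
               tolerance = 1e-3)
})

test_that("source sampling is reproducible, bounded by kVp and covers the paddle", {
  sc <- test_scene_cc()
  s <- test_spectrum(28)
  b1 <- sample_source_photons(s, 1e5, sc, rng_seed = 5)
  b2 <- sample_source_photons(s, 1e5, sc, rng_seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$energy_keV <= 28 + 0.125))
  # chi-square goodness of fit of sampled energies against the spectrum
  idx <- findInterval(b1$energy_keV, c(s$energy_bins - s$bin_width / 2, 99))
  obs <- tabulate(idx, nbins = length(s$energy_bins))
  keep <- s$fluence_weights * 1e5 > 5
  chi <- sum((obs[keep] - 1e5 * s$fluence_weights[keep])^2 /
               (1e5 * s$fluence_weights[keep]))
  p <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
  # projected intersections with the beam-rectangle plane fill it
  r <- sc$beam_rect
  tt <- (r$corner[3] - b1$z) / b1$dz
  px <- b1$x + tt * b1$dx
  py <- b1$y + tt * b1$dy
  expect_lt(min(px) - r$corner[1], 0.01 * r$u[1])
  expect_lt(r$corner[1] + r$u[1] - max(px), 0.01 * r$u[1])
  expect_lt(min(py) - r$corner[2], 0.01 * r$v[2])
  expect_lt(r$corner[2] + r$v[2] - max(py), 0.01 * r$v[2])
  expect_error(sample_source_photons(s, 0, sc), "positive")
})
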