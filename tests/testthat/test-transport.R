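test_that("delta tracking reproduces analytic attenuation and the ray-marcher", {
  sc <- build_box_scene(get_material("water"), size_mm = c(40, 40, 40),
                        voxel_mm = 4)
  mu <- lookup_mu(get_material("water"), 25, "total")
  p0 <- c(0, 0, -0.5); dir <- c(0, 0, -1)
  analytic <- exp(-mu * 3.95)               # ~39.5 mm of water below the start
  marched <- raymarch_transmission(sc, p0, dir, 25)
  expect_equal(marched, analytic, tolerance = 0.02)
  est <- delta_transmission(sc, p0, dir, 25, n = 4e4, rng_seed = 8)
  expect_lt(abs(est$transmission - marched), 3 * est$stderr + 1e-12)
})

test_that("a heterogeneous stack agrees between delta tracking and ray marching", {
  sc <- build_box_scene(get_material("water"), size_mm = c(40, 40, 40),
                        voxel_mm = 4)
  # swap two slabs to bone to make the stack heterogeneous
  sc$grids[[1]]$labels[, , 3:4] <- 33L
  sc$labels <- rbind(sc$labels,
                     data.frame(label = 33L, material = "bone_cortical",
                                organ = NA, region = 1L, breast = FALSE))
  marched <- raymarch_transmission(sc, c(0, 0, -0.5), c(0, 0, -1), 30)
  est <- delta_transmission(sc, c(0, 0, -0.5), c(0, 0, -1), 30,
                            n = 6e4, rng_seed = 9)
  expect_lt(abs(est$transmission - marched), 3 * est$stderr + 1e-12)
})

test_that("energy is conserved per batch to 1e-6", {
  expect_lt(energy_balance(test_tally_cc()), 1e-6)
  expect_lt(energy_balance(test_tally_mlo()), 1e-6)
})

test_that("a near-empty scene yields a purely primary probe reading", {
  sc <- build_halfspace_scene(NULL, NULL)
  tl <- run_transport(sc, test_spectrum(), 5e4, rng_seed = 21)
  expect_gt(tl$provenance_split[["primary"]], 0.995)
})

test_that("the probe standard error scales as one over root N", {
  sp <- test_spectrum()
  sc <- build_halfspace_scene(get_material("muscle"))
  ns <- c(2.5e4, 5e4, 1e5, 2e5)
  se <- vapply(seq_along(ns), function(i)
    run_transport(sc, sp, ns[i], rng_seed = 30 + i)$surface_air_kerma_stderr,
    numeric(1))
  ratios <- se[-length(se)] / se[-1]
  expect_true(all(ratios > 0.9 & ratios < 2.3))
  # overall halving across the three doublings: expect ~ 2^1.5 total
  expect_equal(log2(se[1] / se[4]), 1.5, tolerance = 0.75)
})

test_that("transport is bit-reproducible for a fixed seed", {
  sp <- test_spectrum()
  sc <- build_halfspace_scene(get_material("muscle"))
  a <- run_transport(sc, sp, 3e4, rng_seed = 77)
  b <- run_transport(sc, sp, 3e4, rng_seed = 77)
  expect_identical(a$organ_dose, b$organ_dose)
  expect_identical(a$probe_kerma, b$probe_kerma)
  expect_identical(a$ledger, b$ledger)
  c_ <- run_transport(sc, sp, 3e4, rng_seed = 78)
  expect_false(identical(a$probe_kerma, c_$probe_kerma))
})

test_that("backscatter factors behave physically", {
  sp <- test_spectrum()
  # vacuum half-space: factor 1
  f0 <- backscatter_factor(NULL, NULL, sp, histories = 3e4, rng_seed = 50)
  expect_equal(f0$factor, 1, tolerance = 0.02)
  # muscle backscatter is substantial at mammographic qualities
  fm <- backscatter_factor(get_material("muscle"), NULL, sp,
                           histories = 1e5, rng_seed = 51)
  expect_gt(fm$factor, 1.05)
  # a lead overlay suppresses the backscatter (shielding monotonicity)
  fp <- backscatter_factor(get_material("muscle"),
                           shield_spec("collar", thickness_mm = 0.25), sp,
                           histories = 1e5, rng_seed = 52)
  expect_lt(fp$factor, fm$factor)
  expect_error(backscatter_factor(get_material("muscle"),
                                  shield_spec("collar", thickness_mm = 6),
                                  sp), "thinner than 5")
})

test_that("the thyroid collar shields the probe behind it", {
  sp <- test_spectrum()
  sc_on <- build_scene(breast_spec(5.6),
                       collar = shield_spec("collar", thickness_mm = 0.25),
                       view = "CC")
  t_on <- run_transport(sc_on, sp, 1e5, rng_seed = 60)
  t_off <- run_transport(test_scene_cc(), sp, 1e5, rng_seed = 60)
  expect_lt(t_on$probe_kerma[["probe_inner"]],
            0.2 * t_off$probe_kerma[["probe_inner"]])
  # the outer probe, in front of the collar, is not shielded
  expect_gt(t_on$probe_kerma[["probe_outer"]],
            0.5 * t_off$probe_kerma[["probe_outer"]])
})

test_that("tally invariants hold on the standard scene", {
  tl <- test_tally_cc()
  expect_true(all(tl$organ_dose >= 0))
  expect_true(all(tl$organ_dose_stderr >= 0))
  expect_equal(sum(tl$provenance_split), 1, tolerance = 1e-9)
  expect_true(all(tl$provenance_split >= 0))
  # tissue attenuation: thyroid organ dose below the surface probe kerma
  expect_lt(tl$organ_dose[["thyroid"]], tl$surface_air_kerma)
})
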