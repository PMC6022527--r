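test_that("organ masses match the constructive-solid oracle", {
  sc <- test_scene_cc()
  # independent analytic volumes of the constructive solids (cm^3)
  thy_vol <- 2 * (4 / 3) * pi * 0.9 * 0.9 * 2.1 + 1.6 * 0.8 * 1.6
  expect_equal(organ_mass(sc, "thyroid"), thy_vol * 1.06, tolerance = 0.10)
  # thyroid within the configurable adult reference band
  expect_lt(abs(organ_mass(sc, "thyroid") - 20) / 20, 0.20)
  # breast slab: footprint x thickness minus the skin shell
  expect_equal(organ_mass(sc, "breast_ipsi") +
                 organ_mass(sc, "skin") * 0,   # skin accounted separately
               17 * 14 * 5.4 * 0.98, tolerance = 0.12)
  # air probe mass = rho_air * probe volume (2 x 2 x 1 voxels)
  v <- sc$voxel_mm / 10
  expect_equal(organ_mass(sc, "probe_inner"),
               (2 * v) * (2 * v) * v * get_material("air")$density,
               tolerance = 1e-9)
  expect_error(organ_mass(sc, "spleen"), "unknown organ")
})

test_that("voxel refinement leaves organ masses stable", {
  sc2 <- test_scene_cc()
  sc4 <- build_scene(breast_spec(5.6), view = "CC",
                     options = list(voxel_mm = 4))
  for (org in c("lung", "liver", "intestine", "brain")) {
    m2 <- organ_mass(sc2, org); m4 <- organ_mass(sc4, org)
    expect_lt(abs(m2 - m4) / m2, 0.05, label = org)
  }
})

test_that("the primary path crosses only paddle and breast voxels", {
  sc <- test_scene_cc()
  g <- sc$grids[[1]]
  r <- sc$nominal_rect
  target <- r$corner + 0.5 * r$u + 0.5 * r$v
  f <- sc$focal_spot
  dir <- (target - f) / sqrt(sum((target - f)^2))
  labs <- c()
  for (t in seq(0, 1, by = 0.002)) {
    p <- target + t * 700 * dir   # continue downward to the support
    idx <- floor((p - g$origin) / g$vox) + 1
    if (any(idx < 1) || any(idx > g$dim)) next
    labs <- c(labs, g$labels[idx[1], idx[2], idx[3]])
    if (labs[length(labs)] %in% c(4L, 5L)) break
  }
  # paddle(3), skin(19), breast(2), then support(4)/detector(5); nothing else
  expect_true(all(labs %in% c(0L, 3L, 19L, 2L, 4L, 5L)))
  expect_true(2L %in% labs && 3L %in% labs)
})

test_that("paddle height rises with compression thickness", {
  tops <- vapply(c(4, 5.6, 7), function(C) {
    sc <- if (C == 5.6) test_scene_cc() else build_scene(breast_spec(C),
                                                         view = "CC")
    g <- sc$grids[[1]]
    iz <- which(apply(g$labels == 3L, 3, any))
    g$origin[3] + max(iz) * g$vox[3]
  }, numeric(1))
  expect_true(all(diff(tops) > 0))
})

test_that("MLO differs from CC only in the imaging-chain pose", {
  cc <- test_scene_cc(); ml <- test_scene_mlo()
  fixed <- !cc$organ_table$organ %in% c("breast_ipsi", "breast_contra",
                                       "skin")
  expect_equal(cc$organ_table$mass_g[fixed], ml$organ_table$mass_g[fixed],
               tolerance = 1e-9)
  expect_equal(organ_mass(cc, "breast_ipsi"), organ_mass(ml, "breast_ipsi"),
               tolerance = 0.05)
  expect_equal(organ_mass(cc, "breast_contra"), organ_mass(ml, "breast_contra"),
               tolerance = 0.02)
  expect_false(isTRUE(all.equal(cc$focal_spot, ml$focal_spot)))
})

test_that("the collar sits between the probes and outside the beam", {
  sc <- build_scene(breast_spec(5.6),
                    collar = shield_spec("collar", thickness_mm = 0.25),
                    view = "CC")
  lb <- sc$lead_boxes
  collar <- lb[lb[, "class"] == 3, , drop = FALSE]
  expect_equal(nrow(collar), 1L)
  expect_equal(unname(2 * collar[1, 5]), 0.25, tolerance = 1e-9)
  yc <- collar[1, 2]
  y_in <- sc$probe_points["probe_inner", 2]
  y_out <- sc$probe_points["probe_outer", 2]
  expect_true(y_in < yc && yc < y_out)
  # collar corners lie outside the primary beam pyramid
  expect_false(mammoscatter:::.point_in_beam(c(0, yc, 200), sc$focal_spot,
                                             sc$nominal_rect))
  # a hypothetical collar inside the field would be caught
  expect_true(mammoscatter:::.point_in_beam(c(60, 70, 40), sc$focal_spot,
                                            sc$nominal_rect))
})

test_that("scene construction is deterministic and the manifest is stable", {
  a <- build_scene(breast_spec(4), view = "CC", options = list(voxel_mm = 4))
  b <- build_scene(breast_spec(4), view = "CC", options = list(voxel_mm = 4))
  expect_identical(a$grids[[1]]$labels, b$grids[[1]]$labels)
  ma <- scene_manifest(a); mb <- scene_manifest(b)
  expect_identical(ma$config_hash, mb$config_hash)
  # every label present in the grid is described in the label table
  labs <- sort(unique(as.vector(a$grids[[1]]$labels)))
  expect_true(all(labs %in% a$labels$label))
})
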