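# Monte Carlo driver: configuration marshalling for the compiled kernel,
# tally post-processing, and the backscatter-factor operation.

.E0_GRID <- 5; .DE_GRID <- 0.05; .NE_GRID <- 701   # 5-40 keV lookup grid
.KEV_PER_G_TO_GY <- 1.602176634e-13
.PB_L3_EDGE <- 13.0352
.PB_L_LINE <- 10.55
.PB_L_YIELD <- 0.29    # effective L-shell photoabsorption share x fluorescence yield

# log-log interpolation with power-law extrapolation outside the table
.loglog_extrap <- function(x, y, xout) {
  lx <- log(x); ly <- log(y); lo <- log(xout)
  out <- approx(lx, ly, xout = lo, rule = 2)$y
  below <- lo < lx[1]
  if (any(below)) {
    sl <- (ly[2] - ly[1]) / (lx[2] - lx[1])
    out[below] <- ly[1] + sl * (lo[below] - lx[1])
  }
  above <- lo > lx[length(lx)]
  if (any(above)) {
    n <- length(lx)
    sl <- (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1])
    out[above] <- ly[n] + sl * (lo[above] - lx[n])
  }
  exp(out)
}

.scene_materials <- function(scene) {
  reg <- material_registry()
  specials <- list(breast_3to2 = breast_material(), lung = lung_material(),
                   detector = .detector_material())
  nm <- unique(scene$labels$material)
  mats <- lapply(nm, function(n) {
    if (!is.null(scene$extra_materials[[n]])) scene$extra_materials[[n]]
    else if (n %in% names(specials)) specials[[n]]
    else if (n %in% names(reg)) reg[[n]]
    else stop("scene references unknown material '", n, "'")
  })
  names(mats) <- nm
  mats
}

# marshal a scene + spectrum into the flat config list the kernel expects
.build_cfg <- function(scene, spectrum, cutoff_keV = 5, min_tally_keV = 0) {
  stopifnot(inherits(scene, "voxel_scene"), inherits(spectrum, "spectrum"))
  if (cutoff_keV >= min(spectrum$energy_bins))
    stop("cutoff energy must lie below the softest spectrum bin")
  mats <- .scene_materials(scene)
  Eg <- .E0_GRID + (seq_len(.NE_GRID) - 1) * .DE_GRID
  nmat <- length(mats)
  mu_tot <- mu_en <- cum_pe <- cum_incoh <- matrix(0, .NE_GRID, nmat)
  for (i in seq_len(nmat)) {
    tb <- mats[[i]]$table; rho <- mats[[i]]$density
    pe <- .loglog_extrap(tb$energy_keV, tb$pe, Eg)
    inc <- .loglog_extrap(tb$energy_keV, tb$incoh, Eg)
    coh <- .loglog_extrap(tb$energy_keV, tb$coh, Eg)
    tot <- pe + inc + coh
    mu_tot[, i] <- rho * tot
    mu_en[, i] <- rho * .loglog_extrap(tb$energy_keV, tb$muen, Eg)
    cum_pe[, i] <- pe / tot
    cum_incoh[, i] <- (pe + inc) / tot
  }
  majorant <- apply(mu_tot, 1, max)
  pb <- scene$lead_material
  pb_pe <- .loglog_extrap(pb$table$energy_keV, pb$table$pe, Eg)
  pb_inc <- .loglog_extrap(pb$table$energy_keV, pb$table$incoh, Eg)
  pb_coh <- .loglog_extrap(pb$table$energy_keV, pb$table$coh, Eg)
  pb_tot <- pb$density * (pb_pe + pb_inc + pb_coh)
  gl <- get_material("glandular")
  muen_gland <- .loglog_extrap(gl$table$energy_keV, gl$table$muen, Eg)

  lt <- scene$labels
  maxlab <- max(lt$label)
  mat_of <- org_of <- reg_of <- breast_of <- integer(maxlab + 1L)
  orgs <- as.character(unique(lt$organ[!is.na(lt$organ)]))
  for (i in seq_len(nrow(lt))) {
    l <- lt$label[i] + 1L
    mat_of[l] <- match(lt$material[i], names(mats)) - 1L
    org_of[l] <- if (is.na(lt$organ[i])) 0L else match(lt$organ[i], orgs)
    reg_of[l] <- lt$region[i]
    breast_of[l] <- as.integer(lt$breast[i])
  }
  probe_org <- c(0L, as.integer(startsWith(orgs, "probe")))

  gl_list <- lapply(scene$grids, function(g)
    list(labels = as.integer(g$labels), dim = as.integer(g$dim),
         origin = as.numeric(g$origin), vox = as.numeric(g$vox)))
  lb <- scene$lead_boxes
  if (is.null(lb)) lb <- matrix(0, 0, 7)
  lR <- scene$lead_R
  if (is.null(lR)) lR <- list()

  pts <- rbind(scene$focal_spot,
               scene$beam_rect$corner,
               scene$beam_rect$corner + scene$beam_rect$u + scene$beam_rect$v)
  for (g in scene$grids)
    pts <- rbind(pts, g$origin, g$origin + g$vox * g$dim)
  if (nrow(lb) > 0) pts <- rbind(pts, lb[, 1:3] - lb[, 4:6] - 5,
                                 lb[, 1:3] + lb[, 4:6] + 5)
  world_lo <- apply(pts, 2, min) - 100
  world_hi <- apply(pts, 2, max) + 100

  list(grids = gl_list,
       lead_boxes = unname(as.matrix(lb)), lead_R = lR,
       mat_of = mat_of, org_of = org_of, reg_of = reg_of,
       breast_of = breast_of,
       nE = .NE_GRID, e0 = .E0_GRID, de = .DE_GRID, nmat = nmat,
       mu_tot = mu_tot, mu_en = mu_en, cum_pe = cum_pe, cum_incoh = cum_incoh,
       majorant = majorant, mu_air = mu_tot[, match("air", names(mats))],
       pb_tot = pb_tot,
       pb_cum_pe = pb_pe / (pb_pe + pb_inc + pb_coh),
       pb_cum_incoh = (pb_pe + pb_inc) / (pb_pe + pb_inc + pb_coh),
       muen_gland = muen_gland,
       air_idx = match("air", names(mats)),
       fluor_energy = .PB_L_LINE, fluor_yield = .PB_L_YIELD,
       fluor_edge = .PB_L3_EDGE,
       fluorescence = isTRUE(scene$fluorescence),
       cutoff_keV = cutoff_keV, min_tally_keV = min_tally_keV,
       probe_org = probe_org,
       world_lo = world_lo, world_hi = world_hi,
       src_type = if (!is.null(scene$parallel_dir)) 1L else 0L,
       focal = scene$focal_spot,
       rect_corner = scene$beam_rect$corner,
       rect_u = scene$beam_rect$u, rect_v = scene$beam_rect$v,
       parallel_dir = if (!is.null(scene$parallel_dir)) scene$parallel_dir
                      else c(0, 0, -1),
       spec_E = spectrum$energy_bins,
       spec_w = spectrum$fluence_weights,
       spec_bw = rep(spectrum$bin_width, length.out = length(spectrum$energy_bins)),
       probe_points = if (is.null(scene$probe_points)) matrix(0, 0, 3)
                      else scene$probe_points,
       muen_air_mass = {
         air <- get_material("air")
         .loglog_extrap(air$table$energy_keV, air$table$muen, Eg)
       },
       soften2 = 4,          # mm^2; volume-averaging of the 1/r^2 kernel
       norg = length(orgs), organs = orgs)
}

# analytic primary (uncollided) kerma at each probe point, Gy per history
.primary_kerma_at_probes <- function(scene, spectrum, cfg) {
  pp <- cfg$probe_points
  if (nrow(pp) == 0) return(numeric(0))
  E <- spectrum$energy_bins
  w <- spectrum$fluence_weights
  muen <- cfg$muen_air_mass[round((E - .E0_GRID) / .DE_GRID) + 1]
  out <- numeric(nrow(pp))
  r <- scene$beam_rect
  for (i in seq_len(nrow(pp))) {
    q <- pp[i, ]
    if (!is.null(scene$parallel_dir)) {
      dirn <- scene$parallel_dir / sqrt(sum(scene$parallel_dir^2))
      nrm <- cross3(r$u, r$v); nrm <- nrm / sqrt(sum(nrm^2))
      den <- sum(dirn * nrm)
      if (abs(den) < 1e-9) next
      tt <- sum((q - r$corner) * nrm) / den
      s <- q - tt * dirn
      rel <- s - r$corner
      su <- sum(rel * r$u) / sum(r$u^2)
      sv <- sum(rel * r$v) / sum(r$v^2)
      if (su < 0 || su > 1 || sv < 0 || sv > 1) next
      tau <- cpp_ray_tau(cfg, s, q, E)$tau
      area <- sqrt(sum(r$u^2)) * sqrt(sum(r$v^2))
      out[i] <- sum(w * E * muen * exp(-tau)) * 100 / area *
        .KEV_PER_G_TO_GY
    } else {
      if (!.point_in_beam(q, scene$focal_spot, r)) next
      tau <- cpp_ray_tau(cfg, scene$focal_spot, q, E)$tau
      omega <- solid_angle_rect(scene$focal_spot, r)
      r2 <- sum((q - scene$focal_spot)^2)
      out[i] <- sum(w * E * muen * exp(-tau)) * 100 / (omega * r2) *
        .KEV_PER_G_TO_GY
    }
  }
  names(out) <- rownames(pp)
  out
}

# analytic free-in-air entrance kerma at the paddle-entrance reference point,
# Gy per emitted photon (primary only, upstream shield + air attenuation,
# no backscatter); NA for parallel-beam QA scenes
.entrance_kerma_per_history <- function(scene, spectrum) {
  if (is.null(scene$nominal_rect)) return(NA_real_)
  r <- scene$nominal_rect
  centre <- r$corner + 0.5 * r$u + 0.5 * r$v
  f <- scene$focal_spot
  Rmm <- sqrt(sum((centre - f)^2))
  omega <- solid_angle_rect(f, scene$beam_rect)
  E <- spectrum$energy_bins
  w <- spectrum$fluence_weights
  air <- get_material("air")
  muen_air <- .loglog_extrap(air$table$energy_keV, air$table$muen, E)
  mu_air <- lookup_mu(air, E, "total")
  t_sh <- 0
  if (length(scene$grids) > 1) {
    axis <- (centre - f) / Rmm
    t_sh <- 2 / abs(axis[3])
  }
  Tband <- exp(-mu_air * (Rmm - t_sh) / 10)
  if (t_sh > 0) {
    pmma <- get_material("pmma")
    Tband <- Tband * exp(-lookup_mu(pmma, E, "total") * t_sh / 10)
  }
  flu <- 100 / (omega * Rmm^2)          # cm^-2 per history on the axis
  sum(w * flu * E * muen_air * Tband) * .KEV_PER_G_TO_GY
}

#' Run Monte Carlo photon transport
#'
#' Transports \code{histories} photons sampled from \code{spectrum} through
#' the scene and returns per-organ absorbed doses (kerma approximation),
#' the surface air kerma at the thyroid-position probe with its
#' provenance split (primary / backscatter from breast, support, detector and
#' body / collimator-side scatter from paddle, face shield and x-ray head /
#' collar-transmitted), the mean glandular dose tally, and per-batch energy
#' bookkeeping. All results are per simulated history; use
#' \code{\link{normalize_tallies}} to scale to a clinical protocol.
#'
#' @param scene a \code{voxel_scene}.
#' @param spectrum a \code{spectrum}.
#' @param histories number of photon histories (>= 1000).
#' @param rng_seed integer seed (recorded in the result).
#' @param options list: \code{nbatch} (default 20 batches for the standard
#'   error), \code{cutoff_keV} (5), \code{min_tally_keV} (0; probe tallies
#'   ignore photons below this energy).
#' @return object of class \code{tally_result}.
#' @export
run_transport <- function(scene, spectrum, histories = 2e5, rng_seed = 1L,
                          options = list()) {
  opt <- modifyList(list(nbatch = 20L, cutoff_keV = 5, min_tally_keV = 0),
                    options)
  if (histories < 1e3) stop("histories must be >= 1000")
  cfg <- .build_cfg(scene, spectrum, opt$cutoff_keV, opt$min_tally_keV)
  set.seed(rng_seed)
  raw <- cpp_run_transport(cfg, as.integer(histories), as.integer(opt$nbatch))
  nb <- opt$nbatch
  orgs <- cfg$organs
  arr <- raw$organ                       # [organ, class, batch], keV
  per <- raw$per_batch
  # organ masses (g): from the scene registry where available
  mass <- setNames(rep(NA_real_, length(orgs)), orgs)
  m <- match(orgs, scene$organ_table$organ)
  mass[!is.na(m)] <- scene$organ_table$mass_g[m[!is.na(m)]]
  batch_dose <- matrix(0, length(orgs), nb)
  for (b in seq_len(nb)) {
    bd <- arr[, , b, drop = FALSE]
    dim(bd) <- dim(arr)[1:2]
    batch_dose[, b] <- rowSums(bd) / per / mass * .KEV_PER_G_TO_GY
  }
  dose <- rowMeans(batch_dose)
  dose_se <- apply(batch_dose, 1, sd) / sqrt(nb)
  names(dose) <- names(dose_se) <- orgs

  # probe kerma: next-event (point-detector) scatter estimate + analytic
  # primary term
  np <- nrow(cfg$probe_points)
  probe_kerma <- probe_se <- numeric(0)
  split <- setNames(rep(0, 4),
                    c("primary", "backscatter", "collimator", "collar"))
  if (np > 0) {
    kprim <- .primary_kerma_at_probes(scene, spectrum, cfg)
    f5 <- raw$f5 / per * .KEV_PER_G_TO_GY       # [probe, class, batch] Gy
    scat_batch <- apply(f5, c(1, 3), sum)
    dim(scat_batch) <- c(np, nb)
    probe_kerma <- kprim + rowMeans(scat_batch)
    probe_se <- apply(scat_batch, 1, sd) / sqrt(nb)
    names(probe_kerma) <- names(probe_se) <- rownames(cfg$probe_points)
    si <- match(scene$surface_probe, names(probe_kerma))
    f5s <- f5[si, , , drop = FALSE]
    dim(f5s) <- c(4, nb)
    cls_tot <- rowMeans(f5s)
    cls_tot[1] <- cls_tot[1] + kprim[si]
    split <- if (sum(cls_tot) > 0) cls_tot / sum(cls_tot) else cls_tot
    names(split) <- c("primary", "backscatter", "collimator", "collar")
  }

  # MGD per history (Gy): glandular kerma averaged over the breast slab
  vol_breast <- sum(scene$grids[[1]]$labels == 2L) *
    prod(scene$grids[[1]]$vox) / 1000
  mgd_batch <- if (vol_breast > 0)
    raw$mgd / per / vol_breast * .KEV_PER_G_TO_GY else rep(NA_real_, nb)

  si <- match(scene$surface_probe, names(probe_kerma))
  structure(list(
    organ_dose = dose, organ_dose_stderr = dose_se,
    organ_mass_g = mass,
    batch_dose = batch_dose,
    probe_kerma = probe_kerma,
    probe_kerma_stderr = probe_se,
    surface_air_kerma = if (length(probe_kerma)) unname(probe_kerma[si])
                        else NA_real_,
    surface_air_kerma_stderr = if (length(probe_se)) unname(probe_se[si])
                               else NA_real_,
    provenance_split = split,
    mgd_per_history = mean(mgd_batch),
    mgd_per_history_stderr = sd(mgd_batch) / sqrt(nb),
    entrance_kerma_per_history = .entrance_kerma_per_history(scene, spectrum),
    ledger = raw$ledger,
    histories = raw$histories, per_batch = per, nbatch = nb,
    rng_seed = rng_seed,
    steps = raw$steps, real_collisions = raw$real_collisions,
    view = scene$view,
    spectrum_kvp = spectrum$kvp), class = "tally_result")
}

#' @export
print.tally_result <- function(x, ...) {
  cat(sprintf("<tally_result> %s histories (%d batches), seed %d\n",
              format(x$histories, big.mark = ","), x$nbatch, x$rng_seed))
  cat(sprintf("  surface air kerma: %.3e Gy/history (+- %.1e)\n",
              x$surface_air_kerma, x$surface_air_kerma_stderr))
  sp <- x$provenance_split
  cat(sprintf("  provenance: primary %.1f%%, backscatter %.1f%%, collimator %.1f%%, collar %.1f%%\n",
              100 * sp[1], 100 * sp[2], 100 * sp[3], 100 * sp[4]))
  invisible(x)
}

#' Per-batch energy conservation check
#'
#' @param tally a \code{tally_result}.
#' @return maximum relative imbalance |emitted - deposited - escaped -
#'   cutoff| / emitted over batches.
#' @export
energy_balance <- function(tally) {
  l <- tally$ledger
  max(abs(l[, "emitted"] - l[, "deposited"] - l[, "escaped"] - l[, "cutoff"]) /
        l[, "emitted"])
}

#' Backscatter factor above a half-space
#'
#' Ratio of the probe air kerma with the half-space (and optional overlay
#' sheet) present to the free-in-air value under the same broad parallel
#' beam. The probe tally applies an 18 keV low-energy threshold by default,
#' matching the sensitivity range of the solid-state survey dosimeters whose
#' calibration this comparison mirrors (lead L-fluorescence at ~10.5 keV is
#' invisible to them).
#'
#' @param material half-space material (e.g. muscle).
#' @param overlay optional \code{shield_spec} (< 5 mm) laid on the surface.
#' @param spectrum a \code{spectrum}.
#' @param histories histories per run.
#' @param rng_seed integer seed.
#' @param min_tally_keV probe tally threshold (default 18).
#' @return list with \code{factor}, \code{stderr}, and the two kerma values.
#' @export
backscatter_factor <- function(material, overlay = NULL, spectrum,
                               histories = 2e5, rng_seed = 1L,
                               min_tally_keV = 18) {
  if (!is.null(overlay) && overlay$thickness_mm >= 5)
    stop("overlay must be thinner than 5 mm")
  sc1 <- build_halfspace_scene(material, overlay)
  sc0 <- build_halfspace_scene(NULL, NULL)
  t1 <- run_transport(sc1, spectrum, histories, rng_seed,
                      options = list(min_tally_keV = min_tally_keV))
  t0 <- run_transport(sc0, spectrum, histories, rng_seed + 1L,
                      options = list(min_tally_keV = min_tally_keV))
  k1 <- t1$surface_air_kerma; k0 <- t0$surface_air_kerma
  f <- k1 / k0
  se <- f * sqrt((t1$surface_air_kerma_stderr / k1)^2 +
                   (t0$surface_air_kerma_stderr / k0)^2)
  list(factor = f, stderr = se, kerma = k1, kerma_free = k0,
       histories = histories, rng_seed = rng_seed)
}

#' Deterministic ray-marched attenuation through a scene
#'
#' Exact voxel traversal (Amanatides-Woo stepping) of \eqn{\exp(-\int \mu
#' dl)} along a ray, the independent oracle for the delta-tracking estimate.
#'
#' @param scene a \code{voxel_scene}.
#' @param p0 start point, mm (should lie inside the first grid).
#' @param dir unit direction.
#' @param energy photon energy, keV.
#' @return transmission probability.
#' @export
raymarch_transmission <- function(scene, p0, dir, energy) {
  g <- scene$grids[[1]]
  mats <- .scene_materials(scene)
  mu_of_label <- setNames(vapply(seq_len(nrow(scene$labels)), function(i)
    lookup_mu(mats[[scene$labels$material[i]]], energy, "total"),
    numeric(1)), scene$labels$label)
  dir <- dir / sqrt(sum(dir^2))
  p <- p0
  tau <- 0
  hi <- g$origin + g$vox * g$dim
  step_len <- min(g$vox) / 4
  repeat {
    if (any(p < g$origin) || any(p >= hi)) break
    idx <- pmin(pmax(floor((p - g$origin) / g$vox) + 1, 1), g$dim)
    lab <- g$labels[idx[1], idx[2], idx[3]]
    # distance to next voxel face along dir
    tnext <- Inf
    for (a in 1:3) {
      if (dir[a] > 1e-12)
        tnext <- min(tnext, (g$origin[a] + idx[a] * g$vox[a] - p[a]) / dir[a])
      else if (dir[a] < -1e-12)
        tnext <- min(tnext, (g$origin[a] + (idx[a] - 1) * g$vox[a] - p[a]) / dir[a])
    }
    tnext <- max(tnext, 1e-9) + 1e-9
    tau <- tau + mu_of_label[[as.character(lab)]] * tnext / 10
    p <- p + tnext * dir
  }
  exp(-tau)
}

#' Delta-tracking transmission estimate
#'
#' Monte Carlo companion of \code{\link{raymarch_transmission}}: fraction of
#' photons traversing the scene along a fixed ray without a real collision.
#'
#' @inheritParams raymarch_transmission
#' @param n number of trials.
#' @param rng_seed integer seed.
#' @return list with \code{transmission} and \code{stderr}.
#' @export
delta_transmission <- function(scene, p0, dir, energy, n = 1e5, rng_seed = 1L) {
  spec <- mono_spectrum(max(energy, 10))
  cfg <- .build_cfg(scene, spec, cutoff_keV = 5, min_tally_keV = 0)
  set.seed(rng_seed)
  dir <- dir / sqrt(sum(dir^2))
  cpp_delta_transmission(cfg, as.numeric(p0), as.numeric(dir), energy,
                         as.integer(n))
}
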