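# Stylized female voxel phantom for mammographic scatter dosimetry.
#
# Coordinates: right-handed, millimetres. z vertical (beam travels -z in the
# CC view), y anterior (+y from the chest wall plane towards the nipple),
# x lateral. Breast support plate top defines z = 0; the chest wall plane is
# y = 0. Voxels are half-open boxes [i*s, (i+1)*s); a voxel belongs to the
# shape containing its centre.

#' Compressed-breast specification
#'
#' @param compression_thickness_cm compressed thickness, 3-7 cm.
#' @param footprint_cm c(width, chest-wall-to-nipple) of the compressed slab.
#' @param composition a \code{material}; default the 3:2 fat/glandular
#'   mixture; the phantom-study configuration uses PMMA.
#' @param view "CC" or "MLO".
#' @return object of class \code{breast_spec}.
#' @export
breast_spec <- function(compression_thickness_cm = 5.5,
                        footprint_cm = c(17, 14),
                        composition = breast_material(),
                        view = c("CC", "MLO")) {
  view <- match.arg(view)
  if (compression_thickness_cm < 3 || compression_thickness_cm > 7)
    stop("compression thickness must lie in [3, 7] cm")
  stopifnot(inherits(composition, "material"))
  structure(list(thickness_mm = compression_thickness_cm * 10,
                 footprint_mm = footprint_cm * 10,
                 composition = composition, view = view),
            class = "breast_spec")
}

#' Shield specification
#'
#' @param kind "collar", "head_wall" or "dosimeter_cap".
#' @param material shield material (default lead).
#' @param thickness_mm shield thickness (> 0); the modified thyroid collar has
#'   a 0.25 mm lead equivalent.
#' @return object of class \code{shield_spec}.
#' @export
shield_spec <- function(kind = c("collar", "head_wall", "dosimeter_cap"),
                        material = get_material("lead"), thickness_mm = 0.25) {
  kind <- match.arg(kind)
  if (thickness_mm <= 0) stop("shield thickness must be positive")
  stopifnot(inherits(material, "material"))
  structure(list(kind = kind, material = material,
                 thickness_mm = thickness_mm), class = "shield_spec")
}

# organ index registry: order fixed; C++ tallies use these indices
.organ_names <- c("breast_ipsi", "breast_contra", "thyroid", "lung", "liver",
                  "stomach", "bladder", "intestine", "gonads", "oesophagus",
                  "salivary", "brain", "red_bone_marrow", "bone_surface",
                  "skin", "remainder", "probe_inner", "probe_outer")

# label table: label id -> material name, organ name (or NA), provenance
# region (1 = backscatter side: body/breast/support/detector; 2 = collimator
# side: paddle, face shield, x-ray head), breast-slab flag for the MGD tally
.label_defs <- function() {
  d <- function(label, material, organ, region, breast = FALSE)
    data.frame(label = label, material = material, organ = organ,
               region = region, breast = breast, stringsAsFactors = FALSE)
  rbind(
    d(0L,  "air",          NA,               1L),
    d(1L,  "soft_tissue",  NA,               1L),
    d(2L,  "breast_3to2",  "breast_ipsi",    1L, TRUE),
    d(3L,  "pmma",         NA,               2L),          # paddle
    d(4L,  "pmma",         NA,               1L),          # support plate
    d(5L,  "detector",     NA,               1L),
    d(6L,  "soft_tissue",  "thyroid",        1L),
    d(7L,  "bone_cortical","bone_surface",   1L),
    d(8L,  "soft_tissue",  "red_bone_marrow",1L),
    d(9L,  "lung",         "lung",           1L),
    d(10L, "soft_tissue",  "liver",          1L),
    d(11L, "soft_tissue",  "stomach",        1L),
    d(12L, "soft_tissue",  "bladder",        1L),
    d(13L, "soft_tissue",  "intestine",      1L),
    d(14L, "soft_tissue",  "gonads",         1L),
    d(15L, "soft_tissue",  "oesophagus",     1L),
    d(16L, "soft_tissue",  "salivary",       1L),
    d(17L, "soft_tissue",  "brain",          1L),
    d(18L, "soft_tissue",  "remainder",      1L),
    d(19L, "skin",         "skin",           1L),
    d(20L, "breast_3to2",  "breast_contra",  1L),
    d(21L, "air",          "probe_inner",    1L),
    d(22L, "air",          "probe_outer",    1L),
    d(23L, "air",          NA,               1L),          # collar marker
    d(24L, "pmma",         NA,               2L)           # face shield
  )
}

# rotation about the y-directed line through (x0, z0) by theta (degrees);
# used for the MLO pose of slab/paddle/support/focal spot
.mlo_rot <- function(theta_deg, x0, z0) {
  th <- theta_deg * pi / 180
  list(fwd = function(p) {
    # p: matrix n x 3 or length-3
    pm <- if (is.null(dim(p))) matrix(p, 1) else p
    dx <- pm[, 1] - x0; dz <- pm[, 3] - z0
    out <- cbind(x0 + cos(th) * dx - sin(th) * dz, pm[, 2],
                 z0 + sin(th) * dx + cos(th) * dz)
    if (is.null(dim(p))) out[1, ] else out
  }, inv = function(p) {
    pm <- if (is.null(dim(p))) matrix(p, 1) else p
    dx <- pm[, 1] - x0; dz <- pm[, 3] - z0
    out <- cbind(x0 + cos(th) * dx + sin(th) * dz, pm[, 2],
                 z0 - sin(th) * dx + cos(th) * dz)
    if (is.null(dim(p))) out[1, ] else out
  }, R = matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                3, 3))  # columns are images of the axes
}

# paint labels where pred(X, Y, Z) is TRUE, restricted to bbox (mm)
.paint <- function(grid, pred, bbox, label, only_if = NULL) {
  v <- grid$vox; o <- grid$origin; dm <- grid$dim
  i0 <- pmax(1L, floor((bbox[c(1, 3, 5)] - o) / v) + 1L)
  i1 <- pmin(dm, ceiling((bbox[c(2, 4, 6)] - o) / v))
  if (any(i0 > i1)) return(grid)
  ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
  xs <- o[1] + (ix - 0.5) * v[1]
  ys <- o[2] + (iy - 0.5) * v[2]
  zs <- o[3] + (iz - 0.5) * v[3]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  X <- array(xs, c(nx, ny, nz))
  Y <- array(rep(ys, each = nx), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  m <- pred(X, Y, Z)
  sub <- grid$labels[ix, iy, iz, drop = FALSE]
  if (!is.null(only_if)) m <- m & (sub %in% only_if)
  sub[m] <- label
  grid$labels[ix, iy, iz] <- sub
  grid
}

.in_box <- function(b) function(X, Y, Z)
  X >= b[1] & X < b[2] & Y >= b[3] & Y < b[4] & Z >= b[5] & Z < b[6]

.in_ellipsoid <- function(c0, s) function(X, Y, Z)
  ((X - c0[1]) / s[1])^2 + ((Y - c0[2]) / s[2])^2 + ((Z - c0[3]) / s[3])^2 <= 1

# z-cylinder with elliptic cross-section
.in_zcyl <- function(cx, cy, a, b, z0, z1) function(X, Y, Z)
  ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1 & Z >= z0 & Z < z1

# 6-neighbour erosion of a logical 3d array
.erode6 <- function(m) {
  d <- dim(m)
  pad <- function(a, axis, from) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (from > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
    else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  m & pad(m, 1, 1) & pad(m, 1, -1) & pad(m, 2, 1) & pad(m, 2, -1) &
    pad(m, 3, 1) & pad(m, 3, -1)
}

#' Build the stylized voxel scene
#'
#' Constructs the torso/head/thyroid phantom with a compressed breast slab,
#' compression paddle, support plate and detector slab, the lead x-ray head
#' bottom wall with beam aperture, the transparent face shield, and (optional)
#' the modified thyroid collar. Two small air probes sit at the anterior neck
#' midline at thyroid height: \code{probe_inner} directly outside the skin
#' and \code{probe_outer} in front of the collar position; with a collar
#' present the 0.25 mm lead sheet lies between them. Deterministic.
#'
#' @param breast a \code{breast_spec}.
#' @param collar optional \code{shield_spec} of kind "collar".
#' @param view "CC" or "MLO"; overrides the view in \code{breast}.
#' @param options list: \code{voxel_mm} (default 2), \code{sid_mm} (650),
#'   \code{shield} (TRUE: 2 mm PMMA face shield), \code{beam_margin} (1.08,
#'   linear over-sampling of the nominal field so that the aperture edge is
#'   irradiated), \code{mlo_angle_deg} (45), \code{fluorescence} (TRUE).
#' @return object of class \code{voxel_scene}.
#' @export
build_scene <- function(breast = breast_spec(), collar = NULL,
                        view = breast$view, options = list()) {
  opt <- modifyList(list(voxel_mm = 2, sid_mm = 650, shield = TRUE,
                         beam_margin = 1.08, mlo_angle_deg = 45,
                         fluorescence = TRUE, thyroid_area_cm2 = 4),
                    options)
  if (!is.null(collar) && collar$kind != "collar")
    stop("collar argument must be a shield_spec of kind 'collar'")
  v <- opt$voxel_mm
  C <- breast$thickness_mm
  fp <- breast$footprint_mm
  xc <- 60                                   # slab centre, lateral
  slab_x <- c(xc - fp[1] / 2, xc + fp[1] / 2)

  origin <- c(-172, -240, -300)
  extent <- c(172, 160, 416)
  dm <- as.integer(ceiling((extent - origin) / v))
  grid <- list(labels = array(0L, dm), origin = origin, vox = rep(v, 3),
               dim = dm)

  ## ---- body ----
  grid <- .paint(grid, .in_zcyl(0, -110, 170, 110, -300, 170),
                 c(-170, 170, -220, 0, -300, 170), 1L)
  grid <- .paint(grid, .in_zcyl(0, -60, 50, 50, 170, 262),
                 c(-50, 50, -110, -10, 170, 262), 1L)
  grid <- .paint(grid, .in_ellipsoid(c(0, -70, 330), c(70, 75, 85)),
                 c(-70, 70, -145, 5, 245, 415), 1L)
  # contralateral (right) breast: ellipsoid bulging through the chest wall
  grid <- .paint(grid, .in_ellipsoid(c(-85, 10, 35), c(55, 45, 40)),
                 c(-140, -30, -35, 55, -5, 75), 20L)

  ## ---- remainder proxy and internal organs (overwrite torso tissue) ----
  grid <- .paint(grid, .in_box(c(-80, 80, -120, -30, -100, -10)),
                 c(-80, 80, -120, -30, -100, -10), 18L, only_if = 1L)
  grid <- .paint(grid, .in_box(c(30, 140, -180, -40, 10, 150)),
                 c(30, 140, -180, -40, 10, 150), 9L, only_if = 1L)
  grid <- .paint(grid, .in_box(c(-140, -30, -180, -40, 10, 150)),
                 c(-140, -30, -180, -40, 10, 150), 9L, only_if = 1L)
  grid <- .paint(grid, .in_box(c(10, 140, -170, -20, -90, 0)),
                 c(10, 140, -170, -20, -90, 0), 10L, only_if = c(1L, 18L))
  grid <- .paint(grid, .in_box(c(-120, -30, -160, -30, -70, 0)),
                 c(-120, -30, -160, -30, -70, 0), 11L, only_if = c(1L, 18L))
  grid <- .paint(grid, .in_box(c(-120, 120, -180, -20, -230, -100)),
                 c(-120, 120, -180, -20, -230, -100), 13L, only_if = 1L)
  grid <- .paint(grid, .in_box(c(-40, 40, -160, -80, -280, -240)),
                 c(-40, 40, -160, -80, -280, -240), 12L, only_if = 1L)
  for (sx in c(-1, 1)) {
    b <- c(min(sx * 50, sx * 30), max(sx * 50, sx * 30),
           -140, -100, -235, -215)
    grid <- .paint(grid, .in_box(b), b, 14L, only_if = 1L)
  }
  grid <- .paint(grid, .in_box(c(-10, 10, -160, -140, 10, 170)),
                 c(-10, 10, -160, -140, 10, 170), 15L, only_if = 1L)
  for (sx in c(-1, 1))
    grid <- .paint(grid, .in_box(c(min(sx * 45, sx * 20), max(sx * 45, sx * 20),
                                   -70, -45, 240, 262)),
                   c(min(sx * 45, sx * 20), max(sx * 45, sx * 20),
                     -70, -45, 240, 262), 16L, only_if = 1L)
  grid <- .paint(grid, .in_ellipsoid(c(0, -70, 345), c(55, 60, 65)),
                 c(-55, 55, -130, -10, 280, 410), 17L, only_if = 1L)
  # spine: thoracolumbar + cervical, cortical shell with marrow core
  grid <- .paint(grid, .in_zcyl(0, -165, 16, 16, -300, 150),
                 c(-16, 16, -181, -149, -300, 150), 7L)
  grid <- .paint(grid, .in_zcyl(0, -165, 9, 9, -300, 150),
                 c(-9, 9, -174, -156, -300, 150), 8L)
  grid <- .paint(grid, .in_zcyl(0, -75, 12, 12, 150, 262),
                 c(-12, 12, -87, -63, 150, 262), 7L)
  grid <- .paint(grid, .in_zcyl(0, -75, 6, 6, 150, 262),
                 c(-6, 6, -81, -69, 150, 262), 8L)

  ## ---- slab, paddle, support, detector (posed per view) ----
  mlo <- identical(view, "MLO")
  rot <- if (mlo) .mlo_rot(opt$mlo_angle_deg, slab_x[1], 0) else NULL
  pose <- function(pred) {
    if (!mlo) return(pred)
    function(X, Y, Z) {
      n <- length(X)
      p <- rot$inv(cbind(as.vector(X), as.vector(Y), as.vector(Z)))
      array(pred(array(p[, 1], dim(X)), array(p[, 2], dim(X)),
                 array(p[, 3], dim(X))), dim(X))
    }
  }
  posed_bbox <- function(b) {
    if (!mlo) return(b)
    corners <- as.matrix(expand.grid(b[1:2], b[3:4], b[5:6]))
    cc <- rot$fwd(corners)
    c(min(cc[, 1]), max(cc[, 1]), min(cc[, 2]), max(cc[, 2]),
      min(cc[, 3]), max(cc[, 3]))
  }
  slab_box <- c(slab_x, 0, fp[2], 0, C)
  paddle_box <- c(slab_x[1] - 2, slab_x[2] + 2, 0, fp[2] + 10, C, C + 2)
  support_box <- c(xc - 110, xc + 110, 0, fp[2] + 30, -2, 0)
  det_box <- c(xc - 110, xc + 110, 0, fp[2] + 30, -6, -2)
  # imaging chain displaces air only; it must not carve into the body
  grid <- .paint(grid, pose(.in_box(slab_box)), posed_bbox(slab_box), 2L,
                 only_if = 0L)
  grid <- .paint(grid, pose(.in_box(paddle_box)), posed_bbox(paddle_box), 3L,
                 only_if = 0L)
  grid <- .paint(grid, pose(.in_box(support_box)), posed_bbox(support_box), 4L,
                 only_if = 0L)
  grid <- .paint(grid, pose(.in_box(det_box)), posed_bbox(det_box), 5L,
                 only_if = 0L)

  ## ---- skin: outermost voxel layer of the body ----
  body_labels <- c(1L, 2L, 6L:18L, 20L)
  body <- array(grid$labels %in% body_labels, dim(grid$labels))
  shell <- body & !.erode6(body)
  keep <- array(grid$labels %in% c(1L, 2L, 20L), dim(grid$labels))
  grid$labels[shell & keep] <- 19L

  ## ---- thyroid (after skin; interior by construction) ----
  for (sx in c(-1, 1))
    grid <- .paint(grid, .in_ellipsoid(c(sx * 16, -26, 200), c(9, 9, 21)),
                   c(sx * 16 - 9, sx * 16 + 9, -35, -17, 179, 221), 6L)
  grid <- .paint(grid, .in_box(c(-8, 8, -24, -16, 190, 206)),
                 c(-8, 8, -24, -16, 190, 206), 6L)

  ## ---- probes and collar marker (probe box = 2 x 2 x 1 voxels) ----
  pb <- function(ylo) c(-v, v, ylo, ylo + v, 200 - v, 200 + v)
  grid <- .paint(grid, .in_box(pb(-10)), pb(-10), 21L, only_if = 0L)
  grid <- .paint(grid, .in_box(pb(-6)), pb(-6), 22L, only_if = 0L)
  collar_box_mm <- c(-44, 44, -7.125, -6.875, 174, 254)
  if (!is.null(collar)) {
    collar_box_mm[3] <- -7 - collar$thickness_mm / 2
    collar_box_mm[4] <- -7 + collar$thickness_mm / 2
    marker <- c(-44, 44, -8, -6, 174, 254)
    grid <- .paint(grid, .in_box(marker), marker, 23L, only_if = 0L)
  }

  ## ---- beam geometry ----
  sid <- opt$sid_mm
  focal <- c(xc, 0, sid)
  nominal <- list(corner = c(slab_x[1] - 2, 0, C + 2),
                  u = c(fp[1] + 4, 0, 0), v = c(0, fp[2] + 10, 0))
  m <- opt$beam_margin
  samp <- list(corner = c(xc - (fp[1] / 2 + 2) * m, 0, C + 2),
               u = c((fp[1] + 4) * m, 0, 0), v = c(0, (fp[2] + 10) * m, 0))
  # lead x-ray head bottom wall (z in [sid-20, sid-19]) with aperture hole:
  # four boxes around the projection of the nominal field
  zw <- sid - 20
  tproj <- (sid - zw) / (sid - nominal$corner[3])
  ap_x <- focal[1] + c(nominal$corner[1] - focal[1],
                       nominal$corner[1] + nominal$u[1] - focal[1]) * tproj
  ap_y <- focal[2] + c(0, nominal$v[2]) * tproj
  wall_ext <- 120
  mkbox <- function(b) c((b[1] + b[2]) / 2, (b[3] + b[4]) / 2, (b[5] + b[6]) / 2,
                         (b[2] - b[1]) / 2, (b[4] - b[3]) / 2, (b[6] - b[5]) / 2)
  wall <- rbind(
    mkbox(c(focal[1] - wall_ext, ap_x[1], focal[2] - wall_ext,
            focal[2] + wall_ext, zw, zw + 1)),
    mkbox(c(ap_x[2], focal[1] + wall_ext, focal[2] - wall_ext,
            focal[2] + wall_ext, zw, zw + 1)),
    mkbox(c(ap_x[1], ap_x[2], focal[2] - wall_ext, ap_y[1], zw, zw + 1)),
    mkbox(c(ap_x[1], ap_x[2], ap_y[2], focal[2] + wall_ext, zw, zw + 1)))
  lead_boxes <- cbind(wall, class = 2)
  Rmat <- diag(3)
  if (mlo) {
    lead_boxes[, 1:3] <- rot$fwd(lead_boxes[, 1:3, drop = FALSE])
    focal <- rot$fwd(focal)
    for (nm in c("corner")) {
      nominal[[nm]] <- rot$fwd(nominal[[nm]])
      samp[[nm]] <- rot$fwd(samp[[nm]])
    }
    for (nm in c("u", "v")) {
      nominal[[nm]] <- as.vector(rot$R %*% nominal[[nm]])
      samp[[nm]] <- as.vector(rot$R %*% samp[[nm]])
    }
    Rmat <- rot$R
  }
  lead_R <- lapply(seq_len(nrow(lead_boxes)), function(i) Rmat)
  if (!is.null(collar)) {
    lead_boxes <- rbind(lead_boxes, c(mkbox(collar_box_mm), class = 3))
    lead_R <- c(lead_R, list(diag(3)))
  }

  ## ---- collar/beam interference check (primary field integrity) ----
  if (!is.null(collar)) {
    corners <- as.matrix(expand.grid(collar_box_mm[1:2], collar_box_mm[3:4],
                                     collar_box_mm[5:6]))
    inbeam <- apply(corners, 1, function(p) .point_in_beam(p, focal, nominal))
    if (any(inbeam))
      stop("geometry error: thyroid collar intersects the primary beam cone")
  }

  ## ---- face shield grid (2 mm PMMA slab ~50 mm downstream of the focus) ----
  grids <- list(grid)
  if (isTRUE(opt$shield)) {
    centre_rect <- nominal$corner + 0.5 * nominal$u + 0.5 * nominal$v
    axis <- centre_rect - focal; axis <- axis / sqrt(sum(axis^2))
    p50 <- focal + 50 * axis
    hw <- if (mlo) 40 else 30
    sh_origin <- c(p50[1] - hw, p50[2] - hw, p50[3] - 3)
    sh_dim <- c(2L, 2L, 6L)
    sh_vox <- c(hw, hw, 1)
    sh_lab <- array(0L, sh_dim)
    sh_lab[, , 3:4] <- 24L
    grids <- c(grids, list(list(labels = sh_lab, origin = sh_origin,
                                vox = sh_vox, dim = sh_dim)))
  }

  labels_df <- .label_defs()
  labels_df$material[labels_df$label == 2L] <- breast$composition$name
  sc <- structure(list(
    extra_materials = setNames(list(breast$composition),
                               breast$composition$name),
    grids = grids, labels = labels_df,
    focal_spot = focal, beam_rect = samp, nominal_rect = nominal,
    lead_boxes = lead_boxes, lead_R = lead_R,
    lead_material = get_material("lead"),
    fluorescence = isTRUE(opt$fluorescence),
    view = view, compression_cm = C / 10, sid_mm = sid,
    voxel_mm = v, options = opt,
    surface_probe = "probe_inner",
    probe_points = matrix(c(0, -10 + v / 2, 200,
                            0, -6 + v / 2, 200), 2, 3, byrow = TRUE,
                          dimnames = list(c("probe_inner", "probe_outer"),
                                          NULL)),
    thyroid_area_cm2 = opt$thyroid_area_cm2), class = "voxel_scene")
  sc$organ_table <- .organ_registry(sc)
  sc
}

# point inside the pyramid spanned by the focal spot and the nominal field?
.point_in_beam <- function(p, focal, rect) {
  nrm <- cross3(rect$u, rect$v)
  denom <- sum((p - focal) * nrm)
  if (abs(denom) < 1e-12) return(FALSE)
  tt <- sum((rect$corner - focal) * nrm) / denom
  if (tt <= 0) return(FALSE)      # behind the focal spot
  q <- focal + tt * (p - focal)
  rel <- q - rect$corner
  su <- sum(rel * rect$u) / sum(rect$u^2)
  sv <- sum(rel * rect$v) / sum(rect$v^2)
  su >= 0 && su <= 1 && sv >= 0 && sv <= 1
}

# per-organ voxel volume and mass bookkeeping
.organ_registry <- function(scene) {
  mats <- .scene_materials(scene)
  counts <- integer(length(.organ_names))
  names(counts) <- .organ_names
  vol_cc <- prod(scene$grids[[1]]$vox) / 1000
  lt <- scene$labels
  tab <- tabulate(scene$grids[[1]]$labels + 1L, nbins = max(lt$label) + 1L)
  dens <- vapply(lt$material, function(m) mats[[m]]$density, numeric(1))
  out <- data.frame(organ = .organ_names, volume_cc = 0, mass_g = 0)
  for (i in seq_len(nrow(lt))) {
    org <- lt$organ[i]
    if (is.na(org)) next
    n <- tab[lt$label[i] + 1L]
    j <- match(org, out$organ)
    out$volume_cc[j] <- out$volume_cc[j] + n * vol_cc
    out$mass_g[j] <- out$mass_g[j] + n * vol_cc * dens[i]
  }
  out
}

.detector_material <- function() {
  al <- get_material("aluminium")
  new_material("detector", 1.0, al$table, composition = al$composition)
}

#' Organ mass
#' @param scene a \code{voxel_scene}.
#' @param organ organ name (see \code{scene$organ_table$organ}).
#' @return mass in grams.
#' @export
organ_mass <- function(scene, organ) {
  stopifnot(inherits(scene, "voxel_scene"))
  j <- match(organ, scene$organ_table$organ)
  if (is.na(j)) stop("unknown organ '", organ, "'")
  scene$organ_table$mass_g[j]
}

#' @export
print.voxel_scene <- function(x, ...) {
  g <- x$grids[[1]]
  cat(sprintf("<voxel_scene> %s view, compression %.1f cm, voxel %g mm, grid %s\n",
              x$view, x$compression_cm, x$voxel_mm,
              paste(g$dim, collapse = "x")))
  cat(sprintf("  collar: %s, face shield: %s, SID %g mm\n",
              if (any(x$lead_boxes[, "class"] == 3)) "yes" else "no",
              if (length(x$grids) > 1) "yes" else "no", x$sid_mm))
  invisible(x)
}

#' Scene manifest
#'
#' Deterministic JSON-able summary of a scene: grid shape, per-organ voxel
#' volumes and masses, lead parts, beam geometry and the configuration hash.
#' @param scene a \code{voxel_scene}.
#' @return a list.
#' @export
scene_manifest <- function(scene) {
  cfg <- list(view = scene$view, compression_cm = scene$compression_cm,
              sid_mm = scene$sid_mm, voxel_mm = scene$voxel_mm,
              options = scene$options)
  list(grid_dim = scene$grids[[1]]$dim,
       voxel_mm = scene$voxel_mm,
       organ_table = scene$organ_table,
       lead_boxes = unname(apply(scene$lead_boxes, 1, as.list)),
       focal_spot_mm = scene$focal_spot,
       thyroid_reference_area_cm2 = scene$thyroid_area_cm2,
       config_hash = .hash_config(cfg))
}

.hash_config <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Homogeneous half-space scene for backscatter studies
#'
#' A slab of \code{material} below z = 0 (thickness \code{slab_cm}), an
#' optional overlay sheet on top, and a small free-in-air probe above the
#' surface, irradiated by a broad parallel beam travelling -z.
#'
#' @param material half-space material (NULL for free-in-air reference).
#' @param overlay optional \code{shield_spec}; lead overlays are handled
#'   analytically at true thickness, other materials are voxelised.
#' @param slab_cm slab thickness.
#' @param half_width_mm lateral half-size of slab and beam.
#' @return a \code{voxel_scene} (reduced label set).
#' @export
build_halfspace_scene <- function(material = get_material("muscle"),
                                  overlay = NULL, slab_cm = 12,
                                  half_width_mm = 140) {
  hw <- half_width_mm
  vz <- 0.5
  zlo <- -slab_cm * 10
  origin <- c(-hw, -hw, zlo)
  dm <- c(as.integer(hw), as.integer(hw), as.integer((8 - zlo) / vz))
  vox <- c(2, 2, vz)
  labs <- array(0L, dm)
  nz_slab <- as.integer(-zlo / vz)
  mat_name <- if (is.null(material)) NULL else material$name
  if (!is.null(material)) labs[, , seq_len(nz_slab)] <- 30L
  lead_boxes <- NULL; lead_R <- list()
  if (!is.null(overlay)) {
    if (overlay$material$name == "lead") {
      lead_boxes <- matrix(c(0, 0, overlay$thickness_mm / 2,
                             hw, hw, overlay$thickness_mm / 2, 3), 1)
      colnames(lead_boxes) <- c("cx", "cy", "cz", "hx", "hy", "hz", "class")
      lead_R <- list(diag(3))
    } else {
      n_ov <- as.integer(round(overlay$thickness_mm / vz))
      labs[, , nz_slab + seq_len(n_ov)] <- 31L
    }
  }
  # probe: thin air box just above the surface/overlay
  zp <- as.integer((4 - zlo) / vz)
  ip <- (dm[1] %/% 2) + (-2:2); jp <- (dm[2] %/% 2) + (-2:2)
  labs[ip, jp, zp + 0:1] <- 32L
  ldf <- rbind(
    data.frame(label = 0L, material = "air", organ = NA, region = 1L,
               breast = FALSE, stringsAsFactors = FALSE),
    if (!is.null(mat_name))
      data.frame(label = 30L, material = mat_name, organ = NA, region = 1L,
                 breast = FALSE, stringsAsFactors = FALSE),
    if (!is.null(overlay) && overlay$material$name != "lead")
      data.frame(label = 31L, material = overlay$material$name, organ = NA,
                 region = 1L, breast = FALSE, stringsAsFactors = FALSE),
    data.frame(label = 32L, material = "air", organ = "probe_inner",
               region = 1L, breast = FALSE, stringsAsFactors = FALSE))
  beam_hw <- hw - 20
  structure(list(
    grids = list(list(labels = labs, origin = origin, vox = vox, dim = dm)),
    labels = ldf,
    focal_spot = c(0, 0, 1000),
    beam_rect = list(corner = c(-beam_hw, -beam_hw, 20),
                     u = c(2 * beam_hw, 0, 0), v = c(0, 2 * beam_hw, 0)),
    nominal_rect = NULL,
    parallel_dir = c(0, 0, -1),
    lead_boxes = lead_boxes, lead_R = lead_R,
    lead_material = get_material("lead"),
    fluorescence = TRUE,
    view = "halfspace", compression_cm = NA, sid_mm = NA,
    voxel_mm = 2, options = list(),
    surface_probe = "probe_inner",
    probe_points = matrix(c(0, 0, 4.5), 1, 3,
                          dimnames = list("probe_inner", NULL)),
    organ_table = {
      vol <- length(ip) * length(jp) * 2 * prod(vox) / 1000
      data.frame(organ = "probe_inner", volume_cc = vol,
                 mass_g = vol * get_material("air")$density)
    }), class = "voxel_scene")
}

#' Homogeneous box scene (QA geometries)
#'
#' A box of one material with an optional thin scoring layer at depth, used
#' for analytic-attenuation and estimator checks with a narrow parallel beam.
#'
#' @param material box material.
#' @param size_mm c(x, y, z) box size.
#' @param voxel_mm voxel size.
#' @param score_depth_mm optional depth (from the +z entry face) of a 1-voxel
#'   scoring layer tallied as \code{probe_inner}.
#' @return a \code{voxel_scene}.
#' @export
build_box_scene <- function(material = get_material("water"),
                            size_mm = c(60, 60, 100), voxel_mm = 2,
                            score_depth_mm = NULL) {
  dm <- as.integer(round(size_mm / voxel_mm))
  labs <- array(30L, dm)
  ldf <- rbind(
    data.frame(label = 0L, material = "air", organ = NA, region = 1L,
               breast = FALSE, stringsAsFactors = FALSE),
    data.frame(label = 30L, material = material$name, organ = NA, region = 1L,
               breast = FALSE, stringsAsFactors = FALSE))
  if (!is.null(score_depth_mm)) {
    k <- dm[3] - as.integer(round(score_depth_mm / voxel_mm))
    labs[, , k] <- 32L
    ldf <- rbind(ldf, data.frame(label = 32L, material = material$name,
                                 organ = "probe_inner", region = 1L,
                                 breast = FALSE, stringsAsFactors = FALSE))
  }
  origin <- c(-size_mm[1] / 2, -size_mm[2] / 2, -size_mm[3])
  structure(list(
    grids = list(list(labels = labs, origin = origin,
                      vox = rep(voxel_mm, 3), dim = dm)),
    labels = ldf,
    focal_spot = c(0, 0, 500),
    beam_rect = list(corner = c(-2, -2, 2), u = c(4, 0, 0), v = c(0, 4, 0)),
    nominal_rect = NULL,
    parallel_dir = c(0, 0, -1),
    lead_boxes = NULL, lead_R = list(),
    lead_material = get_material("lead"),
    fluorescence = TRUE,
    view = "box", compression_cm = NA, sid_mm = NA,
    voxel_mm = voxel_mm, options = list(),
    surface_probe = "probe_inner",
    organ_table = {
      vol <- if (is.null(score_depth_mm)) NA_real_ else
        dm[1] * dm[2] * voxel_mm^3 / 1000
      data.frame(organ = "probe_inner", volume_cc = vol,
                 mass_g = vol * material$density)
    }), class = "voxel_scene")
}
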