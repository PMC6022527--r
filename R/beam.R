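#' Tube setting
#'
#' Describes the x-ray tube configuration: peak voltage, anode angle,
#' added filtration and the tube current-time product (mAs). The mAs value
#' only enters as a linear normalisation of emitted photon count; dose
#' normalisation in this package is by entrance kerma, so mAs is carried for
#' bookkeeping.
#'
#' @param kvp peak tube voltage, kV (typical mammographic range 26-35).
#' @param anode_angle_deg anode inclination, degrees.
#' @param filtration list of \code{list(material, thickness_mm)}; default
#'   50 um rhodium.
#' @param anode_self_filtration_um effective tungsten path (um) hardening the
#'   raw bremsstrahlung before the added filtration. The default 3 um puts
#'   the 28 kVp W/Rh half-value layer at ~0.51 mm Al, the published beam
#'   quality of this anode/filter combination; 0 disables it.
#' @param mas tube current-time product, mA s.
#' @return object of class \code{tube_setting}.
#' @export
tube_setting <- function(kvp = 28, anode_angle_deg = 20,
                         filtration = list(list(get_material("rhodium"), 0.050)),
                         anode_self_filtration_um = 3,
                         mas = 100) {
  if (!is.numeric(kvp) || kvp < 20 || kvp > 40)
    stop("kvp must lie in [20, 40] kV")
  if (anode_self_filtration_um < 0)
    stop("anode self-filtration must be >= 0")
  for (f in filtration) {
    stopifnot(inherits(f[[1]], "material"))
    if (f[[2]] < 0) stop("filtration thickness must be >= 0")
  }
  structure(list(kvp = kvp, anode_angle_deg = anode_angle_deg,
                 filtration = filtration,
                 anode_self_filtration_um = anode_self_filtration_um,
                 mas = mas),
            class = "tube_setting")
}

#' Generate a filtered bremsstrahlung spectrum
#'
#' Kramers-form unfiltered fluence \eqn{N(E) \propto (kVp - E)/E}, integrated
#' over 0.25 keV bins from 8 keV (tube window filtration truncates the band
#' below 8 keV) to kVp, attenuated through each added filtration layer by
#' \eqn{\exp(-\mu(E) t)} and renormalised to unit sum. Optional tungsten
#' L-lines (8.40, 9.67 keV) can be added; they are off by default because the
#' rhodium filter suppresses them almost completely.
#'
#' @param setting a \code{tube_setting}.
#' @param bin_keV bin width, keV (<= 0.25).
#' @param w_lines logical; add W L-line delta contributions.
#' @param line_fraction unfiltered fluence fraction assigned to the L-lines
#'   when \code{w_lines} is TRUE.
#' @return object of class \code{spectrum}: \code{energy_bins} (bin centres,
#'   keV), \code{fluence_weights} (sum 1), \code{kvp}.
#' @export
generate_spectrum <- function(setting, bin_keV = 0.25, w_lines = FALSE,
                              line_fraction = 0.05) {
  stopifnot(inherits(setting, "tube_setting"))
  kvp <- setting$kvp
  if (kvp <= 8) stop("kvp below the 8 keV spectral cutoff")
  edges <- seq(8, kvp, by = bin_keV)
  if (edges[length(edges)] < kvp) edges <- c(edges, kvp)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  centre <- (lo + hi) / 2
  # integral of (kvp - E)/E over the bin
  w <- kvp * log(hi / lo) - (hi - lo)
  if (w_lines) {
    for (el in c(8.40, 9.67)) {
      i <- findInterval(el, edges, rightmost.closed = TRUE)
      if (i >= 1 && i <= length(w))
        w[i] <- w[i] + line_fraction / 2 * sum(w)
    }
  }
  tsf <- setting$anode_self_filtration_um %||% 0
  if (tsf > 0) {
    wmat <- get_material("tungsten")
    w <- w * exp(-lookup_mu(wmat, centre, "total") * tsf * 1e-4)
  }
  for (f in setting$filtration) {
    t_cm <- f[[2]] / 10
    if (t_cm > 0) w <- w * exp(-lookup_mu(f[[1]], centre, "total") * t_cm)
  }
  w[w < 0] <- 0
  s <- sum(w)
  if (s <= 0) stop("spectrum empty after filtration")
  structure(list(energy_bins = centre, bin_width = hi - lo,
                 fluence_weights = w / s, kvp = kvp,
                 mas = setting$mas),
            class = "spectrum")
}

#' Monoenergetic pseudo-spectrum
#' @param energy line energy, keV.
#' @return a \code{spectrum} with a single populated bin.
#' @export
mono_spectrum <- function(energy) {
  structure(list(energy_bins = energy, bin_width = 0,
                 fluence_weights = 1, kvp = energy, mas = 1),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> kVp = %g, %d bins, mean energy %.2f keV\n",
              x$kvp, length(x$energy_bins), mean_energy(x)))
  invisible(x)
}

#' Fluence-weighted mean energy of a spectrum
#' @param spectrum a \code{spectrum}.
#' @return keV.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$energy_bins * spectrum$fluence_weights) /
    sum(spectrum$fluence_weights)
}

# spectrum-weighted air-kerma transmission through thickness t_mm of material
.kerma_transmission <- function(spectrum, material, t_mm) {
  E <- spectrum$energy_bins
  w <- spectrum$fluence_weights
  air <- get_material("air")
  k <- w * E * loglog_interp(air$table$energy_keV, air$table$muen, E)
  mu <- lookup_mu(material, E, "total")
  sum(k * exp(-mu * t_mm / 10)) / sum(k)
}

#' Half-value layer
#'
#' Absorber thickness that halves the spectrum-weighted air kerma, found by
#' bisection to 1e-4 mm. Scale-invariant in the spectrum weights.
#'
#' @param spectrum a \code{spectrum}.
#' @param material absorber (default aluminium).
#' @return thickness in mm.
#' @export
half_value_layer <- function(spectrum, material = get_material("aluminium")) {
  f <- function(t) .kerma_transmission(spectrum, material, t) - 0.5
  lo <- 0; hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e4) stop("half_value_layer: bisection failed to bracket")
  }
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# uniform sampling inside the spherical cap around axis `a` with cos >= cmin
.sample_cap <- function(n, a, cmin) {
  cz <- cmin + runif(n) * (1 - cmin)
  phi <- 2 * pi * runif(n)
  st <- sqrt(pmax(0, 1 - cz^2))
  d <- cbind(st * cos(phi), st * sin(phi), cz)
  # rotate z-axis onto a
  rotate_to_axis(d, a)
}

rotate_to_axis <- function(d, a) {
  a <- a / sqrt(sum(a^2))
  if (abs(a[3]) > 0.999999) {
    if (a[3] > 0) return(d)
    return(cbind(d[, 1], -d[, 2], -d[, 3]))
  }
  # Rodrigues rotation taking (0,0,1) to a
  v <- c(-a[2], a[1], 0); s <- sqrt(sum(v^2)); cth <- a[3]
  v <- v / s
  k <- 1 - cth
  R <- matrix(c(
    cth + v[1]^2 * k,  v[1] * v[2] * k,  s * v[2],
    v[1] * v[2] * k,   cth + v[2]^2 * k, -s * v[1],
    -s * v[2],         s * v[1],         cth), 3, 3, byrow = TRUE)
  d %*% t(R)
}

#' Sample source photons
#'
#' Draws photon energies from the spectrum and directions uniformly over the
#' solid angle subtended by the scene's sampled beam rectangle from the focal
#' spot (rejection against the bounding spherical cap). Reproducible for a
#' fixed seed.
#'
#' @param spectrum a \code{spectrum}.
#' @param n number of photons (> 0).
#' @param scene a \code{voxel_scene} (supplies focal spot and beam rectangle).
#' @param rng_seed integer seed.
#' @return data.frame with columns x, y, z (mm), dx, dy, dz, energy_keV,
#'   weight.
#' @export
sample_source_photons <- function(spectrum, n, scene, rng_seed = 1L) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive")
  n <- as.integer(n)
  set.seed(rng_seed)
  E <- sample(spectrum$energy_bins, n, replace = TRUE,
              prob = spectrum$fluence_weights)
  jit <- (runif(n) - 0.5) * rep(spectrum$bin_width, length.out = length(spectrum$energy_bins))[
    match(E, spectrum$energy_bins)]
  E <- E + jit
  f <- scene$focal_spot
  r <- scene$beam_rect      # list(corner, u, v): corner + s*u + t*v, s,t in [0,1]
  corners <- rbind(r$corner, r$corner + r$u, r$corner + r$v, r$corner + r$u + r$v)
  centre <- r$corner + 0.5 * r$u + 0.5 * r$v
  axis <- centre - f
  axis <- axis / sqrt(sum(axis^2))
  cmin <- min(apply(corners, 1, function(p) {
    d <- p - f; sum(d * axis) / sqrt(sum(d^2))
  }))
  # padding so the cap strictly contains the rectangle
  cmin <- max(-1, 1 - (1 - cmin) * 1.05)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    d <- .sample_cap(2L * (n - nrow(out)) + 16L, axis, cmin)
    # keep those whose ray crosses the rectangle
    nrm <- cross3(r$u, r$v)
    tt <- as.numeric(((centre - f) %*% nrm)) / as.numeric(d %*% nrm)
    hit <- tt > 0
    p <- f + d * tt
    rel <- sweep(p, 2, r$corner)
    su <- as.numeric(rel %*% r$u) / sum(r$u^2)
    sv <- as.numeric(rel %*% r$v) / sum(r$v^2)
    keep <- hit & su >= 0 & su <= 1 & sv >= 0 & sv <= 1
    out <- rbind(out, d[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  data.frame(x = f[1], y = f[2], z = f[3],
             dx = out[, 1], dy = out[, 2], dz = out[, 3],
             energy_keV = E, weight = 1)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# analytic solid angle of a planar rectangle seen from a point (sum over the
# four corner sub-rectangles after projecting the point onto the plane)
solid_angle_rect <- function(point, rect) {
  nrm <- cross3(rect$u, rect$v)
  nrm <- nrm / sqrt(sum(nrm^2))
  d <- abs(sum((rect$corner - point) * nrm))
  # in-plane coordinates of the projected point
  eu <- rect$u / sqrt(sum(rect$u^2)); ev <- rect$v / sqrt(sum(rect$v^2))
  rel <- point - rect$corner
  pu <- sum(rel * eu); pv <- sum(rel * ev)
  Lu <- sqrt(sum(rect$u^2)); Lv <- sqrt(sum(rect$v^2))
  corner_sa <- function(a, b, d) {
    atan(a * b / (d * sqrt(a^2 + b^2 + d^2)))
  }
  sgn <- function(x) if (x >= 0) 1 else -1
  # decompose into four signed corner rectangles
  a1 <- pu; a2 <- Lu - pu; b1 <- pv; b2 <- Lv - pv
  sa <- 0
  for (a in list(c(a1, 1), c(a2, 1))) for (b in list(c(b1, 1), c(b2, 1))) {
    aa <- a[1]; bb <- b[1]
    sa <- sa + sgn(aa) * sgn(bb) * corner_sa(abs(aa), abs(bb), d)
  }
  sa
}
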