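# Normalisation of raw Monte Carlo tallies to clinical exposure quantities,
# ICRP 103 effective dose, and the worked-example conversion factors.

#' ICRP 103 tissue weighting factors
#'
#' The 13 remainder tissues are represented by the phantom's single
#' remainder-proxy organ carrying the full remainder weight (arithmetic-mean
#' rule collapses to the proxy mean dose). Weights sum to 1.
#' @return named numeric vector.
#' @export
icrp103_weights <- function() {
  c(breast = 0.12, red_bone_marrow = 0.12, colon = 0.12, lung = 0.12,
    stomach = 0.12, gonads = 0.08, bladder = 0.04, oesophagus = 0.04,
    liver = 0.04, thyroid = 0.04, bone_surface = 0.01, brain = 0.01,
    salivary = 0.01, skin = 0.01, remainder = 0.12)
}

# scene organ -> ICRP 103 tissue
.icrp_map <- c(thyroid = "thyroid", lung = "lung", liver = "liver",
               stomach = "stomach", bladder = "bladder",
               intestine = "colon", gonads = "gonads",
               oesophagus = "oesophagus", salivary = "salivary",
               brain = "brain", red_bone_marrow = "red_bone_marrow",
               bone_surface = "bone_surface", skin = "skin",
               remainder = "remainder")

#' Exposure protocol
#'
#' A two-view bilateral mammography is 4 exposures (CC and MLO of each
#' breast). Entrance dose is the free-in-air air kerma per view at the
#' paddle-entrance reference point on the beam axis.
#'
#' @param views data.frame with columns \code{view} ("CC"/"MLO"),
#'   \code{side} ("left"/"right"), \code{entrance_mGy}; default 4 views at
#'   3.6 mGy each.
#' @param kvp tube voltage for bookkeeping.
#' @param mgd_per_view_mGy optional nominal MGD anchor (0.9 mGy for a CC
#'   view), carried as metadata.
#' @return object of class \code{exposure_protocol}.
#' @export
exposure_protocol <- function(views = NULL, kvp = 28, mgd_per_view_mGy = 0.9) {
  if (is.null(views))
    views <- data.frame(view = c("CC", "MLO", "CC", "MLO"),
                        side = c("left", "left", "right", "right"),
                        entrance_mGy = 3.6)
  if (nrow(views) > 0 && any(views$entrance_mGy <= 0))
    stop("entrance dose per view must be positive")
  structure(list(views = views, kvp = kvp,
                 mgd_per_view_mGy = mgd_per_view_mGy),
            class = "exposure_protocol")
}

#' Normalise tallies to a protocol
#'
#' Scales per-history organ doses so the simulated free-in-air entrance kerma
#' at the paddle-entrance reference point equals the protocol's entrance dose
#' for each view, and sums over all exposures. Right-breast exposures reuse
#' the left-breast tallies by mirror symmetry (ipsilateral and contralateral
#' breast doses swapped, midline organs unchanged); the output records this.
#'
#' ICRP tissue-equivalent doses are the phantom organ doses, with one
#' correction: the skin equivalent dose is the phantom skin energy averaged
#' over the reference person's whole-body skin mass (ICRP 89 adult female,
#' 2300 g), since the stylized phantom carries no limb skin and its partial
#' shell would otherwise overstate the mass-averaged skin dose.
#'
#' @param tallies named list of \code{tally_result} per view (e.g.
#'   \code{list(CC = ..., MLO = ...)}); a single \code{tally_result} is
#'   accepted and reused for every view.
#' @param protocol an \code{exposure_protocol}.
#' @param scene the \code{voxel_scene} the tallies were computed on.
#' @param reference_skin_mass_g whole-body skin mass used for the skin
#'   equivalent dose (default 2300 g).
#' @return object of class \code{organ_dose_table}: data.frame of ICRP organ
#'   doses in uGy for the whole protocol, with the breast entry the mean
#'   glandular dose over both breasts; attributes carry the surface air kerma
#'   at thyroid position, provenance split, and per-view MGD.
#' @export
normalize_tallies <- function(tallies, protocol, scene,
                              reference_skin_mass_g = 2300) {
  stopifnot(inherits(protocol, "exposure_protocol"))
  if (inherits(tallies, "tally_result")) {
    tallies <- list(CC = tallies, MLO = tallies)
  }
  views <- protocol$views
  organs <- union(unname(.icrp_map), c("breast"))
  dose <- setNames(numeric(length(organs)), organs)
  var_ <- dose
  surface <- 0; surface_var <- 0
  H_left <- 0; H_right <- 0
  mgd_view <- c()
  prov_acc <- numeric(4)
  if (nrow(views) == 0)
    return(.organ_dose_table(dose, sqrt(var_), 0, 0, numeric(4), numeric(0),
                             protocol))
  for (i in seq_len(nrow(views))) {
    v <- views$view[i]
    tl <- tallies[[v]]
    if (is.null(tl)) stop("no tally supplied for view ", v)
    kref <- tl$entrance_kerma_per_history
    if (!is.finite(kref) || kref <= 0)
      stop("tally lacks the entrance reference kerma")
    fac <- views$entrance_mGy[i] * 1e-3 / kref       # effective histories
    for (org in names(.icrp_map)) {
      if (!org %in% names(tl$organ_dose)) next
      icrp <- .icrp_map[[org]]
      dose[icrp] <- dose[icrp] + tl$organ_dose[[org]] * fac * 1e6
      var_[icrp] <- var_[icrp] + (tl$organ_dose_stderr[[org]] * fac * 1e6)^2
    }
    surface <- surface + tl$surface_air_kerma * fac * 1e6
    surface_var <- surface_var + (tl$surface_air_kerma_stderr * fac * 1e6)^2
    prov_acc <- prov_acc + tl$provenance_split * tl$surface_air_kerma * fac
    mgd_i <- tl$mgd_per_history * fac * 1e3          # mGy
    contra_i <- tl$organ_dose[["breast_contra"]] * fac * 1e3
    if (views$side[i] == "left") {
      H_left <- H_left + mgd_i
      H_right <- H_right + contra_i
    } else {
      H_right <- H_right + mgd_i
      H_left <- H_left + contra_i
    }
    mgd_view <- c(mgd_view, setNames(mgd_i, paste0(v, "_", views$side[i])))
  }
  dose["breast"] <- mean(c(H_left, H_right)) * 1e3   # mGy -> uGy
  skin_m <- organ_mass(scene, "skin")
  if (is.finite(skin_m) && reference_skin_mass_g > 0) {
    sc_f <- min(1, skin_m / reference_skin_mass_g)
    dose["skin"] <- dose["skin"] * sc_f
    var_["skin"] <- var_["skin"] * sc_f^2
  }
  prov <- if (sum(prov_acc) > 0) prov_acc / sum(prov_acc) else prov_acc
  names(prov) <- c("primary", "backscatter", "collimator", "collar")
  .organ_dose_table(dose, sqrt(var_), surface, sqrt(surface_var), prov,
                    mgd_view, protocol)
}

.organ_dose_table <- function(dose, se, surface, surface_se, prov, mgd_view,
                              protocol) {
  df <- data.frame(organ = names(dose), dose_uGy = unname(dose),
                   stderr_uGy = unname(se))
  structure(df, class = c("organ_dose_table", "data.frame"),
            surface_air_kerma_uGy = surface,
            surface_air_kerma_stderr_uGy = surface_se,
            provenance_split = prov,
            mgd_per_view_mGy = mgd_view,
            protocol = protocol,
            sides_by_symmetry = TRUE,
            weights_version = "ICRP103")
}

#' Effective dose (ICRP 103)
#'
#' \eqn{E = \sum_T w_T H_T} with the embedded ICRP 103 weights applied to the
#' organ-dose table (photon radiation weighting factor 1, so H_T equals the
#' absorbed organ dose). Organs absent from the table are zero-filled with a
#' warning.
#'
#' @param table an \code{organ_dose_table} (doses in uGy).
#' @return list: \code{effective_uSv}, \code{contributions} (percent by
#'   tissue, summing to 100), \code{weights_version}.
#' @export
effective_dose <- function(table) {
  w <- icrp103_weights()
  H <- setNames(numeric(length(w)), names(w))
  m <- match(table$organ, names(w))
  if (any(table$dose_uGy < 0)) stop("negative organ dose")
  H[m[!is.na(m)]] <- table$dose_uGy[!is.na(m)]
  missing <- names(w)[!names(w) %in% table$organ]
  if (length(missing))
    warning("tissues absent from table, zero-filled: ",
            paste(missing, collapse = ", "))
  E <- sum(w * H)                     # uGy ~ uSv for photons
  contrib <- if (E > 0) 100 * w * H / E else w * 0
  list(effective_uSv = E, contributions_percent = contrib,
       weights_version = "ICRP103")
}

#' Mean glandular dose estimate
#'
#' MGD for a single view: the breast-slab glandular kerma tally (homogeneous
#' 3:2 fat/glandular mixture, glandular mass-energy-absorption weighting)
#' normalised to the view's entrance dose.
#'
#' @param tally a \code{tally_result} with a breast slab in its scene.
#' @param entrance_mGy entrance free-in-air kerma for the view (default the
#'   patient-study average, 3.6 mGy).
#' @return MGD in mGy.
#' @export
mgd_estimate <- function(tally, entrance_mGy = 3.6) {
  if (!is.finite(tally$mgd_per_history) || tally$mgd_per_history <= 0)
    stop("tally has no glandular mass / breast slab")
  kref <- tally$entrance_kerma_per_history
  if (!is.finite(kref) || kref <= 0)
    stop("tally lacks the entrance reference kerma")
  tally$mgd_per_history * entrance_mGy * 1e-3 / kref * 1e3
}

#' Measurement-to-simulation conversion factor
#'
#' Plain ratio of a measured to a simulated surface air kerma, used to scale
#' simulated organ doses to the measured exposure level.
#'
#' @param surface_measured measured surface kerma (uGy).
#' @param surface_mcs simulated surface kerma (uGy).
#' @param stderr_measured,stderr_mcs optional standard errors.
#' @return list: \code{factor}, \code{stderr}.
#' @export
conversion_factor <- function(surface_measured, surface_mcs,
                              stderr_measured = 0, stderr_mcs = 0) {
  if (surface_measured <= 0 || surface_mcs <= 0)
    stop("kerma values must be positive")
  f <- surface_measured / surface_mcs
  se <- f * sqrt((stderr_measured / surface_measured)^2 +
                   (stderr_mcs / surface_mcs)^2)
  list(factor = f, stderr = se)
}

#' Scale a simulated thyroid dose by a conversion factor
#' @param thyroid_mcs_uGy simulated thyroid dose (uGy).
#' @param factor conversion factor (list from \code{conversion_factor} or a
#'   number).
#' @param stderr_thyroid optional standard error of the thyroid dose.
#' @return list: \code{dose_uGy}, \code{stderr}.
#' @export
scaled_thyroid_dose <- function(thyroid_mcs_uGy, factor, stderr_thyroid = 0) {
  fse <- 0
  if (is.list(factor)) { fse <- factor$stderr; factor <- factor$factor }
  if (thyroid_mcs_uGy <= 0 || factor <= 0) stop("inputs must be positive")
  d <- thyroid_mcs_uGy * factor
  se <- d * sqrt((fse / factor)^2 +
                   (stderr_thyroid / thyroid_mcs_uGy)^2)
  list(dose_uGy = d, stderr = se)
}

#' Effective-dose increase when scaling all non-breast organ doses
#'
#' Multiplies every organ dose except the directly irradiated breast by
#' \code{factor} and reports the percent increase of the effective dose.
#' Closed form: \eqn{100 (factor - 1)(1 - f_{breast})} with \eqn{f_{breast}}
#' the breast contribution fraction.
#'
#' @param table an \code{organ_dose_table}.
#' @param factor scaling factor (> 0).
#' @return percent increase.
#' @export
scaled_effective_dose_increase <- function(table, factor) {
  if (factor <= 0) stop("factor must be positive")
  e0 <- effective_dose(table)
  t2 <- table
  nb <- t2$organ != "breast"
  t2$dose_uGy[nb] <- t2$dose_uGy[nb] * factor
  e1 <- effective_dose(t2)
  100 * (e1$effective_uSv - e0$effective_uSv) / e0$effective_uSv
}
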