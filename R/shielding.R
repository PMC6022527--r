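# Analytic narrow-beam (Beer-Lambert) shielding transmission.

#' Monoenergetic narrow-beam transmission
#'
#' \eqn{T = \exp(-\mu(E) t)} through the shield, no buildup (narrow-beam
#' geometry; broad-beam effects are covered by the Monte Carlo collar runs).
#'
#' @param shield a \code{shield_spec}.
#' @param energy photon energy, keV (vectorised).
#' @return transmission in [0, 1].
#' @export
transmission <- function(shield, energy) {
  stopifnot(inherits(shield, "shield_spec"))
  exp(-lookup_mu(shield$material, energy, "total") * shield$thickness_mm / 10)
}

#' Spectrum-weighted shield transmission
#'
#' \eqn{T = \sum_i w_i q_i e^{-\mu(E_i) t} / \sum_i w_i q_i} with
#' \eqn{q_i = 1} for fluence weighting or \eqn{q_i = E_i \mu_{en,air}(E_i)/\rho}
#' for air-kerma weighting. Bounded between the monoenergetic transmissions at
#' the populated bins.
#'
#' @param shield a \code{shield_spec}.
#' @param spectrum a \code{spectrum}.
#' @param weighting "air-kerma" (default) or "fluence".
#' @return transmission in [0, 1].
#' @export
spectrum_transmission <- function(shield, spectrum,
                                  weighting = c("air-kerma", "fluence")) {
  weighting <- match.arg(weighting)
  E <- spectrum$energy_bins
  w <- spectrum$fluence_weights
  q <- if (weighting == "fluence") rep(1, length(E)) else {
    air <- get_material("air")
    E * loglog_interp(air$table$energy_keV, air$table$muen, E)
  }
  Tm <- transmission(shield, E)
  sum(w * q * Tm) / sum(w * q)
}
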