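# Orchestration: scenario pipelines reproducing the study's experiments,
# with provenance-stamped result bundles.

#' Run configuration
#'
#' @param scenario one of "paper-mcs-28", "paper-mcs-35", "phantom-sweep",
#'   "collar-study", "cohort-stats".
#' @param seed integer seed recorded in every output.
#' @param histories photon histories per transport run.
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV/JSON with a provenance manifest.
#' @param overrides named list of module overrides (compression_cm,
#'   entrance_mGy, collar_thickness_mm, cohort config fields, ...).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(scenario = c("paper-mcs-28", "paper-mcs-35",
                                    "phantom-sweep", "collar-study",
                                    "cohort-stats"),
                       seed = 1L, histories = 4e5, out_dir = NULL,
                       overrides = list()) {
  scenario <- match.arg(scenario)
  structure(list(scenario = scenario, seed = as.integer(seed),
                 histories = histories, out_dir = out_dir,
                 overrides = overrides), class = "run_config")
}

# one full simulated protocol at a given kVp: CC + MLO transports,
# normalisation, effective dose and contribution table
.simulate_protocol <- function(kvp, histories, seed, overrides = list()) {
  Ccc <- overrides$compression_cc_cm %||% 5.6
  Cml <- overrides$compression_mlo_cm %||% 5.6
  entrance <- overrides$entrance_mGy %||% 3.6
  spec <- generate_spectrum(tube_setting(kvp = kvp))
  sc_cc <- build_scene(breast_spec(Ccc), view = "CC")
  sc_ml <- build_scene(breast_spec(Cml), view = "MLO")
  t_cc <- run_transport(sc_cc, spec, histories, seed)
  t_ml <- run_transport(sc_ml, spec, histories, seed + 1L)
  proto <- exposure_protocol(
    views = data.frame(view = c("CC", "MLO", "CC", "MLO"),
                       side = c("left", "left", "right", "right"),
                       entrance_mGy = entrance),
    kvp = kvp)
  tab <- normalize_tallies(list(CC = t_cc, MLO = t_ml), proto, sc_cc)
  ed <- effective_dose(tab)
  sp <- attr(tab, "provenance_split")
  scat <- sp[c("backscatter", "collimator", "collar")]
  list(kvp = kvp,
       tallies = list(CC = t_cc, MLO = t_ml),
       scene = sc_cc,
       organ_dose_table = tab,
       effective_uSv = ed$effective_uSv,
       contributions_percent = ed$contributions_percent,
       surface_air_kerma_uGy = attr(tab, "surface_air_kerma_uGy"),
       surface_air_kerma_stderr_uGy = attr(tab, "surface_air_kerma_stderr_uGy"),
       thyroid_uGy = tab$dose_uGy[tab$organ == "thyroid"],
       thyroid_stderr_uGy = tab$stderr_uGy[tab$organ == "thyroid"],
       mgd_per_view_mGy = attr(tab, "mgd_per_view_mGy"),
       provenance_split = sp,
       backscatter_share_of_scatter = unname(scat["backscatter"] / sum(scat)),
       effective_increase_factor_2p3_percent =
         scaled_effective_dose_increase(tab, 2.3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario
#'
#' \describe{
#' \item{paper-mcs-28 / paper-mcs-35}{Full simulated two-view bilateral
#'   protocol at 28 or 35 kV: surface kerma at thyroid position, thyroid
#'   dose, effective dose with per-organ contributions, scatter provenance
#'   split, and the sensitivity of the surface kerma to the unprinted
#'   phantom geometry (reported, not assumed).}
#' \item{phantom-sweep}{Transport at compressions 3-7 cm, exponential fit of
#'   the surface kerma against compression.}
#' \item{collar-study}{Protocol with and without the 0.25 mm collar;
#'   inside/outside kerma at the neck probes.}
#' \item{cohort-stats}{Synthetic cohort generation plus the full statistics
#'   pipeline.}}
#'
#' @param config a \code{run_config}.
#' @return result bundle (list) with a provenance manifest; files are
#'   written when \code{out_dir} is set.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  ov <- config$overrides
  res <- switch(config$scenario,
    "paper-mcs-28" = .simulate_protocol(28, config$histories, seed, ov),
    "paper-mcs-35" = .simulate_protocol(35, config$histories, seed, ov),
    "phantom-sweep" = {
      spec <- generate_spectrum(tube_setting(kvp = ov$kvp %||% 30))
      comps <- ov$compressions_cm %||% c(3, 4, 5, 6, 7)
      per <- max(5e4, round(config$histories / length(comps)))
      rows <- lapply(seq_along(comps), function(i) {
        sc <- build_scene(breast_spec(comps[i],
                                      composition = get_material("pmma")),
                          view = "CC")
        tl <- run_transport(sc, spec, per, seed + i)
        k <- tl$surface_air_kerma / tl$entrance_kerma_per_history * 3.6e-3 * 1e6
        data.frame(compression_cm = comps[i], surface_kerma_uGy_per_view = k)
      })
      sweep <- do.call(rbind, rows)
      fit <- fit_exponential(sweep$compression_cm,
                             sweep$surface_kerma_uGy_per_view)
      list(sweep = sweep, fit = fit)
    },
    "collar-study" = {
      spec <- generate_spectrum(tube_setting(kvp = ov$kvp %||% 28))
      collar <- shield_spec("collar",
                            thickness_mm = ov$collar_thickness_mm %||% 0.25)
      sc_on <- build_scene(breast_spec(ov$compression_cc_cm %||% 5.6),
                           collar = collar, view = "CC")
      sc_off <- build_scene(breast_spec(ov$compression_cc_cm %||% 5.6),
                            view = "CC")
      t_on <- run_transport(sc_on, spec, config$histories, seed)
      t_off <- run_transport(sc_off, spec, config$histories, seed + 1L)
      norm <- 3.6e-3 * 1e6
      k <- function(t, org) t$probe_kerma[[org]] / t$entrance_kerma_per_history * norm
      list(
        outside_uGy_per_view = k(t_on, "probe_outer"),
        inside_uGy_per_view = k(t_on, "probe_inner"),
        inside_over_outside = k(t_on, "probe_inner") / k(t_on, "probe_outer"),
        no_collar_inner_uGy_per_view = k(t_off, "probe_inner"),
        reduction_factor = k(t_off, "probe_inner") / k(t_on, "probe_inner"),
        tallies = list(collar = t_on, open = t_off))
    },
    "cohort-stats" = {
      cfg <- do.call(cohort_config,
                     c(list(seed = seed),
                       ov[names(ov) %in% names(formals(cohort_config))]))
      cohort <- generate_cohort(cfg)
      list(cohort = cohort, stats = cohort_stats(cohort))
    })
  res$manifest <- list(scenario = config$scenario, seed = seed,
                       histories = config$histories,
                       config_hash = .hash_config(config[
                         c("scenario", "seed", "histories", "overrides")]),
                       package_version =
                         as.character(utils::packageVersion("mammoscatter")))
  if (!is.null(config$out_dir)) .write_bundle(res, config)
  res
}

.write_bundle <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(res$organ_dose_table)) {
    tab <- res$organ_dose_table
    ed <- effective_dose(tab)
    tab$contribution_percent <-
      ed$contributions_percent[match(tab$organ,
                                     names(ed$contributions_percent))]
    write.csv(tab, p("organ_doses.csv"), row.names = FALSE)
    jsonlite::write_json(
      res[c("kvp", "effective_uSv", "surface_air_kerma_uGy", "thyroid_uGy",
            "mgd_per_view_mGy", "provenance_split",
            "backscatter_share_of_scatter")],
      p("summary.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$sweep)) write.csv(res$sweep, p("sweep.csv"),
                                     row.names = FALSE)
  if (!is.null(res$cohort)) write_cohort(res$cohort, p("cohort.csv"))
  invisible(config$out_dir)
}
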