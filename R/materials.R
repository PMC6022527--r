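#' @useDynLib mammoscatter, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx rnorm runif rlnorm sd qnorm setNames
#' @importFrom utils read.delim write.csv read.csv modifyList
NULL

# Interaction channels recognised by lookup_mu()
.mu_channels <- c("total", "photoelectric", "incoherent", "coherent",
                  "energy_absorption")
.mu_columns <- c(total = "total", photoelectric = "pe", incoherent = "incoh",
                 coherent = "coh", energy_absorption = "muen")

.pkg_cache <- new.env(parent = emptyenv())

#' Photon interaction material registry
#'
#' Reads the coefficient tables shipped with the package (one delimited text
#' table per material; columns \code{energy_keV, pe, incoh, coh, total, muen},
#' all mass coefficients in cm^2/g) together with the registry JSON mapping
#' material names to densities and compositions.
#'
#' @return Named list of \code{material} objects.
#' @export
material_registry <- function() {
  if (!is.null(.pkg_cache$registry)) return(.pkg_cache$registry)
  dir <- system.file("extdata", package = "mammoscatter")
  reg <- jsonlite::read_json(file.path(dir, "materials.json"))
  out <- lapply(names(reg), function(nm) {
    tab <- read.delim(file.path(dir, reg[[nm]]$table), comment.char = "#")
    new_material(nm, reg[[nm]]$density_g_cc, tab,
                 composition = unlist(reg[[nm]]$composition))
  })
  names(out) <- names(reg)
  .pkg_cache$registry <- out
  out
}

#' Construct a material
#'
#' @param name material identifier.
#' @param density mass density in g/cm^3.
#' @param table data frame with columns \code{energy_keV, pe, incoh, coh,
#'   total, muen} (mass coefficients, cm^2/g, ascending energy).
#' @param composition optional named vector of element mass fractions
#'   (provenance only; must sum to 1 within 1e-6 when given).
#' @return object of class \code{material}.
#' @export
new_material <- function(name, density, table, composition = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || density <= 0)
    stop("material '", name, "': density must be positive")
  need <- c("energy_keV", "pe", "incoh", "coh", "total", "muen")
  if (!all(need %in% names(table)))
    stop("material '", name, "': table must have columns ",
         paste(need, collapse = ", "))
  if (is.unsorted(table$energy_keV, strictly = TRUE))
    stop("material '", name, "': energy grid must be strictly ascending")
  if (any(as.matrix(table[need[-1]]) <= 0))
    stop("material '", name, "': coefficients must be strictly positive")
  if (!is.null(composition)) {
    if (abs(sum(composition) - 1) > 1e-6)
      stop("material '", name, "': mass fractions must sum to 1")
    if (any(composition <= 0))
      stop("material '", name, "': mass fractions must be positive")
  }
  structure(list(name = name, density = density,
                 table = table[need], composition = composition),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  rng <- range(x$table$energy_keV)
  cat(sprintf("<material> %s  rho = %g g/cm^3  grid %g-%g keV (%d pts)\n",
              x$name, x$density, rng[1], rng[2], nrow(x$table)))
  invisible(x)
}

#' Fetch one material from the shipped registry
#' @param name registry name, e.g. \code{"lead"}, \code{"pmma"}, \code{"air"}.
#' @return a \code{material}.
#' @export
get_material <- function(name) {
  reg <- material_registry()
  if (!name %in% names(reg))
    stop("unknown material '", name, "'; registry has: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

# log-log linear interpolation of a positive tabulated function
loglog_interp <- function(x, y, xout) {
  exp(approx(log(x), log(y), xout = log(xout), rule = 1)$y)
}

#' Linear attenuation coefficient lookup
#'
#' Interpolates the material's mass coefficient log-log on its energy grid and
#' multiplies by density: \eqn{\mu = \rho \cdot (\mu/\rho)}.
#'
#' @param material a \code{material}.
#' @param energy photon energy in keV (vectorised).
#' @param channel one of \code{"total"}, \code{"photoelectric"},
#'   \code{"incoherent"}, \code{"coherent"}, \code{"energy_absorption"}.
#' @return linear coefficient(s) in cm^-1.
#' @export
lookup_mu <- function(material, energy, channel = "total") {
  stopifnot(inherits(material, "material"))
  channel <- match.arg(channel, .mu_channels)
  tab <- material$table
  rng <- range(tab$energy_keV)
  if (any(energy < rng[1] | energy > rng[2]))
    stop(sprintf("energy outside table range for material '%s' [%g, %g] keV",
                 material$name, rng[1], rng[2]))
  col <- .mu_columns[[channel]]
  material$density * loglog_interp(tab$energy_keV, tab[[col]], energy)
}

#' Mix materials by mass fraction
#'
#' Mixture mass coefficients are mass-fraction weighted sums per channel on the
#' merged energy grid. The default density follows the harmonic mass-weighted
#' rule \eqn{1/\rho = \sum_i w_i/\rho_i}; pass \code{density} to override
#' (e.g. the 3:2 fat/glandular breast mixture is set to 0.98 g/cm^3).
#'
#' @param components list of \code{list(material, fraction)} pairs (or a named
#'   numeric vector of fractions with registry material names).
#' @param name name of the mixture.
#' @param density optional explicit density g/cm^3.
#' @return a \code{material}.
#' @export
mix_materials <- function(components, name = "mixture", density = NULL) {
  if (is.numeric(components) && !is.null(names(components)))
    components <- lapply(names(components), function(nm)
      list(get_material(nm), unname(components[[nm]])))
  if (length(components) == 0L) stop("empty component list")
  mats <- lapply(components, `[[`, 1L)
  w <- vapply(components, function(x) as.numeric(x[[2L]]), numeric(1))
  if (any(w <= 0)) stop("mass fractions must be positive")
  if (abs(sum(w) - 1) > 1e-6) stop("mass fractions must sum to 1 (got ",
                                   format(sum(w)), ")")
  egrid <- sort(unique(unlist(lapply(mats, function(m) m$table$energy_keV))))
  lo <- max(vapply(mats, function(m) min(m$table$energy_keV), numeric(1)))
  hi <- min(vapply(mats, function(m) max(m$table$energy_keV), numeric(1)))
  egrid <- egrid[egrid >= lo & egrid <= hi]
  cols <- c("pe", "incoh", "coh", "muen")
  acc <- matrix(0, length(egrid), length(cols), dimnames = list(NULL, cols))
  for (i in seq_along(mats)) {
    tab <- mats[[i]]$table
    for (cl in cols)
      acc[, cl] <- acc[, cl] + w[i] * loglog_interp(tab$energy_keV, tab[[cl]], egrid)
  }
  if (is.null(density)) density <- 1 / sum(w / vapply(mats, `[[`, numeric(1), "density"))
  comp <- NULL
  if (all(!vapply(mats, function(m) is.null(m$composition), logical(1)))) {
    all_el <- unique(unlist(lapply(mats, function(m) names(m$composition))))
    comp <- setNames(numeric(length(all_el)), all_el)
    for (i in seq_along(mats)) {
      ci <- mats[[i]]$composition
      comp[names(ci)] <- comp[names(ci)] + w[i] * ci
    }
  }
  tab <- data.frame(energy_keV = egrid, pe = acc[, "pe"], incoh = acc[, "incoh"],
                    coh = acc[, "coh"], total = rowSums(acc[, c("pe", "incoh", "coh")]),
                    muen = acc[, "muen"])
  new_material(name, density, tab, composition = comp)
}

#' The 3:2 fat/glandular compressed-breast mixture
#'
#' Breast tissue modelled as adipose and glandular tissue mixed 3:2 by mass
#' (60% adipose / 40% glandular), density 0.98 g/cm^3.
#' @return a \code{material} named \code{"breast_3to2"}.
#' @export
breast_material <- function() {
  if (is.null(.pkg_cache$breast))
    .pkg_cache$breast <- mix_materials(c(adipose = 0.6, glandular = 0.4),
                                       name = "breast_3to2", density = 0.98)
  .pkg_cache$breast
}

#' Lung tissue stand-in
#'
#' Soft-tissue coefficients at inflated-lung density (0.26 g/cm^3).
#' @return a \code{material}.
#' @export
lung_material <- function() {
  st <- get_material("soft_tissue")
  new_material("lung", 0.26, st$table, composition = st$composition)
}
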