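# Element cross-section table and mixture-rule material coefficients.
#
# The element table (inst/extdata/xsec_elements.csv) holds, per element and
# energy, the total mass attenuation coefficient mu/rho, the mass
# energy-absorption coefficient mu_en/rho, and the partial interaction
# fractions (photoelectric / incoherent / coherent) used by the transport
# kernel to branch between interaction channels.

.kv_cache <- new.env(parent = emptyenv())

#' Element photon cross-section table
#'
#' Returns the built-in element cross-section table as a data frame with one
#' row per (element, energy) pair. Columns: \code{symbol}, \code{Z}, \code{A},
#' \code{energy_keV}, \code{mu_rho} (total mass attenuation, cm^2/g),
#' \code{mu_en_rho} (mass energy-absorption, cm^2/g) and the partial
#' interaction fractions \code{f_photo}, \code{f_incoh}, \code{f_coh}.
#'
#' @param symbol Optional element symbol; if given, only that element's rows
#'   are returned.
#' @return A data frame.
#' @export
element_table <- function(symbol = NULL) {
  if (is.null(.kv_cache$xsec)) {
    path <- system.file("extdata", "xsec_elements.csv", package = "kvdosim")
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    .kv_cache$xsec <- split(tab, tab$symbol)
  }
  if (is.null(symbol)) {
    return(do.call(rbind, c(.kv_cache$xsec, make.row.names = FALSE)))
  }
  rec <- .kv_cache$xsec[[symbol]]
  if (is.null(rec)) {
    stop("unknown element '", symbol, "'; available: ",
         paste(sort(names(.kv_cache$xsec)), collapse = ", "))
  }
  rec
}

# log-log interpolation of a tabulated coefficient; exact at table energies.
# Falls back to linear interpolation where a value is zero (e.g. H photo).
.interp_coef <- function(energy_tab, value_tab, energy) {
  if (any(energy < min(energy_tab)) || any(energy > max(energy_tab))) {
    stop("energy out of tabulated range [", min(energy_tab), ", ",
         max(energy_tab), "] keV")
  }
  if (all(value_tab > 0)) {
    exp(stats::approx(log(energy_tab), log(value_tab), xout = log(energy),
                      ties = "ordered")$y)
  } else {
    stats::approx(energy_tab, value_tab, xout = energy, ties = "ordered")$y
  }
}

.element_coef <- function(symbol, energy, column) {
  rec <- element_table(symbol)
  .interp_coef(rec$energy_keV, rec[[column]], energy)
}

#' Define a material by elemental composition
#'
#' @param name Material name.
#' @param density Bulk density in g/cm^3.
#' @param composition Named numeric vector of elemental mass fractions
#'   (must sum to 1 within 1e-4; element symbols must exist in the
#'   element table).
#' @param note Optional free-text provenance note.
#' @return An object of class \code{kv_material}.
#' @export
material <- function(name, density, composition, note = NULL) {
  composition <- unlist(composition)
  if (is.null(names(composition)) || any(names(composition) == "")) {
    stop("composition must be a named vector of mass fractions")
  }
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    stop("density must be a single positive number (g/cm^3)")
  }
  if (any(composition < 0)) stop("mass fractions must be non-negative")
  s <- sum(composition)
  if (abs(s - 1) > 1e-4) {
    stop(sprintf("mass fractions of '%s' sum to %.6f, not 1 (tolerance 1e-4)",
                 name, s))
  }
  for (el in names(composition)) element_table(el)  # errors if unknown
  structure(list(name = name, density = density,
                 composition = composition, note = note),
            class = "kv_material")
}

#' @export
print.kv_material <- function(x, ...) {
  cat(sprintf("<material> %s  (rho = %.4g g/cm^3)\n", x$name, x$density))
  comp <- paste(sprintf("%s %.4g%%", names(x$composition),
                        100 * x$composition), collapse = ", ")
  cat(" ", comp, "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Built-in material catalogue
#'
#' Loads the material catalogue shipped with the package: liquid water, dry
#' air, Plastic Water LR, RB2 average-bone equivalent, lead, PMMA (Perspex
#' shelf), beryllium, copper and tungsten.
#'
#' @param path Optional path to an alternative catalogue file (see
#'   \code{\link{read_materials}} for the format).
#' @return Named list of \code{kv_material} objects.
#' @export
builtin_materials <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.kv_cache$materials)) return(.kv_cache$materials)
    path <- system.file("extdata", "materials.yaml", package = "kvdosim")
    .kv_cache$materials <- read_materials(path)
    return(.kv_cache$materials)
  }
  read_materials(path)
}

#' Read / write a material catalogue
#'
#' The catalogue is a YAML file with a \code{schema_version} field and a
#' \code{materials} map of \code{density} / \code{composition} / \code{note}
#' entries. The schema is validated strictly on load.
#'
#' @param path File path.
#' @return \code{read_materials}: named list of \code{kv_material};
#'   \code{write_materials}: the path, invisibly.
#' @export
read_materials <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version) || doc$schema_version != 1) {
    stop("material catalogue: missing or unsupported schema_version")
  }
  if (!is.list(doc$materials) || length(doc$materials) == 0) {
    stop("material catalogue: no 'materials' map")
  }
  out <- lapply(names(doc$materials), function(nm) {
    m <- doc$materials[[nm]]
    extra <- setdiff(names(m), c("density", "composition", "note"))
    if (length(extra)) {
      stop("material '", nm, "': unknown fields ", paste(extra, collapse = ", "))
    }
    if (is.null(m$density) || is.null(m$composition)) {
      stop("material '", nm, "': density and composition are required")
    }
    material(nm, m$density, unlist(m$composition), note = m$note)
  })
  names(out) <- names(doc$materials)
  out
}

#' @rdname read_materials
#' @param materials Named list of \code{kv_material} objects.
#' @export
write_materials <- function(materials, path) {
  entries <- lapply(materials, function(m) {
    e <- list(density = m$density, composition = as.list(m$composition))
    if (!is.null(m$note)) e$note <- m$note
    e
  })
  names(entries) <- vapply(materials, `[[`, "", "name")
  yaml::write_yaml(list(schema_version = 1, materials = entries), path)
  invisible(path)
}

# Resolve a material given by name or object.
get_material <- function(x) {
  if (inherits(x, "kv_material")) return(x)
  if (is.character(x) && length(x) == 1L) {
    cat_ <- builtin_materials()
    if (!x %in% names(cat_)) {
      stop("unknown material '", x, "'; available: ",
           paste(names(cat_), collapse = ", "))
    }
    return(cat_[[x]])
  }
  stop("expected a material name or a kv_material object")
}

#' Mass attenuation and energy-absorption coefficients
#'
#' Mixture-rule coefficients: the weighted sum over the material's elements of
#' the tabulated element coefficients, log-log interpolated in energy.
#'
#' @param mat A \code{kv_material} or the name of a built-in material.
#' @param energy Photon energy (keV), vectorized; must lie inside the
#'   tabulated range (1 keV - 1 MeV).
#' @return Coefficient in cm^2/g (\code{linear_attenuation}: 1/cm).
#' @export
mass_attenuation <- function(mat, energy) {
  mat <- get_material(mat)
  out <- 0
  for (el in names(mat$composition)) {
    out <- out + mat$composition[[el]] * .element_coef(el, energy, "mu_rho")
  }
  out
}

#' @rdname mass_attenuation
#' @export
mass_energy_absorption <- function(mat, energy) {
  mat <- get_material(mat)
  out <- 0
  for (el in names(mat$composition)) {
    out <- out + mat$composition[[el]] * .element_coef(el, energy, "mu_en_rho")
  }
  out
}

#' @rdname mass_attenuation
#' @export
linear_attenuation <- function(mat, energy) {
  mat <- get_material(mat)
  mass_attenuation(mat, energy) * mat$density
}

# Per-channel mass attenuation components (cm^2/g) for the transport kernel:
# photoelectric, incoherent (Compton), coherent (Rayleigh).
material_channels <- function(mat, energy) {
  mat <- get_material(mat)
  pe <- inc <- coh <- 0
  for (el in names(mat$composition)) {
    rec <- element_table(el)
    w <- mat$composition[[el]]
    pe  <- pe  + w * .interp_coef(rec$energy_keV, rec$mu_rho * rec$f_photo, energy)
    inc <- inc + w * .interp_coef(rec$energy_keV, rec$mu_rho * rec$f_incoh, energy)
    coh <- coh + w * .interp_coef(rec$energy_keV, rec$mu_rho * rec$f_coh, energy)
  }
  list(photo = pe, incoh = inc, coh = coh)
}
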