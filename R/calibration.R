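# Absolute calibration: conversion of Monte Carlo output (Gy/particle) to
# absolute dose via a per-machine reference scaling factor S_ref and the
# spectrum-ratio conversion factor
#   F_cal = S_ref * (int N_beam dE / int N_ref dE)
#               * (A_beam * d_ref^2) / (A_ref * d_beam^2),
# with the spectrum integrals taken as plain fluence-bin sums.

#' Reference calibration for a machine
#'
#' @param s_ref Experimentally determined scaling factor (particles/mAs) for
#'   the reference beam.
#' @param spectrum The reference \code{kv_spectrum}.
#' @param a_ref_mm2 Reference beam area at isocenter (mm^2).
#' @param d_ref_mm Reference source-to-isocenter distance (mm).
#' @param hvl_mm First HVL of the reference beam in \code{hvl_material}
#'   (computed from the spectrum when omitted).
#' @param hvl_material HVL material (default copper).
#' @param provenance List of measurement provenance fields (measured
#'   air-kerma rate, date, chamber, ...).
#' @return An object of class \code{kv_reference}.
#' @export
reference_calibration <- function(s_ref, spectrum, a_ref_mm2, d_ref_mm,
                                  hvl_mm = NULL, hvl_material = "copper",
                                  provenance = list()) {
  if (s_ref <= 0) stop("s_ref must be positive")
  if (a_ref_mm2 <= 0 || d_ref_mm <= 0) stop("reference geometry must be positive")
  if (is.null(hvl_mm)) hvl_mm <- half_value_layer(spectrum, hvl_material)
  structure(list(s_ref = s_ref, spectrum = spectrum,
                 a_ref_mm2 = a_ref_mm2, d_ref_mm = d_ref_mm,
                 hvl_mm = hvl_mm, hvl_material = hvl_material,
                 provenance = provenance),
            class = "kv_reference")
}

#' @export
print.kv_reference <- function(x, ...) {
  cat(sprintf("<reference calibration> S_ref = %.6g particles/mAs\n", x$s_ref))
  cat(sprintf("  %g kVp, HVL %.3f mm %s, A_ref %.4g mm^2, d_ref %g mm\n",
              x$spectrum$kvp, x$hvl_mm, x$hvl_material, x$a_ref_mm2,
              x$d_ref_mm))
  invisible(x)
}

#' Determine S_ref from a measured air-kerma rate
#'
#' Chooses S_ref so that the calibrated simulation reproduces the measured
#' air-kerma rate exactly at the reference point:
#' \code{s_ref = measured_rate / (kerma_per_particle * current * 60)}.
#'
#' @param measured_kerma_rate Measured air-kerma rate in Gy/min.
#' @param beam The reference \code{kv_beam} (supplies spectrum, geometry and
#'   current).
#' @param kerma_per_particle Simulated air kerma per source particle at the
#'   reference point (Gy/particle).
#' @param provenance Measurement provenance fields.
#' @return A \code{kv_reference}.
#' @export
determine_sref <- function(measured_kerma_rate, beam, kerma_per_particle,
                           provenance = list()) {
  if (measured_kerma_rate <= 0 || kerma_per_particle <= 0 ||
      beam$current_mA <= 0) {
    stop("measured rate, simulated kerma and current must be positive")
  }
  s_ref <- measured_kerma_rate /
    (kerma_per_particle * beam$current_mA * 60)
  reference_calibration(
    s_ref, beam$spectrum,
    a_ref_mm2 = prod(beam$field_mm), d_ref_mm = beam$sid_mm,
    provenance = c(list(measured_kerma_rate_gy_min = measured_kerma_rate,
                        current_mA = beam$current_mA), provenance))
}

#' Eq.-style conversion factor for a beam
#'
#' @param ref A \code{kv_reference}.
#' @param beam A \code{kv_beam} on the same absolute normalization scheme as
#'   the reference spectrum.
#' @return An object of class \code{kv_conversion} with \code{f_cal} in
#'   particles/mAs.
#' @export
conversion_factor <- function(ref, beam) {
  if (!isTRUE(ref$spectrum$absolute) || !isTRUE(beam$spectrum$absolute)) {
    stop("conversion requires both spectra on the absolute scale")
  }
  a_beam <- prod(beam$field_mm)
  f_cal <- ref$s_ref *
    (sum(beam$spectrum$fluence) / sum(ref$spectrum$fluence)) *
    (a_beam * ref$d_ref_mm^2) / (ref$a_ref_mm2 * beam$sid_mm^2)
  structure(list(f_cal = f_cal, kvp = beam$spectrum$kvp,
                 sid_mm = beam$sid_mm, field_mm = beam$field_mm,
                 s_ref = ref$s_ref, ref_kvp = ref$spectrum$kvp),
            class = "kv_conversion")
}

#' @export
print.kv_conversion <- function(x, ...) {
  cat(sprintf("<conversion factor> F_cal = %.6g particles/mAs (%s kVp beam, ref %s kVp)\n",
              x$f_cal, x$kvp, x$ref_kvp))
  invisible(x)
}

#' Pick the nearest reference by half-value layer
#'
#' Returns the reference whose HVL (in the same material) is closest to the
#' beam's; ties are broken toward the higher tube potential.
#'
#' @param refs Non-empty list of \code{kv_reference}.
#' @param beam A \code{kv_beam}.
#' @return A \code{kv_reference}.
#' @export
nearest_reference <- function(refs, beam) {
  if (!length(refs)) stop("no reference calibrations available")
  beam_hvl <- half_value_layer(beam$spectrum, refs[[1]]$hvl_material)
  d <- vapply(refs, function(r) abs(r$hvl_mm - beam_hvl), 0)
  kvps <- vapply(refs, function(r) {
    if (is.na(r$spectrum$kvp)) Inf else r$spectrum$kvp
  }, 0)
  best <- which(d == min(d))
  refs[[best[which.max(kvps[best])]]]
}

#' Convert a dose grid to absolute dose
#'
#' \code{Gy = dose[Gy/particle] * f_cal[particles/mAs] * current[mA] *
#' time[s]}; the rate variant returns Gy/min at the stated current.
#'
#' @param dose A \code{kv_dose} in Gy/particle.
#' @param fcal A \code{kv_conversion}.
#' @param current_mA Tube current in mA.
#' @param time_s Exposure time in seconds (ignored for \code{rate = TRUE}).
#' @param rate If TRUE return a dose-rate grid in Gy/min.
#' @return The absolute \code{kv_dose}.
#' @export
to_absolute <- function(dose, fcal, current_mA, time_s = NULL, rate = FALSE) {
  stopifnot(inherits(dose, "kv_dose"), inherits(fcal, "kv_conversion"))
  if (isTRUE(dose$absolute)) {
    stop("dose grid is already absolute; refusing double calibration")
  }
  fac <- if (rate) {
    fcal$f_cal * current_mA * 60
  } else {
    if (is.null(time_s)) stop("time_s required unless rate = TRUE")
    fcal$f_cal * current_mA * time_s
  }
  out <- dose
  out$dose <- dose$dose * fac
  out$absolute <- TRUE
  out$provenance$f_cal <- fcal$f_cal
  out$provenance$current_mA <- current_mA
  out$provenance$time_s <- time_s
  out$provenance$unit <- if (rate) "Gy/min" else "Gy"
  out
}

#' Read / write a machine calibration file
#'
#' Versioned YAML schema listing reference calibrations (kvp, filtration,
#' HVL, s_ref, geometry, provenance). Spectra are regenerated from the
#' recorded tube settings on load.
#'
#' @param path File path.
#' @return \code{read_calibrations}: list of \code{kv_reference};
#'   \code{write_calibrations}: the path invisibly.
#' @export
read_calibrations <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version) || doc$schema_version != 1) {
    stop("calibration file: missing or unsupported schema_version")
  }
  lapply(doc$references, function(r) {
    filt <- unlist(r$filtration_mm)
    sp <- generate_spectrum(r$kvp, anode_angle = r$anode_angle,
                            filtration = filt)
    reference_calibration(r$s_ref, sp, r$a_ref_mm2, r$d_ref_mm,
                          hvl_mm = r$hvl_mm,
                          hvl_material = r$hvl_material %||% "copper",
                          provenance = r$provenance %||% list())
  })
}

#' @rdname read_calibrations
#' @param refs List of \code{kv_reference}.
#' @export
write_calibrations <- function(refs, path) {
  entries <- lapply(refs, function(r) {
    list(kvp = r$spectrum$kvp, anode_angle = r$spectrum$anode_angle,
         filtration_mm = as.list(r$spectrum$filtration),
         hvl_mm = r$hvl_mm, hvl_material = r$hvl_material,
         s_ref = r$s_ref, a_ref_mm2 = r$a_ref_mm2, d_ref_mm = r$d_ref_mm,
         provenance = r$provenance)
  })
  yaml::write_yaml(list(schema_version = 1, references = entries), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference air-kerma measurement points
#'
#' The shipped air-kerma reference set for the 320 kV cabinet: measured
#' free-in-air rates at 500 mm / 10 mA per tube potential, with the
#' corresponding analytic-model rates used for calibration scaling.
#'
#' @return Data frame with columns \code{kvp}, \code{measured_gy_min},
#'   \code{measured_sd}, \code{analytic_gy_min}; attributes
#'   \code{distance_mm} and \code{current_mA}.
#' @export
reference_airkerma <- function() {
  doc <- yaml::read_yaml(system.file("extdata", "airkerma_reference.yaml",
                                     package = "kvdosim"))
  out <- do.call(rbind, lapply(doc$points, as.data.frame))
  attr(out, "distance_mm") <- doc$distance_mm
  attr(out, "current_mA") <- doc$current_mA
  out
}
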