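# 3D dose-distribution evaluation: depth-dose and lateral profiles, FWHM,
# high-dose region metrics, dose-volume histograms, dose-quantifier
# conversion and the structured irradiation report.

#' Depth-dose profile
#'
#' Mean dose over a lateral region of interest at each z plane, with the
#' combined (quadrature) statistical uncertainty of the averaged voxels.
#'
#' @param dose A \code{kv_dose}.
#' @param roi_xy List with \code{x} and \code{y} ranges in mm (default: the
#'   central 10 x 10 mm).
#' @return A \code{kv_profile} data frame with columns \code{position_mm}
#'   (z voxel centers), \code{dose}, \code{uncertainty} (absolute, 1 sigma);
#'   attribute \code{depth_mm} gives depth below the grid top surface.
#' @export
depth_dose <- function(dose, roi_xy = list(x = c(-5, 5), y = c(-5, 5))) {
  stopifnot(inherits(dose, "kv_dose"))
  ctr <- dose_centers(dose)
  ix <- which(ctr$x >= roi_xy$x[1] & ctr$x <= roi_xy$x[2])
  iy <- which(ctr$y >= roi_xy$y[1] & ctr$y <= roi_xy$y[2])
  if (!length(ix) || !length(iy)) stop("empty region of interest")
  nz <- length(ctr$z)
  d <- vapply(seq_len(nz), function(k) mean(dose$dose[ix, iy, k]), 0)
  u <- vapply(seq_len(nz), function(k) {
    sub <- dose$dose[ix, iy, k] * dose$rel_unc[ix, iy, k]
    sqrt(sum(sub^2)) / length(sub)
  }, 0)
  out <- data.frame(position_mm = ctr$z, dose = d, uncertainty = u)
  attr(out, "axis") <- "z"
  attr(out, "window") <- roi_xy
  attr(out, "depth_mm") <- max(dose$z_edges) - ctr$z
  class(out) <- c("kv_profile", "data.frame")
  out
}

#' Lateral dose profile at a depth
#'
#' @param dose A \code{kv_dose}.
#' @param z_mm z position (mm, world frame) of the plane to sample (nearest
#'   voxel plane is used).
#' @param axis \code{"x"} or \code{"y"}.
#' @param window Averaging half-width (mm) along the other lateral axis
#'   (default 5).
#' @return A \code{kv_profile} data frame.
#' @export
lateral_profile <- function(dose, z_mm, axis = c("x", "y"), window = 5) {
  stopifnot(inherits(dose, "kv_dose"))
  axis <- match.arg(axis)
  ctr <- dose_centers(dose)
  k <- which.min(abs(ctr$z - z_mm))
  other <- if (axis == "x") "y" else "x"
  io <- which(abs(ctr[[other]]) <= window)
  if (!length(io)) stop("empty averaging window")
  sl <- dose$dose[, , k]
  su <- dose$rel_unc[, , k]
  if (axis == "y") { sl <- t(sl); su <- t(su) }
  d <- rowMeans(sl[, io, drop = FALSE])
  u <- sqrt(rowSums((sl[, io, drop = FALSE] * su[, io, drop = FALSE])^2)) /
    length(io)
  out <- data.frame(position_mm = ctr[[axis]], dose = d, uncertainty = u)
  attr(out, "axis") <- axis
  attr(out, "z_mm") <- ctr$z[k]
  class(out) <- c("kv_profile", "data.frame")
  out
}

#' @export
plot.kv_profile <- function(x, ...) {
  graphics::plot(x$position_mm, x$dose, type = "b",
                 xlab = sprintf("%s (mm)", attr(x, "axis") %||% "position"),
                 ylab = "dose", ...)
  invisible(x)
}

#' Full width at half maximum of a profile
#'
#' Linear interpolation of the two half-maximum crossings around the peak.
#'
#' @param profile A \code{kv_profile} (or data frame with
#'   \code{position_mm} and \code{dose}).
#' @return FWHM in mm.
#' @export
fwhm <- function(profile) {
  p <- profile$position_mm
  d <- profile$dose
  imax <- which.max(d)
  half <- d[imax] / 2
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(imax)) else imax:length(d)
    below <- which(d[idx] < half)
    if (!length(below)) {
      stop("profile never crosses half maximum on the ", side,
           " side (truncated field)")
    }
    i2 <- idx[below[1]]          # first sample below half
    i1 <- if (side == "left") i2 + 1L else i2 - 1L
    p[i1] + (half - d[i1]) * (p[i2] - p[i1]) / (d[i2] - d[i1])
  }
  abs(cross("right") - cross("left"))
}

#' Mean over the high-dose region
#'
#' Mean of all elements with at least \code{threshold} (default 80%) of the
#' maximum; the threshold boundary value is included.
#'
#' @param x A \code{kv_dose}, \code{kv_profile} or numeric vector/array.
#' @param threshold Fraction of the maximum (default 0.8).
#' @return Mean dose over the selected elements.
#' @export
region_mean_80 <- function(x, threshold = 0.8) {
  v <- if (inherits(x, "kv_dose")) x$dose
       else if (inherits(x, "kv_profile")) x$dose
       else x
  if (!length(v) || all(v == 0)) stop("input has no dose")
  sel <- v >= threshold * max(v)
  mean(v[sel])
}

#' Cumulative dose-volume histogram
#'
#' @param dose A \code{kv_dose} or numeric array.
#' @param mask Logical array selecting the structure (default: all voxels).
#' @param n_bins Number of evenly spaced dose thresholds.
#' @param label Structure label for reporting.
#' @return A \code{kv_dvh} data frame with columns \code{dose} (threshold)
#'   and \code{volume_fraction} (fraction of masked voxels with dose >=
#'   threshold), monotone non-increasing from 1 to 0.
#' @export
dvh <- function(dose, mask = NULL, n_bins = 200, label = "structure") {
  v <- if (inherits(dose, "kv_dose")) dose$dose else dose
  if (is.null(mask)) mask <- rep(TRUE, length(v))
  if (!sum(mask)) stop("empty structure mask")
  vv <- v[mask]
  thr <- seq(0, max(vv) * (1 + 1e-9), length.out = n_bins)
  frac <- vapply(thr, function(t) mean(vv >= t), 0)
  out <- data.frame(dose = thr, volume_fraction = frac)
  attr(out, "label") <- label
  class(out) <- c("kv_dvh", "data.frame")
  out
}

#' Dose-volume metric from a DVH
#'
#' \code{"Dxx"}: dose received by at least xx% of the volume;
#' \code{"Vyy"} or \code{"VyyGy"}: volume fraction receiving at least yy
#' dose units. Values are obtained by linear interpolation of the cumulative
#' curve.
#'
#' @param dvh_curve A \code{kv_dvh}.
#' @param metric Metric string, e.g. \code{"D50"} or \code{"V2Gy"}.
#' @return The metric value.
#' @export
dose_volume_metric <- function(dvh_curve, metric) {
  m <- regmatches(metric, regexec("^([DV])([0-9.]+)", metric))[[1]]
  if (length(m) != 3) stop("metric must look like 'D50' or 'V2Gy'")
  val <- as.numeric(m[3])
  d <- dvh_curve$dose
  f <- dvh_curve$volume_fraction
  if (m[2] == "V") {
    stats::approx(d, f, xout = val, rule = 2, ties = "ordered")$y
  } else {
    # dose at which the curve crosses val% volume; curve is non-increasing
    target <- val / 100
    idx <- which(f <= target)
    if (!length(idx)) return(max(d))
    i2 <- idx[1]
    if (i2 == 1) return(d[1])
    i1 <- i2 - 1L
    if (f[i1] == f[i2]) return(d[i1])
    d[i1] + (target - f[i1]) * (d[i2] - d[i1]) / (f[i2] - f[i1])
  }
}

#' Convert dose-to-medium to dose-to-water
#'
#' Multiplies each voxel by the water-to-medium mass energy-absorption
#' coefficient ratio averaged over the beam's primary spectrum
#' (fluence-weighted); water voxels are unchanged. The in-phantom spectral
#' drift with depth is neglected (a user-supplied local spectrum may be
#' passed instead). Applying the conversion twice is an error, enforced via
#' the grid's quantifier metadata.
#'
#' @param dose A \code{kv_dose} carrying Dm,m.
#' @param phantom The \code{kv_phantom} the dose was scored on.
#' @param spectrum Fluence-weighting \code{kv_spectrum} (the primary beam
#'   spectrum, or a local estimate).
#' @return A \code{kv_dose} carrying Dw,m.
#' @export
dose_to_water <- function(dose, phantom, spectrum) {
  stopifnot(inherits(dose, "kv_dose"), inherits(phantom, "kv_phantom"))
  if (!identical(dose$quantifier, "Dm,m")) {
    stop("dose grid carries ", dose$quantifier,
         "; dose-to-water conversion applies to Dm,m only")
  }
  w <- spectrum$fluence / sum(spectrum$fluence)
  muen_w <- mass_energy_absorption("water", spectrum$energy)
  factors <- vapply(phantom$materials, function(m) {
    sum(w * muen_w) / sum(w * mass_energy_absorption(m, spectrum$energy))
  }, 0)
  is_water <- vapply(phantom$materials, function(m) {
    identical(m$composition, get_material("water")$composition)
  }, TRUE)
  factors[is_water] <- 1
  out <- dose
  out$dose <- dose$dose * array(factors[phantom$labels], dim = dim(dose$dose))
  out$quantifier <- "Dw,m"
  out
}

#' Write a profile or DVH as CSV
#' @param x A \code{kv_profile} or \code{kv_dvh}.
#' @param path Output path.
#' @export
write_profile_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# required fields of the irradiation report
.kv_report_fields <- c("machine", "kvp", "filtration_mm", "hvl_mm",
                       "sid_mm", "field_mm", "current_mA", "phantom",
                       "calibration", "dose_metrics", "uncertainty",
                       "software_version", "seed")

#' Export a structured irradiation report
#'
#' Collects the reporting-checklist core (machine, tube potential,
#' filtration, HVL, geometry, current, phantom description, calibration
#' provenance, dose metrics, uncertainty summary, software version and seed)
#' into a JSON document plus a human-readable text rendering. Missing fields
#' raise a validation error naming them.
#'
#' @param fields Named list covering all required report fields.
#' @param path Output path for the JSON report (a \code{.txt} rendering is
#'   written alongside). NULL returns the validated list only.
#' @return The validated report list, invisibly.
#' @export
export_report <- function(fields, path = NULL) {
  missing <- setdiff(.kv_report_fields, names(fields))
  if (length(missing)) {
    stop("report validation failed; missing fields: ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(path)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    txt <- c("Irradiation report", strrep("-", 60),
             vapply(names(fields), function(nm) {
               sprintf("%-20s %s", nm,
                       paste(format(unlist(fields[[nm]]), trim = TRUE),
                             collapse = " "))
             }, ""))
    writeLines(txt, sub("\\.json$", ".txt", path))
  }
  invisible(fields)
}

#' Read a report written by \code{export_report}
#' @param path Path to the JSON report.
#' @return The report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
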