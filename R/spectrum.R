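# Analytic kilovoltage x-ray tube spectra and beam-quality indices.
#
# The tube model is a semi-empirical thick-target tungsten model: Kramers
# emission per electron path segment combined with a Thomson-Whiddington
# depth-energy relation for target self-attenuation, plus tungsten K
# characteristic lines above the K edge. Spectra are carried as photon counts
# per energy bin per mAs per steradian on the central axis.

KV_ELECTRONS_PER_MAS <- 1e-3 / 1.602176634e-19   # electrons per mAs
KV_KEV_TO_J <- 1.602176634e-16
KV_W_KEDGE <- 69.525                              # keV

# Semi-empirical model constants (see methods vignette):
#  - kramers_k: Kramers constant, photons/(electron keV) per unit Z, fixed by
#    the thick-target efficiency rule eta ~ 1e-9 Z V.
#  - brems_p0/p1: bremsstrahlung shape exponent p = p0 + p1 * kvp/100 in
#    N(E) ~ Z (E0-E)^p / E; p = 1 is the classical Kramers shape, p > 1
#    softens the high-kV end the way NIST-cross-section thick-target models
#    do.
#  - tw_c: Thomson-Whiddington constant for tungsten, keV^2 cm^2/g.
#  - kchar_a: K characteristic yield coefficient, photons/electron in
#    (E0/E_K - 1)^1.67 scaling; mid-range of published thick-target yields.
# The shape exponent and tw_c are calibrated so the model reproduces the
# first HVLs in copper of the 100/200/300 kV reference beams (see methods
# vignette).
.kv_tube_const <- list(kramers_k = 2e-6, brems_p0 = 1.25, brems_p1 = 0.2,
                       tw_c = 1.3e6, kchar_a = 4e-4, kchar_exp = 1.67)

# Tungsten K lines: energy (keV), relative intensity
.kv_wlines <- data.frame(
  energy = c(59.318, 57.982, 67.244, 69.067),
  rel    = c(100, 57.6, 30.7, 8.1)
)

#' Construct an energy spectrum object
#'
#' @param energy Bin centers in keV (strictly increasing, constant spacing)
#'   or a single line energy when \code{is_line_spectrum = TRUE}.
#' @param fluence Photons per energy bin per mAs per steradian on the central
#'   axis (arbitrary units when \code{absolute = FALSE}).
#' @param kvp Tube potential in kV (NA for line sources).
#' @param anode_angle Anode angle in degrees (NA for line sources).
#' @param filtration Named numeric vector of filter thicknesses in mm
#'   (names are material names).
#' @param is_line_spectrum Flag for monoenergetic sources.
#' @param absolute TRUE when the fluence scale is photons/mAs/sr.
#' @return An object of class \code{kv_spectrum}.
#' @export
energy_spectrum <- function(energy, fluence, kvp = NA, anode_angle = NA,
                            filtration = numeric(), is_line_spectrum = FALSE,
                            absolute = TRUE) {
  if (length(energy) != length(fluence)) stop("energy/fluence length mismatch")
  if (any(fluence < 0)) stop("fluence must be non-negative")
  if (length(energy) > 1L) {
    d <- diff(energy)
    if (any(d <= 0)) stop("bin grid must be strictly increasing")
    if (max(d) - min(d) > 1e-9 * mean(d)) stop("bin spacing must be constant")
  }
  if (length(filtration) && any(filtration < 0)) {
    stop("filtration thicknesses must be non-negative")
  }
  if (!is_line_spectrum && !is.na(kvp) && any(fluence[energy > kvp] > 0)) {
    stop("fluence above the tube potential must be zero")
  }
  structure(list(energy = as.numeric(energy), fluence = as.numeric(fluence),
                 kvp = kvp, anode_angle = anode_angle,
                 filtration = filtration,
                 is_line_spectrum = is_line_spectrum, absolute = absolute),
            class = "kv_spectrum")
}

#' @export
print.kv_spectrum <- function(x, ...) {
  if (x$is_line_spectrum) {
    cat(sprintf("<spectrum> line source: %.6g photons at %.1f keV\n",
                sum(x$fluence), x$energy[which.max(x$fluence)]))
  } else {
    filt <- if (length(x$filtration)) {
      paste(sprintf("%s %.4g mm", names(x$filtration), x$filtration),
            collapse = " + ")
    } else "none"
    cat(sprintf("<spectrum> %g kVp, anode %g deg, filtration: %s\n",
                x$kvp, x$anode_angle, filt))
    cat(sprintf("  %d bins, mean energy %.1f keV, total %.4g photons/mAs/sr%s\n",
                length(x$energy), mean_energy(x), sum(x$fluence),
                if (x$absolute) "" else " (relative scale)"))
  }
  invisible(x)
}

#' @export
plot.kv_spectrum <- function(x, ...) {
  graphics::plot(x$energy, x$fluence, type = "h",
                 xlab = "energy (keV)", ylab = "photons / bin / mAs / sr", ...)
  invisible(x)
}

#' Mean energy of a spectrum
#' @param spectrum A \code{kv_spectrum}.
#' @return Fluence-weighted mean photon energy in keV.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$energy * spectrum$fluence) / sum(spectrum$fluence)
}

#' Generate an analytic tungsten tube spectrum
#'
#' Semi-empirical thick-target model: Kramers bremsstrahlung emission along
#' the electron slowing-down path, with target self-attenuation through the
#' Thomson-Whiddington depth-energy relation and the anode take-off angle,
#' plus tungsten K characteristic lines above 69.5 kV. The raw anode spectrum
#' is then attenuated through the stated filtration per bin (Beer-Lambert).
#'
#' @param kvp Tube potential in kV (30-320).
#' @param anode_angle Anode (take-off) angle in degrees, in (0, 90].
#' @param filtration Named numeric vector of filter thicknesses in mm, e.g.
#'   \code{c(beryllium = 3, copper = 0.2)}; applied in order.
#' @param bin_width Energy bin width in keV (default 1; bin centers at
#'   half-integer multiples).
#' @param normalization Global absolute-output scaling constant (default 1).
#' @return A \code{kv_spectrum} in photons/mAs/sr.
#' @export
generate_spectrum <- function(kvp, anode_angle = 30,
                              filtration = c(beryllium = 3, copper = 0.2),
                              bin_width = 1, normalization = 1) {
  if (!is.numeric(kvp) || kvp < 30 || kvp > 320) {
    stop("kvp must be in [30, 320] kV")
  }
  if (anode_angle <= 0 || anode_angle > 90) {
    stop("anode_angle must be in (0, 90] degrees")
  }
  cst <- .kv_tube_const
  csc <- 1 / sin(anode_angle * pi / 180)
  centers <- seq(bin_width / 2, kvp, by = bin_width)
  # sub-keV bins are below the cross-section table and carry no fluence
  # through any realistic inherent filtration
  centers <- centers[centers < kvp & centers >= 1]
  mu_w <- mass_attenuation("tungsten", centers)   # cm^2/g

  # Emission along the electron slowing-down path: d2N/(dE dT) proportional
  # to (T - E)^(p-1); photons created while the electron has energy T escape
  # through a tungsten path (T0^2 - T^2)/C_TW * csc(theta). At p = 1 this is
  # the classical Kramers kZ(E0/E - 1). 16-point Gauss-Legendre per bin.
  gl <- .gauss_legendre16()
  p <- cst$brems_p0 + cst$brems_p1 * kvp / 100
  n <- vapply(seq_along(centers), function(i) {
    e <- centers[i]
    t_nodes <- e + (kvp - e) * (gl$x + 1) / 2
    att <- exp(-mu_w[i] * (kvp^2 - t_nodes^2) / cst$tw_c * csc)
    shape <- p * ((t_nodes - e) / kvp)^(p - 1)
    (cst$kramers_k * 74 / e) * (kvp - e) / 2 * sum(gl$w * att * shape)
  }, 0)

  fl <- n * bin_width

  # tungsten K characteristic lines
  if (kvp > KV_W_KEDGE) {
    n_k <- cst$kchar_a * ((kvp / KV_W_KEDGE) - 1)^cst$kchar_exp
    mu_l <- mass_attenuation("tungsten", .kv_wlines$energy)
    for (j in seq_len(nrow(.kv_wlines))) {
      el <- .kv_wlines$energy[j]
      t_nodes <- KV_W_KEDGE + (kvp - KV_W_KEDGE) * (gl$x + 1) / 2
      att <- sum(gl$w * exp(-mu_l[j] * (kvp^2 - t_nodes^2) / cst$tw_c * csc)) / 2
      idx <- findInterval(el, centers - bin_width / 2)
      if (idx >= 1 && idx <= length(fl)) {
        fl[idx] <- fl[idx] +
          n_k * .kv_wlines$rel[j] / sum(.kv_wlines$rel) * att
      }
    }
  }

  fl <- fl * KV_ELECTRONS_PER_MAS / (4 * pi) * normalization
  sp <- energy_spectrum(centers, fl, kvp = kvp, anode_angle = anode_angle,
                        filtration = numeric(), absolute = TRUE)
  for (i in seq_along(filtration)) {
    sp <- apply_filter(sp, names(filtration)[i], filtration[[i]])
  }
  sp
}

.gauss_legendre16 <- function() {
  if (is.null(.kv_cache$gl16)) {
    # Golub-Welsch from the Jacobi matrix
    k <- 1:15
    b <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, 16, 16)
    J[cbind(k, k + 1)] <- b
    J[cbind(k + 1, k)] <- b
    ev <- eigen(J, symmetric = TRUE)
    .kv_cache$gl16 <- list(x = rev(ev$values), w = rev(2 * ev$vectors[1, ]^2))
  }
  .kv_cache$gl16
}

#' Attenuate a spectrum through a filter
#'
#' Per-bin Beer-Lambert attenuation: fluence is multiplied by
#' \code{exp(-(mu/rho)(E) * rho * t)}; the filtration record is extended.
#'
#' @param spectrum A \code{kv_spectrum}.
#' @param mat Filter material (name or \code{kv_material}).
#' @param thickness_mm Filter thickness in mm (>= 0).
#' @return The filtered \code{kv_spectrum}.
#' @export
apply_filter <- function(spectrum, mat, thickness_mm) {
  if (thickness_mm < 0) stop("filter thickness must be non-negative")
  mat <- get_material(mat)
  mu <- linear_attenuation(mat, spectrum$energy)       # 1/cm
  out <- spectrum
  out$fluence <- spectrum$fluence * exp(-mu * thickness_mm / 10)
  filt <- stats::setNames(thickness_mm, mat$name)
  out$filtration <- c(spectrum$filtration, filt)
  out
}

# Relative air-kerma weighting Sum N_i E_i (mu_en/rho)_air(E_i); distance and
# unit constants cancel in kerma ratios.
.kerma_weight <- function(spectrum) {
  muen <- mass_energy_absorption("air", spectrum$energy)
  sum(spectrum$fluence * spectrum$energy * muen)
}

#' First half-value layer of a spectrum
#'
#' Thickness of \code{mat} that halves the air-kerma rate, solved by
#' bracketing and bisection to the requested tolerance.
#'
#' @param spectrum A \code{kv_spectrum} with positive total fluence.
#' @param mat Attenuator material (default copper).
#' @param tol_mm Solution tolerance in mm (default 1e-3).
#' @return HVL in mm.
#' @export
half_value_layer <- function(spectrum, mat = "copper", tol_mm = 1e-3) {
  if (sum(spectrum$fluence) <= 0) stop("spectrum has no fluence")
  mat <- get_material(mat)
  k0 <- .kerma_weight(spectrum)
  f <- function(x) .kerma_weight(apply_filter(spectrum, mat, x)) / k0 - 0.5
  hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1024) stop("half-value layer search failed to bracket within 1 m")
  }
  stats::uniroot(f, c(0, hi), tol = tol_mm)$root
}

#' Central-axis air-kerma rate of an absolute spectrum
#'
#' Point detector on the central axis in vacuum geometry:
#' K = Sum N_i E_i (mu_en/rho)_air(E_i) / d^2, converted to Gy/min at the
#' stated tube current.
#'
#' @param spectrum A \code{kv_spectrum} on the absolute (photons/mAs/sr) scale.
#' @param distance_mm Source-detector distance in mm (> 0).
#' @param current_mA Tube current in mA (> 0).
#' @return Air-kerma rate in Gy/min.
#' @export
air_kerma_rate <- function(spectrum, distance_mm = 500, current_mA = 10) {
  if (!isTRUE(spectrum$absolute)) {
    stop("spectrum is on a relative scale; absolute normalization required")
  }
  if (distance_mm <= 0 || current_mA <= 0) {
    stop("distance and current must be positive")
  }
  d_cm <- distance_mm / 10
  muen <- mass_energy_absorption("air", spectrum$energy)
  k_per_mas <- sum(spectrum$fluence * spectrum$energy * KV_KEV_TO_J * muen) *
    1000 / d_cm^2
  k_per_mas * current_mA * 60
}

#' Cs-137 line spectrum
#'
#' @param normalization Total photons/mAs/sr equivalent normalization
#'   (arbitrary source strength unit; default 1).
#' @return A monoenergetic \code{kv_spectrum} with a single line at 662 keV.
#' @export
cs137_spectrum <- function(normalization = 1) {
  energy_spectrum(662, normalization, kvp = NA, anode_angle = NA,
                  is_line_spectrum = TRUE, absolute = TRUE)
}

#' Read / write spectra as two-column text
#'
#' Plain-text serialization: \code{#}-prefixed header lines record kvp, anode
#' angle, filtration, and scale; data lines hold \code{energy_keV fluence}.
#'
#' @param spectrum A \code{kv_spectrum}.
#' @param path File path.
#' @return \code{write_spectrum}: the path invisibly; \code{read_spectrum}:
#'   a \code{kv_spectrum}.
#' @export
write_spectrum <- function(spectrum, path) {
  hdr <- c(
    sprintf("# kvp: %s", spectrum$kvp),
    sprintf("# anode_angle: %s", spectrum$anode_angle),
    sprintf("# filtration: %s",
            paste(sprintf("%s=%.6g", names(spectrum$filtration),
                          spectrum$filtration), collapse = " ")),
    sprintf("# is_line_spectrum: %s", spectrum$is_line_spectrum),
    sprintf("# absolute: %s", spectrum$absolute),
    "# energy_keV fluence"
  )
  writeLines(c(hdr, sprintf("%.6f %.8e", spectrum$energy, spectrum$fluence)),
             path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  dat <- utils::read.table(text = grep("^#", lines, value = TRUE,
                                       invert = TRUE))
  filt <- numeric()
  fs <- get_field("filtration")
  if (!is.na(fs) && nzchar(fs)) {
    parts <- strsplit(strsplit(fs, " +")[[1]], "=")
    filt <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0),
                            vapply(parts, `[`, "", 1))
  }
  energy_spectrum(dat[[1]], dat[[2]],
                  kvp = suppressWarnings(as.numeric(get_field("kvp"))),
                  anode_angle =
                    suppressWarnings(as.numeric(get_field("anode_angle"))),
                  filtration = filt,
                  is_line_spectrum = identical(get_field("is_line_spectrum"),
                                               "TRUE"),
                  absolute = !identical(get_field("absolute"), "FALSE"))
}
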