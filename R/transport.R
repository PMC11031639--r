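# R interface to the Monte Carlo transport kernel: configuration, material
# table preparation, dose grid construction, uncertainty estimation and
# MetaImage-style dose I/O.

KV_MAX_SOURCE_KEV <- 320  # kerma-approximation validity bound for tubes

#' Transport configuration
#'
#' @param n_histories Number of primary histories (>= 1). All descendants of
#'   one primary are scored as one history.
#' @param seed Integer RNG seed; every history draws from its own
#'   deterministic substream, so results are independent of scheduling.
#' @param pcut_keV Photon cutoff energy in keV (default 10); photons falling
#'   below it deposit locally.
#' @param rayleigh Include coherent (Rayleigh) scattering (default TRUE).
#' @param n_split Interaction splitting factor for primaries (collision
#'   estimator only; default 1 = analog).
#' @param primaries_only Terminate histories at the first interaction
#'   (oracle scoring mode).
#' @param estimator \code{"track"} (expected-value track-length kerma
#'   scoring, default) or \code{"collision"} (analog deposits at interaction
#'   sites).
#' @param batch_size Accepted for interface compatibility; scoring is
#'   history-by-history, so results do not depend on any batching.
#' @return An object of class \code{kv_transport_config}.
#' @export
transport_config <- function(n_histories = 1e5, seed = 1L, pcut_keV = 10,
                             rayleigh = TRUE, n_split = 1L,
                             primaries_only = FALSE,
                             estimator = c("track", "collision"),
                             batch_size = NULL) {
  if (n_histories < 1) stop("n_histories must be >= 1")
  if (pcut_keV <= 0) stop("pcut_keV must be positive")
  if (n_split < 1) stop("n_split must be >= 1")
  structure(list(n_histories = as.integer(n_histories),
                 seed = as.integer(seed), pcut_keV = pcut_keV,
                 rayleigh = isTRUE(rayleigh), n_split = as.integer(n_split),
                 primaries_only = isTRUE(primaries_only),
                 estimator = match.arg(estimator),
                 batch_size = batch_size),
            class = "kv_transport_config")
}

# per-material 1-keV-grid lookup tables for the kernel
.material_tables <- function(materials, e_max, rayleigh = TRUE) {
  energies <- seq(1, ceiling(e_max) + 1)
  nmat <- length(materials)
  mu <- muen <- fpe <- finc <- matrix(0, length(energies), nmat)
  for (m in seq_len(nmat)) {
    mat <- materials[[m]]
    ch <- material_channels(mat, energies)           # cm^2/g
    coh <- if (rayleigh) ch$coh else 0
    tot <- ch$photo + ch$incoh + coh
    mu[, m] <- tot * mat$density                     # 1/cm
    muen[, m] <- mass_energy_absorption(mat, energies) * mat$density
    fpe[, m] <- ch$photo / tot
    finc[, m] <- ch$incoh / tot
  }
  list(energies = energies, mu = mu, muen = muen, fpe = fpe, finc = finc)
}

#' Run photon Monte Carlo transport
#'
#' Transports \code{n_histories} primaries from the beam's truncated
#' isotropic point source through the voxel phantom. Energy deposition uses
#' the kerma approximation (secondary electrons deposit at the photon
#' interaction site), valid for source energies up to 320 keV where electron
#' ranges are sub-millimetre; a warning is issued above that. Statistical
#' uncertainty is estimated history by history.
#'
#' @param phantom A \code{kv_phantom}.
#' @param beam A \code{kv_beam}; the beam must intersect the phantom bounds.
#' @param config A \code{kv_transport_config}.
#' @return A \code{kv_dose} grid: per-voxel dose in Gy per source particle,
#'   relative (1 sigma) uncertainty, history count and provenance.
#' @export
run_transport <- function(phantom, beam, config = transport_config()) {
  stopifnot(inherits(phantom, "kv_phantom"), inherits(beam, "kv_beam"))
  d <- dim(phantom$labels)
  e_max <- max(beam$spectrum$energy)
  if (e_max > KV_MAX_SOURCE_KEV && !beam$spectrum$is_line_spectrum) {
    warning("source energies above 320 keV: kerma approximation may bias ",
            "dose near interfaces")
  }
  if (config$pcut_keV >= e_max) stop("pcut must be below the maximum source energy")

  # beam must intersect the phantom bounds: check the field pyramid against
  # the grid's lateral extent at the grid top
  hx <- beam$field_mm[1] / 2
  hy <- beam$field_mm[2] / 2
  ztop <- utils::tail(phantom$z_edges, 1)
  scale <- (beam$sid_mm - ztop) / beam$sid_mm
  if (scale <= 0) stop("phantom extends to or above the focal spot")
  xr <- c(phantom$origin[1], phantom$origin[1] + d[1] * phantom$dx)
  yr <- c(phantom$origin[2], phantom$origin[2] + d[2] * phantom$dy)
  if (xr[1] > hx * scale || xr[2] < -hx * scale ||
      yr[1] > hy * scale || yr[2] < -hy * scale) {
    if (hx > 0 && hy > 0) stop("beam field misses the phantom entirely")
  }

  tb <- .material_tables(phantom$materials, e_max, config$rayleigh)
  cdf <- cumsum(beam$spectrum$fluence) / sum(beam$spectrum$fluence)
  res <- cpp_transport(as.integer(phantom$labels), as.integer(d),
                       phantom$origin, phantom$dx, phantom$dy,
                       phantom$z_edges,
                       tb$mu, tb$muen, tb$fpe, tb$finc, tb$energies[1],
                       beam$sid_mm, c(hx, hy),
                       beam$spectrum$energy, cdf,
                       config$n_histories, as.numeric(config$seed),
                       config$pcut_keV, config$primaries_only,
                       if (config$estimator == "track") 0L else 1L,
                       config$n_split)

  n <- config$n_histories
  s1 <- array(res$s1, dim = d)
  s2 <- array(res$s2, dim = d)
  mean_e <- s1 / n                     # keV per history per voxel
  var_e <- pmax(0, (s2 / n - mean_e^2) / (n - 1))
  rel <- array(0, dim = d)
  pos <- mean_e > 0
  rel[pos] <- sqrt(var_e[pos]) / mean_e[pos]

  dens <- vapply(phantom$materials, `[[`, 0, "density")[phantom$labels]
  dz <- diff(phantom$z_edges)
  vol_cm3 <- array(phantom$dx * phantom$dy, dim = d) *
    aperm(array(dz, dim = d[c(3, 1, 2)]), c(2, 3, 1)) / 1000
  mass_g <- array(dens, dim = d) * vol_cm3
  dose <- array(0, dim = d)
  dose[mass_g > 0] <- mean_e[mass_g > 0] * 1.602176634e-13 / mass_g[mass_g > 0]

  structure(list(
    dose = dose, rel_unc = rel,
    origin = phantom$origin, dx = phantom$dx, dy = phantom$dy,
    z_edges = phantom$z_edges, n_histories = n,
    quantifier = "Dm,m", absolute = FALSE,
    edep_total_keV = res$edep_total, e_emitted_keV = res$e_emitted,
    provenance = list(
      seed = config$seed, n_histories = n, pcut_keV = config$pcut_keV,
      rayleigh = config$rayleigh, estimator = config$estimator,
      n_split = config$n_split, primaries_only = config$primaries_only,
      kvp = beam$spectrum$kvp, filtration = as.list(beam$spectrum$filtration),
      sid_mm = beam$sid_mm, field_mm = beam$field_mm,
      phantom_hash = phantom_hash(phantom),
      package_version = as.character(utils::packageVersion("kvdosim"))
    )
  ), class = "kv_dose")
}

# stable content hash of a phantom (geometry + labels + materials)
phantom_hash <- function(phantom) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(dim(phantom$labels), as.integer(phantom$labels),
               phantom$origin, phantom$dx, phantom$dy, phantom$z_edges,
               lapply(phantom$materials, function(m) {
                 list(m$name, m$density, m$composition)
               })), f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.kv_dose <- function(x, ...) {
  d <- dim(x$dose)
  cat(sprintf("<dose grid> %d x %d x %d voxels, %s, %s\n", d[1], d[2], d[3],
              if (x$absolute) "Gy (absolute)" else "Gy/particle", x$quantifier))
  cat(sprintf("  %g histories, max dose %.4g, median rel. uncertainty %.3g\n",
              x$n_histories, max(x$dose),
              stats::median(x$rel_unc[x$dose > 0])))
  invisible(x)
}

# voxel center coordinates of a dose grid
dose_centers <- function(dose) {
  d <- dim(dose$dose)
  list(x = dose$origin[1] + (seq_len(d[1]) - 0.5) * dose$dx,
       y = dose$origin[2] + (seq_len(d[2]) - 0.5) * dose$dy,
       z = (dose$z_edges[-1] + dose$z_edges[-length(dose$z_edges)]) / 2)
}

#' History-by-history relative uncertainty from accumulated sums
#'
#' \code{sigma_rel = sqrt((S2/N - (S1/N)^2) / (N - 1)) / (S1/N)} with S1, S2
#' the per-history sum and sum of squares of the scored quantity.
#'
#' @param s1,s2 Per-voxel sum and sum of squares over histories.
#' @param n Number of histories (>= 2).
#' @return Relative (1 sigma) uncertainty, 0 where nothing was scored.
#' @export
estimate_uncertainty <- function(s1, s2, n) {
  if (n < 2) stop("history-by-history uncertainty requires n >= 2 histories")
  m <- s1 / n
  v <- pmax(0, (s2 / n - m^2) / (n - 1))
  out <- rep(0, length(m))
  out[m > 0] <- sqrt(v[m > 0]) / m[m > 0]
  if (is.null(dim(s1))) out else array(out, dim = dim(s1))
}

#' Uncertainty summary over the high-dose region
#'
#' Maximum and mean relative uncertainty over voxels receiving more than
#' \code{threshold} of the maximum dose (the reference acceptance region
#' uses threshold 0.5).
#'
#' @param dose A \code{kv_dose}.
#' @param threshold Dose threshold as a fraction of the maximum.
#' @return List with \code{max}, \code{mean}, and \code{n_voxels}.
#' @export
region_uncertainty <- function(dose, threshold = 0.5) {
  stopifnot(inherits(dose, "kv_dose"))
  mx <- max(dose$dose)
  if (mx <= 0) stop("dose grid is all zero")
  sel <- dose$dose > threshold * mx
  list(max = max(dose$rel_unc[sel]), mean = mean(dose$rel_unc[sel]),
       n_voxels = sum(sel))
}

#' Write / read a dose grid
#'
#' MetaImage header/raw pairs for dose (\code{<base>_dose.mhd/.raw}) and
#' relative uncertainty (\code{<base>_unc.mhd/.raw}, MET_DOUBLE), plus a
#' JSON provenance sidecar \code{<base>_provenance.json} recording the beam,
#' phantom hash, transport configuration, seed and exact z edges.
#'
#' @param dose A \code{kv_dose}.
#' @param base Path base.
#' @return \code{write_dose}: base invisibly; \code{read_dose}: a
#'   \code{kv_dose}.
#' @export
write_dose <- function(dose, base) {
  d <- dim(dose$dose)
  write_field <- function(arr, suffix) {
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False",
             sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
             sprintf("ElementSpacing = %.9g %.9g %.9g", dose$dx, dose$dy,
                     mean(diff(dose$z_edges))),
             sprintf("Offset = %.9g %.9g %.9g", dose$origin[1],
                     dose$origin[2], dose$origin[3]),
             "ElementType = MET_DOUBLE",
             sprintf("ElementDataFile = %s_%s.raw", basename(base), suffix))
    writeLines(hdr, sprintf("%s_%s.mhd", base, suffix))
    con <- file(sprintf("%s_%s.raw", base, suffix), "wb")
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
    close(con)
  }
  write_field(dose$dose, "dose")
  write_field(dose$rel_unc, "unc")
  meta <- list(n_histories = dose$n_histories, quantifier = dose$quantifier,
               absolute = dose$absolute, z_edges = dose$z_edges,
               edep_total_keV = dose$edep_total_keV,
               e_emitted_keV = dose$e_emitted_keV,
               provenance = dose$provenance)
  jsonlite::write_json(meta, paste0(base, "_provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(base)
}

#' @rdname write_dose
#' @export
read_dose <- function(base) {
  read_field <- function(suffix) {
    hdr <- readLines(sprintf("%s_%s.mhd", base, suffix))
    get <- function(key) {
      trimws(sub("^[^=]*=", "", grep(paste0("^", key, " *="), hdr,
                                     value = TRUE)[1]))
    }
    d <- as.integer(strsplit(get("DimSize"), " +")[[1]])
    off <- as.numeric(strsplit(get("Offset"), " +")[[1]])
    sp <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
    con <- file(sprintf("%s_%s.raw", base, suffix), "rb")
    v <- readBin(con, "numeric", n = prod(d), size = 8L, endian = "little")
    close(con)
    list(arr = array(v, dim = d), origin = off, sp = sp)
  }
  dd <- read_field("dose")
  uu <- read_field("unc")
  meta <- jsonlite::read_json(paste0(base, "_provenance.json"),
                              simplifyVector = TRUE)
  structure(list(dose = dd$arr, rel_unc = uu$arr, origin = dd$origin,
                 dx = dd$sp[1], dy = dd$sp[2],
                 z_edges = as.numeric(meta$z_edges),
                 n_histories = meta$n_histories,
                 quantifier = meta$quantifier, absolute = meta$absolute,
                 edep_total_keV = meta$edep_total_keV,
                 e_emitted_keV = meta$e_emitted_keV,
                 provenance = as.list(meta$provenance)),
            class = "kv_dose")
}
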