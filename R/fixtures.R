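# Named experimental fixtures: the depth-dose stacks, the lead slit-shield
# setups, the radial film layout and the in-air calibration point, each with
# its matching beam. Tube currents follow the machine settings used per
# potential (300 kV / 10 mA, 200 kV / 12 mA, 100 kV / 25 mA).

.kv_fixture_names <- c("depth_dose_pw", "depth_dose_rb2", "slit_3mm",
                       "slit_5mm", "slit_10mm", "slit_10mm_offset100",
                       "radial_film_x", "radial_film_y", "airkerma_point")

.kv_current_for <- function(kvp) {
  if (kvp >= 300) 10 else if (kvp >= 200) 12 else 25
}

#' Experimental fixtures
#'
#' Builds one of the named cabinet setups with its printed dimensions:
#' 60 x 60 mm slab stacks (5.04 mm Plastic Water LR or 5.03 mm RB2 bone)
#' interleaved with five 0.278 mm films on a 10 mm base and the 10 mm PMMA
#' shelf at SID 500 mm; 80 x 80 x 3.454 mm lead slit shields (3/5/10 mm
#' slits, 0 or 100 mm lateral offset) on the Plastic Water stack at 0.25 mm
#' lateral voxels; the 300 mm radial film span under 5 mm of Plastic Water;
#' and the free-in-air kerma point at 500 mm.
#'
#' @param name Fixture name; one of \code{depth_dose_pw},
#'   \code{depth_dose_rb2}, \code{slit_3mm}, \code{slit_5mm},
#'   \code{slit_10mm}, \code{slit_10mm_offset100}, \code{radial_film_x},
#'   \code{radial_film_y}, \code{airkerma_point}.
#' @param kvp Tube potential; defaults to 300 kV for depth-dose, radial and
#'   air-kerma fixtures and 100 kV for the slit fixtures.
#' @param voxel_xy_mm Lateral voxel size; defaults to 1 mm (0.25 mm for the
#'   slit fixtures, 2 mm for the radial film grid).
#' @return List with \code{name}, \code{phantom} (NULL for the in-air
#'   point), \code{beam}, and \code{description}.
#' @export
fixture <- function(name, kvp = NULL, voxel_xy_mm = NULL) {
  if (!name %in% .kv_fixture_names) {
    stop("unknown fixture '", name, "'; available: ",
         paste(.kv_fixture_names, collapse = ", "))
  }
  is_slit <- grepl("^slit", name)
  if (is.null(kvp)) kvp <- if (is_slit) 100 else 300
  sp <- generate_spectrum(kvp)
  mk_beam <- function(field) {
    beam_config(sp, sid_mm = 500, field_mm = field,
                current_mA = .kv_current_for(kvp))
  }

  if (name == "airkerma_point") {
    return(list(name = name, phantom = NULL, beam = mk_beam(c(320, 320)),
                description = "free-in-air kerma point, 500 mm on axis"))
  }
  if (name %in% c("depth_dose_pw", "depth_dose_rb2")) {
    vx <- voxel_xy_mm %||% 1
    ph <- if (name == "depth_dose_pw") {
      build_depth_dose_phantom(voxel_xy_mm = vx)
    } else {
      build_depth_dose_phantom(slab_material = "rb2_bone",
                               slab_thickness = 5.03, voxel_xy_mm = vx)
    }
    # field covers the whole cropped grid (open field) so every scoring
    # column sees the full truncated-isotropic fluence
    return(list(name = name, phantom = ph, beam = mk_beam(c(120, 120)),
                description = "slab/film depth-dose stack on the shelf"))
  }
  if (is_slit) {
    vx <- voxel_xy_mm %||% 0.25
    slit <- c(slit_3mm = 3, slit_5mm = 5, slit_10mm = 10,
              slit_10mm_offset100 = 10)[[name]]
    off <- if (name == "slit_10mm_offset100") 100 else 0
    ph <- build_depth_dose_phantom(voxel_xy_mm = vx)
    ph <- add_slit_shield(ph, slit_width_mm = slit,
                          lateral_offset_mm = off)
    return(list(name = name, phantom = ph, beam = mk_beam(c(320, 320)),
                description = sprintf(
                  "lead slit shield (%g mm slit, %g mm offset) on the Plastic Water stack",
                  slit, off)))
  }
  # radial film fixtures: a single large film strip band under 5 mm of
  # Plastic Water spanning 300 mm across the shelf
  vx <- voxel_xy_mm %||% 2
  along_x <- name == "radial_film_x"
  span <- 320; width <- 60
  nx <- as.integer(round((if (along_x) span else width) / vx))
  ny <- as.integer(round((if (along_x) width else span) / vx))
  z_edges <- c(-10, -5, 0, 0.278, 0.278 + 2.5, 0.278 + 5)
  mats <- list(get_material("air"), get_material("pmma"),
               get_material("water"), get_material("plastic_water_lr"))
  labels <- array(1L, dim = c(nx, ny, length(z_edges) - 1L))
  labels[, , 1:2] <- 2L   # shelf
  labels[, , 3] <- 3L     # film plane
  labels[, , 4:5] <- 4L   # 5 mm plastic water cover
  ph <- voxel_phantom(labels,
                      origin = c(-(if (along_x) span else width) / 2,
                                 -(if (along_x) width else span) / 2, -10),
                      dx = vx, dy = vx, z_edges = z_edges, materials = mats)
  attr(ph, "film_z_mm") <- 0.139
  list(name = name, phantom = ph, beam = mk_beam(c(320, 320)),
       description = "radial film band under 5 mm Plastic Water")
}

#' List available fixtures
#' @return Character vector of fixture names.
#' @export
fixture_names <- function() .kv_fixture_names
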