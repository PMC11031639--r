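# Dose evaluation: profiles, FWHM, region metrics, DVH, quantifiers, report

fake_dose <- function(arr, dx = 1, dy = 1, unc = NULL) {
  d <- dim(arr)
  structure(list(dose = arr,
                 rel_unc = if (is.null(unc)) array(0, d) else unc,
                 origin = c(-d[1] * dx / 2, -d[2] * dy / 2, -d[3]),
                 dx = dx, dy = dy, z_edges = seq(-d[3], 0, by = 1),
                 n_histories = 10, quantifier = "Dm,m", absolute = FALSE,
                 provenance = list()), class = "kv_dose")
}

test_that("depth_dose averages the ROI and propagates uncertainty", {
  arr <- array(rep(1:4, each = 16), dim = c(4, 4, 4))
  d <- fake_dose(arr)
  prof <- depth_dose(d, roi_xy = list(x = c(-2, 2), y = c(-2, 2)))
  expect_equal(prof$dose, 1:4)
  expect_equal(attr(prof, "depth_mm"), c(3.5, 2.5, 1.5, 0.5))
  # single-column ROI returns that column
  one <- depth_dose(d, roi_xy = list(x = c(-2, -1.5), y = c(-2, -1.5)))
  expect_equal(one$dose, as.numeric(arr[1, 1, ]))
  expect_error(depth_dose(d, roi_xy = list(x = c(9, 10), y = c(0, 1))),
               "empty region")
  # uniform grid -> flat profile; quadrature of equal absolute errors
  u <- fake_dose(array(2, dim = c(4, 4, 4)),
                 unc = array(0.1, dim = c(4, 4, 4)))
  pu <- depth_dose(u, roi_xy = list(x = c(-2, 2), y = c(-2, 2)))
  expect_true(all(pu$dose == 2))
  expect_equal(pu$uncertainty, rep(0.2 / 4, 4))   # sqrt(16)*0.2/16
})

test_that("fwhm recovers closed-form widths", {
  # symmetric triangle peaking at 1 with a 10 mm base -> FWHM 5
  tri <- data.frame(position_mm = seq(-5, 5, by = 0.5))
  tri$dose <- pmax(0, 1 - abs(tri$position_mm) / 5)
  expect_equal(fwhm(tri), 5, tolerance = 1e-9)
  # sampled Gaussian -> 2.355 sigma within the grid resolution
  g <- data.frame(position_mm = seq(-15, 15, by = 0.25))
  g$dose <- exp(-g$position_mm^2 / (2 * 3^2))
  expect_equal(fwhm(g), 2 * sqrt(2 * log(2)) * 3, tolerance = 0.25)
  # truncated profile errors
  tr <- data.frame(position_mm = 0:10, dose = seq(1, 0.6, length.out = 11))
  expect_error(fwhm(tr), "truncated")
})

test_that("region_mean_80 matches hand computation and is inclusive", {
  expect_equal(region_mean_80(c(10, 9, 8.5, 1)), mean(c(10, 9, 8.5)))
  expect_equal(region_mean_80(c(10, 9, 8.5, 1)), 9.166667, tolerance = 1e-6)
  # boundary value exactly 0.8 * max is included
  expect_equal(region_mean_80(c(10, 8, 1)), 9)
  expect_equal(region_mean_80(rep(4.2, 7)), 4.2)
  expect_error(region_mean_80(numeric()), "no dose")
})

test_that("DVH is monotone, normalized and matches brute-force counting", {
  expect_error(dvh(array(1, c(2, 2, 2)), mask = array(FALSE, c(2, 2, 2))),
               "empty structure")
  u <- dvh(array(2, c(3, 3, 3)))
  expect_equal(u$volume_fraction[1], 1)
  expect_true(all(diff(u$volume_fraction) <= 0))
  expect_equal(dose_volume_metric(u, "D50"), 2, tolerance = 0.02)

  two <- dvh(c(1, 3), n_bins = 101)
  expect_equal(dose_volume_metric(two, "V2Gy"), 0.5)

  set.seed(99)
  vals <- array(stats::runif(1000, 0, 5), dim = c(10, 10, 10))
  curve <- dvh(vals, n_bins = 60)
  for (i in c(1, 17, 35, 60)) {
    expect_equal(curve$volume_fraction[i],
                 mean(vals >= curve$dose[i]))        # counting oracle
  }
  expect_equal(curve$volume_fraction[60], 0)  # curve ends at 0
})

test_that("dose-to-water conversion follows the coefficient ratios", {
  labels <- array(1L, dim = c(2, 2, 2))
  ph_w <- voxel_phantom(labels, c(0, 0, 0), 1, 1, 0:2,
                        materials = list("water"))
  d <- fake_dose(array(3, c(2, 2, 2)))
  sp <- generate_spectrum(100)
  expect_equal(dose_to_water(d, ph_w, sp)$dose, d$dose)   # water unchanged

  ph_b <- voxel_phantom(labels, c(0, 0, 0), 1, 1, 0:2,
                        materials = list("rb2_bone"))
  line <- energy_spectrum(60, 1, is_line_spectrum = TRUE)
  conv <- dose_to_water(d, ph_b, line)
  fac <- mass_energy_absorption("water", 60) /
    mass_energy_absorption("rb2_bone", 60)
  expect_equal(conv$dose[1] / d$dose[1], fac, tolerance = 1e-12)
  expect_lt(fac, 1)                # bone Dm,m exceeds Dw,m at low energy
  expect_identical(conv$quantifier, "Dw,m")
  # conversion is not an involution: applying twice is an error
  expect_error(dose_to_water(conv, ph_b, line), "Dw,m")
})

test_that("lateral profiles slice the requested plane and axis", {
  arr <- array(0, dim = c(9, 5, 3))
  arr[, , 3] <- matrix(rep(c(1, 2, 5, 2, 1, 0, 0, 0, 0), 5), 9, 5)
  d <- fake_dose(arr)
  prof <- lateral_profile(d, z_mm = -0.5, axis = "x", window = 3)
  expect_equal(prof$dose[3], 5)
  expect_equal(which.max(prof$dose), 3L)
})

test_that("reports validate, round-trip and name missing fields", {
  fields <- list(machine = "cabinet", kvp = 300,
                 filtration_mm = list(beryllium = 3, copper = 0.2),
                 hvl_mm = 1.15, sid_mm = 500, field_mm = c(100, 100),
                 current_mA = 10, phantom = "depth_dose_pw",
                 calibration = "F_cal 3e11 particles/mAs",
                 dose_metrics = list(max = 1.3), uncertainty = list(max = 0.01),
                 software_version = "0.1.0", seed = 1)
  f <- tempfile(fileext = ".json")
  export_report(fields, f)
  back <- read_report(f)
  expect_equal(back$kvp, 300)
  expect_equal(back$hvl_mm, 1.15)
  expect_true(file.exists(sub("json$", "txt", f)))
  expect_error(export_report(fields[setdiff(names(fields), "calibration")]),
               "calibration")
})
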