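# Reference calibration, conversion factor, absolute dose

test_that("conversion factor is the identity for the reference beam", {
  sp <- generate_spectrum(300)
  beam <- beam_config(sp, sid_mm = 500, field_mm = c(100, 100))
  ref <- reference_calibration(2.5e11, sp, a_ref_mm2 = 100 * 100,
                               d_ref_mm = 500)
  expect_equal(conversion_factor(ref, beam)$f_cal, 2.5e11)
})

test_that("conversion factor scales linearly as the formula states", {
  sp3 <- generate_spectrum(300)
  sp1 <- generate_spectrum(100)
  ref <- reference_calibration(1e11, sp3, a_ref_mm2 = 1e4, d_ref_mm = 500)
  b0 <- beam_config(sp1, sid_mm = 500, field_mm = c(100, 100))
  f0 <- conversion_factor(ref, b0)$f_cal
  # doubled fluence doubles f_cal
  sp1x2 <- sp1; sp1x2$fluence <- 2 * sp1$fluence
  expect_equal(conversion_factor(ref, beam_config(sp1x2, 500,
                                                  c(100, 100)))$f_cal,
               2 * f0, tolerance = 1e-12)
  # halved distance quadruples f_cal
  expect_equal(conversion_factor(ref, beam_config(sp1, 250,
                                                  c(100, 100)))$f_cal,
               4 * f0, tolerance = 1e-12)
  # hand-computed ratio product
  hand <- 1e11 * sum(sp1$fluence) / sum(sp3$fluence) *
    (100 * 100 * 500^2) / (1e4 * 500^2)
  expect_equal(f0, hand, tolerance = 1e-12)
})

test_that("determine_sref round-trips the measured rate", {
  sp <- generate_spectrum(300)
  beam <- beam_config(sp, current_mA = 10)
  k_pp <- 2.3e-13                       # Gy/particle at the reference point
  ref <- determine_sref(1.560, beam, k_pp)
  expect_equal(k_pp * ref$s_ref * 10 * 60, 1.560, tolerance = 1e-12)
  expect_equal(determine_sref(2 * 1.560, beam, k_pp)$s_ref, 2 * ref$s_ref)
  expect_error(determine_sref(-1, beam, k_pp), "positive")
})

test_that("nearest_reference picks by HVL distance with kvp tie-break", {
  sp3 <- generate_spectrum(300)   # HVL ~1.15 mm Cu
  sp1 <- generate_spectrum(100)   # HVL ~0.20 mm Cu
  refs <- list(reference_calibration(1, sp3, 1e4, 500),
               reference_calibration(2, sp1, 1e4, 500))
  # beam at 200 kV has HVL ~0.56: |0.56-1.15| = 0.59 > |0.56-0.20| = 0.36
  beam <- beam_config(generate_spectrum(200))
  expect_equal(nearest_reference(refs, beam)$s_ref, 2)
  # single reference is returned regardless
  expect_equal(nearest_reference(refs[1], beam)$s_ref, 1)
  # exact tie: higher kvp wins
  beam06 <- beam_config(sp1)
  bh <- half_value_layer(beam06$spectrum)
  tie <- list(reference_calibration(10, sp1, 1e4, 500, hvl_mm = bh),
              reference_calibration(20, sp3, 1e4, 500, hvl_mm = bh))
  expect_equal(nearest_reference(tie, beam06)$s_ref, 20)
  expect_error(nearest_reference(list(), beam06), "no reference")
})

test_that("to_absolute applies mAs linearly and refuses double calibration", {
  dose <- structure(list(dose = array(2e-13, c(2, 2, 2)),
                         rel_unc = array(0, c(2, 2, 2)),
                         origin = c(0, 0, 0), dx = 1, dy = 1, z_edges = 0:2,
                         n_histories = 1, quantifier = "Dm,m",
                         absolute = FALSE, provenance = list()),
                    class = "kv_dose")
  fcal <- structure(list(f_cal = 1e11, kvp = 300, sid_mm = 500,
                         field_mm = c(100, 100), s_ref = 1e11,
                         ref_kvp = 300), class = "kv_conversion")
  # 600 mAs (10 mA x 60 s)
  abs1 <- to_absolute(dose, fcal, current_mA = 10, time_s = 60)
  expect_equal(abs1$dose[1], 2e-13 * 1e11 * 600)
  abs2 <- to_absolute(dose, fcal, current_mA = 10, time_s = 120)
  expect_equal(abs2$dose, 2 * abs1$dose)
  expect_equal(to_absolute(dose, fcal, 10, time_s = 0)$dose[1], 0)
  rate <- to_absolute(dose, fcal, current_mA = 10, rate = TRUE)
  expect_equal(rate$dose[1], 2e-13 * 1e11 * 600)  # Gy/min at 10 mA
  expect_error(to_absolute(abs1, fcal, 10, 60), "already absolute")
})

test_that("calibration files round-trip through the versioned schema", {
  refs <- list(reference_calibration(3.2e11, generate_spectrum(300), 1e4, 500,
                                     provenance = list(chamber = "NE2581",
                                                       date = "2024-01-01")),
               reference_calibration(1.1e11, generate_spectrum(100), 1e4, 500))
  f <- tempfile(fileext = ".yaml")
  write_calibrations(refs, f)
  back <- read_calibrations(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$s_ref, 3.2e11)
  expect_equal(back[[1]]$hvl_mm, refs[[1]]$hvl_mm, tolerance = 1e-6)
  expect_equal(back[[2]]$spectrum$kvp, 100)
  expect_equal(back[[1]]$provenance$chamber, "NE2581")
})

test_that("analytic kerma per particle matches a transport run in air", {
  sp <- generate_spectrum(300)
  beam <- beam_config(sp, sid_mm = 500, field_mm = c(60, 60),
                      t_filter_mm = 0)
  # thin air slab centered on the isocenter plane
  labels <- array(1L, dim = c(3, 3, 1))
  ph <- voxel_phantom(labels, c(-15, -15, -1), 10, 10, c(-1, 1),
                      materials = list("air"))
  d <- run_transport(ph, beam, transport_config(4e5, seed = 6))
  expect_equal(d$dose[2, 2, 1], air_kerma_per_particle(beam),
               tolerance = 0.05)
})

test_that("shipped air-kerma reference points load with provenance", {
  tab <- reference_airkerma()
  expect_equal(tab$kvp, c(300, 200, 100))
  expect_equal(tab$measured_gy_min, c(1.560, 0.715, 0.162))
  expect_equal(attr(tab, "distance_mm"), 500)
  expect_equal(attr(tab, "current_mA"), 10)
})
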