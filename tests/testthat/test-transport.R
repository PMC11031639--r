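# Monte Carlo transport: attenuation oracle, energy bookkeeping,
# history-by-history statistics, determinism, interfaces

water_column <- function(nz = 40, dz = 1, nxy = 1, dxy = 10) {
  labels <- array(2L, dim = c(nxy, nxy, nz))
  voxel_phantom(labels, origin = c(-nxy * dxy / 2, -nxy * dxy / 2, -nz * dz),
                dx = dxy, dy = dxy, z_edges = seq(-nz * dz, 0, by = dz),
                materials = list("air", "water"))
}

pencil_beam <- function(energy = 100) {
  sp <- energy_spectrum(energy, 1, is_line_spectrum = TRUE)
  beam_config(sp, sid_mm = 500, field_mm = c(0, 0), t_filter_mm = 0)
}

test_that("primaries-only depth dose follows exp(-mu d) within 3 sigma", {
  ph <- water_column()
  d <- run_transport(ph, pencil_beam(100),
                     transport_config(n_histories = 4e5, seed = 7,
                                      primaries_only = TRUE,
                                      estimator = "collision"))
  counts <- d$dose[1, 1, ] / max(d$dose)          # collision density
  depth_mm <- rev(seq_along(counts)) - 0.5
  fit <- stats::lm(log(counts) ~ depth_mm, weights = counts)
  slope <- -stats::coef(fit)[[2]] * 10            # 1/cm
  se <- summary(fit)$coefficients[2, 2] * 10
  mu <- linear_attenuation("water", 100)
  expect_lt(abs(slope - mu), 3 * max(se, 1e-4))
})

test_that("track and collision estimators agree on the mean dose", {
  ph <- water_column(nz = 10, dz = 4)
  beam <- pencil_beam(80)
  d_tr <- run_transport(ph, beam, transport_config(2e4, seed = 1))
  d_co <- run_transport(ph, beam, transport_config(2e5, seed = 2,
                                                   estimator = "collision"))
  expect_equal(mean(d_tr$dose), mean(d_co$dose), tolerance = 0.05)
})

test_that("near-vacuum phantoms collect no dose", {
  vac <- material("near_vacuum", 1e-12, c(H = 1))
  labels <- array(1L, dim = c(3, 3, 5))
  ph <- voxel_phantom(labels, c(-15, -15, -5), 10, 10, seq(-5, 0, 1),
                      materials = list(vac))
  d <- run_transport(ph, pencil_beam(100),
                     transport_config(1e3, seed = 1, estimator = "collision"))
  expect_true(all(d$dose == 0))
})

test_that("deposited energy never exceeds emitted energy", {
  ph <- water_column(nz = 20, dz = 5)
  sp <- generate_spectrum(300)
  beam <- beam_config(sp, field_mm = c(10, 10), t_filter_mm = 0)
  d <- run_transport(ph, beam, transport_config(5e4, seed = 5,
                                                estimator = "collision"))
  expect_lte(d$edep_total_keV, d$e_emitted_keV)
  expect_gt(d$edep_total_keV, 0)
})

test_that("fixed seeds reproduce dose grids exactly; seeds matter", {
  ph <- water_column(nz = 10, dz = 4, nxy = 3)
  sp <- generate_spectrum(100)
  beam <- beam_config(sp, field_mm = c(30, 30), t_filter_mm = 0)
  a <- run_transport(ph, beam, transport_config(2e4, seed = 42))
  b <- run_transport(ph, beam, transport_config(2e4, seed = 42))
  c <- run_transport(ph, beam, transport_config(2e4, seed = 43))
  expect_identical(a$dose, b$dose)
  expect_identical(a$rel_unc, b$rel_unc)
  expect_false(identical(a$dose, c$dose))
})

test_that("interaction splitting agrees with analog collision scoring", {
  ph <- water_column(nz = 10, dz = 4)
  beam <- pencil_beam(100)
  an <- run_transport(ph, beam, transport_config(2e5, seed = 3,
                                                 estimator = "collision"))
  sp <- run_transport(ph, beam, transport_config(2e4, seed = 4,
                                                 estimator = "collision",
                                                 n_split = 32))
  expect_equal(mean(sp$dose), mean(an$dose), tolerance = 0.05)
  # splitting improves per-voxel statistics at equal histories
  eq <- run_transport(ph, beam, transport_config(2e4, seed = 4,
                                                 estimator = "collision"))
  expect_lt(mean(sp$rel_unc[sp$dose > 0]), mean(eq$rel_unc[eq$dose > 0]))
})

test_that("history-by-history uncertainty has the stated closed forms", {
  # identical deposit every history -> zero variance
  # four histories each depositing 2.5: S1 = 10, S2 = 4 * 2.5^2 = 25
  expect_equal(estimate_uncertainty(rep(10, 4), rep(25, 4), 4), rep(0, 4))
  s1 <- c(5, 0)
  expect_equal(estimate_uncertainty(s1, s1^2, 100)[1], 1)  # single history
  expect_equal(estimate_uncertainty(s1, s1^2, 100)[2], 0)  # nothing scored
  expect_error(estimate_uncertainty(1, 1, 1), "n >= 2")
})

test_that("uncertainty scales as 1/sqrt(N)", {
  fx <- fixture("depth_dose_pw", kvp = 300, voxel_xy_mm = 4)
  r1 <- region_uncertainty(run_transport(fx$phantom, fx$beam,
                                         transport_config(5e4, seed = 1)))
  r4 <- region_uncertainty(run_transport(fx$phantom, fx$beam,
                                         transport_config(2e5, seed = 1)))
  expect_equal(r1$mean / r4$mean, 2, tolerance = 0.1)
})

test_that("region_uncertainty matches a brute-force mask oracle", {
  set.seed(31)
  dose <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  unc <- array(runif(5 * 4 * 3, 0, 0.2), dim = c(5, 4, 3))
  d <- structure(list(dose = dose, rel_unc = unc, origin = c(0, 0, 0),
                      dx = 1, dy = 1, z_edges = 0:3, n_histories = 10,
                      quantifier = "Dm,m", absolute = FALSE,
                      provenance = list()), class = "kv_dose")
  for (thr in c(0.3, 0.5, 0.9)) {
    mask <- dose > thr * max(dose)
    r <- region_uncertainty(d, thr)
    expect_equal(r$max, max(unc[mask]))
    expect_equal(r$mean, mean(unc[mask]))
    expect_equal(r$n_voxels, sum(mask))
  }
  # threshold 1 selects the argmax voxel only
  expect_equal(region_uncertainty(d, 1 - 1e-12)$n_voxels, 1)
})

test_that("bone voxels receive more dose than plastic water at 100 kV", {
  # side-by-side columns at the same depth (photoelectric enhancement)
  labels <- array(2L, dim = c(2, 1, 8))
  labels[2, , ] <- 3L
  ph <- voxel_phantom(labels, c(-20, -10, -16), 20, 20, seq(-16, 0, by = 2),
                      materials = list("air", "plastic_water_lr", "rb2_bone"))
  sp <- generate_spectrum(100)
  beam <- beam_config(sp, field_mm = c(40, 20), t_filter_mm = 0)
  d <- run_transport(ph, beam, transport_config(4e4, seed = 8))
  expect_true(all(d$dose[2, 1, ] > d$dose[1, 1, ]))
})

test_that("transport rejects impossible setups and warns above 320 keV", {
  ph <- water_column(nz = 5, dz = 2)
  sp <- generate_spectrum(100)
  off_beam <- beam_config(sp, field_mm = c(4, 4), t_filter_mm = 0)
  ph_far <- ph
  ph_far$origin[1] <- 500
  expect_error(run_transport(ph_far, off_beam, transport_config(10, seed = 1)),
               "misses the phantom")
  expect_warning(run_transport(ph, beam_config(energy_spectrum(
    seq(100.5, 500, by = 1), rep(1, 400), kvp = 500), field_mm = c(0, 0),
    t_filter_mm = 0), transport_config(100, seed = 1)),
    "kerma approximation")
})

test_that("dose grids round-trip through MetaImage I/O", {
  ph <- water_column(nz = 5, dz = 2, nxy = 2)
  d <- run_transport(ph, pencil_beam(60), transport_config(5e3, seed = 2))
  base <- file.path(tempdir(), "dose_roundtrip")
  write_dose(d, base)
  back <- read_dose(base)
  expect_equal(back$dose, d$dose, tolerance = 1e-12)
  expect_equal(back$rel_unc, d$rel_unc, tolerance = 1e-12)
  expect_equal(back$z_edges, d$z_edges)
  expect_equal(back$provenance$seed, d$provenance$seed)
})
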