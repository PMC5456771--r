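# Force-displacement processing: stretch/stress conversion, preload
# referencing, curve construction, resampling and averaging.

test_that("stretch and Cauchy stress conversions follow the tensile formulas", {
  expect_equal(stretch_from_displacement(0, 5), 1)
  expect_equal(stretch_from_displacement(1, 2), 1.5)
  expect_equal(stretch_from_displacement(0.32, 1.60), 1.2)
  expect_error(stretch_from_displacement(-0.1, 5), "compression")
  expect_error(stretch_from_displacement(0.1, 0), "positive")

  expect_equal(cauchy_stress_from_force(0, 2, 1.3), 0)
  expect_equal(cauchy_stress_from_force(1, 1, 1.5), 1.5)
  expect_equal(cauchy_stress_from_force(2, 4, 1.2), 0.6)
  expect_error(cauchy_stress_from_force(1, 0, 1.2), "positive")
  # doubling the area halves the stress (unit contract)
  expect_equal(cauchy_stress_from_force(2, 2, 1.2),
               cauchy_stress_from_force(2, 1, 1.2) / 2)
})

test_that("preload referencing re-origins the record at the first crossing", {
  geo <- specimen_geometry(2, 1)
  rec <- fd_record("sp1", "su1", "cartilage",
                   displacement = c(0, 0.1, 0.2, 0.5),
                   force = c(0, 0.05, 0.1, 0.4), geo)
  ref <- preload_reference(rec, preload = 0.1)
  expect_equal(ref$displacement, c(0, 0.3))
  expect_equal(ref$force, c(0.1, 0.4))

  # already at preload: unchanged
  rec2 <- fd_record("sp2", "su1", "cartilage",
                    displacement = c(0, 0.2, 0.4),
                    force = c(0.1, 0.2, 0.3), geo)
  ref2 <- preload_reference(rec2)
  expect_equal(ref2$displacement, rec2$displacement)
  expect_equal(ref2$force, rec2$force)

  # never reaching the preload is a rejected record
  rec3 <- fd_record("sp3", "su1", "cartilage",
                    displacement = c(0, 0.1), force = c(0.0, 0.05), geo)
  expect_error(preload_reference(rec3), "never reaches")
})

test_that("records with machine jitter are cleaned with a diagnostic", {
  geo <- specimen_geometry(2, 1)
  expect_message(
    rec <- fd_record("spj", "su", "connective",
                     displacement = c(0, 0.1, 0.1, 0.2, 0.15, 0.3),
                     force = c(0, 1, 2, 3, 4, 5), geo),
    "non-increasing")
  expect_equal(rec$displacement, c(0, 0.1, 0.2, 0.3))
  expect_equal(rec$force, c(0, 1, 3, 5))
})

test_that("a noiseless simulated record round-trips to its stress function", {
  p <- hyper_params("neo_hookean", 1)
  geo <- specimen_geometry(1, 1)
  rec <- simulate_record(p, scale = 1, geometry = geo, tissue = "smooth_muscle",
                         noise_sd = 0)
  cv <- record_to_curve(preload_reference(rec))
  expect_equal(cv$stretch[1], 1)
  expect_equal(cv$stress[1], 0)
  expect_lt(max(abs(cv$stress - cauchy_stress(p, cv$stretch))), 1e-9)

  # zero-force record maps to an all-zero stress curve
  geo2 <- specimen_geometry(2, 3)
  rec0 <- fd_record("z", "z", "cartilage", seq(0, 0.4, 0.1), rep(0.1, 5), geo2)
  cv0 <- record_to_curve(preload_reference(rec0))
  expect_equal(cv0$stress, rep(0, 5))

  # a curve from the reported cartilage coefficients has ~21 MPa linear slope
  rec_c <- simulate_record(tissue_yeoh$cartilage, 1,
                           specimen_geometry(4.13, 5), "cartilage", noise_sd = 0)
  cv_c <- record_to_curve(preload_reference(rec_c))
  expect_equal(linear_modulus(cv_c, 1.2)$modulus, 20.6, tolerance = 0.02)
})

test_that("stress scales inversely with cross-section but stretch does not", {
  p <- tissue_yeoh$connective
  set.seed(5)
  r1 <- simulate_record(p, 1, specimen_geometry(1.6, 2), "connective", noise_sd = 0)
  r2 <- simulate_record(p, 1, specimen_geometry(1.6, 4), "connective", noise_sd = 0)
  # doubling A0 roughly doubles forces (preload offset aside) ...
  expect_equal(max(r2$force), 2 * max(r1$force) - 0.1, tolerance = 1e-9)
  # ... but the recovered stress curve is unchanged
  c1 <- record_to_curve(preload_reference(r1))
  c2 <- record_to_curve(preload_reference(r2))
  expect_equal(c1$stress, c2$stress, tolerance = 1e-12)
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  cv <- stress_stretch_curve(seq(1, 1.5, 0.05), 10 * (seq(1, 1.5, 0.05) - 1))
  same <- resample_to_grid(cv, cv$stretch)
  expect_equal(same$stress, cv$stress)
  # interpolation is exact on a straight line
  g <- c(1.012, 1.111, 1.499)
  expect_equal(resample_to_grid(cv, g)$stress, 10 * (g - 1), tolerance = 1e-12)
  expect_error(resample_to_grid(cv, c(1.2, 1.51)), "extrapolation")
})

test_that("curve averaging has the closed-form mean and SD and is symmetric", {
  g <- seq(1, 1.5, 0.01)
  c1 <- stress_stretch_curve(g, 2 * (g - 1), tissue = "connective")
  c2 <- stress_stretch_curve(g, 4 * (g - 1), tissue = "connective")
  avg <- average_curves(list(c1, c2), lambda_max = 1.5)
  expect_equal(avg$stress, 3 * (g - 1), tolerance = 1e-12)
  expect_equal(avg$stress_sd, sqrt(2) * (g - 1), tolerance = 1e-12)
  expect_equal(avg$n_samples, 2L)

  # permutation invariance and idempotence on identical inputs
  avg_rev <- average_curves(list(c2, c1), lambda_max = 1.5)
  expect_equal(avg$stress, avg_rev$stress)
  twin <- average_curves(list(c1, c1), lambda_max = 1.5)
  expect_equal(twin$stress, c1$stress)
  expect_equal(twin$stress_sd, rep(0, length(g)))

  solo <- average_curves(list(c1), lambda_max = 1.5)
  expect_equal(solo$stress, c1$stress)
  expect_equal(solo$n_samples, 1L)

  # a short curve is excluded with a warning, not an error
  short <- stress_stretch_curve(seq(1, 1.3, 0.01), seq(0, 0.3, 0.01),
                                tissue = "connective")
  expect_warning(avg2 <- average_curves(list(c1, short), lambda_max = 1.5),
                 "excluding")
  expect_equal(avg2$n_samples, 1L)
  expect_error(average_curves(list(c1,
    stress_stretch_curve(g, g - 1, tissue = "cartilage"))), "mix")
})

test_that("record and curve CSVs round-trip through disk", {
  dir <- withr::local_tempdir()
  geo <- specimen_geometry(1.6, 3)
  set.seed(9)
  rec <- simulate_record(tissue_yeoh$connective, 1.2, geo, "connective")
  path <- file.path(dir, "rec.csv")
  write_record_csv(rec, path)
  back <- read_record_csv(path, rec$specimen_id, rec$subject_id, rec$tissue,
                          geo$L0, geo$A0)
  expect_equal(back$displacement, rec$displacement, tolerance = 1e-12)
  expect_equal(back$force, rec$force, tolerance = 1e-12)

  cv <- record_to_curve(preload_reference(rec))
  cpath <- file.path(dir, "curve.csv")
  write_curve_csv(cv, cpath)
  d <- read.csv(cpath)
  expect_named(d, c("stretch", "stress_MPa"))
  expect_equal(d$stress_MPa, cv$stress, tolerance = 1e-12)
})
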