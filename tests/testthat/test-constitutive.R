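# Strain-energy functions, uniaxial kinematics and Cauchy stress closed forms.

test_that("uniaxial invariants follow the incompressible closed forms", {
  st <- uniaxial_invariants(1)
  expect_equal(c(st$I1, st$I2, st$I3), c(3, 3, 1))

  st <- uniaxial_invariants(1.2)
  expect_equal(st$I1, 1.2^2 + 2 / 1.2, tolerance = 1e-12)
  expect_equal(st$I1, 3.10667, tolerance = 1e-5)
  expect_equal(st$I2, 3.09444, tolerance = 1e-5)
  expect_equal(st$I3, 1)
  expect_equal(st$lambda2, 1.2^-0.5)
  expect_equal(uniaxial_invariants(1.5)$I1, 3.58333, tolerance = 1e-5)

  # I1, I2 >= 3 for any positive stretch, I3 = 1 exactly
  lam <- exp(seq(log(0.3), log(3), length.out = 40))
  st <- uniaxial_invariants(lam)
  expect_true(all(st$I1 >= 3 - 1e-12))
  expect_true(all(st$I2 >= 3 - 1e-12))
  expect_equal(st$I3, rep(1, 40))

  expect_error(uniaxial_invariants(0), "positive")
  expect_error(uniaxial_invariants(-1), "positive")
})

test_that("deformation gradient is volume preserving and consistent with invariants", {
  expect_equal(deformation_gradient_uniaxial(1), diag(3))
  F4 <- deformation_gradient_uniaxial(4)
  expect_equal(F4, diag(c(4, 0.5, 0.5)))
  expect_equal(det(F4), 1, tolerance = 1e-14)

  # tr(C) for C = F'F reproduces I1 from the invariant formulas
  for (lam in c(1.05, 1.2, 1.5, 2)) {
    Fm <- deformation_gradient_uniaxial(lam)
    C <- t(Fm) %*% Fm
    expect_equal(sum(diag(C)), uniaxial_invariants(lam)$I1, tolerance = 1e-12)
    expect_equal(det(Fm), 1, tolerance = 1e-12)
  }
  expect_error(deformation_gradient_uniaxial(-0.5), "positive")
})

test_that("strain energy vanishes at the reference state and matches closed forms", {
  for (m in hyperelastic_models()) {
    set.seed(7)
    p <- random_params(m)
    expect_equal(strain_energy(p, 1), 0, tolerance = 1e-12)
    expect_equal(cauchy_stress(p, 1), 0, tolerance = 1e-12)
  }
  expect_equal(strain_energy(hyper_params("neo_hookean", 1), 1.2),
               1.2^2 + 2 / 1.2 - 3, tolerance = 1e-12)
  # Yeoh with only a linear term is the Neo-Hookean solid
  lam <- seq(1, 1.6, by = 0.05)
  expect_equal(strain_energy(hyper_params("yeoh", c(1, 0, 0)), lam),
               strain_energy(hyper_params("neo_hookean", 1), lam))
})

test_that("parameter validation enforces coefficient counts and nonzero exponents", {
  expect_error(hyper_params("yeoh", c(1, 2)), "3")
  expect_error(hyper_params("unknown_model", 1), "unknown")
  expect_error(hyper_params("fung", c(1, 0)), "nonzero")
  expect_error(hyper_params("humphrey", c(1, 0)), "nonzero")
  expect_error(hyper_params("veronda_westmann", c(1, 0)), "nonzero")
  expect_error(hyper_params("ogden", c(1, 2, 1, 0, 1, 2)), "nonzero")
  expect_silent(hyper_params("mooney_rivlin", c(1, -2)))
})

test_that("closed-form stresses reproduce reported-coefficient values", {
  # Yeoh cartilage at lambda = 1.2 and Mooney-Rivlin smooth muscle at 1.5,
  # frozen from independent finite-difference evaluation of W
  expect_equal(cauchy_stress(tissue_yeoh$cartilage, 1.2), 4.18927,
               tolerance = 1e-5)
  expect_equal(cauchy_stress(tissue_mr$smooth_muscle, 1.5), 1.10411,
               tolerance = 1e-5)
  expect_equal(cauchy_stress(hyper_params("neo_hookean", 1), 1.2),
               2 * (1.44 - 1 / 1.2), tolerance = 1e-12)
})

test_that("finite-difference oracle matches every closed-form stress", {
  lam <- seq(1.01, 1.6, by = 0.01)
  set.seed(101)
  for (m in hyperelastic_models()) {
    for (k in 1:25) {
      p <- random_params(m)
      s_cf <- cauchy_stress(p, lam)
      s_fd <- cauchy_stress_fd(p, lam)
      denom <- max(max(abs(s_cf)), 1e-9)
      expect_lt(max(abs(s_cf - s_fd)) / denom, 1e-6,
                label = sprintf("oracle gap for %s draw %d", m, k))
    }
    # zero stress at the reference state
    p <- random_params(m)
    expect_lt(abs(cauchy_stress_fd(p, 1)), 1e-8)
  }
})

test_that("Fung and Humphrey are reparameterizations of each other", {
  lam <- seq(1, 1.6, by = 0.02)
  set.seed(11)
  for (k in 1:10) {
    a1 <- runif(1, 0.05, 3); a2 <- runif(1, 0.2, 4)
    s_f <- cauchy_stress(hyper_params("fung", c(a1, a2)), lam)
    s_h <- cauchy_stress(hyper_params("humphrey", c(a1 / (2 * a2), a2)), lam)
    expect_equal(s_f, s_h, tolerance = 1e-12)
  }
})

test_that("nested models coincide where coefficients degenerate", {
  lam <- seq(1, 1.6, by = 0.02)
  c0 <- 0.8
  s_nh <- cauchy_stress(hyper_params("neo_hookean", c0), lam)
  expect_equal(cauchy_stress(hyper_params("yeoh", c(c0, 0, 0)), lam), s_nh)
  expect_equal(cauchy_stress(hyper_params("mooney_rivlin", c(c0, 0)), lam), s_nh)
  # one-term Ogden with exponent 2 and modulus 2c reduces to Neo-Hookean
  s_og <- cauchy_stress(hyper_params("ogden", c(2 * c0, 2, 1e-30, 1, 1e-30, 1)), lam)
  expect_equal(s_og, s_nh, tolerance = 1e-12)
})

test_that("initial tangent modulus closed forms match numerical slopes", {
  h <- 1e-6
  set.seed(23)
  for (m in hyperelastic_models()) {
    for (k in 1:10) {
      p <- random_params(m)
      num <- (cauchy_stress(p, 1 + h) - cauchy_stress(p, 1 - h)) / (2 * h)
      expect_equal(initial_tangent_modulus(p), num, tolerance = 1e-6,
                   label = sprintf("tangent modulus for %s", m))
    }
  }
  expect_equal(initial_tangent_modulus(hyper_params("neo_hookean", 1)), 6)
  expect_equal(initial_tangent_modulus(tissue_yeoh$cartilage), 6 * 3.583)
  # negative small-strain stiffness of the smooth-muscle Mooney-Rivlin set
  expect_equal(initial_tangent_modulus(tissue_mr$smooth_muscle),
               6 * (1.164 - 1.223))
  expect_lt(initial_tangent_modulus(tissue_mr$smooth_muscle), 0)
})

test_that("parameters serialize to and from JSON", {
  p <- tissue_yeoh$smooth_muscle
  q <- hyper_params_from_json(hyper_params_to_json(p))
  expect_equal(q$model, p$model)
  expect_equal(q$coeffs, p$coeffs)
})
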