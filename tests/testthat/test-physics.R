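# Closed-form frequency-mass relations, in CGS internally, ug at the API.

test_that("Sauerbrey shift matches independent arithmetic and is linear", {
  qz <- quartz_spec()
  expect_identical(sauerbreyShift(qz, 0), 0)
  # oracle: -2 * (5e6)^2 * 1e-6 / (1 * sqrt(2.648 * 2.947e11)), frozen
  expect_equal(sauerbreyShift(qz, 1), -56.600585, tolerance = 1e-6)
  # homogeneity: doubling the mass exactly doubles the magnitude
  for (spec in random_specs(10)) {
    m <- runif(1, 0.01, 20)
    expect_equal(sauerbreyShift(spec, 2 * m), 2 * sauerbreyShift(spec, m),
                 tolerance = 1e-12)
    expect_lte(sauerbreyShift(spec, m), 0)
  }
})

test_that("Sauerbrey shift from areal loading agrees with total mass", {
  qz <- quartz_spec()
  dmA <- 3.7e-7
  direct <- -2 * qz@f0^2 * dmA / sqrt(qz@rho_q * qz@mu_q)
  expect_equal(sauerbreyShift(qz, massLoad(delta_mA = dmA, area_cm2 = qz@A)),
               direct, tolerance = 1e-12)
})

test_that("Sauerbrey shift validates its inputs", {
  incomplete <- resonatorSpec(f0_hz = 5e6, area_cm2 = 1) # no substrate
  expect_error(sauerbreyShift(incomplete, 1), "missing required field")
  expect_error(sauerbreyShift(quartz_spec(), -1), "nonnegative")
})

test_that("theoretical sensitivity is consistent with the shift and f0^2", {
  qz <- quartz_spec()
  s <- theoreticalSensitivity(qz)
  expect_equal(s@S_M, 56.600585, tolerance = 1e-6)
  expect_identical(s@S_M_unit, "Hz/ug")
  # quadratic scaling in f0
  qz2 <- resonatorSpec(f0_hz = 1e7, area_cm2 = 1, rho_q = 2.648,
                       mu_q = 2.947e11)
  expect_equal(theoreticalSensitivity(qz2)@S_M / s@S_M, 4, tolerance = 1e-12)
  # algebraic identity against the shift, on random specs
  for (spec in random_specs(100, seed = 9)) {
    m <- runif(1, 0.01, 10)
    expect_equal(sauerbreyShift(spec, m),
                 -theoreticalSensitivity(spec)@S_M * m, tolerance = 1e-12)
  }
})

test_that("empirical sensitivity is -shift/mass with a guarded zero mass", {
  expect_equal(empiricalSensitivity(-56.6, 1)@S_m, 56.6)
  expect_equal(empiricalSensitivity(0, 5)@S_m, 0)
  expect_equal(empiricalSensitivity(-10, 2)@S_m, 5)
  expect_error(empiricalSensitivity(-10, 0), "nonzero")
})

test_that("thin-film shift follows -f0*dmA/(2 rho t) with stated scaling", {
  sp <- pvdfSpec()
  expect_identical(filmShift(sp, massLoad(delta_mA = 0, area_cm2 = sp@A)), 0)
  # oracle: -8500 * 1e-6 / (2 * 1.78 * 28e-4), frozen
  expect_equal(filmShift(sp, massLoad(delta_mA = 1e-6)), -0.85272865,
               tolerance = 1e-6)
  # dmA = rho*t is far outside the thin-load assumption: -f0/2, with warning
  expect_warning(
    big <- filmShift(sp, massLoad(delta_mA = sp@rho * sp@thickness)),
    "thin-film"
  )
  expect_equal(big, -sp@f0 / 2, tolerance = 1e-12)
  # direct in f0, inverse in rho and in t
  dmA <- 1e-6
  base <- filmShift(sp, massLoad(delta_mA = dmA))
  sp_f2 <- resonatorSpec(f0_hz = 17000, diameter_mm = 5, rho_g_cm3 = 1.78,
                         thickness_um = 28)
  expect_equal(filmShift(sp_f2, massLoad(delta_mA = dmA)), 2 * base,
               tolerance = 1e-12)
  sp_r2 <- resonatorSpec(f0_hz = 8500, diameter_mm = 5, rho_g_cm3 = 3.56,
                         thickness_um = 28)
  expect_equal(filmShift(sp_r2, massLoad(delta_mA = dmA)), base / 2,
               tolerance = 1e-12)
  sp_t2 <- resonatorSpec(f0_hz = 8500, diameter_mm = 5, rho_g_cm3 = 1.78,
                         thickness_um = 56)
  expect_equal(filmShift(sp_t2, massLoad(delta_mA = dmA)), base / 2,
               tolerance = 1e-12)
  # homogeneity on the areal path
  expect_equal(filmShift(sp, massLoad(delta_mA = 3 * dmA)), 3 * base,
               tolerance = 1e-12)
})

test_that("film shift converts total mass through the active area", {
  sp <- pvdfSpec()
  m_ug <- 2.5
  expect_equal(filmShift(sp, m_ug),
               filmShift(sp, massLoad(delta_mA = m_ug * 1e-6 / sp@A)),
               tolerance = 1e-12)
  no_area <- resonatorSpec(f0_hz = 8500, rho_g_cm3 = 1.78, thickness_um = 28)
  expect_error(filmShift(no_area, 1), "area")
})

test_that("quality factor and bandwidth round-trip", {
  expect_equal(round(qualityFactor(8500, 308), 1), 27.6)
  expect_equal(qualityFactor(1234.5, 1234.5), 1)
  expect_equal(qualityFactor(8500, 425), 20.0)
  expect_error(qualityFactor(-1, 10))
  expect_error(bandwidthFromQ(8500, 0))
  for (f in c(10, 8500, 5e6)) {
    bw <- f / runif(1, 2, 300)
    expect_equal(bandwidthFromQ(f, qualityFactor(f, bw)), bw,
                 tolerance = 1e-12)
  }
})

test_that("mass inversion is the exact inverse of the sensitivity", {
  expect_equal(invertMass(-56.6, 56.6), 1.0)
  expect_equal(invertMass(0, 5), 0)
  expect_error(invertMass(-10, -5), "positive")
  ptfm:::with_seed(31, {
    for (i in 1:100) {
      m <- runif(1, 0, 10); s <- runif(1, 0.1, 100)
      expect_equal(invertMass(-s * m, s), m, tolerance = 1e-12)
      # round-trip through the empirical sensitivity
      df <- -runif(1, 0, 50); dm <- runif(1, 0.1, 10)
      expect_equal(invertMass(df, empiricalSensitivity(df, dm)), dm,
                   tolerance = 1e-12)
    }
  })
})

test_that("resonator spec enforces unit and consistency invariants", {
  sp <- pvdfSpec()
  expect_equal(sp@thickness, 28e-4) # um at the API, cm internally
  expect_equal(sp@A, pi * (5 / 20)^2, tolerance = 1e-12)
  expect_error(resonatorSpec(f0_hz = -5), "f0")
  expect_error(resonatorSpec(f0_hz = 8500, q = 27.6, bandwidth_hz = 400),
               "inconsistent")
  expect_error(resonatorSpec(f0_hz = 8500, diameter_mm = 5, area_cm2 = 1),
               "inconsistent")
  # consistent redundant inputs are accepted
  expect_s4_class(resonatorSpec(f0_hz = 8500, q = 8500 / 308,
                                bandwidth_hz = 308), "ResonatorSpec")
})

test_that("mass load conversions tie delta_m and delta_mA through the area", {
  ml <- massLoad(delta_m_ug = 2, area_cm2 = 0.5)
  expect_equal(ml@delta_mA, 4e-6, tolerance = 1e-12)
  ml2 <- massLoad(delta_mA = 4e-6, area_cm2 = 0.5)
  expect_equal(ml2@delta_m, 2, tolerance = 1e-12)
  expect_error(massLoad(delta_m_ug = 2, delta_mA = 1e-3, area_cm2 = 0.5),
               "inconsistent")
  expect_error(massLoad(delta_m_ug = -1), "delta_m")
  expect_error(massLoad(), "at least one")
})
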