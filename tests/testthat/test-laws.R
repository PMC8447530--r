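test_that("subarachnoid exponential law hits its anchor and is convex", {
  pv <- table_pv()
  # at the unstressed volume the exponent vanishes
  expect_equal(sas_pressure(pv$cranial_unstressed_volume, pv),
               pv$sas_a + pv$sas_c)
  # printed baseline anchor: 9.5 mmHg at 1610 ml
  expect_equal(sas_pressure(1610, pv), 9.5, tolerance = 1e-9)
  # strictly increasing and convex on a grid around baseline
  v <- seq(1550, 1680, length.out = 60)
  p <- sas_pressure(v, pv)
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(diff(p)) > 0))
  # convexity example: equal volume increments give growing pressure steps
  d <- 10
  expect_gt(sas_pressure(1610 + 2 * d, pv) - sas_pressure(1610 + d, pv),
            sas_pressure(1610 + d, pv) - sas_pressure(1610, pv))
})

test_that("subarachnoid law rejects bad input and flags runaway volume", {
  pv <- table_pv()
  expect_error(sas_pressure(NaN, pv), "finite")
  expect_error(sas_pressure(-5, pv), "positive")
  expect_error(sas_pressure(1e6, pv), "runaway")
})

test_that("brain cubic is anchored at the printed transmural pressure and monotone", {
  pv <- table_pv()
  # printed ICP_BR - ICP_SAS = 10.5 - 9.5 at the enclosed baseline volume
  expect_equal(brain_transmural_pressure(1575, pv), 1.0, tolerance = 1e-9)
  # derivative positive at 50 grid points across the operating range
  rng <- attr(pv, "brain_range")
  g <- seq(rng[1] + 1, rng[2] - 1, length.out = 50)
  h <- 1e-3
  slope <- (brain_transmural_pressure(g + h, pv) -
              brain_transmural_pressure(g - h, pv)) / (2 * h)
  expect_true(all(slope > 0))
  expect_error(brain_transmural_pressure(rng[2] + 10, pv), "operating range")
})

test_that("degenerate polynomials reduce to their constant terms", {
  pv <- degenerate_pv(ven_d = 0.42, brain_d = 1.7)
  expect_equal(ventricle_transmural_pressure(c(1, 25, 80), pv),
               rep(0.42, 3))
  expect_equal(brain_transmural_pressure(c(500, 1575), pv), rep(1.7, 2))
  expect_equal(spinal_pressure(c(10, 70), pv), rep(9.5, 2))
})

test_that("ventricular cubic matches the printed transmural pressure and signs collapse", {
  pv <- table_pv()
  # printed ICP_VEN - ICP_BR = 10.8 - 10.5
  expect_equal(ventricle_transmural_pressure(25, pv), 0.3, tolerance = 1e-9)
  # driven far enough below its unstressed volume the transmural pressure
  # reverses: the collapse regime (flow-consistent calibration)
  expect_lt(ventricle_transmural_pressure(1, default_params()$pv), 0)
  expect_error(ventricle_transmural_pressure(1e3, pv), "operating range")
})

test_that("vascular linear law is volume over compliance", {
  expect_equal(vascular_transmural_pressure(100, 5), 20)
  expect_equal(vascular_transmural_pressure(0, 3), 0)
  # venous cross-check: 10.5 + 30/5 = 16.5, near the printed venous 17 mmHg
  expect_equal(10.5 + vascular_transmural_pressure(30, 5), 16.5)
  expect_error(vascular_transmural_pressure(10, 0), "compliance")
  expect_error(vascular_transmural_pressure(-1, 5), "non-negative")
})

test_that("spinal quadratic hits its anchor and baseline balances the foramen", {
  pv <- table_pv()
  expect_equal(spinal_pressure(70, pv), 9.5, tolerance = 1e-9)
  # equal pressures across the foramen magnum resistor mean zero flow
  expect_equal((9.5 - spinal_pressure(70, pv)) / 15, 0)
})

test_that("volume-scaled resistance follows the inverse-square law", {
  expect_equal(volume_scaled_resistance(280, 35, 35), 280)
  expect_equal(volume_scaled_resistance(280, 70, 35), 70)
  expect_equal(volume_scaled_resistance(100, 17.5, 35), 400)
  for (k in c(0.5, 1, 2, 4)) {
    expect_identical(volume_scaled_resistance(1200, k * 30, 30), 1200 / k^2)
  }
  # collapse floor: below 2% of baseline the resistance saturates
  expect_equal(volume_scaled_resistance(280, 1e-9, 35),
               volume_scaled_resistance(280, 0.02 * 35, 35))
})

test_that("pressure-volume laws invert to better than 1e-9 ml", {
  pv <- default_params()$pv
  for (v in c(1580, 1600, 1620, 1650)) {
    expect_equal(icpsim:::sas_volume(sas_pressure(v, pv), pv), v,
                 tolerance = 1e-10)
  }
  for (v in c(3, 10, 25, 60, 150)) {
    p <- ventricle_transmural_pressure(v, pv)
    expect_equal(icpsim:::cubic_invert(p, pv$ven_a, pv$ven_b, pv$ven_c,
                                       pv$ven_d, 0.1, 400), v,
                 tolerance = 1e-9)
  }
  for (p in c(8, 9.5, 12, 20)) {
    expect_equal(spinal_pressure(icpsim:::spinal_volume(p, pv), pv), p,
                 tolerance = 1e-10)
  }
})

test_that("absolute pressures compose the nested compartment laws", {
  params <- icp_params(pv = table_pv())
  pr <- absolute_pressures(baseline_state(params), params)
  # printed baseline column, within the 0.1 mmHg calibration tolerance
  expect_equal(pr$icp_sas, 9.5, tolerance = 0.1 / 9.5)
  expect_equal(pr$icp_br, 10.5, tolerance = 0.1 / 10.5)
  expect_equal(pr$icp_ven, 10.8, tolerance = 0.1 / 10.8)
  expect_equal(pr$p_spi, 9.5, tolerance = 0.1 / 9.5)
  # capillary absolute = ICP_BR + V_C/C_C = 30.5, vs printed 30
  expect_equal(pr$p_c, pr$icp_br + 20)
  expect_equal(pr$p_sss, 7.4)
  expect_equal(pr$p_ao, 93)
})
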