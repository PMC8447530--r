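test_that("baseline steady state balances every internal node", {
  ss <- baseline_steady()
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-9)
  # spinal sac in equilibrium with the subarachnoid space
  expect_equal(ss$flows$q_fm, 0, tolerance = 1e-12)
  expect_equal(ss$state$v_spi, 70, tolerance = 0.01)
  # configured baseline volumes are (near-)exact steady states under the
  # flow-consistent calibration
  expect_equal(ss$state$v_ven, 25, tolerance = 0.02)
  expect_equal(ss$state$v_br, 1400, tolerance = 0.002)
  expect_equal(ss$state$v_sas, 35, tolerance = 0.02)
})

test_that("baseline pressure hierarchies match the physiological ordering", {
  p <- baseline_steady()$pressures
  expect_true(p$p_ao > p$p_arl)
  expect_true(p$p_arl > p$p_c)
  expect_true(p$p_c > p$p_v)
  expect_true(p$p_v > p$p_sss)
  expect_true(p$icp_ven > p$icp_br)
  expect_true(p$icp_br > p$icp_sas)
  expect_true(p$icp_sas > p$p_sss)
})

test_that("the full solver reproduces the Davson closed form on the CSF network", {
  # with a practically impermeable barrier (no vascular leak into the CSF
  # network) and the CSF resistances uncoupled from their volumes, the
  # algebraic solution must reproduce the closed form exactly
  params <- icp_params(R_BBB = 1e15,
                       coupling = c(R_OUT = FALSE, R_FM = FALSE,
                                    R_BF = FALSE, R_VEN = FALSE))
  ss <- solve_steady_state(params)
  d <- davson_icp(params$Q_CSF, params$Q_ISF, params$R_BF, params$R_OUT,
                  params$P_SSS)
  expect_lt(abs(ss$pressures$icp_sas - d$icp_sas), 1e-9)
  expect_lt(abs(ss$pressures$icp_br - d$icp_br), 1e-9)
  # with the default volume couplings the closed form still holds to the
  # model's internal slack
  ss2 <- baseline_steady()
  expect_lt(abs(ss2$pressures$icp_sas - d$icp_sas), 0.05)
})

test_that("baseline cerebral blood flow is near 65 ml/100g/min", {
  ss <- baseline_steady()
  expect_equal(cbf_from_state(ss), 65, tolerance = 0.10)
  # unit arithmetic: 910 ml/min over a 1400 g brain
  fake <- ss
  fake$flows$q_a <- 910 / 60
  expect_equal(cbf_from_state(fake, 1400), 65, tolerance = 1e-12)
  fake$flows$q_a <- 0
  expect_equal(cbf_from_state(fake), 0)
})

test_that("a cycle-averaged Euler run started at the solution stays put", {
  ss <- baseline_steady()
  init <- ss$state[, c("time", icpsim:::.compartments)]
  init$time <- 0
  tr <- simulate_icp(default_params(), duration = 300, dt = 0.1,
                     pulsatile = FALSE, init = init)
  last <- tr[nrow(tr), ]
  dv <- abs(as.numeric(last[, icpsim:::.compartments]) -
              as.numeric(ss$state[, icpsim:::.compartments]))
  expect_true(all(dv < 0.5))
  expect_lt(abs(last$icp_br - ss$pressures$icp_br), 0.2)
  expect_lt(abs(last$icp_sas - ss$pressures$icp_sas), 0.2)
})

test_that("Newton solution agrees with long-run stiff integration under perturbation", {
  params <- default_params()
  set.seed(42)
  # admissible perturbation ranges stay below each resistor's runaway fold
  # (beyond it the swelling feedback leaves the physiological branch)
  hi <- c(R_A = 4, R_C = 4, R_V = 4, R_BV = 4, R_VEN = 1.6, R_BF = 1.15,
          R_OUT = 4, R_FM = 4)
  resistors <- names(hi)
  for (i in 1:20) {
    rn <- sample(resistors, 1)
    fac <- stats::runif(1, 0.5, hi[[rn]])
    ov <- list(); ov[[rn]] <- params[[rn]] * fac
    ss <- solve_steady_state(params, ov)
    pp <- params; pp[[rn]] <- pp[[rn]] * fac
    v_end <- icpsim:::integrate_averaged(
      icpsim:::state_vec(baseline_steady()$state), pp, 2e7,
      rtol = 1e-11, atol = 1e-9, maxsteps = 2e5)
    expect_true(all(abs(v_end[1:6] -
                          as.numeric(ss$state[, icpsim:::.compartments[1:6]]))
                    < 0.5),
                info = paste(rn, "x", round(fac, 3)))
    p_ode <- icpsim:::pressures_vec(v_end, pp, pp$P_AO)
    expect_lt(abs(p_ode[[2]] - ss$pressures$icp_br), 0.2)
  }
})

test_that("steady ICP responds monotonically to each pathological resistance", {
  params <- default_params()
  for (rn in c("R_OUT", "R_VEN", "R_BF")) {
    icps <- numeric(0)
    init <- NULL
    for (fac in c(1, 1.15, 1.3, 1.5, 1.7)) {
      ov <- list(); ov[[rn]] <- params[[rn]] * fac
      ss <- solve_steady_state(params, ov, init = init)
      init <- ss$state
      icps <- c(icps, ss$pressures$icp_br)
    }
    expect_true(all(diff(icps) >= -1e-8), info = rn)
  }
  icps <- numeric(0)
  init <- NULL
  for (fac in c(1, 0.1, 0.03, 0.01, 0.003)) {
    ss <- solve_steady_state(params, list(R_BBB = 1e7 * fac), init = init)
    init <- ss$state
    icps <- c(icps, ss$pressures$icp_br)
  }
  expect_true(all(diff(icps) >= -1e-8))
})

test_that("ventricular collapse activates the floor and is reported, not an error", {
  params <- default_params()
  rr <- ramp_resistance_to_icp("R_BF", 32, params)
  expect_true("v_ven" %in% rr$report$floor_active)
  expect_equal(rr$report$state$v_ven, 0.02 * 25)
  expect_true(rr$report$converged)
})

test_that("steady-state report tidiers expose volumes, deltas and pressures", {
  ss <- baseline_steady()
  td <- tidy(ss)
  expect_equal(nrow(td), 7)
  expect_named(td, c("compartment", "volume", "baseline", "delta", "pressure"))
  gl <- glance(ss)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_error(solve_steady_state(default_params(), list(nope = 1)),
               "unknown override")
})
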