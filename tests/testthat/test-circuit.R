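test_that("circuit topology has exactly the expected edges and boundaries", {
  topo <- circuit_topology()
  expect_equal(nrow(topo), 11)
  expect_setequal(topo$resistor[!is.na(topo$resistor)],
                  c("R_A", "R_C", "R_V", "R_BV", "R_BBB", "R_VEN", "R_BF",
                    "R_OUT", "R_FM"))
  # the two constant production edges are drawn from the capillary node
  src <- topo[is.na(topo$resistor), ]
  expect_equal(src$from, c("v_c", "v_c"))
  expect_setequal(src$to, c("v_ven", "v_br"))
  # boundary nodes: aortic inflow and sagittal-sinus outflow only
  nodes <- unique(c(topo$from, topo$to))
  expect_setequal(setdiff(nodes, icpsim:::.compartments), c("p_ao", "p_sss"))
  # connectivity: every compartment is reachable along the undirected graph
  expect_true(all(icpsim:::.compartments %in% nodes))
})

test_that("arterial driver has an exact mean and a systolic peak near 120 mmHg", {
  expect_equal(arterial_driver(seq(0, 1, 0.1), pulse_amplitude = 0),
               rep(93, 11))
  t <- seq(0, 1, length.out = 20001)[-1]
  w <- arterial_driver(t)
  expect_equal(mean(w), 93, tolerance = 0.1 / 93)
  expect_gt(max(w), 115); expect_lt(max(w), 125)
  expect_error(arterial_driver(0, heart_rate = 0), "heart_rate")
})

test_that("effective resistances apply the inverse-square coupling per flag", {
  params <- default_params()
  r0 <- effective_resistances(baseline_state(params), params)
  expect_equal(as.numeric(r0[1, c("R_A", "R_C", "R_V", "R_BV", "R_BBB",
                                  "R_VEN", "R_BF", "R_OUT", "R_FM")]),
               c(1.9, 2.5, 0.8, 0.7, 1e7, 250, 1200, 280, 15))
  st <- baseline_state(params); st$v_c <- 50
  pc <- icp_params(coupling = c(R_C = TRUE))
  expect_equal(effective_resistances(st, pc)$R_C, 10)   # 4 x 2.5
  # flag off: halving the subarachnoid volume leaves an uncoupled R_OUT at 280
  st2 <- baseline_state(params); st2$v_sas <- 17.5
  poff <- icp_params(coupling = c(R_OUT = FALSE))
  expect_equal(effective_resistances(st2, poff)$R_OUT, 280)
  expect_equal(effective_resistances(st2, params)$R_OUT, 280 * 4)
})

test_that("edge flows follow the Ohm analogue with constant production sources", {
  params <- default_params()
  pr <- tibble::tibble(icp_sas = 9.5, icp_br = 10.5, icp_ven = 10.8,
                       p_arl = 64, p_c = 30, p_v = 17, p_spi = 9.5,
                       p_sss = 7.4, p_ao = 93)
  rs <- effective_resistances(baseline_state(params), params)
  q <- compute_flows(pr, rs, params)
  expect_equal(q$q_out, (9.5 - 7.4) / 280)          # 0.0075 ml/s
  expect_equal(q$q_fm, 0)                           # equal pressures
  expect_equal(q$q_bf, (10.5 - 9.5) / 1200)         # ~ Q_ISF
  expect_equal(q$q_bf, 0.00083, tolerance = 0.005)
  expect_equal(q$q_csf, 0.0042)
  expect_equal(q$q_isf, 0.00083)
})

test_that("an Euler step increments volumes by net flow and conserves totals", {
  params <- default_params()
  st <- baseline_state(params)
  zero <- tibble::as_tibble(as.list(stats::setNames(rep(0, 11),
                                                    icpsim:::.edges)))
  st1 <- euler_step(st, zero, 0.001, params)
  expect_equal(st1$time, 0.001)
  expect_equal(as.numeric(st1[, icpsim:::.compartments]),
               as.numeric(st[, icpsim:::.compartments]))
  # a net 0.01 ml/s inflow to the ventricles for 1 ms adds 1e-5 ml
  q <- zero; q$q_csf <- 0.01
  st2 <- euler_step(st, q, 0.001, params)
  expect_equal(st2$v_ven - st$v_ven, 1e-5)
  # telescoping: the sum of volume changes equals boundary in minus out
  pr <- absolute_pressures(st, params)
  rs <- effective_resistances(st, params)
  qq <- compute_flows(pr, rs, params)
  st3 <- euler_step(st, qq, 0.001, params)
  dv_tot <- sum(st3[, icpsim:::.compartments]) - sum(st[, icpsim:::.compartments])
  expect_lt(abs(dv_tot - (qq$q_a - qq$q_bv - qq$q_out) * 0.001), 1e-12)
  bad <- zero; bad$q_a <- NaN
  expect_error(euler_step(st, bad, 0.001, params), "q_a")
})

test_that("the Euler integrator conserves volume to the telescoping identity", {
  params <- default_params()
  tr <- simulate_icp(params, duration = 1, dt = 1e-3, pulsatile = TRUE,
                     record_dt = 1e-3)
  vols <- rowSums(tr[, icpsim:::.compartments])
  net <- tr$q_a - tr$q_bv - tr$q_out
  n <- nrow(tr)
  # explicit Euler: state change over the run equals dt * sum of step flows
  expect_equal(vols[n] - vols[1], sum(net[-n]) * 1e-3, tolerance = 1e-6)
})

test_that("simulation is deterministic and insensitive to halving dt", {
  params <- default_params()
  a <- simulate_icp(params, duration = 2, dt = 0.01, pulsatile = FALSE)
  b <- simulate_icp(params, duration = 2, dt = 0.01, pulsatile = FALSE)
  expect_identical(a, b)
  c1 <- simulate_icp(params, duration = 10, dt = 0.02, pulsatile = FALSE)
  c2 <- simulate_icp(params, duration = 10, dt = 0.01, pulsatile = FALSE)
  last1 <- as.numeric(c1[nrow(c1), icpsim:::.compartments])
  last2 <- as.numeric(c2[nrow(c2), icpsim:::.compartments])
  expect_true(all(abs(last1 - last2) < 0.01))
})

test_that("baseline is stable: CSF compartments hold within 2 ml over 300 s", {
  params <- default_params()
  tr <- simulate_icp(params, duration = 300, dt = 0.05, pulsatile = FALSE)
  csf <- c("v_ven", "v_br", "v_sas", "v_spi")
  drift <- abs(as.numeric(tr[nrow(tr), csf]) - as.numeric(tr[1, csf]))
  expect_true(all(drift < 2))
  # the vascular chambers settle within the run to the network's operating
  # point (the printed vascular volumes carry a few ml of internal slack)
  ss <- baseline_steady()
  vasc <- c("v_a", "v_c", "v_v")
  expect_true(all(abs(as.numeric(tr[nrow(tr), vasc]) -
                        as.numeric(ss$state[, vasc])) < 0.5))
})

test_that("a zero-rate injection schedule leaves the trace unchanged", {
  params <- default_params()
  plain <- simulate_icp(params, duration = 2, dt = 0.01, pulsatile = FALSE)
  sched <- simulate_icp(params, duration = 2, dt = 0.01, pulsatile = FALSE,
                        schedule = list(from = 0, to = 1,
                                        inject_into = "v_sas",
                                        inject_rate = 0))
  expect_identical(as.matrix(as.data.frame(plain)),
                   as.matrix(as.data.frame(sched)))
})

test_that("the instability detector aborts with advice to reduce dt", {
  params <- default_params()
  expect_error(
    simulate_icp(params, duration = 10, dt = 2, pulsatile = FALSE,
                 schedule = list(overrides = list(R_A = 0.2))),
    "reduce dt")
})
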