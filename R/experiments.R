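# continuation along a resistance path: solve steady states while stepping a
# resistor multiplicatively, refining the step whenever the state jumps too
# much (steep response) or the solver fails. Stops once ICP_BR passes
# `target_icp` (plus a margin) or the resistance reaches `r_stop`. Returns
# the cached path of (resistance, icp_steady) nodes.
continuation_path <- function(resistor, params, r_stop, target_icp = Inf,
                              base = NULL, max_jump = 3, min_factor = 1.0005,
                              max_solves = 400) {
  if (is.null(base)) base <- solve_steady_state(params)
  r0 <- params[[resistor]]
  decreasing <- r_stop < r0
  path <- list(list(r = r0, ss = base))
  r <- r0
  factor0 <- if (decreasing) 0.5 else 2
  factor <- factor0
  solves <- 0
  while ((if (decreasing) r > r_stop else r < r_stop) &&
         path[[length(path)]]$ss$pressures$icp_br < target_icp + 0.5 &&
         solves < max_solves) {
    r_try <- if (decreasing) max(r * factor, r_stop) else min(r * factor, r_stop)
    ov <- list(); ov[[resistor]] <- r_try
    last <- path[[length(path)]]
    ss <- tryCatch(solve_steady_state(params, ov, init = last$ss$state),
                   error = function(e) NULL)
    solves <- solves + 1
    jump <- if (is.null(ss)) Inf else
      max(abs(ss$pressures$icp_br - last$ss$pressures$icp_br),
          abs(ss$state$v_ven - last$ss$state$v_ven) / 10)
    if (jump > max_jump) {
      factor <- sqrt(factor)
      if (abs(log(factor)) < log(min_factor)) {
        # response is near-vertical here; accept the step
        if (is.null(ss)) break
        path[[length(path) + 1]] <- list(r = r_try, ss = ss)
        r <- r_try
        factor <- factor0
      }
      next
    }
    path[[length(path) + 1]] <- list(r = r_try, ss = ss)
    r <- r_try
  }
  path
}

#' Ramp a resistance until the parenchymal ICP reaches a target
#'
#' Recovers the resistance value that produces a given steady-state brain
#' parenchymal pressure — the resistance actually applied in the
#' pathological simulations is never an input, only the resulting ICP — by
#' monotone bisection on the resistance (logarithmic for the blood-brain
#' barrier, which is swept downward), with warm-started continuation so the
#' solver tracks the physiological branch across steep response regions.
#'
#' @param resistor one of `"R_OUT"`, `"R_VEN"`, `"R_BF"` (swept upward) or
#'   `"R_BBB"` (swept downward).
#' @param target_icp_br steady-state parenchymal pressure to reach [mmHg];
#'   must be at or above the baseline value.
#' @param params an [icp_params()] object.
#' @param tol bisection tolerance on ICP_BR [mmHg].
#' @param r_max,r_min sweep bounds [mmHg.s/ml].
#' @return A list with `resistance` (the recovered value), `report` (the
#'   `icp_steady` at that value) and `baseline` (the unperturbed
#'   `icp_steady`).
#' @export
ramp_resistance_to_icp <- function(resistor = c("R_OUT", "R_VEN", "R_BF", "R_BBB"),
                                   target_icp_br, params = icp_params(),
                                   tol = 0.05, r_max = 1e5, r_min = 10) {
  resistor <- match.arg(resistor)
  decreasing <- resistor == "R_BBB"
  base <- solve_steady_state(params)
  icp0 <- base$pressures$icp_br
  if (target_icp_br < icp0 - tol) {
    stop("target ICP ", target_icp_br, " mmHg is below the baseline ",
         signif(icp0, 4), " mmHg", call. = FALSE)
  }
  if (abs(target_icp_br - icp0) <= tol) {
    return(list(resistance = params[[resistor]], report = base, baseline = base))
  }
  bound <- if (decreasing) r_min else r_max
  path <- continuation_path(resistor, params, bound, target_icp = target_icp_br,
                            base = base)
  icps <- vapply(path, function(n) n$ss$pressures$icp_br, numeric(1))
  rs <- vapply(path, function(n) n$r, numeric(1))
  if (max(icps) < target_icp_br - tol) {
    stop("target ICP ", target_icp_br, " mmHg unreachable by sweeping ",
         resistor, " to ", bound, " (max ", signif(max(icps), 4), " mmHg)",
         call. = FALSE)
  }
  hi <- which(icps >= target_icp_br)[1]
  lo <- hi - 1L
  # r_lo sits on the low-ICP side of the target, r_hi on the high-ICP side
  r_lo <- rs[lo]; r_hi <- rs[hi]
  ss_near <- path[[lo]]$ss
  best <- path[[hi]]
  for (i in 1:80) {
    r_mid <- exp((log(r_lo) + log(r_hi)) / 2)
    ov <- list(); ov[[resistor]] <- r_mid
    ss <- tryCatch(solve_steady_state(params, ov, init = ss_near$state),
                   error = function(e) NULL)
    if (is.null(ss)) {
      # failures occur on the runaway high-pressure side
      r_hi <- r_mid
      next
    }
    if (abs(ss$pressures$icp_br - target_icp_br) <= tol) {
      return(list(resistance = r_mid, report = ss, baseline = base))
    }
    if (ss$pressures$icp_br < target_icp_br) r_lo <- r_mid else r_hi <- r_mid
    ss_near <- ss
    best <- list(r = r_mid, ss = ss)
  }
  list(resistance = best$r, report = best$ss, baseline = base)
}

#' Steady-state compartment shifts under the four pathological conditions
#'
#' Runs the four resistance ramps — raised CSF outflow resistance
#' (non-absorptive hydrocephalus), raised ventricular flow resistance
#' (obstructive hydrocephalus), raised interstitial bulk-flow resistance
#' (cytotoxic edema) and lowered blood-brain-barrier resistance (vasogenic
#' edema) — each until the parenchymal ICP reaches `target_icp`, and
#' tabulates the steady-state volume shifts against baseline.
#'
#' @param target_icp parenchymal ICP reached in each condition [mmHg].
#' @param params an [icp_params()] object.
#' @param tol bisection tolerance on ICP [mmHg].
#' @return A tibble with one row per condition: the recovered resistance,
#'   changes in brain tissue, ventricular, subarachnoid and cerebral blood
#'   volume [ml], ventricular volume as percent of its configured baseline,
#'   and the change in CBF [ml/100g/min].
#' @export
pathology_report <- function(target_icp = 30, params = icp_params(),
                             tol = 0.05) {
  conditions <- c("R_OUT", "R_VEN", "R_BF", "R_BBB")
  rows <- purrr::map(conditions, function(rn) {
    rr <- ramp_resistance_to_icp(rn, target_icp, params, tol = tol)
    s <- rr$report$state
    b <- rr$baseline$state
    tibble::tibble(
      condition = rn,
      resistance = rr$resistance,
      icp_br = rr$report$pressures$icp_br,
      d_brain = s$v_br - b$v_br,
      d_ventricles = s$v_ven - b$v_ven,
      d_sas = s$v_sas - b$v_sas,
      d_blood = (s$v_a + s$v_c + s$v_v) - (b$v_a + b$v_c + b$v_v),
      ventricles_pct = 100 * s$v_ven / params$V_VEN,
      d_cbf = rr$report$cbf - rr$baseline$cbf
    )
  })
  dplyr::bind_rows(rows)
}

#' Hyper- and hypoventilation via the arteriolar resistance
#'
#' Ventilation acts on cerebral physiology through CO2 reactivity of the
#' arterioles; the experiment recovers the arteriolar resistance that
#' produces a requested percent change in cerebral blood flow and reports
#' the concomitant percent change in parenchymal ICP. Responses are
#' evaluated on the minutes timescale (cycle-averaged integration over
#' `horizon` seconds from the solved baseline): the acute regime in which
#' vascular volumes have re-equilibrated but the slow CSF compartments have
#' not yet compensated.
#'
#' @param target_cbf_change requested CBF change from baseline, in percent
#'   (signed: -20 means hyperventilation to 80 percent of baseline flow).
#' @param params an [icp_params()] object.
#' @param horizon evaluation horizon [s]; the default (600 s) is the sustained
#'   acute regime: vascular volumes fully re-equilibrated, slow CSF
#'   compensation still minor.
#' @param tol tolerance on the achieved CBF change [percentage points].
#' @param r_a_range admissible arteriolar resistance range [mmHg.s/ml].
#' @return A one-row tibble: `r_a` used, `cbf_change` and `icp_change`
#'   achieved [percent].
#' @export
ventilation_experiment <- function(target_cbf_change, params = icp_params(),
                                   horizon = 600, tol = 0.1,
                                   r_a_range = c(0.2, 20)) {
  base <- solve_steady_state(params)
  cbf0 <- base$flows$q_a
  icp0 <- base$pressures$icp_br
  if (abs(target_cbf_change) < tol) {
    return(tibble::tibble(r_a = params$R_A, cbf_change = 0, icp_change = 0))
  }
  v0 <- state_vec(base$state)
  run <- function(r_a) {
    pa <- params
    pa$R_A <- r_a
    v <- integrate_averaged(v0, pa, horizon)
    p <- pressures_vec(v, pa, pa$P_AO)
    r <- resistances_vec(v, pa)
    q <- flows_vec(p, r, pa)
    c(cbf = 100 * (q[[1]] - cbf0) / cbf0,
      icp = 100 * (p[[2]] - icp0) / icp0)
  }
  lo <- r_a_range[1]; hi <- r_a_range[2]
  f_lo <- run(lo)[["cbf"]]; f_hi <- run(hi)[["cbf"]]
  if (target_cbf_change > f_lo || target_cbf_change < f_hi) {
    stop("target CBF change ", target_cbf_change,
         "% outside the achievable range [", signif(f_hi, 3), ", ",
         signif(f_lo, 3), "]% for R_A in [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    res <- run(mid)
    if (abs(res[["cbf"]] - target_cbf_change) <= tol) break
    if (res[["cbf"]] > target_cbf_change) lo <- mid else hi <- mid
  }
  tibble::tibble(r_a = mid, cbf_change = res[["cbf"]], icp_change = res[["icp"]])
}

#' Pressure-volume curve by rapid intracranial fluid injection
#'
#' Simulates rapid constant-rate injection of increasing fluid volumes into
#' the subarachnoid space and records the peak parenchymal ICP reached —
#' the classic bolus test that exposes the exponential-like intracranial
#' pressure-volume relationship.
#'
#' @param volumes injected volumes [ml].
#' @param injection_duration duration of each injection [s].
#' @param params an [icp_params()] object.
#' @param dt Euler step [s] (cycle-averaged mode).
#' @param settle post-injection observation window [s].
#' @return A tibble with `volume` [ml] and `peak_icp_br` [mmHg].
#' @export
bolus_pv_curve <- function(volumes = 0:10, injection_duration = 1,
                           params = icp_params(), dt = 0.002, settle = 3) {
  stopifnot(all(volumes >= 0), injection_duration > 0)
  base <- solve_steady_state(params)
  init <- dplyr::mutate(base$state[, c("time", .compartments)], time = 0)
  peaks <- vapply(volumes, function(dv) {
    if (dv == 0) return(base$pressures$icp_br)
    tr <- simulate_icp(
      params, duration = injection_duration + settle, dt = dt,
      pulsatile = FALSE,
      schedule = list(from = 0, to = injection_duration,
                      inject_into = "v_sas",
                      inject_rate = dv / injection_duration),
      init = init, record_dt = dt)
    max(tr$icp_br)
  }, numeric(1))
  tibble::tibble(volume = volumes, peak_icp_br = peaks)
}

#' ICP pulse amplitude as a function of mean ICP
#'
#' With rising mean ICP the cranium operates on an ever-steeper part of its
#' exponential pressure-volume curve, so the same cardiac-cycle blood-volume
#' excursion produces a growing ICP pulse pressure. Mean ICP is raised by
#' ramping the interstitial bulk-flow resistance (cerebral edema); at each
#' level a pulsatile run from the steady state yields the parenchymal pulse
#' amplitude.
#'
#' @param mean_icp_grid target mean parenchymal pressures [mmHg].
#' @param params an [icp_params()] object.
#' @param cycles number of cardiac cycles to simulate (the last one is
#'   measured).
#' @param dt Euler step for the pulsatile runs [s].
#' @return A tibble with `mean_icp` (the achieved steady value) and
#'   `pulse_amplitude` (max minus min of ICP_BR over the final cycle)
#'   [mmHg].
#' @export
pulse_amplitude_vs_mean_icp <- function(mean_icp_grid = c(10, 20, 30, 40, 50),
                                        params = icp_params(), cycles = 10,
                                        dt = 5e-4) {
  base <- solve_steady_state(params)
  rows <- purrr::map(mean_icp_grid, function(target) {
    if (target <= base$pressures$icp_br) {
      ss <- base
      r_bf <- params$R_BF
    } else {
      rr <- ramp_resistance_to_icp("R_BF", target, params)
      ss <- rr$report
      r_bf <- rr$resistance
    }
    period <- 1 / params$heart_rate
    tr <- simulate_icp(params, duration = cycles * period, dt = dt,
                       pulsatile = TRUE,
                       schedule = list(overrides = list(R_BF = r_bf)),
                       init = dplyr::mutate(
                         ss$state[, c("time", .compartments)], time = 0),
                       record_dt = dt)
    last <- dplyr::filter(tr, .data$time >= (cycles - 1) * period)
    tibble::tibble(mean_icp = mean(last$icp_br),
                   pulse_amplitude = max(last$icp_br) - min(last$icp_br))
  })
  dplyr::bind_rows(rows)
}
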