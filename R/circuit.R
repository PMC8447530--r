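# canonical orderings shared by the fast simulation core
.compartments <- c("v_a", "v_c", "v_v", "v_ven", "v_br", "v_sas", "v_spi")
.resistors <- c("R_A", "R_C", "R_V", "R_BV", "R_BBB", "R_VEN", "R_BF",
                "R_OUT", "R_FM")
.edges <- c("q_a", "q_c", "q_v", "q_bv", "q_bbb", "q_ven", "q_bf", "q_out",
            "q_fm", "q_csf", "q_isf")

#' Circuit topology of the electrical-analog model
#'
#' The directed edge list of the flow network: the cerebrovascular chain
#' from the aorta through arteriolar, capillary and venous chambers to the
#' sagittal sinus; the CSF pathway from the ventricles through the
#' subarachnoid space to the sinus and the spinal sac; the interstitial
#' bulk-flow pathway from brain tissue to the subarachnoid space; the
#' blood-brain-barrier leak; and the two constant production sources, both
#' drawn from the capillary node so that total volume is conserved by
#' construction.
#'
#' @return A tibble with one row per edge: `edge`, `from`, `to`, `resistor`
#'   (`NA` for the constant sources) and `coupling_volume` (the compartment
#'   whose volume rescales the resistor, `NA` if none).
#' @export
circuit_topology <- function() {
  tibble::tibble(
    edge = .edges,
    from = c("p_ao", "v_a", "v_c", "v_v", "v_c", "v_ven", "v_br", "v_sas",
             "v_sas", "v_c", "v_c"),
    to = c("v_a", "v_c", "v_v", "p_sss", "v_br", "v_sas", "v_sas", "p_sss",
           "v_spi", "v_ven", "v_br"),
    resistor = c("R_A", "R_C", "R_V", "R_BV", "R_BBB", "R_VEN", "R_BF",
                 "R_OUT", "R_FM", NA, NA),
    coupling_volume = c("v_a", "v_c", "v_v", "v_v", NA, "v_ven", "v_br",
                        "v_sas", "v_sas", NA, NA)
  )
}

#' Pulsatile arterial pressure driver
#'
#' A two-harmonic arterial waveform
#' \eqn{P(t) = \bar P + A[\sin(2\pi f t) + h_2 \sin(4\pi f t + \phi)]}
#' whose cycle average equals the mean exactly and whose systolic peak is
#' `mean + 1.35 A` (about 120 mmHg at the defaults).
#'
#' @param t time [s], vectorised.
#' @param mean mean arterial pressure [mmHg].
#' @param pulse_amplitude fundamental amplitude `A` [mmHg]; 0 gives a
#'   constant driver.
#' @param heart_rate cardiac frequency [1/s].
#' @param harmonic relative amplitude of the second harmonic.
#' @param phase phase of the second harmonic [rad].
#' @return Pressure [mmHg].
#' @export
arterial_driver <- function(t, mean = 93, pulse_amplitude = 20, heart_rate = 1,
                            harmonic = 0.35, phase = -pi / 2) {
  if (heart_rate <= 0) stop("heart_rate must be positive", call. = FALSE)
  stopifnot(mean > 0, pulse_amplitude >= 0)
  w <- 2 * pi * heart_rate * t
  mean + pulse_amplitude * (sin(w) + harmonic * sin(2 * w + phase))
}

# internal: resistances as numeric[9] in .resistors order
resistances_vec <- function(v, params) {
  cp <- params$coupling
  ff <- params$collapse_floor_frac
  scale2 <- function(r0, vol, v0, on) {
    if (!on) return(r0)
    vol <- max(vol, ff * v0)
    r0 / (vol / v0)^2
  }
  c(R_A = scale2(params$R_A, v[[1]], params$V_A, cp[["R_A"]]),
    R_C = scale2(params$R_C, v[[2]], params$V_C, cp[["R_C"]]),
    R_V = scale2(params$R_V, v[[3]], params$V_V, cp[["R_V"]]),
    R_BV = scale2(params$R_BV, v[[3]], params$V_V, cp[["R_BV"]]),
    R_BBB = scale2(params$R_BBB, v[[5]], params$V_BR, cp[["R_BBB"]]),
    R_VEN = scale2(params$R_VEN, v[[4]], params$V_VEN, cp[["R_VEN"]]),
    R_BF = scale2(params$R_BF, v[[5]], params$V_BR, cp[["R_BF"]]),
    R_OUT = scale2(params$R_OUT, v[[6]], params$V_SAS, cp[["R_OUT"]]),
    R_FM = scale2(params$R_FM, v[[6]], params$V_SAS, cp[["R_FM"]]))
}

#' Effective (volume-scaled) resistances for a state
#'
#' Applies the Hagen-Poiseuille volume rescaling to every resistor whose
#' coupling flag is on, against the volume of the compartment it traverses;
#' uncoupled resistors return their configured values.
#'
#' @inheritParams absolute_pressures
#' @return A one-row tibble with one column per resistor [mmHg.s/ml].
#' @export
effective_resistances <- function(state, params = icp_params()) {
  tibble::as_tibble(as.list(resistances_vec(state_vec(state), params)))
}

# internal: flows as numeric[11] in .edges order
flows_vec <- function(p, r, params) {
  c(q_a = (p[[9]] - p[[4]]) / r[[1]],
    q_c = (p[[4]] - p[[5]]) / r[[2]],
    q_v = (p[[5]] - p[[6]]) / r[[3]],
    q_bv = (p[[6]] - p[[8]]) / r[[4]],
    q_bbb = (p[[5]] - p[[2]]) / r[[5]],
    q_ven = (p[[3]] - p[[1]]) / r[[6]],
    q_bf = (p[[2]] - p[[1]]) / r[[7]],
    q_out = (p[[1]] - p[[8]]) / r[[8]],
    q_fm = (p[[1]] - p[[7]]) / r[[9]],
    q_csf = params$Q_CSF,
    q_isf = params$Q_ISF)
}

#' Edge flows from pressures and resistances
#'
#' Ohm's-law analogue: each resistive edge carries
#' \eqn{Q = \Delta P / R} in its canonical direction; the CSF and
#' interstitial-fluid production edges carry their constant rates
#' irrespective of pressure.
#'
#' @param pressures one-row tibble from [absolute_pressures()].
#' @param resistances one-row tibble from [effective_resistances()].
#' @param params an [icp_params()] object (production rates).
#' @return A one-row tibble with one column per edge [ml/s].
#' @export
compute_flows <- function(pressures, resistances, params = icp_params()) {
  p <- as.numeric(pressures[1, c("icp_sas", "icp_br", "icp_ven", "p_arl",
                                 "p_c", "p_v", "p_spi", "p_sss", "p_ao")])
  r <- as.numeric(resistances[1, .resistors])
  if (any(r <= 0)) stop("all resistances must be positive", call. = FALSE)
  tibble::as_tibble(as.list(flows_vec(p, r, params)))
}

# internal: volume derivatives numeric[7] from flows numeric[11]
derivs_vec <- function(q) {
  c(q[[1]] - q[[2]],
    q[[2]] - q[[3]] - q[[5]] - q[[10]] - q[[11]],
    q[[3]] - q[[4]],
    q[[10]] - q[[6]],
    q[[11]] + q[[5]] - q[[7]],
    q[[6]] + q[[7]] - q[[8]] - q[[9]],
    q[[9]])
}

#' Advance the compartment volumes one explicit Euler step
#'
#' Each compartment volume is incremented by its net inflow times `dt`,
#' clamped at the collapse floor, and time advances by `dt`.
#'
#' @param state one-row state tibble.
#' @param flows one-row tibble from [compute_flows()].
#' @param dt time step [s].
#' @param params an [icp_params()] object (collapse floors).
#' @return The updated one-row state tibble.
#' @export
euler_step <- function(state, flows, dt, params = icp_params()) {
  stopifnot(dt > 0)
  q <- as.numeric(flows[1, .edges])
  if (any(!is.finite(q))) {
    stop("non-finite flow on edge ", .edges[which(!is.finite(q))[1]],
         call. = FALSE)
  }
  v <- state_vec(state) + derivs_vec(q) * dt
  fl <- params$collapse_floor_frac *
    c(params$V_A, params$V_C, params$V_V, params$V_VEN, params$V_BR,
      params$V_SAS, params$V_SPI)
  v <- pmax(v, fl)
  out <- tibble::as_tibble(as.list(v))
  out$time <- state$time[1] + dt
  out[, c("time", .compartments)]
}

# normalise a perturbation schedule into a list of segments
normalise_schedule <- function(schedule, duration) {
  if (is.null(schedule)) return(list())
  if (!is.null(schedule$from) || !is.null(schedule$overrides) ||
      !is.null(schedule$inject_into)) {
    schedule <- list(schedule)
  }
  lapply(schedule, function(s) {
    list(from = if (is.null(s$from)) 0 else s$from,
         to = if (is.null(s$to)) duration else s$to,
         overrides = if (is.null(s$overrides)) list() else s$overrides,
         inject_into = s$inject_into,
         inject_rate = if (is.null(s$inject_rate)) 0 else s$inject_rate)
  })
}

#' Simulate the model by explicit Euler time-marching
#'
#' Runs the full per-step loop — constitutive pressures, volume-rescaled
#' resistances, Ohm-analogue flows, Euler volume update — from an initial
#' state, optionally under a piecewise-constant perturbation schedule
#' (parameter overrides and/or constant-rate fluid injection into a named
#' compartment). The run is fully deterministic.
#'
#' @param params an [icp_params()] object.
#' @param duration simulated time [s].
#' @param dt Euler step [s]; 0.5 ms resolves the cardiac waveform, while
#'   cycle-averaged (non-pulsatile) runs are stable up to ~0.25 s.
#' @param pulsatile if `FALSE` the arterial driver returns its mean
#'   (cycle-averaged mode, for steady-state experiments).
#' @param schedule `NULL`, a segment, or a list of segments; each segment is
#'   a list with `from`, `to` [s], `overrides` (named parameter values) and
#'   optionally `inject_into` (a compartment name) with `inject_rate`
#'   [ml/s].
#' @param init initial one-row state tibble; defaults to
#'   [baseline_state()].
#' @param record_dt interval between recorded samples [s]; defaults to
#'   about 2000 rows per run.
#' @return An `icp_trace` tibble: `time`, the 7 volumes, the 9 node
#'   pressures and the 11 edge flows per recorded sample, with `dt` and the
#'   schedule stored as attributes.
#' @export
simulate_icp <- function(params = icp_params(), duration = 60, dt = 5e-4,
                         pulsatile = TRUE, schedule = NULL, init = NULL,
                         record_dt = NULL) {
  stopifnot(duration > 0, dt > 0)
  if (is.null(init)) init <- baseline_state(params)
  segs <- normalise_schedule(schedule, duration)
  n <- ceiling(duration / dt)
  stride <- if (is.null(record_dt)) max(1L, floor(n / 2000)) else
    max(1L, round(record_dt / dt))
  v <- state_vec(init)
  t0 <- init$time[1]
  base_vols <- c(params$V_A, params$V_C, params$V_V, params$V_VEN,
                 params$V_BR, params$V_SAS, params$V_SPI)
  floor_vols <- params$collapse_floor_frac * base_vols
  max_step <- 0.01 * base_vols
  nrec <- floor(n / stride) + 2L
  rec <- matrix(NA_real_, nrow = nrec, ncol = 1 + 7 + 9 + 11)
  irec <- 1L
  # per-segment effective parameter objects
  seg_params <- lapply(segs, function(s) {
    p <- params
    if (length(s$overrides)) p[names(s$overrides)] <- s$overrides
    p
  })
  inj_idx <- vapply(segs, function(s) {
    if (is.null(s$inject_into)) 0L else match(s$inject_into, .compartments)
  }, integer(1))
  t <- t0
  for (i in seq_len(n + 1L)) {
    # active segment (last one whose window contains t), if any
    pa <- params; inj <- 0L; inj_rate <- 0
    if (length(segs)) {
      for (k in seq_along(segs)) {
        if (t >= segs[[k]]$from && t < segs[[k]]$to) {
          pa <- seg_params[[k]]
          inj <- inj_idx[k]; inj_rate <- segs[[k]]$inject_rate
        }
      }
    }
    p_ao <- if (pulsatile) {
      arterial_driver(t, pa$P_AO, pa$pulse_amplitude, pa$heart_rate,
                      pa$pulse_harmonic, pa$pulse_phase)
    } else pa$P_AO
    p <- pressures_vec(v, pa, p_ao)
    r <- resistances_vec(v, pa)
    q <- flows_vec(p, r, pa)
    if (any(!is.finite(q))) {
      stop("non-finite flow on edge ", .edges[which(!is.finite(q))[1]],
           " at t = ", t, call. = FALSE)
    }
    if (((i - 1L) %% stride == 0L || i == n + 1L) && irec <= nrec) {
      rec[irec, ] <- c(t, v, p, q)
      irec <- irec + 1L
    }
    if (i > n) break
    dv <- derivs_vec(q) * dt
    if (inj > 0L) dv[inj] <- dv[inj] + inj_rate * dt
    if (any(abs(dv) > max_step)) {
      j <- which(abs(dv) > max_step)[1]
      stop("instability: ", .compartments[j], " changed by ",
           signif(dv[j], 3), " ml in one step at t = ", t,
           "; reduce dt", call. = FALSE)
    }
    v <- pmax(v + dv, floor_vols)
    t <- t0 + i * dt
  }
  rec <- rec[seq_len(irec - 1L), , drop = FALSE]
  colnames(rec) <- c("time", .compartments,
                     c("icp_sas", "icp_br", "icp_ven", "p_arl", "p_c", "p_v",
                       "p_spi", "p_sss", "p_ao"), .edges)
  out <- tibble::as_tibble(rec)
  attr(out, "dt") <- dt
  attr(out, "pulsatile") <- pulsatile
  attr(out, "schedule") <- segs
  class(out) <- c("icp_trace", class(out))
  out
}
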