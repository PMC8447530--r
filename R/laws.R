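# --- polynomial helpers -----------------------------------------------------

cubic_eval <- function(v, a, b, c, d) ((a * v + b) * v + c) * v + d
cubic_slope <- function(v, a, b, c) (3 * a * v + 2 * b) * v + c

# inverse of a strictly increasing cubic by bracketed root search
cubic_invert <- function(p, a, b, c, d, lower, upper, tol = 1e-12) {
  f <- function(v) cubic_eval(v, a, b, c, d) - p
  lo <- lower; hi <- upper
  while (f(lo) > 0) lo <- lo - (hi - lo)
  while (f(hi) < 0) hi <- hi + (hi - lo)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

# --- constitutive pressure-volume laws --------------------------------------

#' Subarachnoid (cranial) exponential pressure-volume law
#'
#' Absolute subarachnoid pressure as an exponential function of total
#' intracranial volume: \eqn{a_s e^{b_s (V_{tot} - V_0)} + c_s}. The
#' exponential form captures the exhaustion of cranial volume-reserve
#' capacity: the law is strictly increasing and convex.
#'
#' @param v_tot total intracranial volume [ml] (brain tissue + ventricles +
#'   subarachnoid space + blood).
#' @param pv calibrated coefficients from [calibrate_pv_coefficients()].
#' @return Pressure [mmHg].
#' @export
sas_pressure <- function(v_tot, pv) {
  if (any(!is.finite(v_tot)) || any(v_tot <= 0)) {
    stop("v_tot must be positive and finite", call. = FALSE)
  }
  ex <- pv$sas_b * (v_tot - pv$cranial_unstressed_volume)
  if (any(ex > 500)) {
    stop("subarachnoid law overflow: total intracranial volume ",
         max(v_tot), " ml signals a runaway simulation", call. = FALSE)
  }
  pv$sas_a * exp(ex) + pv$sas_c
}

# inverse of the exponential law
sas_volume <- function(p, pv) {
  stopifnot(all(p > pv$sas_c))
  pv$cranial_unstressed_volume + log((p - pv$sas_c) / pv$sas_a) / pv$sas_b
}

#' Brain transmural pressure (cubic law)
#'
#' Transmural pressure of the brain compartment as a cubic polynomial of the
#' volume enclosed by the pia (brain tissue + ventricles + intracranial
#' blood). The absolute parenchymal pressure is the subarachnoid pressure
#' plus this value.
#'
#' @param v_br_enclosed volume enclosed by the pia [ml].
#' @inheritParams sas_pressure
#' @return Transmural pressure [mmHg].
#' @export
brain_transmural_pressure <- function(v_br_enclosed, pv) {
  rng <- attr(pv, "brain_range")
  if (any(v_br_enclosed < rng[1] | v_br_enclosed > rng[2])) {
    stop("enclosed brain volume outside monotonic operating range [",
         rng[1], ", ", rng[2], "] ml", call. = FALSE)
  }
  cubic_eval(v_br_enclosed, pv$brain_a, pv$brain_b, pv$brain_c, pv$brain_d)
}

#' Ventricular transmural pressure (cubic law)
#'
#' Transmural pressure of the ventricles over the surrounding brain
#' parenchyma, as a cubic polynomial of ventricular volume. Negative values
#' indicate the collapse regime, in which the ventricles are compressed
#' below their unstressed volume by the swollen brain.
#'
#' @param v_ven ventricular volume [ml].
#' @inheritParams sas_pressure
#' @return Transmural pressure [mmHg]; absolute ventricular pressure is the
#'   brain parenchymal pressure plus this value.
#' @export
ventricle_transmural_pressure <- function(v_ven, pv) {
  rng <- attr(pv, "ven_range")
  if (any(v_ven < rng[1] | v_ven > rng[2])) {
    stop("ventricular volume outside monotonic operating range [",
         rng[1], ", ", rng[2], "] ml", call. = FALSE)
  }
  cubic_eval(v_ven, pv$ven_a, pv$ven_b, pv$ven_c, pv$ven_d)
}

#' Vascular transmural pressure (linear law)
#'
#' Transmural pressure of an intracranial vascular chamber (arterial,
#' capillary or venous): volume over compliance. The chamber wall is exposed
#' to the brain parenchymal pressure, so the absolute intravascular pressure
#' is `icp_br + v / c`.
#'
#' @param v chamber blood volume [ml].
#' @param c chamber compliance [ml/mmHg].
#' @return Transmural pressure [mmHg].
#' @export
vascular_transmural_pressure <- function(v, c) {
  if (any(c <= 0)) stop("compliance must be positive", call. = FALSE)
  if (any(v < 0)) stop("volume must be non-negative", call. = FALSE)
  v / c
}

#' Spinal thecal sac pressure (quadratic law)
#'
#' Absolute pressure of the extracranial spinal thecal sac as a quadratic
#' function of its volume. The sac communicates with the cranial
#' subarachnoid space through the foramen magnum and buffers acute cranial
#' volume loads.
#'
#' @param v_spi spinal sac volume [ml].
#' @inheritParams sas_pressure
#' @return Pressure [mmHg], absolute.
#' @export
spinal_pressure <- function(v_spi, pv) {
  (pv$spi_a * v_spi + pv$spi_b) * v_spi + pv$spi_c
}

# inverse of the spinal quadratic on its increasing branch
spinal_volume <- function(p, pv) {
  a <- pv$spi_a; b <- pv$spi_b; c <- pv$spi_c - p
  if (a == 0) return(-c / b)
  disc <- b^2 - 4 * a * c
  if (any(disc < 0)) stop("spinal pressure below the law's minimum", call. = FALSE)
  (-b + sqrt(disc)) / (2 * a)
}

#' Volume-dependent flow resistance (Hagen-Poiseuille scaling)
#'
#' Rescales a baseline resistance with the volume of the conduit it runs
#' through: \eqn{R = R_0 / (V/V_0)^2}, the lumped form of Poiseuille's law
#' for a collapsing/distending cylinder. Below the collapse floor
#' (`floor_frac` of baseline volume) the volume is clamped, yielding a large
#' but finite resistance.
#'
#' @param r0 baseline resistance [mmHg.s/ml] at volume `v0`.
#' @param v current conduit volume [ml].
#' @param v0 baseline conduit volume [ml].
#' @param floor_frac collapse floor as a fraction of `v0`.
#' @return Resistance [mmHg.s/ml].
#' @examples
#' volume_scaled_resistance(280, 70, 35)  # doubled volume: 70
#' @export
volume_scaled_resistance <- function(r0, v, v0, floor_frac = 0.02) {
  stopifnot(all(r0 > 0), all(v0 > 0))
  v <- pmax(v, floor_frac * v0)
  r0 / (v / v0)^2
}

# --- pressure composition ---------------------------------------------------

# internal fast path: volumes numeric[7] -> named numeric[9] of absolute
# pressures; p_ao supplied by the caller (driver or mean).
pressures_vec <- function(v, params, p_ao) {
  pv <- params$pv
  v_tot <- v[[1]] + v[[2]] + v[[3]] + v[[4]] + v[[5]] + v[[6]]
  v_enc <- v[[1]] + v[[2]] + v[[3]] + v[[4]] + v[[5]]
  icp_sas <- sas_pressure(v_tot, pv)
  icp_br <- icp_sas + cubic_eval(v_enc, pv$brain_a, pv$brain_b, pv$brain_c,
                                 pv$brain_d)
  icp_ven <- icp_br + cubic_eval(v[[4]], pv$ven_a, pv$ven_b, pv$ven_c, pv$ven_d)
  c(icp_sas = icp_sas,
    icp_br = icp_br,
    icp_ven = icp_ven,
    p_arl = icp_br + v[[1]] / params$C_A,
    p_c = icp_br + v[[2]] / params$C_C,
    p_v = icp_br + v[[3]] / params$C_V,
    p_spi = (pv$spi_a * v[[7]] + pv$spi_b) * v[[7]] + pv$spi_c,
    p_sss = params$P_SSS,
    p_ao = p_ao)
}

#' Absolute pressures at every node
#'
#' Composes the five constitutive laws into absolute pressures following the
#' anatomical nesting: the subarachnoid space references the rigid skull,
#' the brain references the subarachnoid space, the ventricles and the
#' vascular chambers reference the brain, and the spinal sac is absolute.
#'
#' @param state a one-row state tibble (see [baseline_state()]).
#' @param params an [icp_params()] object.
#' @param t time [s], used to evaluate the arterial driver.
#' @param pulsatile if `FALSE` the arterial node takes its mean pressure.
#' @return A one-row tibble with columns `icp_sas`, `icp_br`, `icp_ven`,
#'   `p_arl`, `p_c`, `p_v`, `p_spi`, `p_sss`, `p_ao` [mmHg].
#' @export
absolute_pressures <- function(state, params = icp_params(), t = 0,
                               pulsatile = FALSE) {
  v <- state_vec(state)
  # range checks via the public laws (fast path skips them)
  brain_transmural_pressure(enclosed_brain_volume(v), params$pv)
  ventricle_transmural_pressure(v[["v_ven"]], params$pv)
  p_ao <- if (pulsatile) {
    arterial_driver(t, params$P_AO, params$pulse_amplitude, params$heart_rate,
                    params$pulse_harmonic, params$pulse_phase)
  } else {
    params$P_AO
  }
  tibble::as_tibble(as.list(pressures_vec(v, params, p_ao)))
}
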