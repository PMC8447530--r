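#' Baseline model parameters
#'
#' Constructs the full parameter set of the four-compartment intracranial
#' model: baseline compartment volumes, vascular compliances, flow
#' resistances, CSF/ISF production rates, boundary pressures, the arterial
#' pulse driver, and the calibrated pressure-volume coefficients.
#'
#' Defaults are the model's baseline operating point: arterial-arteriolar
#' volume 20 ml, capillary 100 ml, venous 30 ml, ventricles 25 ml, brain
#' tissue (including interstitial fluid) 1400 ml, subarachnoid space 35 ml,
#' spinal thecal sac 70 ml; CSF production 0.0042 ml/s and interstitial-fluid
#' production 0.00083 ml/s; mean aortic pressure 93 mmHg and sagittal-sinus
#' pressure 7.4 mmHg. Units are ml, mmHg and seconds throughout; resistances
#' are mmHg.s/ml and compliances ml/mmHg.
#'
#' @param ... named overrides of any scalar parameter (e.g. `R_BF = 2400`).
#'   Unknown names are an error.
#' @param pv pressure-volume coefficients, as returned by
#'   [calibrate_pv_coefficients()]. The default calibrates with
#'   flow-consistent anchors (`pv_targets(anchors = "consistent")`) so that
#'   the solved baseline volumes equal the configured baseline volumes
#'   exactly; pass `calibrate_pv_coefficients(pv_targets("table"))` to anchor
#'   the laws on the printed baseline pressures instead (9.5 / 10.5 / 10.8
#'   mmHg), at the cost of a small baseline drift.
#' @param coupling named logical vector switching the volume dependence
#'   (Hagen-Poiseuille rescaling) of individual resistors on or off.
#'   Partial vectors override the defaults: on for the collapsible bridging
#'   veins (`R_BV`, venous volume), CSF outflow and foramen-magnum
#'   resistance (`R_OUT`/`R_FM`, subarachnoid volume) and interstitial
#'   bulk-flow resistance (`R_BF`, brain volume); off for the remaining
#'   resistors, whose conduits are either swept as independent variables
#'   (`R_VEN`, `R_BBB`) or are pressure-buffered upstream chambers whose
#'   coupling would introduce an unphysiological perfusion-collapse
#'   equilibrium (`R_A`, `R_C`, `R_V`).
#'
#' @return An object of class `icp_params`: a named list of scalars plus the
#'   `pv` coefficient object and the `coupling` flags.
#' @examples
#' p <- icp_params()
#' p$R_OUT
#' icp_params(R_BF = 2400)$R_BF
#' @export
icp_params <- function(..., pv = NULL, coupling = NULL) {
  base <- list(
    # baseline volumes [ml]
    V_A = 20, V_C = 100, V_V = 30, V_VEN = 25, V_BR = 1400, V_SAS = 35,
    V_SPI = 70,
    # vascular compliances [ml/mmHg]
    C_A = 0.4, C_C = 5, C_V = 5,
    # resistances [mmHg.s/ml]
    R_A = 1.9, R_C = 2.5, R_V = 0.8, R_BV = 0.7, R_BBB = 1e7,
    R_VEN = 250, R_BF = 1200, R_OUT = 280, R_FM = 15,
    # production rates [ml/s]
    Q_CSF = 0.0042, Q_ISF = 0.00083,
    # boundary pressures [mmHg]
    P_AO = 93, P_SSS = 7.4,
    # arterial pulse driver: P_AO + A*(sin(2*pi*f*t) + h2*sin(4*pi*f*t + phase))
    pulse_amplitude = 20, heart_rate = 1, pulse_harmonic = 0.35,
    pulse_phase = -pi / 2,
    # numerics
    collapse_floor_frac = 0.02,
    brain_mass = 1400
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    base[names(dots)] <- dots
  }
  cpl <- c(R_A = FALSE, R_C = FALSE, R_V = FALSE, R_BV = TRUE, R_BBB = FALSE,
           R_VEN = FALSE, R_BF = TRUE, R_OUT = TRUE, R_FM = TRUE)
  if (!is.null(coupling)) {
    bad <- setdiff(names(coupling), names(cpl))
    if (length(bad)) stop("unknown coupling flag(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cpl[names(coupling)] <- as.logical(coupling)
  }
  base$coupling <- cpl
  if (is.null(pv)) pv <- calibrate_pv_coefficients(pv_targets(anchors = "consistent"))
  stopifnot(inherits(pv, "icp_pv"))
  base$pv <- pv
  out <- structure(base, class = "icp_params")
  validate_icp_params(out)
  out
}

validate_icp_params <- function(p) {
  pos <- c("V_A", "V_C", "V_V", "V_VEN", "V_BR", "V_SAS", "V_SPI",
           "C_A", "C_C", "C_V", "R_A", "R_C", "R_V", "R_BV", "R_BBB",
           "R_VEN", "R_BF", "R_OUT", "R_FM", "Q_CSF", "Q_ISF", "P_AO",
           "heart_rate", "brain_mass")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter ", nm, " must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (p$pulse_amplitude < 0) stop("pulse_amplitude must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.icp_params <- function(x, ...) {
  cat("<icp_params>\n")
  cat("  intracranial baseline volume:",
      x$V_A + x$V_C + x$V_V + x$V_VEN + x$V_BR + x$V_SAS, "ml\n")
  cat("  Q_CSF:", x$Q_CSF, "ml/s  Q_ISF:", x$Q_ISF, "ml/s\n")
  cat("  R_OUT:", x$R_OUT, " R_VEN:", x$R_VEN, " R_BF:", x$R_BF,
      " R_BBB:", format(x$R_BBB), "mmHg.s/ml\n")
  cat("  coupling on:", paste(names(x$coupling)[x$coupling], collapse = " "), "\n")
  invisible(x)
}

#' Baseline compartment state
#'
#' The seven state volumes (arterial, capillary, venous, ventricular, brain
#' tissue, subarachnoid, spinal) at the configured baseline, as a one-row
#' tibble with a `time` column.
#'
#' @param params an [icp_params()] object.
#' @return A one-row tibble with columns `time`, `v_a`, `v_c`, `v_v`,
#'   `v_ven`, `v_br`, `v_sas`, `v_spi`.
#' @export
baseline_state <- function(params = icp_params()) {
  tibble::tibble(
    time = 0,
    v_a = params$V_A, v_c = params$V_C, v_v = params$V_V,
    v_ven = params$V_VEN, v_br = params$V_BR, v_sas = params$V_SAS,
    v_spi = params$V_SPI
  )
}

# internal: state tibble/row -> plain numeric[7] in canonical order
state_vec <- function(state) {
  nm <- c("v_a", "v_c", "v_v", "v_ven", "v_br", "v_sas", "v_spi")
  v <- as.numeric(state[1, nm])
  names(v) <- nm
  v
}

# total intracranial volume (spinal sac excluded)
intracranial_volume <- function(v) {
  v[["v_a"]] + v[["v_c"]] + v[["v_v"]] + v[["v_ven"]] + v[["v_br"]] + v[["v_sas"]]
}

# volume enclosed by the pia: brain tissue + ventricles + blood vessels
enclosed_brain_volume <- function(v) {
  v[["v_br"]] + v[["v_ven"]] + v[["v_a"]] + v[["v_c"]] + v[["v_v"]]
}
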