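# keys accepted in a run configuration file
.config_sections <- c("parameters", "coupling", "calibration", "simulation",
                      "experiment", "output")

#' Load a run configuration (YAML or JSON)
#'
#' Reads a configuration file and resolves it against the documented
#' defaults: the `parameters` section overrides [icp_params()] scalars,
#' `coupling` sets per-resistor volume-coupling flags, `calibration`
#' overrides [pv_targets()] shape settings, `simulation` holds integrator
#' settings (`dt`, `duration`, `pulsatile`) and `experiment` an experiment
#' description. An empty file yields the full defaults. Unknown keys are
#' rejected with the offending name.
#'
#' @param path file path; format chosen by extension (`.json` or YAML
#'   otherwise; YAML is a superset of JSON).
#' @return A list of class `icp_config` with elements `params` (a resolved
#'   [icp_params()] object), `simulation`, `experiment` and `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), .config_sections)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cal <- raw$calibration %||% list()
  tg <- do.call(pv_targets, cal)
  pv <- calibrate_pv_coefficients(tg)
  pars <- raw$parameters %||% list()
  params <- tryCatch(
    do.call(icp_params, c(pars, list(pv = pv, coupling = raw$coupling))),
    error = function(e) stop("invalid configuration: ", conditionMessage(e),
                             call. = FALSE))
  sim <- utils::modifyList(list(dt = 5e-4, duration = 60, pulsatile = TRUE),
                           raw$simulation %||% list())
  structure(list(params = params, calibration = cal,
                 parameters = pars, coupling = raw$coupling,
                 simulation = sim, experiment = raw$experiment,
                 output = raw$output),
            class = "icp_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes the resolved override sections (not the defaults) back to YAML or
#' JSON, so that `load_config(save_config(cfg, path))` reproduces the same
#' configuration.
#'
#' @param config an `icp_config` object from [load_config()], or a bare
#'   list with the same sections.
#' @param path destination file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- list(parameters = config$parameters, coupling = config$coupling,
              calibration = config$calibration,
              simulation = config$simulation, experiment = config$experiment,
              output = config$output)
  out <- out[!vapply(out, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

# full-precision numeric formatting for lossless CSV round-trips
fmt_full <- function(x) {
  ifelse(is.finite(x), sprintf("%.17g", x), as.character(x))
}

#' Write a simulation trace to CSV with a JSON sidecar
#'
#' One row per recorded sample (time, the 7 compartment volumes, the 9 node
#' pressures and the 11 edge flows), comma-separated with a mandatory
#' header and full float precision, so that [read_trace()] reproduces the
#' values exactly. Metadata (time step, pulsatile flag, schedule) goes to
#' `<path>.json`.
#'
#' @param trace an `icp_trace` from [simulate_icp()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  chr <- as.data.frame(lapply(df, fmt_full), check.names = FALSE)
  tryCatch(
    utils::write.csv(chr, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write trace to ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  meta <- list(dt = attr(trace, "dt"), pulsatile = attr(trace, "pulsatile"),
               schedule = attr(trace, "schedule"), n = nrow(trace))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back a simulation trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return An `icp_trace` tibble; metadata restored from the JSON sidecar
#'   when present.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  out <- tibble::as_tibble(df)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "dt") <- meta$dt
    attr(out, "pulsatile") <- meta$pulsatile
  }
  class(out) <- c("icp_trace", class(out))
  out
}

#' Generate the deterministic reference fixtures
#'
#' Writes the package's regression surface to `outdir`: (a) the calibrated
#' default coefficients (both anchor modes) as JSON, (b) the baseline
#' steady-state report as JSON, (c) the pathological compartment-shift
#' table at `target_icp` as CSV, (d) a bolus pressure-volume grid as CSV
#' and (e) ventilation results as CSV. Two invocations produce
#' byte-identical files (the model has no randomness).
#'
#' @param outdir output directory (created if needed).
#' @param params an [icp_params()] object.
#' @param target_icp ICP level for the pathology table [mmHg].
#' @param bolus_volumes injected volumes for the PV grid [ml].
#' @param cbf_changes ventilation CBF targets [percent].
#' @return Paths of the written files, invisibly.
#' @export
generate_reference_fixtures <- function(outdir, params = icp_params(),
                                        target_icp = 30,
                                        bolus_volumes = c(0, 2, 4, 8),
                                        cbf_changes = c(-20, 30)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(name) file.path(outdir, name)
  # (a) coefficients
  for (mode in c("consistent", "table")) {
    pv <- calibrate_pv_coefficients(pv_targets(mode))
    pth <- w(paste0("pv_coefficients_", mode, ".json"))
    plain <- stats::setNames(lapply(names(pv), function(n) pv[[n]]), names(pv))
    jsonlite::write_json(plain, pth, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, pth)
  }
  # (b) baseline steady state
  base <- solve_steady_state(params)
  pth <- w("baseline_steady_state.json")
  jsonlite::write_json(list(state = as.list(base$state),
                            pressures = as.list(base$pressures),
                            flows = as.list(base$flows),
                            cbf = base$cbf),
                       pth, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, pth)
  # (c) pathology table
  tab <- pathology_report(target_icp, params)
  pth <- w(sprintf("pathology_icp%g.csv", target_icp))
  utils::write.csv(as.data.frame(lapply(tab, function(x)
    if (is.numeric(x)) fmt_full(x) else x), check.names = FALSE),
    pth, row.names = FALSE, quote = FALSE)
  paths <- c(paths, pth)
  # (d) bolus PV curve
  pv_curve <- bolus_pv_curve(bolus_volumes, params = params)
  pth <- w("bolus_pv_curve.csv")
  utils::write.csv(as.data.frame(lapply(pv_curve, fmt_full)), pth,
                   row.names = FALSE, quote = FALSE)
  paths <- c(paths, pth)
  # (e) ventilation
  vent <- dplyr::bind_rows(lapply(cbf_changes, function(tc)
    dplyr::mutate(ventilation_experiment(tc, params), target = tc)))
  pth <- w("ventilation.csv")
  utils::write.csv(as.data.frame(lapply(vent, fmt_full)), pth,
                   row.names = FALSE, quote = FALSE)
  paths <- c(paths, pth)
  invisible(paths)
}
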