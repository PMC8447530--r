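# steady-state residual: net inflow [ml/s] of the six intracranial
# compartments, with the spinal sac eliminated (zero foramen-magnum flow,
# p_spi = icp_sas, at any steady state).
steady_residual <- function(v6, params) {
  v7 <- c(v6, 0)
  p <- pressures_vec(v7, params, params$P_AO)
  p[[7]] <- p[[1]]  # p_spi = icp_sas
  r <- resistances_vec(v7, params)
  q <- flows_vec(p, r, params)
  derivs_vec(q)[1:6]
}

steady_jacobian <- function(v6, params, free) {
  nf <- length(free)
  J <- matrix(0, nf, nf)
  for (j in seq_len(nf)) {
    h <- max(1e-6, 1e-7 * abs(v6[free[j]]))
    vp <- v6; vp[free[j]] <- vp[free[j]] + h
    vm <- v6; vm[free[j]] <- vm[free[j]] - h
    J[, j] <- (steady_residual(vp, params)[free] -
                 steady_residual(vm, params)[free]) / (2 * h)
  }
  J
}

# cycle-averaged (non-pulsatile) integration of the full 7-state system with
# a stiff solver; used for long-horizon experiments and as the solver's
# pseudo-time fallback. Returns the state at t_end.
integrate_averaged <- function(v7, params, t_end, rtol = 1e-10, atol = 1e-8,
                               maxsteps = 20000) {
  floors <- params$collapse_floor_frac *
    c(params$V_A, params$V_C, params$V_V, params$V_VEN, params$V_BR,
      params$V_SAS, params$V_SPI)
  rhs <- function(t, y, parms) {
    y <- pmax(y, floors)
    p <- pressures_vec(y, params, params$P_AO)
    r <- resistances_vec(y, params)
    q <- flows_vec(p, r, params)
    dv <- derivs_vec(q)
    dv[y <= floors & dv < 0] <- 0
    list(dv)
  }
  # the solver's step-budget diagnostics are routine during pseudo-time
  # relaxation; keep the console clean
  utils::capture.output(
    sol <- suppressWarnings(
      deSolve::lsoda(as.numeric(v7), c(0, t_end), rhs, rtol = rtol,
                     atol = atol, maxsteps = maxsteps)),
    file = nullfile(), type = "output")
  as.numeric(sol[nrow(sol), 2:8])
}

# pseudo-time fallback for the Newton solver
pseudo_time_state <- function(v6, params, t_end = 1e6) {
  y0 <- c(v6, spinal_volume(pressures_vec(c(v6, 0), params, params$P_AO)[[1]],
                            params$pv))
  integrate_averaged(y0, params, t_end, rtol = 1e-8, atol = 1e-7)[1:6]
}

#' Solve the algebraic steady state of the full circuit
#'
#' Finds the compartment volumes at which every internal node of the flow
#' network balances under the non-pulsatile (cycle-averaged) arterial
#' input, generalising the Davson relation to the full nonlinear circuit.
#' A damped Newton iteration with numerical Jacobian is used, falling back
#' to stiff pseudo-time integration if Newton stalls. If the swollen brain
#' drives a compartment to its collapse floor (slit ventricles), the floor
#' is held as an active clamp and reported.
#'
#' @param params an [icp_params()] object.
#' @param overrides named list of scalar parameter overrides (e.g.
#'   `list(R_BF = 24000)`), applied on top of `params`.
#' @param init optional initial guess: a state tibble or numeric vector of
#'   the six intracranial volumes; defaults to the configured baseline.
#' @param tol convergence tolerance on the largest node imbalance [ml/s].
#' @param max_iter maximum Newton iterations.
#' @return An object of class `icp_steady`: a list with the converged
#'   `state` (one-row tibble, spinal volume recovered from its
#'   pressure-volume law), `pressures`, `flows` and `resistances` tibbles,
#'   `deltas` from the configured baseline volumes [ml], `cbf`
#'   [ml/100g/min], `floor_active` (names of clamped compartments),
#'   `converged`, `residual` and the perturbation that produced it.
#' @examples
#' \donttest{
#' ss <- solve_steady_state(icp_params())
#' glance(ss)
#' }
#' @export
solve_steady_state <- function(params = icp_params(), overrides = list(),
                               init = NULL, tol = 1e-10, max_iter = 200) {
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    params[names(overrides)] <- overrides
  }
  if (is.null(init)) {
    v <- c(params$V_A, params$V_C, params$V_V, params$V_VEN, params$V_BR,
           params$V_SAS)
  } else if (is.data.frame(init)) {
    v <- state_vec(init)[1:6]
  } else {
    v <- as.numeric(init)[1:6]
  }
  names(v) <- .compartments[1:6]
  floors <- params$collapse_floor_frac *
    c(params$V_A, params$V_C, params$V_V, params$V_VEN, params$V_BR,
      params$V_SAS)
  clamped <- rep(FALSE, 6)
  newton <- function(v, clamped) {
    free <- which(!clamped)
    Fv <- steady_residual(v, params)
    for (it in seq_len(max_iter)) {
      if (max(abs(Fv[free])) < tol) break
      J <- steady_jacobian(v, params, free)
      step <- tryCatch(solve(J, -Fv[free]), error = function(e) NULL)
      if (is.null(step)) return(list(v = v, ok = FALSE, F = Fv))
      lambda <- 1
      repeat {
        vn <- v
        vn[free] <- pmax(v[free] + lambda * step, floors[free])
        Fn <- steady_residual(vn, params)
        if (max(abs(Fn[free])) < max(abs(Fv[free])) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      if (max(abs(Fn[free])) >= max(abs(Fv[free]))) {
        return(list(v = v, ok = max(abs(Fv[free])) < 1e-8, F = Fv))
      }
      v <- vn; Fv <- Fn
    }
    list(v = v, ok = max(abs(Fv[free])) < tol, F = Fv)
  }
  for (outer in 1:8) {
    res <- newton(v, clamped)
    round <- 0
    while (!res$ok && round < 3) {
      # stiff pseudo-time restart, then retry Newton
      v <- tryCatch(pseudo_time_state(res$v, params),
                    error = function(e) res$v)
      names(v) <- .compartments[1:6]
      v <- pmax(v, floors)
      res <- newton(v, clamped)
      round <- round + 1
    }
    v <- res$v
    hit <- !clamped & (v <= floors + 1e-12) & (res$F < 0)
    release <- clamped & (res$F > 1e-12)
    if (!any(hit) && !any(release)) break
    clamped <- (clamped | hit) & !release
    v[clamped] <- floors[clamped]
  }
  free <- which(!clamped)
  resid <- max(abs(res$F[free]))
  converged <- resid < max(tol, 1e-6)
  if (!converged) {
    stop("steady-state solver did not converge; largest node imbalance ",
         signif(resid, 3), " ml/s", call. = FALSE)
  }
  # recover the spinal volume and assemble the report
  p <- pressures_vec(c(v, 0), params, params$P_AO)
  v_spi <- spinal_volume(p[[1]], params$pv)
  state <- tibble::as_tibble(as.list(c(time = Inf, v, v_spi = v_spi)))
  p[[7]] <- spinal_pressure(v_spi, params$pv)
  r <- resistances_vec(c(v, v_spi), params)
  q <- flows_vec(p, r, params)
  base <- c(params$V_A, params$V_C, params$V_V, params$V_VEN, params$V_BR,
            params$V_SAS, params$V_SPI)
  deltas <- tibble::tibble(
    compartment = .compartments,
    volume = as.numeric(c(v, v_spi)),
    baseline = base,
    delta = as.numeric(c(v, v_spi)) - base
  )
  out <- list(
    state = state,
    pressures = tibble::as_tibble(as.list(p)),
    flows = tibble::as_tibble(as.list(q)),
    resistances = tibble::as_tibble(as.list(r)),
    deltas = deltas,
    cbf = q[[1]] * 60 * 100 / params$brain_mass,
    floor_active = .compartments[clamped],
    converged = converged,
    residual = resid,
    perturbation = overrides,
    params = params
  )
  class(out) <- "icp_steady"
  out
}

#' Cerebral blood flow from a steady-state report
#'
#' Flow through the arterial inflow edge normalised per 100 g of brain
#' tissue per minute, the unit in which cerebral blood flow is reported
#' clinically (baseline about 65 ml/100g/min for a 1400 g brain).
#'
#' @param report an `icp_steady` object.
#' @param brain_mass brain mass [g].
#' @return CBF [ml/100g/min].
#' @export
cbf_from_state <- function(report, brain_mass = report$params$brain_mass) {
  report$flows$q_a * 60 * 100 / brain_mass
}

#' @export
print.icp_steady <- function(x, ...) {
  cat("<icp_steady> converged:", x$converged,
      " max node imbalance:", signif(x$residual, 3), "ml/s\n")
  cat(sprintf("  ICP: ventricles %.2f | brain %.2f | SAS %.2f mmHg; CBF %.1f ml/100g/min\n",
              x$pressures$icp_ven, x$pressures$icp_br, x$pressures$icp_sas,
              x$cbf))
  if (length(x$floor_active)) {
    cat("  collapse floor active:", paste(x$floor_active, collapse = ", "), "\n")
  }
  print(x$deltas)
  invisible(x)
}

#' @rdname solve_steady_state
#' @param x an `icp_steady` object.
#' @param ... unused.
#' @method tidy icp_steady
#' @export
tidy.icp_steady <- function(x, ...) {
  pr <- c(p_arl = x$pressures$p_arl, p_c = x$pressures$p_c,
          p_v = x$pressures$p_v, icp_ven = x$pressures$icp_ven,
          icp_br = x$pressures$icp_br, icp_sas = x$pressures$icp_sas,
          p_spi = x$pressures$p_spi)
  dplyr::mutate(x$deltas,
                pressure = as.numeric(pr[c("p_arl", "p_c", "p_v", "icp_ven",
                                           "icp_br", "icp_sas", "p_spi")]))
}

#' @rdname solve_steady_state
#' @method glance icp_steady
#' @export
glance.icp_steady <- function(x, ...) {
  tibble::tibble(
    icp_br = x$pressures$icp_br,
    icp_sas = x$pressures$icp_sas,
    icp_ven = x$pressures$icp_ven,
    cbf = x$cbf,
    converged = x$converged,
    residual = x$residual,
    floor_active = paste(x$floor_active, collapse = ",")
  )
}
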