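# shared fixtures, built once per test file
default_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- icp_params()
    p
  }
})

table_pv <- local({
  pv <- NULL
  function() {
    if (is.null(pv)) pv <<- calibrate_pv_coefficients(pv_targets("table"))
    pv
  }
})

baseline_steady <- local({
  ss <- NULL
  function() {
    if (is.null(ss)) ss <<- solve_steady_state(default_params())
    ss
  }
})

# a minimal hand-built coefficient object for degenerate-polynomial checks
degenerate_pv <- function(ven_d = 0.3, brain_d = 1) {
  structure(list(
    sas_a = 9.5, sas_b = 0.1, sas_c = 0,
    brain_a = 0, brain_b = 0, brain_c = 0, brain_d = brain_d,
    ven_a = 0, ven_b = 0, ven_c = 0, ven_d = ven_d,
    spi_a = 0, spi_b = 0, spi_c = 9.5,
    cranial_unstressed_volume = 1610
  ), class = "icp_pv",
  brain_range = c(0, 1e4), ven_range = c(0, 1e3))
}
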