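Package: icpsim
Title: Lumped-Parameter Simulation of Intracranial Pressure and Cerebral
    Interstitial Fluid Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-compartment lumped-parameter (electrical-analog) model of
    intracranial pressure dynamics comprising brain parenchyma with bulk flow of
    interstitial fluid, the cerebral ventricles, the subarachnoid space, and the
    cerebral vasculature inside a rigid cranium coupled to an extracranial spinal
    thecal sac. Provides calibrated nonlinear pressure-volume laws for each
    compartment, volume-dependent (Hagen-Poiseuille) flow resistances, an explicit
    Euler time integrator with a pulsatile arterial driver, a Newton steady-state
    solver generalising the Davson equation, and simulated perturbation
    experiments: rapid fluid bolus pressure-volume curves, hyper- and
    hypoventilation via arteriolar resistance, and pathological resistance ramps
    reproducing obstructive and non-absorptive hydrocephalus, cytotoxic cerebral
    edema (impaired interstitial bulk flow), and blood-brain-barrier breakdown.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
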