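# icpsim

A lumped-parameter simulator of intracranial pressure (ICP) dynamics for
computational physiologists and neurocritical-care modellers. The model is
an electrical-analog circuit of four nested intracranial compartments —
subarachnoid space (SAS), brain parenchyma, cerebral ventricles and the
cerebral vasculature — inside a rigid cranium, coupled to an extracranial
spinal thecal sac. Its distinguishing feature is an explicit circuit for
cerebral **interstitial fluid (ISF) bulk flow**: metabolic water produced in
the parenchyma at rate `Q_ISF` drains to the SAS through a bulk-flow
resistance `R_BF`, alongside the classical CSF pathway. That one element
lets the model reproduce what CSF-only models cannot: the physiology of
**brain swelling** — cytotoxic edema (raised `R_BF`) and vasogenic edema
from blood–brain-barrier breakdown (lowered `R_BBB`) — with elevated ICP,
an expanding brain, and collapsing ventricles and cisterns, as well as the
opposite ventricular ballooning of obstructive (`R_VEN`) and
non-absorptive (`R_OUT`) hydrocephalus.

Core relations, in the field's notation:

* cranial pressure–volume law: `ICP_SAS = a_s·exp(b_s(V_tot − V_0)) + c_s`
  (exponential volume-reserve exhaustion; stiffness given by a
  pressure–volume index, default PVI = 25 ml);
* compartment transmural laws: cubic polynomials for brain and ventricles,
  `P = V/C` for the vascular chambers, a quadratic for the spinal sac;
* flows `Q = ΔP/R` with Hagen–Poiseuille volume coupling
  `R = R_0/(V/V_0)²` on selected conduits (notably CSF absorption:
  a squeezed SAS impairs outflow);
* steady-state CSF limb: the Davson relation extended by bulk flow,
  `ICP_SAS = (Q_ISF + Q_CSF)·R_OUT + P_SSS`,
  `ICP_BR = Q_ISF·R_BF + ICP_SAS`;
* dynamics: explicit Euler time-marching of the seven compartment volumes
  with a pulsatile two-harmonic arterial driver (mean 93 mmHg, systolic
  ≈ 120 mmHg), and a damped-Newton algebraic solver for steady states.

## Worked example

```r
library(icpsim)

params <- icp_params()            # baseline parameter set
ss <- solve_steady_state(params)  # algebraic steady state
ss
#> <icp_steady> converged: TRUE  max node imbalance: 1.15e-13 ml/s
#>   ICP: ventricles 9.89 | brain 9.83 | SAS 8.84 mmHg; CBF 63.2 ml/100g/min
```

The pressure hierarchy is the physiological one — ventricles slightly above
parenchyma, parenchyma above the SAS, all above the sagittal sinus
(7.4 mmHg) — and cerebral blood flow is 63 ml/100g/min (≈ 885 ml/min for a
1400 g brain). Now simulate cytotoxic cerebral edema: raise the
interstitial bulk-flow resistance until parenchymal ICP reaches 30 mmHg.

```r
rr <- ramp_resistance_to_icp("R_BF", target_icp_br = 30, params)
rr$resistance
#> [1] 1564.658            # mmHg·s/ml, vs 1200 at baseline
tidy(rr$report)
#> # A tibble: 7 × 5
#>   compartment  volume baseline  delta pressure
#> 1 v_a           16.5        20  -3.53     71.2
#> 2 v_c           62.5       100 -37.5      42.5
#> 3 v_v           16.7        30 -13.3      33.4
#> 4 v_ven          0.5        25 -24.5      30.0
#> 5 v_br        1514.       1400 114.       30.0
#> 6 v_sas          9.01       35 -26.0      28.9
#> 7 v_spi        112.        70   41.6      28.9
```

A 30% rise in one resistance produces the full clinical picture of severe
brain swelling: the parenchyma gains ~114 ml, the ventricles collapse to
slit ventricles (0.5 ml, the 2% collapse floor), the subarachnoid space is
effaced (35 → 9 ml), cerebral blood volume falls ~54 ml, and CSF is
displaced into the spinal sac. `pathology_report(30, params)` tabulates
the same shifts for all four pathological conditions;
`bolus_pv_curve()`, `ventilation_experiment()` and
`pulse_amplitude_vs_mean_icp()` cover the rapid-injection pressure–volume
curve, CO2-reactivity simulations, and the ICP-waveform amplitude growth
with rising mean ICP. Each result has an `autoplot()`/`plot_*()`
companion, and a thin command-line wrapper lives at
`inst/cli/icpsim.R` (`steady`, `run`, `bolus`, `ventilate`, `ramp`,
`table`, `fixtures` subcommands).

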