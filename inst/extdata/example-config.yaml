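# Example run configuration for icpsim.
# All quantities in ml, mmHg, s; resistances mmHg·s/ml; compliances ml/mmHg.
parameters:
  R_BF: 2400        # doubled interstitial bulk-flow resistance (mild edema)
coupling:
  R_VEN: no         # ventricular resistance stays an independent input
calibration:
  pvi: 25           # cranial pressure-volume index [ml per tenfold ICP rise]
simulation:
  dt: 0.0005        # Euler step [s]
  duration: 60      # [s]
  pulsatile: yes
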