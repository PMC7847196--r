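# Illustrative PDX-like control growth parameters (synthetic).
# NOT fitted values from any published dataset: chosen once to reflect the
# high between-animal heterogeneity typical of patient-derived xenografts
# randomised around 200-250 mm^3 with roughly two-week volume doubling.
mu1: 1.28      # log baseline radius (log mm); exp(1.28) ~ 3.6 mm ~ 230 mm^3
mu2: -2.35     # log radius growth rate (log mm/day); ~0.095 mm/day
sigma1: 0.15   # SD log baseline radius
sigma2: 0.65   # SD log growth rate (PDX heterogeneity)
sigma3: 0.12   # proportional residual SD
effect_scale: log_shift
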