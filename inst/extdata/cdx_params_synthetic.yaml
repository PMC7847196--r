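# Illustrative CDX-like control growth parameters (synthetic).
# NOT fitted values from any published dataset: cell-line xenografts grow
# faster and far more uniformly than PDX models.
mu1: 1.28      # log baseline radius (log mm)
mu2: -1.95     # log radius growth rate; ~0.14 mm/day
sigma1: 0.08
sigma2: 0.25   # much lower growth-rate heterogeneity than PDX
sigma3: 0.12
effect_scale: log_shift
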