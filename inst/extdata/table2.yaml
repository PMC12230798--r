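# Published vital-rate estimates for the greenhouse IPMs.
# Sizes are log-transformed plant heights (log-cm). Survival and shoot
# number were estimated from the pooled data (all origins and treatments)
# and are shared by every cell; seeds_per_shoot is a regional field
# estimate; establishment and seed-bank constants come from previously
# published field data on invasive Finnish populations.
constants:
  establishment: 0.122        # e: direct plant establishment
  bank_establishment: 0.122   # e_sb: establishment from the seed bank
  bank_survival: 0.977        # s_sb: annual seed survival in the bank
  seeds_per_shoot:
    invasive_FI: 79.0
    native_US: 42.0
pooled:
  survival: {intercept: 1.13, slope: 1.16}    # logit scale, n = 220
  shoots: {intercept: 2.67, slope: -0.49}     # n = 46 flowering plants
cells:
  invasive_FI:
    intact:
      growth: {intercept: 4.40, slope: -0.16, sigma2: 0.22}   # n = 56
      flowering: {intercept: 7.89, slope: -3.09}              # n = 56
      recruit_size: {mean: 2.52, var: 0.19}                   # n = 55
    autoclaved:
      growth: {intercept: 2.48, slope: 0.44, sigma2: 0.19}    # n = 53
      flowering: {intercept: 0.27, slope: -1.00}              # n = 53
      recruit_size: {mean: 2.38, var: 0.22}                   # n = 55
  native_US:
    intact:
      growth: {intercept: 3.06, slope: 0.19, sigma2: 0.36}    # n = 55
      flowering: {intercept: -0.15, slope: -0.42}             # n = 55
      recruit_size: {mean: 2.15, var: 0.35}                   # n = 55
    autoclaved:
      growth: {intercept: 2.91, slope: 0.26, sigma2: 0.30}    # n = 51
      flowering: {intercept: -8.38, slope: 2.45}              # n = 51
      recruit_size: {mean: 2.12, var: 0.26}                   # n = 55
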