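# Packaged demographic presets.
#
# Values are editable configuration defaults: documented approximations of
# published multi-population calibrations of human demographic history
# (an African-role expansion, a European-role bottleneck, low symmetric
# migration between three continental populations), using 25-year
# generations.  They are rounded, simplified epoch-wise constants, not
# estimates in their own right.
#
# Migration convention (whole package): migration[i][j] = forward-time
# per-generation fraction of subpopulation j's offspring drawn from
# subpopulation i.  Rows are listed in label order.
#
# sweep_defaults: per-preset default selection parameters.  origin_gen was
# calibrated once with tune_origin_generation() so that the mean
# survival-conditioned modern frequency of a favored allele with s = 0.022
# is approximately 0.5 in the sampled subpopulation.

constant:
  name: constant
  labels: [POP]
  sample_subpop: POP
  epochs:
    - start_gen: 0
      end_gen: .inf
      sizes: [10000]
  sweep_defaults:
    s: 0.022
    origin_gen: 323

expansion:
  name: expansion
  labels: [AFR]
  sample_subpop: AFR
  epochs:
    - start_gen: 0
      end_gen: 4000
      sizes: [20000]
    - start_gen: 4000
      end_gen: .inf
      sizes: [10000]
  sweep_defaults:
    s: 0.022
    origin_gen: 362

expansion_migration:
  name: expansion_migration
  labels: [AFR, EUR, ASI]
  sample_subpop: AFR
  epochs:
    - start_gen: 0
      end_gen: 4000
      sizes: [20000, 10000, 10000]
      migration:
        - [0.0,    0.00005, 0.00005]
        - [0.00005, 0.0,    0.00005]
        - [0.00005, 0.00005, 0.0]
    - start_gen: 4000
      end_gen: .inf
      sizes: [10000, 10000, 10000]
      migration:
        - [0.0,    0.00005, 0.00005]
        - [0.00005, 0.0,    0.00005]
        - [0.00005, 0.00005, 0.0]
  sweep_defaults:
    s: 0.022
    origin_gen: 354

bottleneck_migration:
  name: bottleneck_migration
  labels: [AFR, EUR, ASI]
  sample_subpop: EUR
  epochs:
    - start_gen: 0
      end_gen: 1520
      sizes: [10000, 10000, 10000]
      migration:
        - [0.0,    0.00005, 0.00005]
        - [0.00005, 0.0,    0.00005]
        - [0.00005, 0.00005, 0.0]
    - start_gen: 1520
      end_gen: 1920
      sizes: [10000, 1500, 10000]
      migration:
        - [0.0,    0.00005, 0.00005]
        - [0.00005, 0.0,    0.00005]
        - [0.00005, 0.00005, 0.0]
    - start_gen: 1920
      end_gen: .inf
      sizes: [10000, 10000, 10000]
      migration:
        - [0.0,    0.00005, 0.00005]
        - [0.00005, 0.0,    0.00005]
        - [0.00005, 0.00005, 0.0]
  sweep_defaults:
    s: 0.022
    origin_gen: 338
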