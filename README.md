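# lupineIPM

Seed-bank integral projection models (IPMs) for quantifying how soil
microbiota affect the population growth of the perennial legume *Lupinus
polyphyllus*. The package is aimed at plant population ecologists who want
to go from individual-level greenhouse records (size, survival, flowering,
shoot counts) and field fecundity samples to an asymptotic population
growth rate λ with bootstrap confidence intervals and a one-at-a-time
sensitivity analysis — comparing plants of invasive (Finnish) and native
(North American) origin grown with intact vs. autoclaved soil inoculum.

## The model

The population state is a density n(x, t) of plants over log size x plus a
discrete seed bank S(t). One projection interval advances

    S(t+1)   = s_sb (1 - e) S(t)
             + ∫ p(x) f1(x) seed (1 - e) n(x, t) dx

    n(y,t+1) = e_sb f_d(y) S(t)
             + ∫ [ s(x) g(y, x) + p(x) f1(x) seed e f_d(y) ] n(x, t) dx

with logistic survival s(x) and flowering p(x), Gaussian growth g(y, x),
linear flowering-shoot number f1(x) (clamped at 0), Normal recruit-size
distribution f_d, regional seeds-per-shoot constant `seed`, and literature
constants e = e_sb = 0.122 (establishment) and s_sb = 0.977 (seed survival
in the bank). The kernel is discretized by the midpoint rule into a 50 × 50
matrix whose first class is the seed bank; λ is the dominant eigenvalue
(power iteration, cross-checked against a full eigendecomposition).
See the methods vignette (`vignettes/seedbank-ipm.Rmd`) for assumptions,
defaults, and numerical choices.

The five stages are all exported R functions:

| stage | functions |
| --- | --- |
| synthetic data | `generator_spec()`, `simulate_greenhouse()`, `simulate_field_fecundity()` |
| vital rates | `fit_vital_rates()`, `estimate_seed_constant()`, `canonical_params()` |
| kernel | `ipm_config()`, `resolve_size_limits()`, `build_kernel()`, `check_eviction()` |
| demography | `compute_lambda()`, `bootstrap_lambda()`, `sensitivity_analysis()` |
| pipeline | `run_reproduction()`, `write_report_json()`, CLI at `inst/cli/ipm-pipeline.R` |

## Worked example

Build the four origin × treatment IPMs from the published vital-rate
estimates shipped with the package (`extdata/table2.yaml`):

```r
library(lupineIPM)
report <- run_reproduction(mode = "canonical")
report
#> Seed-bank IPM reproduction report (canonical mode)
#>   mesh 50, size limits [-0.2381, 6.9499]
#>       origin  treatment lambda
#>  invasive_FI     intact  8.611
#>  invasive_FI autoclaved  2.837
#>    native_US     intact  3.443
#>    native_US autoclaved  2.686
#>   lambda range: 2.686 - 8.611
#>   invasive_FI: intact vs autoclaved lambda increase 203.5%
#>   native_US: intact vs autoclaved lambda increase 28.2%
#>   eviction: none detected
#>   mesh stability (max |rel. change| 50 -> 100 -> 200): 1.57e-06, 3.94e-07
#>   widened-limit stability (max |rel. change|): 5.1e-05
```

Every λ exceeds 1 (populations growing over the ~1-year interval), the
intact inoculum raises λ for both origins — dramatically so for the
invasive-origin parameter set — no probability mass is evicted from the
size domain, and the eigenvalues are stable under mesh refinement and
widened size limits. A full fitted-mode run on a synthetic cohort, with
bootstrap confidence intervals:

```r
rec <- simulate_greenhouse(generator_spec(seed = 7))
bootstrap_lambda(rec, n_boot = 1000, rng_seed = 3)
#> Asymptotic growth rates (bootstrap, 1000 replicates, seed 3)
#>       origin  treatment lambda         95% CI
#>  invasive_FI     intact  7.221 [5.001, 9.315]
#>  invasive_FI autoclaved  3.805 [1.694, 5.627]
#>    native_US     intact  4.008 [3.010, 5.201]
#>    native_US autoclaved  1.772 [1.177, 2.955]
#>   (168 failed replicates redrawn)
```

(The redrawn replicates are resamples in which the sparsely-flowering
native-autoclaved cell loses one outcome class and the logistic refit is
separated; `?bootstrap_lambda` documents the redraw policy.)

Which parameters matter most:

```r
sensitivity_analysis(canonical_params("native_US", "autoclaved"))
#> Proportional sensitivities |dlambda|/lambda to a 1% reduction (lambda = 2.686)
#>     parameter sensitivity
#>   p_intercept     0.01596
#>       p_slope     0.01375
#>  f1_intercept     0.01151
#>      f1_slope     0.00760
#>       fd_mean     0.00430
#>          seed     0.00377
#>   g_intercept     0.00236
#>             e     0.00229
#>          e_sb     0.00122
#>          s_sb     0.00057
#>       g_slope     0.00039
#>       s_slope     0.00022
#>   s_intercept     0.00011
```

Sensitivity to the flowering components dwarfs sensitivity to survival:
with survival near-uniform, flowering is the demographic bottleneck.

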