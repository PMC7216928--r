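# dwssfp — effective b-values for diffusion-weighted SSFP

Diffusion-weighted steady-state free precession (DW-SSFP) delivers strong
diffusion contrast from short-T2 samples — most prominently fixed postmortem
brain — but its echo is a sum of coherence pathways, each with its own
diffusion time and gradient moment, so a DW-SSFP measurement has **no single
b-value**. In non-Gaussian (restricted) diffusion this makes the apparent
diffusion coefficient (ADC) depend on the flip angle, and bars direct
comparison with conventional diffusion-weighted spin-echo (DW-SE) results.

`dwssfp` implements the framework that resolves this: model non-Gaussian
diffusion as a gamma distribution of diffusivities with mean `Dm` and
standard deviation `Ds`, embed it in a DW-SSFP signal model, fit `(Dm, Ds)`
to ADC estimates acquired at multiple flip angles, and report each flip
angle's ADC at the **effective b-value** — the DW-SE b-value that would give
the same ADC under the shared distribution:

- DW-SE mixture signal: `S(b) = S0 (Dm / (Dm + b Ds^2))^(Dm^2/Ds^2)`
- DW-SE mixture ADC: `ADC(b) = (Dm^2 / (b Ds^2)) log(1 + b Ds^2 / Dm)`
- `b_eff(alpha)` solves `ADC(b) = ADC_SSFP(alpha)`

The package provides three DW-SSFP forward models (two-transverse-period
closed form; a full Buxton-type all-pathway closure; an exact
coherence-order solver), the inference chain, a vectorized Monte-Carlo
spin-walk simulator of both sequences for verification, and a synthetic
data generator with Rician noise and background subtraction.

## Worked example

```r
library(dwssfp)

protocol <- ssfp_protocol(flip_deg = seq(10, 170, 10), tr_ms = 28.2,
                          tau_ms = 13.56, q_per_cm = 300)
tis   <- tissue(t1_ms = 568, t2_ms = 19.8)
truth <- gamma_diffusivity(dm = 1.5e-4, ds = 2.1e-4)  # mm^2/s

tbl <- generate_multiflip_dataset(truth, protocol, tis)
res <- run_translation_pipeline(tbl, protocol, tis, model = "buxton")
glance(res)
#> # A tibble: 1 × 6
#>         dm       ds b_eff_min b_eff_max n_flips model
#>      <dbl>    <dbl>     <dbl>     <dbl>   <int> <chr>
#> 1 0.000150 0.000210      24.0      809.      17 buxton
tidy(res)
#> # A tibble: 17 × 4
#>   flip_deg attenuation      adc b_eff
#>      <dbl>       <dbl>    <dbl> <dbl>
#> 1       10       0.944 0.000135  809.
#> 2       20       0.966 0.000141  439.
#> 3       30       0.978 0.000145  258.
#> # ...
```

The fitted distribution reproduces the generating `Dm = 1.50e-4`,
`Ds = 2.10e-4` mm²/s exactly on noise-free data. The per-flip table shows
the core physics: the ADC *rises* with flip angle (0.000135 → 0.000150
mm²/s from 10° to 170°) because higher flip angles weight short-diffusion-
time pathways, and the effective b-value correspondingly *falls* (809 → 24
s/mm²). `autoplot(res)` overlays these points on the analytic DW-SE ADC(b)
curve; `autoplot(res$fit)` shows the ADC-versus-flip fit.

A thin command-line wrapper is installed at
`system.file("cli", "dwssfp", package = "dwssfp")` with subcommands
`simulate-signal`, `simulate-mc`, `fit-adc`, `run-pipeline` and
`generate-fixtures` operating on YAML configs and CSV tables.

## Scope

1-D spin physics along the diffusion gradient, single diffusion direction,
table-in/table-out. Voxelwise NIfTI processing, B1/T1/T2 mapping and
acquisition-side corrections (Gibbs ringing, coregistration) are out of
scope. See the methods vignette (`vignettes/effective-bvalue-methods.Rmd`)
for the models, assumptions, numerical choices and limitations.
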