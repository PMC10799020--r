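# patchfrap

Quantitative analysis of membrane-receptor complex formation by patch/FRAP.

In fluorescence recovery after photobleaching (FRAP), a focused Gaussian
laser spot bleaches the fluorophores labelling a membrane receptor and the
refill of fluorescence by unbleached molecules reports its lateral mobility:
a diffusion coefficient *D* (µm²/s) and a mobile fraction *R*<sub>f</sub>.
In the patch/FRAP variant, a co-expressed partner receptor is clustered and
immobilized with bivalent IgG ("patching") while the receptor of interest,
labelled only with monovalent Fab', is measured by FRAP. Receptors in
long-lived complexes with the immobilized partner are dragged out of the
mobile pool — *R*<sub>f</sub> drops with no change in *D* — whereas
short-lived complexes slow the receptor down, reducing *D* with no change in
*R*<sub>f</sub>. The fraction of receptors in stable complexes follows from
the relative reduction of the mobile fraction:

```
C = 100 · (R_f,free − R_f,crosslinked) / R_f,free   [%]
```

The package implements the full quantitative chain for this assay:

- **Forward model** — closed-form recovery after Gaussian-spot bleaching of
  a laterally diffusing species with an immobile subpopulation:
  `f(t) = Σ_n (−K)ⁿ/n! · [1 + n(1 + 2t/τ_D)]⁻¹` with bleach parameter `K`,
  characteristic time `τ_D = w²/(4D)`, and spot e⁻² radius `w`
  (`frap_recovery_fraction()`, `frap_model_curve()`).
- **Synthetic data** — noisy recovery curves and multi-condition cohorts
  with realistic between-cell variability (`simulate_frap_curve()`,
  `simulate_frap_cohort()`), plus a reaction–diffusion Monte Carlo
  simulator of receptors exchanging between free diffusion and binding to
  immobile crosslinked patches (`simulate_binding_frap()`), which
  reproduces both patch/FRAP regimes from first principles.
- **Fitting** — bounded nonlinear least squares extracting (R_f, D) per
  curve, with half-time initialization, bleach-depth estimation of `K`, and
  the standard quality-control rule that curves recovering less than 20%
  support only R_f (`fit_frap()`, `fit_frap_cohort()`).
- **Inference** — condition-wise group statistics (one-way ANOVA with
  Bonferroni post-hoc contrasts, Student's t test, mean ± SEM), the
  complex-fraction statistic, and the stable/transient/mixed/none
  interaction call (`compare_groups()`, `complex_fraction()`,
  `classify_interaction()`, `ligand_effect()`).

Everything is tidyverse-native: curves and per-cell results are tibbles,
fitted objects have `tidy()`/`glance()` methods, and result types have
`autoplot()` methods.

## Worked example

```r
library(patchfrap)

# acquisition: 0.77 um spot, ~68% bleach, 2 min of recovery sampling
beam <- beam_protocol(w = 0.77, K = 3, t_grid = seq(0.4, 120, by = 0.4))

# two-arm patch/FRAP cohort: partner free vs IgG-crosslinked, 30 cells each
design <- tibble::tibble(
  condition   = c("free", "crosslinked"),
  crosslinked = c(FALSE, TRUE),
  D = 0.025, R_f = c(0.64, 0.39), n_cells = 30
)
cohort <- simulate_frap_cohort(design, beam, seed = 1)
fits   <- fit_frap_cohort(cohort, w = 0.77)

classify_interaction(fits[fits$condition == "free", ],
                     fits[fits$condition == "crosslinked", ])
#> <interaction_call> stable, complex fraction 38%
#>   R_f contrast: p = 6.52e-17 (****);  D contrast: p = 0.608 (ns)
```

The call reads: crosslinking the partner significantly lowered the mobile
fraction while leaving D untouched, the signature of stable complexes; the
relative R_f reduction puts ~38% of the labelled receptor in complexes with
its immobilized partner. `complex_fraction(64, 39)` gives the same statistic
directly from group means: `39.06` percent.

A command-line front end wraps the pipeline for shell use:

```sh
Rscript inst/cli/frap.R simulate --config inst/extdata/demo_config.yaml --seed 1 --out runs/
Rscript inst/cli/frap.R fit --curves runs/curves.csv --w 0.77 --out runs/results.csv
Rscript inst/cli/frap.R infer --results runs/results.csv \
    --contrasts inst/extdata/demo_contrasts.yaml --out runs/report/
```

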