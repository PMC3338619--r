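# cspkd — chemical shift perturbation titration analysis and K_D estimation

`cspkd` turns assigned ¹H–¹⁵N HSQC peak lists from a protein–ligand
titration into the quantities an NMR binding study reports: per-residue
chemical shift perturbations (CSP) and intensity ratios, data-driven
significance thresholds, exchange-regime classification (fast /
intermediate / slow), per-residue dissociation constants from the
single-site quadratic isotherm with an exclusion-aware average, and a
binding surface mapped onto a PDB structure through solvent-accessibility
and contiguity criteria. It also fits K_D from native mass spectrometry
bound-fraction titrations with bootstrap confidence intervals. The
package was built around the analysis of human PEBP1/RKIP titrated with
nucleotides (GTP, FMN) and Raf-1 peptides, and ships a synthetic-data
generator that emulates all three exchange regimes so the entire pipeline
is testable without spectrometer data.

It is written for NMR spectroscopists and structural biologists who have
peak lists (CSV or Sparky `.list`) and want a reproducible, scriptable
route from titration points to a defensible K_D and binding surface.

## The model

All affinity estimation rests on the exact bound fraction of a 1:1
equilibrium at total concentrations — no excess-ligand approximation:

    f_b = [(P0 + L + K_D) − sqrt((P0 + L + K_D)² − 4·P0·L)] / (2·P0)

Fast-exchange CSP data follow `CSP(L) = CSP_max · f_b(L)` (fit per
residue over K_D and CSP_max, then averaged with exclusion rules);
native-MS bound fractions follow `f_b` directly. Perturbation
significance uses the iterative ⟨CSP⟩ + 2σ procedure: trim values above
mean + 2σ, recompute, repeat to convergence; the converged bound is the
threshold (mean − 2σ with lower-side trimming for intensity ratios).
Combined shifts use `sqrt(ΔδH² + (0.2·ΔδN)²)`.

## Worked example

A noisy synthetic nucleotide titration (truth: K_D = 669 µM, protein
270 µM, ligand 0–4000 µM, shift noise 0.002 ppm, intensity noise 3%):

```r
library(cspkd)
cfg    <- nucleotide_scenario(true_kd = 669, seed = 1,
                              noise_ppm = 0.002, noise_intensity = 0.03)
series <- gen_titration(cfg)
ct     <- csp_titration(series)
ct
#> CSP titration analysis: 30 residues over 6 points ([P]0 = 270 uM)
#>   CSP threshold <CSP>+2s = 0.0033 ppm (7 iterations)
#>   I/I0 threshold <I/I0>-2s = 0.939 (2 iterations)
#>   exchange: fast 11, intermediate 0, slow 1, unperturbed 18

aggregate_kd(fit_kd(ct))
#> Average K_D = 677.6 +/- 26.53 uM from 5 residues (6 excluded: 11 outlier_kd,
#> 19 poor_fit, 20 poor_fit, 21 poor_fit, 24 poor_fit, 30 poor_fit)
```

Reading the output: the iterative threshold settles at 0.0033 ppm —
tight, because the unperturbed background is quiet at this noise level —
so besides the 6 designed binders a handful of noise-grazed background
residues cross it. Those carry no real isotherm, fail the R² ≥ 0.9
filter and are excluded as `poor_fit`; one borderline binder falls to
the median ± 3·MAD outlier rule. The surviving residues average to
677.6 ± 26.5 µM against a generator truth of 669 µM.

The native-MS side, with 2% bound-fraction noise on a 45 µM truth:

```r
ms <- gen_ms_titration(true_kd = 45, P0 = 18,
                       ligand_series = c(0, 5, 10, 25, 50, 100, 200, 300),
                       noise = 0.02, seed = 2)
fit_ms_kd(ms, P0 = 18, n_boot = 500, seed = 3)
#> Native-MS K_D fit: K_D = 44.74 uM (95% CI 41.16-47.56, 500 resamples)
```

Structure mapping takes any single-chain PDB
(`read_structure()` → `compute_sasa()` → `map_binding_surface(ct, sm)`)
and writes a per-residue annotation TSV (residue, label, patch id)
ready for coloring in a molecular viewer. `run_pipeline()` drives all
stages from one YAML config and logs every default it applies;
`inst/scripts/cspkd.R` wraps it for the shell
(`simulate | csp | fit | map | ms-fit | run`).

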