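---
title: "CSP titration analysis: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSP titration analysis: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspkd)
```

## The problem

When a ligand binds a protein, the backbone amide cross-peaks of a
¹H–¹⁵N HSQC spectrum move and/or lose intensity for the residues near the
binding site. Titrating the ligand and following every assigned cross-peak
therefore yields, residue by residue, (i) whether the residue senses the
ligand, (ii) on what NMR time scale the complex exchanges, and (iii) for
fast-exchanging residues, the dissociation constant $K_D$. Projected onto
a structure, the significantly perturbed residues delineate the binding
surface. `cspkd` implements this chain of analysis for assigned peak
lists, plus the analogous single-parameter $K_D$ fit for native-MS bound
fractions, for a synthetic-data generator so the chain is testable end to
end, and for idealized structure fixtures. The reference application is
the human PEBP1/RKIP system (187 residues, conserved ligand-binding
pocket of 16 residues, 3 of them HSQC-invisible prolines) titrated with
nucleotides (GTP, FMN) and Raf-1-derived peptides.

## Models

**Combined chemical shift perturbation.** Peak displacement is combined
across dimensions on the proton ppm scale,

$$\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2},$$

with nitrogen weight $\alpha = 0.2$ by default. This is the conventional
weighting for backbone amides (¹⁵N spans roughly five times the ppm range
of ¹H); $\alpha$ is a configuration key rather than a constant because
laboratories differ in the exact weight they use.

**Significance thresholds.** Most residues in a titration are not
perturbed, so the unperturbed population can define its own noise floor.
Starting from all per-residue values (final CSPs, or final intensity
ratios $I/I_0$), the mean and standard deviation of the retained set are
computed and values beyond mean $+2\sigma$ (CSP, upper direction) or
below mean $-2\sigma$ (intensity ratios, lower direction) are removed;
the statistics are recomputed and the trimming repeated until nothing
moves. The converged mean $\pm 2\sigma$ of the unperturbed residues is
the significance threshold and everything removed along the way is
significant. Numerical choices here, made once and documented because
they are not forced by the procedure itself:

* *sample* standard deviation ($n-1$), appropriate for the few dozen
  residues involved;
* *strict* inequality for removal, which makes an all-equal input a
  clean fixed point and guarantees termination in at most $n$ passes;
* *all* supra-threshold values are removed per pass, not one at a time;
  the unit tests pin this semantics against a brute-force oracle that
  enumerates prefixes of the descending-sorted values and checks the
  fixed-point condition.

One property worth recording: a removal requires a standardized
deviation above 2, which no set of five or fewer values can produce
(the maximum of $(x_i-\bar x)/s$ over $n$ values is $(n-1)/\sqrt{n}$,
below 2 for $n \le 5$). Trimming therefore always terminates with at
least five retained values whenever it starts with six or more, and the
defensive stop-with-warning branch for an over-trimmed set is
unreachable in practice; it is kept as a guard and documented here
rather than exercised by tests.

**Exchange regimes.** The classification uses the final titration point
against both thresholds:

| final CSP vs threshold | final $I/I_0$ vs threshold | class |
|---|---|---|
| above | retained | fast |
| above | below (broadened) | intermediate |
| within | below, or peak disappeared | slow |
| within | retained | unperturbed |

This is a deliberate simplification of lineshape analysis: a full
treatment would fit exchange broadening (Bloch–McConnell), which is out
of scope. Disappearance of the free-state peak is treated as the
slow-exchange signature; absent peaks get intensity ratio 0 and their
CSP is never imputed. When a peak list carries no intensities the
classification honestly degrades to {fast, unperturbed} with a warning
instead of inventing ratios.

**Binding isotherm.** All affinity estimation rests on one kernel, the
exact bound fraction of the 1:1 equilibrium at total concentrations
$[P]_0$ and $[L]$:

$$f_b = \frac{([P]_0+[L]+K_D) - \sqrt{([P]_0+[L]+K_D)^2 - 4[P]_0[L]}}{2[P]_0}.$$

No excess-ligand approximation is made, because protein-observed NMR
titrations routinely run at ligand:protein ratios near 1. Fast-exchange
CSP data follow $\mathrm{CSP}(L) = \mathrm{CSP}_{max} \cdot f_b$; native-MS
bound fractions follow $f_b$ directly. The kernel's limits (stoichiometric
$K_D \to 0$, hyperbolic $[P]_0 \to 0$) and its monotonicity are tested
explicitly, and $[P]_0 = 0$ is an error directing the user to the
hyperbolic form rather than silently dividing by zero.

**Per-residue fits and aggregation.** Each fast-exchange residue is fit
independently over $(K_D, \mathrm{CSP}_{max})$ — $\mathrm{CSP}_{max}$
floats per residue; nothing is shared — by least squares on the log
scale of both parameters (positivity is structural). Plain
Levenberg–Marquardt is ill-conditioned near the stoichiometric corner
(tight binding, $K_D \ll [P]_0$), so a Nelder–Mead search on log
parameters does the work and an LM pass merely polishes the optimum when
it can improve it. Starting values come from the data: $K_{D,0}$ is the
ligand concentration at half the final CSP, $\mathrm{CSP}_{max,0} = 1.2
\times$ the final CSP. Non-convergence yields a `poor_fit` flag, not an
exception.

The aggregate $K_D$ is the mean over surviving residues with exclusions
applied in a fixed order: poor fits ($R^2 < 0.9$ by default), residues
discriminated as buried or isolated when a structure mapping is
available, then $K_D$ outliers outside median $\pm 3$ scaled MAD,
iterated to stability. The MAD rule operationalizes "very different
$K_D$ values" — no numeric criterion exists in the underlying
methodology, so a robust standard one was chosen. The MAD is floored at
$10^{-6}$ of the median so that numerically identical estimates (e.g.
noiseless round-trips) are never declared mutual outliers. Slow-exchange
residues are never fit: peak intensities are not measured accurately
enough for that to be meaningful, so an FMN-like titration dominated by
slow exchange estimates its $K_D$ from the fast-exchange minority and
the result is knowingly an underestimate.

**Native-MS fit.** One parameter ($K_D$) by golden-section least squares
on the kernel, with a percentile bootstrap (default 1000 resamples,
seeded from configuration) over titration points for the confidence
interval. A fit whose data do not span bound fractions below 0.2 and
above 0.6 is returned but flagged low-confidence.

## Structure mapping

Burial and contiguity are computed, not read from annotations:

* **SASA** by Shrake–Rupley with probe 1.4 Å and a deterministic
  golden-spiral mesh of 240 points per heavy atom (doubling the mesh
  moves the total and the typical exposed residue by well under 2%;
  near-buried residues have tiny areas where relative error is
  meaningless, and burial calls are mesh-stable). Relative exposure
  normalizes by Gly-X-Gly maximal areas, so extended residues can
  slightly exceed 1.
* **buried**: relative SASA < 0.15; **isolated**: exposed but no other
  significant exposed residue within 8 Å (Cβ distance, Cα for glycine).
  Both thresholds are configuration keys reported in every output
  header, because the criteria they implement ("located at the surface",
  "define a contiguous patch") are stated qualitatively in the
  methodology they come from.
* **patches**: connected components of the 8 Å contact graph over the
  remaining candidates; components smaller than `min_patch_size = 6` are
  reported but rejected. The default of 6 is an inference from the
  reference analysis, which rejected patches of 4 and 5 residues and
  accepted one of 19; it is configurable for other systems.

Residue numbering follows the input PDB's author numbering. A proline
marked significant is warned about (no amide proton, so it cannot appear
in an HSQC) rather than silently accepted.

## The synthetic generator

The generator emulates exactly the observables the analysis consumes:

* fast exchange — one peak at the population-weighted position
  $\delta_{free} + f_b\,\Delta\delta_{max}$;
* slow exchange — a fading free-state peak ($I_0(1-f_b)$, fixed
  position) and a growing bound-state peak at
  $\delta_{free}+\Delta\delta_{max}$, tagged so the reader can track
  both; peaks under a detection limit (default 5% of $I_0$) disappear,
  reproducing the disappearance signature;
* intermediate exchange — population-weighted position with intensity
  $I_0\,(1 - 4\beta f_b(1-f_b))$, maximally attenuated at half
  saturation. This is a phenomenological stand-in chosen for its shape,
  not derived from exchange dynamics;
* Gaussian position noise (the ¹⁵N dimension receives 5× the ¹H ppm
  sigma so both dimensions contribute comparably after the 0.2
  weighting) and multiplicative Gaussian intensity noise, applied after
  the ideal values; everything is deterministic given the seed.

Default study conditions mirror the reference titration design: protein
at 270 µM with the six-point ligand series 0 / 270 / 540 / 1000 / 2000 /
4000 µM (100 µM protein with ligand up to 6.4 mM for the
near-physiological condition, on a doubling grid), MS titrations at
18 µM protein with eight ligand points up to 320 µM.

The structure fixture is an idealized lattice fold: a snake path through
a cubic lattice (5 Å spacing, five heavy atoms per residue, small seeded
jitter), whose strict interior is a designed buried core and whose top
face is a designed contiguous exposed cluster. The 5 Å spacing was
chosen so both designs hold with margin under the 0.15 burial threshold
(interior ≤ 0.05 relative SASA, top face ≥ 0.24) for any seed. It is a
geometry fixture, not a protein model: side-chain packing, secondary
structure and chemical realism are absent, so structure-stage tests
demonstrate the discrimination logic, not PDB robustness beyond parsing.

What passing synthetic tests do **not** show about real data: peak
overlap and misassignment, titration drift and dilution, non-Gaussian
intensity errors, multi-site or cooperative binding, and exchange
broadening beyond the phenomenological model above. The analysis assumes
constant $[P]_0$ across the titration (dilution correction is explicitly
out of scope) and exactly one reference point at $[L]=0$.

## Problem sizes and reproducibility

The test suite runs scenarios of 30–70 residues over 6–7 titration
points, structure fixtures of 27–64 residues, stochastic recovery
studies of 50 seeds (median $K_D$ error under the stated noise models:
within 15% for the CSP fitter at $\sigma = 0.003$ ppm, within 20% for
the MS fitter at $\sigma_{f_b} = 0.03$), and oracle comparisons on
random value sets of up to 10 elements — sizes at which every check is
exact or statistically stable while the whole suite stays fast. The
acceptance script (`scripts/acceptance.R`) re-derives all reported
binding constants by noiseless generator round-trips and all residue
accounting by running the discrimination and patch machinery over the
published residue sets; deterministic quantities are reproduced to
numerical precision for any seed.

## A worked example

```{r example}
cfg <- nucleotide_scenario(true_kd = 669, seed = 1,
                           noise_ppm = 0.002, noise_intensity = 0.03)
series <- gen_titration(cfg)
ct <- csp_titration(series)
ct

agg <- aggregate_kd(fit_kd(ct))
agg
```

```{r ms}
ms <- gen_ms_titration(true_kd = 45, P0 = 18,
                       ligand_series = c(0, 5, 10, 25, 50, 100, 200, 300),
                       noise = 0.02, seed = 2)
fit_ms_kd(ms, P0 = 18, n_boot = 500, seed = 3)
```

## Known limitations

* Exchange-rate estimation ($k_{ex}$), lineshape fitting and trajectory
  curvature analysis for multi-site binding are out of scope.
* The intermediate/slow boundary rests on intensity thresholds alone;
  linewidths are not used.
* The aggregate-$K_D$ exclusion taxonomy covers the observed cases
  (poor fit, buried, isolated, low intensity, $K_D$ outlier); other
  pathologies surface as one of these or not at all.
* MS bound fractions are taken as input; response-factor calibration and
  raw-spectrum deconvolution belong to the upstream acquisition method.
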