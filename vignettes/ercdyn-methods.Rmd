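---
title: "Quantifying DNA-circle retention, NPC inheritance and replicative ageing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA-circle retention, NPC inheritance and replicative ageing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ercdyn)
```

## Background

Non-centromeric DNA circles — excised rDNA circles (ERCs) and
centromere-less plasmids — replicate in S-phase but lack the machinery
that partitions chromosomes. In budding yeast they are confined to the
mother cell at mitosis with high fidelity, accumulate there over
successive divisions, and shorten the mother's replicative lifespan.
Their confinement is coupled to nuclear pore complexes (NPCs): circles
anchored to pores cluster them into a cap, and the circle-bound pores
are co-retained in the mother, so ageing nuclei grow and accumulate
pores.

`ercdyn` implements the quantitative machinery used to study this
process: the propagation-frequency estimator for telophase segregation
assays, pedigree and half-sectored-colony retention statistics,
FLIP/FRAP photobleaching kinetics, nucleus-image and rim-profile
quantification, particle-track speeds, age-trend fits, and a stochastic
mother-cell simulator. Since the underlying microscopy data are not
redistributable, every input is emulated by a seeded synthetic-data
generator whose defaults are the published point estimates; all
headline statistics are recovered from those synthetic cohorts at the
published cohort sizes.

## The propagation-frequency (pf) estimator

Telophase cells carrying $m \in \{1, 2, 4\}$ labelled plasmids are
scored for whether *all* plasmids stayed in the mother. With $x, y, z$
cells per category and retaining percentages $a, b, c$, each category
estimates the per-plasmid retention $r$ through $r^m = (\text{pct})/100$
under independent segregation. The default (`consistent`) variant
converts each category back to the percent scale before the weighted
average,

$$\mathrm{pf} = 100 - \frac{x \, R_1 + 2y \, R_2 + 4z \, R_4}
                           {x + 2y + 4z},
\qquad R_m = 100 \left(\frac{\text{pct}_m}{100}\right)^{1/m},$$

which makes pf a consistent estimate of $100\,p$ when each plasmid
propagates independently with probability $p$. The assay's formula as
printed takes $\sqrt{b}$ and $\sqrt[4]{c}$ on the raw 0–100 scale;
those roots live on 0–10 and 0–3.2 scales, so the literal formula
reports spurious propagation whenever multi-plasmid cells are scored
(at $b = c = 100$ its root terms are 10 and 3.16, not 100). Both
readings are exposed (`variant = "consistent"` / `"as_printed"`); only
the consistent one reaches the published wild-type value, so it is the
default. The Jensen bias of the root transforms at small counts is
documented here rather than corrected: no correction is part of the
assay.

```{r pf}
counts <- gen_segregation_counts(preset("segregation", "wt"), 20000)
compute_pf(counts)
```

## Synthetic-data generators

Each generator is deterministic given `(preset, seed)`: randomness
comes from one seeded stream per call, sub-seeds for cohorts are
derived by stable hashing (`derive_seed`), and the caller's RNG state
is never touched. The shipped presets (see
`inst/extdata/presets.yaml`) carry the published genotype estimates —
propagation probabilities (wild type 0.039, SAGA/TREX-2 mutants
0.097–0.118), cap intensity ratios (2.02 wild type, 2.29 for the
barrier mutant), enrichment amplitudes (+33.2 %, +4.6 %, −2.0 %), decay
and recovery rates, step SDs, and retention fidelities.

Choices the data do not pin down, made once:

* **Camera noise.** Poisson shot noise scaled by a gain, then additive
  Gaussian read noise (SD 2 counts). Nothing about camera statistics is
  published; this is the generic CCD model.
* **Per-cell variability.** Cap ratio and photon budget vary
  lognormally with CV 0.25, a typical cell-to-cell spread for
  fluorescence ratios. The published ±0.80 on the cap intensity is the
  full observed spread including measurement error, not a generator
  parameter.
* **Division-record spread.** The mother's share of pore fluorescence
  is logit-normal around the published medians (78 % loaded, 63 %
  unloaded) with logit SD 0.25 (percent scale SD ≈ 4–6 points), chosen
  so the median of a 50-cell cohort — the published readout — is stable
  to about one point.
* **Rim geometry.** The rim is an annulus of radius 1 µm with a
  radial Gaussian profile (SD 0.25 µm ≈ optical PSF, truncated at 3
  SD). The blur is applied along the radius only: the angular edges of
  the NPC cap stay sharp, so sector mean intensities of a noiseless
  image recover the generating cap ratio exactly, which is the
  contract the quantifier tests rely on. A full 2-D blur would smear
  the cap edge and bias the sector mean low by a few percent.
* **Enrichment bump.** The green-channel enrichment around the plasmid
  is a truncated Gaussian confined to the ±130 nm co-localization
  window, scaled so the window-mean uplift equals the preset amplitude.
  A noiseless profile therefore returns exactly `100 * amplitude`
  percent from `align_and_average_profiles()`, giving an analytic
  oracle for the alignment pipeline.
* **Track statistics.** 3-D steps are isotropic Gaussian (per-axis SD
  σ per 3 s frame), so step lengths follow a chi distribution with 3
  degrees of freedom and mean $\sigma\sqrt{2}\,\Gamma(2)/\Gamma(3/2)
  \approx 1.596\,\sigma$; preset σ values invert the published speeds
  through this closed form. Reflection at the 1 µm confinement sphere
  shortens recorded displacements by a few percent, so realized cohort
  speeds sit slightly below the unconfined closed form — well inside
  the published SDs.

What the generators deliberately do **not** emulate: real microscope
PSFs and 3-D stacks, segmentation of real micrographs (ROIs and
centres come from ground truth or annotation files), spectral
cross-talk, and focal drift. Passing the recovery tests therefore
shows the *analysis* is correct and unbiased under the stated
statistical model — not that the model captures every property of real
micrographs.

## Photobleaching kinetics

FLIP traces are corrected for acquisition loss by subtracting the mean
fluorescence lost by neighboring unbleached cells frame by frame, then
normalized to 100 % at the last pre-bleach point; FRAP recoveries are
shifted to 0 at the first post-bleach point. The decay model is the
one-phase curve $I(t) = \text{plateau} + (I_0 - \text{plateau})
e^{-kt}$ with $I_0$ fixed by the normalization, fitted by
Levenberg–Marquardt least squares (rate initialized from a log-linear
regression of the first half of the trace, plateau from the last three
points, tolerances $10^{-14}$, up to 1024 iterations).
Time-to-fraction statistics come from the fitted curve, $t_q =
\ln(A/(qI_0 - \text{plateau}))/k$, which reduces to $\ln(1/q)/k$ for a
vanishing plateau; levels at or below the plateau are flagged
unreachable (`Inf`), never extrapolated. A perfectly flat trace (fully
immobile pool) is a degenerate fit with `k = NA`.

One identifiability limit is worth knowing: on the assay's 9 s ×
30-point grid with noise of SD 2 A.U., the *median* relative error of
the fitted rate across random (k, plateau) pairs is below 5 %, but
individual fits with a slow rate and a large free plateau can miss k
by 20 % or more — the plateau and the tail trade off. Published
kinetics average over ≥ 20 cells, which is also what the simulated
cohorts do.

The **barrier index** is the ratio of times needed to lose 40 % of the
initial signal in the bud over the mother compartment during
mother-side FLIP, so a stronger bud-neck diffusion barrier gives a
larger index and free exchange gives 1. The assay is sometimes
described the other way round (mother over bud); this package uses the
bud-over-mother convention because it keeps the sign of the effect
(barrier ⇒ index > 1), with the lost fraction `q_lost` exposed as a
parameter.

```{r kinetics}
flip <- gen_flip_series(preset("flip", "circle_adjacent"), noiseless = TRUE)
fit_exponential_decay(flip$a)
```

## Nucleus-image quantification

Pixels are 0-based with centres at integer positions; ROIs are
half-open pixel sets. `integrated_fluorescence()` is the
background-subtracted integrated density (negative results are
reported, never clipped); on a noiseless synthetic image it equals the
generator's photon bookkeeping to numerical precision.  `cap_ratio()`
measures mean rim intensity in the sector adjacent to the circles
(`Ic`), the residual rim (`Ir`) and the opposite sector (`Io`), then
normalizes by the *cohort* median of `Ir` — whether that median should
be per-experiment or global is not specified anywhere, so per-cohort
is used and recorded. `extract_rim_trace()` samples the rim circle
bilinearly at ≤ half-pixel arc steps, subtracts background and applies
the channel normalizations (green by its mean, red by its maximum).
`align_and_average_profiles()` shifts each profile circularly so the
red peak sits at the origin and reports
$100\,(\bar g_{\text{in}}/\bar g_{\text{out}} - 1)$ with the window
interpreted as 130 nm *on each side* of the peak ("130 nm around the
plasmid" is ambiguous; the half-width is a parameter), and the
baseline taken outside the window (a whole-trace baseline is
selectable and gives slightly smaller values). A "clearly resolvable
distance" from the envelope has no standard definition; the default
threshold is 0.25 µm ≈ the optical resolution, exposed as a
parameter.

## The ageing simulator

The update rule per division is the minimal model consistent with
circles that duplicate every S-phase and are retained per copy:

1. senescence check: the mother dies before budding once she holds
   `T_death` (default 64) or more circles;
2. every circle duplicates; each of the two copies stays in the mother
   independently with probability `rho` (retention fidelity,
   `1 - pf/100`);
3. a new circle forms with probability `f_form` per division;
4. the pore pool grows by `npc_growth` and splits with mother share
   $s_0 + \min(\kappa C, b_{\max})(\phi - s_0)$: a saturating fraction
   of pores is circle-bound and retained with fidelity $\phi = 0.99$,
   the rest with the baseline asymmetry $s_0 = 0.63$. With
   $b_{\max} = (0.78 - 0.63)/(0.99 - 0.63)$ the loaded share saturates
   at the published 78 %.

Expected counts follow $E[C_{g+1}] = 2\rho E[C_g] + f_{\text{form}}$
while the mother lives. Death at the threshold is the simplest
senescence proxy; with perfect retention and a single founding circle
it gives death exactly $\lceil \log_2 T \rceil$ divisions after the
first circle, a useful arithmetic oracle. Daughters are not followed
recursively (the assay that the simulator mirrors traps mothers and
washes daughters away). Whether circle formation accelerates with age
is an open question in the source material; the default keeps
`f_form` age-independent since no functional form is published.

Because the circle count grows roughly like $(2\rho)^g$ once seeded,
lifespan depends only *logarithmically* on the retention fidelity: the
waiting time for the first persistent circle (geometric in `f_form`)
dominates the variance. Parameter scans therefore use common random
numbers — each mother's formation sequence is drawn up-front from a
mother-specific substream, identical across grid points — which makes
the fidelity ordering readable from 200-mother cohorts. The
published genotype contrast (wild type vs. SAGA- or barrier-mutant
fidelities) reproduces as an ordering: lower fidelity ⇒ slower
accumulation ⇒ longer median lifespan, and `calibrate_to_wt()`
bisects `f_form` (deterministically, fixed seed policy) until the
simulated median matches the published wild-type 27 generations.

A known limitation: in this threshold model the NPC mother share stays
near $s_0$ until circles seed and then rises over the final
$\sim\log_2 T$ divisions, so the *population* share-versus-age profile
rises more slowly than the per-mother trajectories do; the published
age trends (56→78 % over 35 generations) are matched in ordering and
endpoints, not in detailed shape.

```{r ageing}
cal <- calibrate_to_wt(27, pf = 3.9, seed = 1, n_mothers = 200)
cal$achieved_median
scan <- retention_sensitivity_scan(cal$preset, c(0.88, 0.92, 0.96, 1.0),
                                   n_mothers = 100, seed = 1)
scan$table
```

## Statistics

Group comparisons use one-way ANOVA with Dunnett's multiple comparison
against a designated control (via `multcomp`) or an unpaired two-sided
Welch t-test; all-constant groups are flagged degenerate and no
p-value is fabricated. Lifespans are compared with the log-rank
(Mantel–Cox) test via `survival::survdiff`; simulated cohorts are
uncensored except for the `max_gen` horizon. Survival medians use the
lower median on ties (the survival-curve crossing of 0.5).

## Problem sizes and reproducibility

The recovery checks run at the published cohort sizes — 20,000
telophase cells for pf (the printed assays pooled ≥ 3 clones of 50–100
cells; 20,000 pins the estimator's sampling error well inside the
printed SDs), 50 nuclei/divisions/profiles/tracks per cohort, 200-mother
cohorts per scan point, 400 per calibration evaluation. One full run of
`scripts/acceptance.R` recomputes every headline number from scratch in
well under a minute of simulation per target. All stochastic stages
take sub-seeds derived from one global seed by hashing the stage name,
so results are reproducible regardless of stage order, and reruns of
`run_pipeline()` with the same configuration are byte-identical.
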