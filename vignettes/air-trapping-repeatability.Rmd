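---
title: "Methods: synthetic cohorts and repeatability statistics for CT air trapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts and repeatability statistics for CT air trapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airtrapr)
```

## The scientific question

Small airways disease in heavy smokers shows up on imaging as *air trapping*:
lung regions that fail to empty at expiration and therefore stay abnormally
gas-rich (low attenuation) on the expiratory CT. Two voxel-level scores are in
common use:

* **EXP~-856~** — the percentage of lung voxels on the expiratory scan with
  attenuation strictly below −856 HU;
* **E/I-ratio~MLD~** — 100 × (expiratory mean lung density) / (inspiratory
  mean lung density).

Whether such scores can track disease over time depends on how much they vary
between repeat examinations when the disease itself is stable. `airtrapr`
implements the full repeatability analysis — paired differences, Bland–Altman
limits of agreement (LoA), Lin's concordance correlation, a statistical lung
volume correction, breath-hold reproducibility subgrouping, and two
dispersion tests — driven by a synthetic paired-CT cohort generator with
known ground truth, since no public repeat-CT cohort with these measures
exists.

## The synthetic cohort generator

### Subject model

Each subject is described by five latent quantities:

| quantity | meaning | default law |
|---|---|---|
| $V_{insp}$ | true inspiratory lung volume (L) | Normal(6.0, 0.5) |
| $r_0$ | normal-tissue emptying factor | Normal(0.45, 0.08), truncated to (0.05, 0.95) |
| $f$ | trapped fraction of inspiratory volume | Beta(1.2, 4.5) |
| $\mu$ | inspiratory lung attenuation (HU) | Normal(−880, 10) |
| visit-2 factors | breath-hold variability | log-normal, see below |

The expiratory-to-inspiratory volume ratio is *constructed* as
$r = f + (1-f)\,r_0$: the trapped compartment cannot empty, so subjects with
more trapping exhale less. This guarantees the feasibility constraint
$r > f$ by design rather than by rejection, and couples trapping to
exhaled volume the way obstructive physiology does.

The trapped compartment is a disease property and is held fixed across the
two visits (stable over a follow-up of weeks): it occupies the fraction $f$
of the *reference* inspiratory volume and retains the reference inspiratory
attenuation $\mu$. Volume closure then gives the shrink factor of normally
emptying tissue, $k = (r-f)/(1-f)$, and the trapped share of the expiratory
volume, $f_{exp} = f/r$ (`trapped_share_expiratory()`).

Attenuation follows the sponge model (`sponge_hu()`): tissue mass per region
is conserved, so a region whose volume scales by $k$ moves from $HU$ to
$-1000 + (1000+HU)/k$. Normally emptying tissue at expiration therefore sits
at `sponge_hu(mu, k)`; the expiratory scan is a function of the expiratory
volume alone, which is what makes EXP~-856~ sensitive to expiratory effort
but not to inspiratory depth. The inspiratory scan tracks the realized
breath depth through the same formula.

Between-visit variability is multiplicative and log-normal, keeping volumes
positive: visit 2 perturbs the expiratory volume by
$\exp(\varepsilon),\ \varepsilon \sim N(0, \sigma_{bh}^2)$ with
$\sigma_{bh} = 0.08$ by default, and the inspiratory volume by an
independent, smaller factor ($\sigma = 0.035$) — expiratory breath holds
reproduce worse than inspiratory ones. In the rare case where the perturbed
volumes violate volume closure (normal tissue would need a shrink factor
below ≈0.12) the perturbation pair is re-drawn; this conditioning is
deterministic under the seed.

### Rendering

Geometry is deliberately simple: the claims under study concern densitometry,
not anatomy. Each lung is an ellipsoid grown voxel-by-voxel from its centre
in a fixed ordering, so a mask of any target volume is exact to half a voxel
(well inside the 2 % tolerance the generator enforces). Trapped regions are
contiguous blobs carved by ranking a spatially smoothed Gaussian random
field inside the expiratory mask, taking exactly the top $f_{exp}$ fraction
of voxels. Voxel attenuations are Gaussian around their compartment mean
with sd $\sqrt{\sigma_{texture}^2 + \sigma_{noise}^2}$ (defaults 30 and
25 HU, a plausible low-dose level); the background is soft tissue near
+50 HU. An optional per-scan global HU offset (`hu_drift_sd`, default 0)
can emulate session-to-session calibration shifts.

The default grid is 48³ voxels at 5.5 mm spacing — coarse for clinical CT
but ample for cohort-level densitometric statistics, and it keeps a
45-subject, two-visit, two-phase cohort renderable in seconds. The
densitometry oracle check uses a finer 64³ grid at 4 mm. Voxel values are
continuous by default (`round_hu` switches on integer quantization).

Defaults were chosen once to emulate the intended study conditions: ~45
heavy smokers, inspiratory volumes ≈5–7 L, expiratory volumes ≈2.5–4.5 L,
EXP~-856~ spanning roughly one to tens of percent, and E/I-ratio~MLD~
roughly 70–99 %.

### What the generator does *not* emulate

No airway trees, lobes or realistic lung shapes; no emphysema-vs-trapping
distinction; no scanner spectral (kVp) effects, beam hardening or
reconstruction-kernel texture; parenchymal texture is white noise, not
spatially correlated; phantom sessions differ only by voxel noise (plus
optional drift), so the phantom QC scatter underestimates the
session-calibration variation of a real scanner. Consequently, passing
tests demonstrate the *statistical machinery* and the *direction* of
volume-dependence effects, not clinical effect sizes: the synthetic limits
of agreement are narrower than those of real repeat CT.

## Densitometry

* The −856 HU cut is **strict** (`<`); ties at exactly −856 are excluded.
  The choice is documented rather than derivable from common usage.
* `smooth_volume()` is a separable Gaussian in physical units (mm), applied
  per axis so anisotropic spacing is handled; kernel rows are renormalized
  at the grid edges so constants are exactly preserved. Both air-trapping
  measures see the identically preprocessed volume.
* Smoothing narrows the within-compartment HU spread, which moves a
  thresholded tail in the direction predicted by `expected_exp856()` with a
  smaller σ — but only for voxels away from mask boundaries. At boundaries,
  partial-volume mixing with the +50 HU background and across trapped/normal
  blob edges can dominate; the property tests therefore evaluate the
  direction on interior voxels (mask eroded by the kernel scale).
* `segment_lungs()` is a deliberate stand-in: threshold at −300 HU, 3D
  6-connected components via `igraph`, border-touching components discarded
  as ambient air, two largest internal components kept. It recovers
  generator masks with Dice ≈ 1 on adequately sized grids, but pipelines on
  synthetic data default to the generator's ground-truth masks; subjects
  whose segmentation fails are excluded and counted, not fatal.
* The phantom ROI is a 20 mm circle in a single axial slice, membership by
  voxel-centre-in-circle — the 2D ROI an observer would draw.

## Statistical lung volume correction

The correction assumes a simple linear relation between a measure and its
paired volume: the cohort-level OLS slope of the between-visit measure
differences on the between-visit volume differences (expiratory volume for
EXP~-856~, exhaled volume for E/I-ratio~MLD~), applied per visit around the
subject's pair-mean volume:

$$m^{corr}_v = m_v - \hat\beta\,(V_v - \bar V_{subject}).$$

This choice — among several defensible ones — is the simplest linear scheme
that preserves each subject's pair mean and nulls the refitted slope exactly
(OLS orthogonality). The slope is estimated on the same cohort it corrects
(there is no external training set); the report records this. Corrected
values are deliberately not clamped: once $\hat\beta \times$ volume-offset
exceeds a small percentage measure the corrected value goes negative, a
known artefact of linear volume correction for expiratory threshold
measures. If both visit volumes are identical for every subject (the
zero-variation verification mode) the slope is unidentifiable and the
correction degrades to the identity, flagged as degenerate.

## Agreement statistics

* **LoA**: mean difference ± 1.96 × sample sd (n−1) of the differences.
  "Sd of the mean difference" is read as the sd of the differences, not a
  standard error; the midpoint and width invariants are asserted for every
  report row.
* **Lin's concordance correlation** uses n-denominator moments (the original
  definition), no bias correction and no confidence interval.
* **Sandvik–Olsson paired-dispersion test**: both series are centred at
  their own means; the Spearman correlation between within-pair sums and
  differences is the statistic (for centred series,
  $\mathrm{cov}(a+b, a-b) = \mathrm{var}(a) - \mathrm{var}(b)$, so a
  positive statistic means the first condition is more dispersed). The p
  value is exact by full permutation for n ≤ 8 and a t approximation with
  n − 2 df otherwise. The literature offers more than one construction under
  this name; this rank-based Pitman–Morgan analogue is documented as the
  package's interpretation. Identical dispersion patterns return
  ρ = 0, p = 1 by definition.
* **Levene's test** is mean-centred (classic) by default, with the
  median-centred Brown–Forsythe variant as an option; the F statistic on
  absolute deviations uses an ordinary one-way ANOVA.
* **Breath-hold subgrouping** uses rank tails of size ⌊n/4⌋ at each end
  (outer quartiles → "inferior" reproducibility) rather than percentile
  cut-offs: deterministic under ties (broken by input order) and yielding
  the 22/23 split at n = 45. Subgrouping uses the measure's own paired
  volume: expiratory volume for EXP~-856~, exhaled volume for
  E/I-ratio~MLD~.
* Significance is fixed at 0.05 with no multiple-testing adjustment,
  matching standard practice for this analysis type.

## Numerical and reproducibility choices

* All randomness flows through one seed; the RNG (Mersenne-Twister,
  inversion) is set explicitly and the caller's RNG state is restored.
  Identical configuration ⇒ bit-identical cohort, measures and report
  (asserted byte-for-byte in the tests, plus a frozen-value regression
  test at 10⁻⁹).
* The zero-variation identity mode (`share_visit_noise = TRUE` with zero
  breath-hold and inspiratory sds) replays visit 1's RNG stream for
  visit 2, so the two visits are voxel-identical and every agreement
  statistic degenerates exactly (Δ = 0, LoA = (0,0), concordance = 1).
* Quantiles use the type-7 (linear interpolation) convention everywhere.
* Report JSON is written atomically (temp file + rename) at full precision.

## Known limitations

* The EXP~-856~ response saturates for subjects far below or far above the
  threshold, so ratio comparisons of LoA widths across perturbation levels
  can compress for cohorts dominated by extreme trapping.
* Lung masks that reach the image border defeat the stand-in segmenter's
  ambient-air heuristic on very small grids; use ground-truth masks or a
  roomier grid there.
* The volume-correction slope is a cohort property; applying it to a single
  new subject is out of scope.
* Effect sizes are synthetic. The package demonstrates directions and
  machinery — e.g. that good breath-hold reproducibility narrows EXP~-856~
  limits much more than E/I-ratio~MLD~ limits — not clinical magnitudes.

## A compact run

```{r, eval = FALSE}
report <- run_pipeline(cohort_config(seed = 1))
print(report)
qc <- phantom_qc(phantom_spec(noise_sd = 2), n_sessions = 20, seed = 2)
attr(qc, "pass")
```
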