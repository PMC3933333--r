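---
title: "Simulating design-based stereology of the Purkinje cell monolayer"
author: "stereoPC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating design-based stereology of the Purkinje cell monolayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereoPC)
```

# The problem

Purkinje cells (PCs) form a one-cell-thick sheet between the molecular and
granule cell layers of the cerebellar cortex. Counting them per unit length
of that sheet is notoriously subjective: the sheet is convoluted, sectioned
at arbitrary angles (so it appears locally "thickened"), and its anatomical
boundaries blur where PCs are sparse. Design-based stereology avoids all of
this by counting PCs per unit *volume* with an optical disector: a square
counting frame with inclusion and exclusion edges, swept through a known
tissue depth, applied on a systematic uniform random (SUR) grid across the
entire region of interest. The density estimate is simply

$$\hat D \;=\; \frac{\sum Q^-}{n_{\text{frames}} \cdot a \cdot h},$$

the total count divided by the summed volume of the counting boxes (frame
area $a$, disector height $h$).

`stereoPC` builds this entire measurement chain *in silico*: virtual
cerebellar regions with known ground truth, virtual sectioning and tissue
degradation, the unbiased counting frame, the Gundersen (m = 1) coefficient
of error, Cavalieri volumes, a calibrated 16-case postmortem cohort
simulator, and the matching statistical battery. Because the phantom's true
density is known by construction, every stage of the pipeline can be
validated quantitatively - something impossible with real tissue.

# The virtual tissue model

A folium is a tube swept along a straight (or gently curved) centerline:
white-matter core plus cortical shell out to the pial surface at radius
$r$, with the PC monolayer on a coaxial surface `pcOffset` (default 300 um,
the molecular-layer depth) beneath the pia. Flat end caps keep volume
($\pi r^2 L$) and monolayer area ($2\pi(r-\text{pcOffset})L$) closed-form;
`mcVolume()` cross-checks them by Monte-Carlo point sampling. Somata are a
Poisson process on the monolayer (expected count = surface density x
area), scattered radially by N(0, 20 um) - the "variable position within
the layer" seen histologically - with a hard-core minimum separation of
one mean soma diameter (25 um; human PC scale, configurable) enforced by
sequential dart throwing. Soma diameters are lognormal (mean 25 um, SD
2.5 um, clipped); the profile radius used by the counting rule and the
leading edge used by the disector derive from the per-soma diameter.

## Why the packaged phantoms are sheared oblique lattices

The four packaged regions (`defaultRegionSpec()`) fill a box contour with
parallel straight tubes. Three geometric choices matter, and all three
exist to reproduce how *real* convoluted folia behave under systematic
sampling:

* **Oblique azimuth.** If tube axes align with the frame grid, the
  in-section soma strips beat against the grid pitch and the replicate
  variance explodes (we measured replicate CVs of ~25% against a CE of
  ~0.05). A single oblique azimuth per region makes every soma strip cross
  many grid columns, restoring smooth occupancy.
* **Common z slope (shear).** A horizontal tube's monolayer has tangent
  planes at two fixed depths, so its soma z profile is a narrow,
  edge-peaked blob; a lattice of such blobs resonates with the 1.2 mm
  section period. Shearing the whole lattice (every tube climbs in z with
  a common slope; rigid shear preserves all inter-tube gaps, so tubes can
  never collide) makes each tube sweep through one or more full section
  periods, flattening the z profile (its CV across section starts drops
  from ~29% to ~2%).
* **Varying caliber.** Tube radii follow a deterministic golden-ratio
  sequence (450-600 um; lobule X 330-450 um, matching its small
  flocculonodular leaflets), spreading the tangent geometry further.

With these choices the survey-scale phantoms achieve replicate CVs of
5-9%, within a factor of two of the mean Gundersen CE - the coherence one
expects of real tissue, and the regime in which the CE is a meaningful
precision summary.

## Calibration to the published survey

The published survey counted ~450 PCs per region in a known number of
19,600 um^2 x 75 um disector boxes, so each region's true density follows
from arithmetic: $D_r = 450 / (n_{\text{frames},r} \times 1.47\times10^{-3}
\text{ mm}^3)$, giving 276.8 (crus I), 374.2 (crus II), 181.1 (lobules
IV-VI) and 219.9 PC/mm^3 (lobule X). Each phantom's bounding box is sized
so that the 1-in-6 series of 200 um sections and the region's grid pitch
(2.5, 2.2, 1.4, 0.4 mm) reproduce the published mean frame counts (1106,
818, 1690, 1392), which implies regional reference volumes of 8,316,
4,753, 3,977 and 267 mm^3. Tubes stay one radius clear of the box faces,
so every soma's counting frame lies inside the contour and the estimator
is exactly unbiased.

# Sectioning, degradation and counting

`cutSections()` applies the series (200 um thickness, every 6th section,
uniform random start). A section is retained when its top plane lies
inside the region - with extents that are whole numbers of the period
this gives the same section count for every random start and keeps the
expected frame count unbiased. Each soma belongs to the section containing
its *leading edge*, the minimum-z point of the soma sphere: the unique
"comes into focus" event of the optical disector, guaranteeing each soma
has exactly one counting opportunity.

`applyDegradation()` emulates processing damage: whole sections lost at a
configurable rate (the survey reported up to 10%) and lateral erosion of
the folia edges ("fraying", default 50 um), deleting both area and the
somata in the eroded shell, so density remains estimable from degraded
material.

`placeFrames()` imposes a square grid with a fresh uniform random offset
per section and places one frame per qualifying cell. The default
qualification rule is **centroid** (frame centre inside the footprint):
this keeps the expected frame count at exactly area/pitch^2 and the
density estimator unbiased. The alternative **intersect** rule (any
footprint overlap) is available, but it dilates the sampled area by one
frame side along the boundary and biases density low by
$s(W+H)/(WH)$ - about 2% for the crus I phantom - which is why it is not
the default.

`countFrame()` implements the unbiased counting frame: a soma is counted
iff its maximal XY profile disk intersects the closed frame, does not
touch the forbidden line (left edge with its upward extension, bottom
edge, and the downward extension at the bottom-right corner; touching the
forbidden line always excludes), and its leading edge falls inside the
half-open disector window (guard, guard + height]. With exclusion
dominating ties, an exhaustive tiling (pitch = side, full-depth window)
counts every soma exactly once - the identity the test suite verifies on
arbitrary point sets.

# The density estimate and its precision

`estimateDensity()` divides the total count by the summed box volume and
attaches the Gundersen (m = 1) CE over the ordered per-section counts:

$$\text{CE} = \frac{\sqrt{\text{noise} + \text{Var}_{\text{SURS}}}}{\sum Q_i},
\qquad \text{Var}_{\text{SURS}} = \frac{3(A - \text{noise}) - 4B + C}{240},$$

with noise $=\sum Q_i$, $A=\sum Q_i^2$, $B=\sum Q_iQ_{i+1}$,
$C=\sum Q_iQ_{i+2}$ in anatomical section order. The exact CE variant used
by commercial stereology software is not always printed; this package
adopts the m = 1 smoothness-class estimator throughout and truncates a
(rare) negative SURS term at zero. Zero counts or fewer than three
sections flag the CE as undefined rather than failing. `cavalieriVolume()`
supplies regional volumes (sum of planimetric areas x section spacing),
and `overallWeightedDensity()` the composite
$\sum_r V_r D_r / \sum_r V_r$, excluding missing regions from both sums.

# The cohort simulator

`defaultCohortSpec()` encodes the study conditions of the published
16-case survey (8 autism / 8 control, 5 males and 3 females each).
Demographics are normal fits per diagnosis-by-sex cell to the packaged
case table (ages, fresh brain weights - autism males are markedly heavier
than autism females in this sample - and pooled PMI), with comorbidity
flags at the reported 38% rates. Regional densities follow a log-linear
multiplicative model: baseline per region, diagnosis ratio per region,
male ratio, a common age slope, a shared case effect (SD 0.10), regional
residuals (SD 0.127, crus I-crus II correlation 0.54), and - for lobule X
only - a brain-weight elasticity term through which the entire
male-autism lobule X deficit is routed (the study's volume-mediation
hypothesis; a direct-effect switch exists).

Two calibration principles, fixed before any acceptance testing:

* **Observed-contrast calibration.** The printed effect sizes are *raw
  group contrasts* that already include the demographic structure, so the
  direct coefficients are solved so that the expected observed contrast
  equals the printed value. For example the direct male multiplier is
  0.843, which - combined with the ~16-year male-female age gap and the
  negative age slope - yields the observed 21% male deficit.
* **Correlation-and-link calibration.** The crus I-crus II residual
  correlation (0.54) and the ADI-R latent-noise SD (0.70) were chosen by
  Monte-Carlo so the measured cross-case correlation and the lobule X
  eye-contact Spearman centre on the published 0.832 and -0.75 (600-cohort
  calibration runs; the frozen values are package constants).

The ADI-R eye-contact item is an ordinal 0-3 score cut from a latent
impairment variable that decreases with lobule X density; one autism case
per cohort is flagged ADI-R-missing, and three domain totals are generated
as density-unrelated noise (the study found no domain-level association).
Measurement is either the `fast_surrogate` (mean-preserving lognormal
noise with CV 0.053, the survey's mean CE - the desk-scale default) or the
`full_pipeline` (a phantom per case and region, resampled through the
whole disector chain, behind a soma-count resource guard).

## What the simulator does and does not capture

Passing recovery tests shows the *pipeline* is consistent: planted effects
of the published size are recovered by the published analysis chain at
n = 16. It does not validate the biological claims; real tissue adds
shrinkage variation, anatomical boundary ambiguity, staining artefacts and
non-lognormal case heterogeneity that the generator does not model.
Regional missingness (the study could not sample every region in every
case) is supported by the composite's exclusion rule but is off by default.

Two published numbers are *not* reproducible from the published effect
structure, and the package reports them honestly rather than forcing
them: (i) the 11% overall volume-weighted diagnosis deficit is
incompatible with 19.8%/21.7% crus deficits once crus I+II carry 75% of
the frame-count-implied volume weight (the composite is then >= ~15%; the
11% is the mixed-model marginal estimate, not the raw composite); (ii)
the 26% lobule X autism-vs-control male deficit cannot coexist with the
fully brain-weight-mediated lobule X model and the case table's ~11%
brain-weight gap between autism and control males. The corresponding
acceptance checks are expected to fail and say so.

# The statistical battery

`analyzeCohort()` mirrors the published analysis plan: four linear mixed
models fitted by maximum likelihood (lme4, Satterthwaite type-III F via
lmerTest) - fixed effects diagnosis x gender x region, a random intercept
per case, residual weights proportional to regional volume in the WLS
variants, and an optional brain-weight covariate (cases missing it are
dropped with a note); Levene-gated regional t-tests (pooled when Levene
p >= 0.05, Welch otherwise) with Benjamini-Hochberg step-up FDR over the
four-region family; and bootstrap Spearman correlations (mid-rank ties,
t-approximation p, 1,000-replicate percentile CIs). `interactionPower()`
computes noncentral-F observed power for the 2x2 interaction; the default
noncentrality convention is the one used by the study's statistics package
($\lambda = f^2(df_1 + df_2 + 1)$, reproducing the printed 0.24 for
f = 0.36, N = 16), with the population convention ($\lambda = f^2 N$,
matched by the `interactionPowerSim()` Monte-Carlo oracle) as an option.

A worked note on the FDR: textbook BH at q = 0.05 on the four printed
regional p-values (0.039, 0.032, 0.512, 0.173) flags nothing (both crus
BH-adjusted p = 0.078); the published FDR-positive footnotes on crus I
and II are reproduced at q = 0.10, or with an a-priori family of the two
crus regions only. `bhFdr()` implements the textbook step-up.

# Numerical and design choices

* Coordinates in um, right-handed, z the sectioning axis; densities
  reported per mm^3 (1e9 um^3/mm^3). Region z extents are whole numbers of
  the section period, which makes section counts offset-invariant.
* Frames anchor at grid-cell corners; "touching" any edge means closed-disk
  intersection; exclusion dominates ties.
* The Gundersen CE truncates a negative SURS covariance term at zero.
* Percent differences are computed on raw densities with the larger-mean
  group as reference; model fits consume natural-log densities.
* Problem sizes in the packaged checks: survey-scale phantoms (59k to 2.3M
  somata) with 12-200 replicate samplings per check, 200 simulated cohorts
  per recovery run, 20,000 replicates for the power oracle, 1,000
  bootstrap replications per correlation.
* Every random stage accepts a seed; `runPipeline()` embeds the seed and
  config hash in its outputs and refuses to overwrite without an explicit
  flag.

# A small worked example

```{r example, eval = FALSE}
reg <- assembleRegion(defaultRegionSpec("lobuleX", rngSeed = 42))
reg
est <- estimateDensity(sampleRegion(reg, seed = 7))
est                      # ~220 PC/mm^3, CE ~0.05, ~450 cells counted

sim <- simulateCohort(seed = 1)
round(cohortContrasts(sim), 3)
res <- analyzeCohort(sim, seed = 1)
res$factorial$test1      # the volume-weighted mixed model
```

# Known limitations

Folium curvature is limited to gentle polylines (volume/area formulas are
tube approximations); anatomically faithful cerebellar geometry, granule
and molecular layer cytology, optical physics (the 75 um depth limit is a
premise, not simulated), lost-caps corrections beyond the guard, and
shrinkage correction to fresh-tissue densities are out of scope. The
footprints of non-axis-aligned folia under the "folia" contour are
conservative bounding boxes; the packaged phantoms use the box contour,
where footprints are exact.
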