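---
title: "Deconstructing the laterality index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconstructing the laterality index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidecon)
```

## The model

Language lateralisation from task fMRI is conventionally summarised by the
laterality index

$$\mathrm{LI} = \frac{L - R}{L + R},$$

where $L$ and $R$ are above-threshold voxel quantities in homologous left-
and right-hemisphere regions of interest. Two well-known pathologies
motivate this package. First, the LI depends on the activity threshold and
the ROI, neither of which has a canonical choice. Second, the ratio hides
the amount of evidence behind it: $L = 0.01, R = 0.09$ and
$L = 0.10, R = 0.90$ both give $\mathrm{LI} = -0.8$, although the first
case is nearly empty of signal. With a fixed threshold the weakest data
produce the most extreme indices; with adaptive thresholds the same data
collapse towards $0$ and masquerade as bilateral.

`lidecon` therefore treats the numerator $\lambda = L - R$ (*laterality*)
and the denominator $s = L + R$ (*strength*) as a two-dimensional feature.
$\lambda$ and $s$ are always defined — there is no division — and
inconclusive cases occupy a predictable region (low $s$, low $|\lambda|$)
instead of scattering over the LI axis. The LI itself is kept as a
first-class quantity: where $s = 0$ it is *undefined* (`NA`), and that
undefinedness propagates rather than erroring, because how undefined cases
drop out of fixed-threshold analyses is part of what the package measures.

Both conventions that make these quantities exact are deliberate:
"above threshold" is *strict* (`value > t`), so the proportion is exactly
$0$ at or above the map maximum and exactly $1$ below the minimum; and $L$,
$R$ are proportions of their (mirrored, equal-sized) ROI masks, which makes
count-based and proportion-based LIs identical while keeping the two
hemispheres symmetric.

## Hemisphere geometry

All left/right decisions are made in world millimetres, never in array
order: a voxel is left-hemispheric iff its world $x < 0$ under the map's
affine (RAS convention). Mirroring requires the grid to be mid-sagittally
symmetric — every voxel must have a partner at $-x$ within a hundredth of a
voxel — and is then a pure lattice permutation, hence an exact involution.
Oblique or asymmetric grids are rejected rather than resampled; resampling
belongs to preprocessing, and silent interpolation would break the exact
mirror properties the tests rely on. Voxels within half a voxel width of
$x = 0$ form a midline band excluded from both hemispheres. Non-finite
voxels are zeroed on read with a counted warning rather than propagated.

## The ROI ladder

The ROIs are data-driven. Conclusive lateralised training cases are aligned
so the dominant hemisphere lies left (right-lateralised maps are mirrored),
each map has its own mirror subtracted to give a left-minus-right
difference image, and a voxel-wise one-sample t-test
($t = \bar d / (\mathrm{sd}/\sqrt n)$, sample sd) summarises the cohort.
Voxels with zero variance get $t = 0$ — not $\pm\infty$ — which keeps them
out of the base set. The *base set* is every left-hemisphere voxel with
$t > 0$; level $p \in \{0, 5, \dots, 95\}$ of the ladder drops the
$\lfloor p\% \cdot n \rfloor$ lowest-scoring base voxels. Ties at the cut
are all retained, so membership is deterministic and independent of voxel
or subject order (a mask may slightly exceed its nominal fraction when
values tie). Each left mask is mirrored to give its right twin. Whether the
percentile steps should be taken over all voxels or positive-$t$ voxels
only was genuinely open; the positive-$t$ base set matches the construction
in which level 0 is "all dominant-hemisphere voxels above zero", and it is
the package's fixed convention.

## Grid search, above-chance selection and the ensemble

Features are computed on a grid of absolute $t$ thresholds (default 0 to 12
in steps of 0.5, covering the informative range) crossed with the 20 ladder
levels. Per cell, the training split is halved 100 times (stratified by
class — unstratified halves would frequently lose a rare class entirely at
realistic cohort sizes), a probabilistic linear classifier is fitted on one
half and scored on the other, and the mean accuracy is kept. A cell is
retained iff an exact one-sided binomial test rejects guessing:
$P(X \ge \mathrm{round}(\mathrm{acc}\cdot n)) < 0.001$ under the
majority-class base rate, with the full training-set $n$ as the default
evaluation size. No normal approximation is used anywhere.

The classifier contract is "linear decision boundaries, calibrated class
probabilities summing to one". The default implementation is linear
discriminant analysis (shared within-class covariance, hence linear
boundaries and closed-form posteriors); multinomial logistic regression is
available via `method = "multinom"`. Both are deterministic given the data,
which keeps every stage exactly reproducible under a seed. Cells whose
training degenerates (a half containing a single class, or zero
within-class variance) score the base rate with a warning and are naturally
screened out by the binomial test.

Prediction averages the member probabilities and takes the argmax
(winner-take-all). Ties fall to the earlier class in the fixed order left,
bilateral, right, inconclusive — i.e. the more frequent class — and are
messaged when they occur. In 1-D LI mode a member abstains where the LI is
undefined; a case on which every member abstains is reported
`"unclassifiable"` in 3-class mode and inconclusive with probability 1 in
4-class mode, so the 2-D pipeline is total while the 1-D pipeline honestly
refuses. Undefined-LI cases are excluded from a cell's training and
evaluation sets rather than counted as errors, and the exclusion count is
reported per cell.

Train/test splitting is patient-wise (a patient's sessions never straddle
the boundary) and stratified by class; half-splitting inside the grid
search is session-wise, mirroring a design in which the outer split guards
against patient leakage and the inner one only estimates cell accuracy.

## Benchmarks, hybrid scheme and Wada scoring

Two classical single-score baselines are built in: the fixed-threshold LI
(voxel counts above $t = 3$ by default) and the adaptive LI, which sets the
threshold to the mean of the positive in-mask voxel values pooled across
both hemisphere ROIs. Whether that adaptive mean should be over the whole
image, in-mask only, or positive values only is underdetermined; pooling
positive in-mask values keeps the two hemispheres symmetric and is exposed
as the `pool` argument. Since no anatomical parcellation ships with the
package, benchmark comparisons use a configurable ladder level (level 50 by
default) as the ROI stand-in for a frontal mask with midline exclusion.

`hybrid_predict` implements the two-stage scheme: the 2-D 4-class ensemble
only *excludes* inconclusive cases, and any single-score LI classifier
labels the remainder — combining the 2-D model's inconclusive detection
with a conventional LI's 3-class behaviour.

Wada results are scored as
$\mathrm{LI} = \frac{L-R}{L+R}\cdot\frac{n}{m}$ (bilateral protocol, $n$
the better hemisphere's score, $m$ the maximum, default 14 = 7 functions
× 2 points) and $\mathrm{HLC} = h/m$ (unilateral). Categorisation uses the
published cutoffs: $\mathrm{LI} > 0.5$ left, $\mathrm{LI} < -0.5$ right,
the inclusive band $[-0.5, 0.5]$ bilateral. The source rule prints
"LI < 0.5" for right-sided dominance, which would make the bilateral band
empty; the package reads it as the evident sign slip $\mathrm{LI} < -0.5$.
For unilateral tests the *tested* hemisphere is the anesthetised,
probed-for-dominance one: $\mathrm{HLC} = 0$ assigns dominance to it,
$\mathrm{HLC} \ge 0.8$ to the contralateral side, $(0, 0.2)$ is excluded
(possible negative bilaterality), and the band $[0.2, 0.8)$ — unaddressed
by the published rule — is flagged `"indeterminate-bilateral"` rather than
silently merged. `cluster_check` confirms rule-based categories against an
order-mapped 3-cluster k-means solution with fixed-seed restarts.

## The synthetic cohort generator

The generator emulates single-subject "task > rest" t-maps directly in
t-units; no time-series or haemodynamic simulation is attempted, since
every downstream stage consumes finished t-maps. A case is

* standard Gaussian background noise (sd 1, in t-units),
* plus three homotopic pairs of Gaussian blobs (sd 8 mm) at
  inferior-frontal (−46, 24, 10), medial-superior (−6, 8, 56) and
  ventral-posterior (−42, −54, −14) world-mm sites with relative weights
  1, 0.7 and 0.8, scaled by left/right peak amplitudes $a_L, a_R$,
* plus symmetric negative blobs at midline default-mode sites (precuneus,
  medial-orbitofrontal), which end up outside the positive-$t$ ROI base set
  exactly as task-negative regions should.

The class regimes drive the feature geometry: lateralised cases draw the
dominant amplitude from $N(8, 1)$ and the non-dominant from $N(1.2, 0.5)$
(strong $|\lambda|$, high $s$); bilateral cases draw both from $N(6, 1)$
($\lambda \approx 0$, high $s$); inconclusive cases draw both from
$N(0.6, 0.3)$ (low $s$). All draws truncate at 0. The true laterality
$\lambda = (a_L - a_R)/(a_L + a_R)$ and strength $s = a_L + a_R$ are
recorded per case as ground truth. Default class counts (134/20/12/34 at
$n = 200$) mirror a referral-population mix of roughly 67% left, 10%
bilateral, 6% right, 17% inconclusive; the grid is a coarse 4 mm
32×38×32 lattice, symmetric about the mid-sagittal plane with no voxel
column on $x = 0$, which keeps the full grid search at desk-scale runtime
(the complete recovery experiment — generation, ladder, 500-cell × 100
half-split search for both the 4-class and 3-class models, prediction and
the pure-noise contrast — runs in a few minutes on one CPU). About 10% of
patients contribute a second session whose amplitudes share the class
regime but are jittered by a lognormal factor (sdlog 0.2), so repeat
sessions differ in strength but not laterality.

Additional smoothing (`smooth_fwhm`) is available but defaults to 0 mm:
the blobs are analytically smooth already, and unsmoothed background noise
keeps closed-form expectations exact — e.g. a pure-noise map's strength at
$t = 3$ is $2\,P(N(0,1) > 3) \approx 0.0027$, which the tests check by
simulation.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot show — includes spatially correlated physiological noise,
motion and susceptibility artefacts, lesion-distorted anatomy, crossed or
multi-focal lateralisation patterns, and inter-subject anatomical
variability beyond amplitude jitter. Recovery results on this cohort
demonstrate the pipeline's internal consistency, not clinical accuracy on
patient data.

## Numerical choices and degenerate inputs

* Strict `>` thresholds; exact curve endpoints $(1, 1)$ and $(0, 0)$.
* LI curves use 101 evenly spaced thresholds spanning the map's range by
  default; a constant map degenerates to a single threshold with a
  warning.
* Undefined LIs are `NA`, never exceptions; $(0,0)$ deconstructs to
  laterality 0, strength 0.
* Percentile cuts are rank-based with ties retained (order-independent).
* Binomial tests and confidence intervals are exact (tail sums and
  Clopper–Pearson via the beta quantile); the 84% interval is nested in
  the 95% one by construction.
* Accuracy-to-successes conversion in the significance test rounds to the
  nearest integer.
* Empty masks, asymmetric grids, <2 subjects, and all-cells-undefined
  predictions all raise explicit errors or labelled fallbacks, never
  silent values.

## Known limitations

The artifact consumes finished, spatially normalised t-maps; registration
quality and template asymmetry are the caller's responsibility (grids that
are not mid-sagittally symmetric are rejected outright). The benchmark ROI
is a ladder level, not an anatomical frontal mask. The bootstrap variant of
adaptive LI computation is out of scope; the fixed and adaptive benchmarks
plus the `single_li_classifier` extension point stand in for it. Detection
of bilateral cases is intrinsically hard for any single-ROI index — crossed
lateralisation across regions cannot be expressed in one $\lambda$ — and
the generator does not model it.
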