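# lidecon — deconstructed laterality indices for fMRI language lateralisation

`lidecon` is an R toolkit for turning voxel-wise statistic maps (t-maps)
from language fMRI into categorical decisions about hemispheric language
dominance — **left**, **bilateral**, **right** — while explicitly modelling
a fourth outcome, **inconclusive**, for maps that carry too little signal to
support any decision. It is aimed at researchers working on presurgical
language lateralisation (e.g. in epilepsy cohorts) and at methodologists
studying the behaviour of laterality indices.

## The problem and the approach

The standard laterality index compares above-threshold voxel quantities in
homologous left/right regions of interest:

```
LI = (L − R) / (L + R)        ∈ [−1, +1]
```

Its value depends on the activity threshold and the ROI, and it behaves
pathologically on weak data: with a fixed threshold, a case with 1 left and
9 right voxels gets LI = −0.8 — a seemingly strong right lateralisation
from almost no evidence — while adaptive thresholds push the same weak data
towards 0, mimicking bilaterality. `lidecon` *deconstructs* the LI into its
numerator **L − R** (laterality) and denominator **L + R** (activation
strength) and treats them as a two-dimensional feature, so that
low-strength/low-laterality cases become identifiable as inconclusive
instead of contaminating the lateralised or bilateral categories.

The pipeline:

1. **Hemisphere geometry** (`read_stat_map`, `mirror_map`,
   `hemisphere_partition`): world-space left/right partition and exact
   mid-sagittal mirroring of NIfTI volumes.
2. **Data-driven ROI ladder** (`cohort_roi_ladder`): conclusive lateralised
   training cases are aligned dominant-side-left, left-minus-right
   difference maps are tested voxel-wise against zero, and the positive-t
   left-hemisphere map is thresholded at percentiles 0, 5, …, 95 into 20
   nested masks, each mirrored to the right hemisphere.
3. **Threshold × ROI grid search** (`grid_accuracy`,
   `significance_mask`): for every combination of t-threshold and ladder
   level, a probabilistic linear classifier is evaluated over repeated
   stratified half-splits of the training data, and cells beating the
   majority-class guessing rate at an exact one-sided binomial test
   (α = 0.001) are retained.
4. **Ensemble prediction** (`fit_ensemble`, `predict`): the above-chance
   cells' classifiers are refitted on the full training split; test cases
   get the average of the members' class probabilities and the
   winner-take-all label. `hybrid_predict` uses the 2-D model only to
   exclude inconclusive cases and any single-score LI classifier for the
   rest.
5. **Wada scoring** (`bilateral_wada_li`, `hlc`, `score_wada_table`,
   `cluster_check`): invasive gold-standard results are scored
   (LI = [(L−R)/(L+R)]·(n/m) for bilateral tests, HLC = h/m for unilateral
   ones), categorised with the published cutoffs, and cross-checked with a
   3-cluster k-means solution.
6. **Synthetic cohorts** (`cohort_spec`, `generate_cohort`): labelled
   t-map cohorts with homotopic activation blobs whose left/right
   amplitudes set the true laterality and strength, so the whole pipeline
   is testable without patient data.

## Worked example

A small synthetic cohort, end to end (seeds fixed; this is exactly what the
code prints):

```r
library(lidecon)
spec <- cohort_spec(n_per_class = c(left = 14, bilateral = 6, right = 6,
                                    inconclusive = 8),
                    grid_shape = c(16L, 20L, 16L), voxel_mm = 8)
sim    <- generate_cohort(spec, seed = 7)
cohort <- patientwise_stratified_split(sim$cohort, seed = 2)

tr     <- cohort$split == "train"
ladder <- cohort_roi_ladder(sim$cases[cohort$case_id[tr]], cohort$label[tr])
ladder
#> <roi_ladder> 20 levels (0...95), base set 1369 voxels, n = 13 subjects

store <- cohort_feature_store(sim$cases, ladder, t_grid = seq(0, 8, 1))
grid  <- significance_mask(grid_accuracy(cohort, store, mode = "2d",
                                         classes = 4, n_splits = 20, seed = 3))
ens   <- fit_ensemble(cohort, store, grid)
ens
#> <li_ensemble> 100 members (2d, 4-class, lda), trained on 22 cases

te   <- cohort$split == "test"
pred <- predict(ens, store)
pred <- pred[match(cohort$case_id[te], pred$case_id), ]
mean(pred$label == cohort$label[te])
#> [1] 0.9166667
round(confusion_matrix(pred$label, cohort$label[te]), 1)
#>                left bilateral right inconclusive
#>   left          100         0     0            0
#>   bilateral       0       100     0            0
#>   right           0        50    50            0
#>   inconclusive    0         0     0          100
```

100 of the 180 (threshold, ROI-level) cells beat guessing; the resulting
ensemble classifies 11 of the 12 held-out sessions correctly (one right
case is confused with bilateral), and every truly inconclusive case is
recognised as such. Per-case probabilities quantify the confidence of each
decision:

```r
head(pred[, c("case_id", "p_left", "p_bilateral", "p_right",
              "p_inconclusive", "label")], 3)
#>   case_id    p_left p_bilateral      p_right p_inconclusive label
#> 1 P001_s1 0.6657039   0.2235900 2.999553e-09    0.110706164  left
#> 6 P005_s1 0.6453976   0.3536302 2.788993e-12    0.000972173  left
#> 7 P006_s1 0.6160308   0.3344136 4.722437e-09    0.049555616  left
```

The worked LI arithmetic and a Wada example:

```r
li(1, 9)
#> [1] -0.8
bilateral_wada_li(10, 4, m = 14)      # (10-4)/14 * 10/14
#> [1] 0.3061224
categorise_bilateral(bilateral_wada_li(10, 4, m = 14))
#> [1] "bilateral"
```

A command-line wrapper over the same functions lives at
`inst/cli/lidecon.R` (subcommands `pipeline`, `simulate`, `wada-score`),
and `run_pipeline()` executes the whole chain from one config.

## Vignette

`vignettes/laterality-deconstruction.Rmd` documents the model, the
generator's assumptions, the numerical conventions (strict thresholds, tie
handling, undefined-LI propagation) and known limitations.
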