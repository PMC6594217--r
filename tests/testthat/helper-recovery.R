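# Full-scale parameter-recovery experiment on the default synthetic cohort
# (n = 200, coarse grid, full threshold x ROI-level search). Used by the
# acceptance tests; takes a couple of minutes.
run_recovery_experiment <- function(seed = 1L, n_splits = 100L) {
  spec <- cohort_spec()
  sim <- generate_cohort(spec, seed = seed)
  cohort <- patientwise_stratified_split(sim$cohort, seed = seed + 1L)
  tr <- cohort$split == "train"
  ladder <- cohort_roi_ladder(sim$cases[cohort$case_id[tr]], cohort$label[tr])
  store <- cohort_feature_store(sim$cases, ladder)

  g4 <- significance_mask(suppressWarnings(
    grid_accuracy(cohort, store, mode = "2d", classes = 4,
                  n_splits = n_splits, seed = seed + 2L)))
  ens4 <- fit_ensemble(cohort, store, g4)
  g3 <- significance_mask(suppressWarnings(
    grid_accuracy(cohort, store, mode = "2d", classes = 3,
                  n_splits = n_splits, seed = seed + 2L)))
  ens3 <- fit_ensemble(cohort, store, g3)

  te <- cohort$split == "test"
  truth <- cohort$label[te]
  p4 <- predict(ens4, store)
  p4 <- p4[match(cohort$case_id[te], p4$case_id), ]
  concl <- te & cohort$label != "inconclusive"
  p3 <- predict(ens3, store)
  p3 <- p3[match(cohort$case_id[concl], p3$case_id), ]

  # pure-noise cohort: amplitudes exactly zero
  spec0 <- cohort_spec(
    n_per_class = c(left = 0, bilateral = 0, right = 0, inconclusive = 100),
    amplitude_params = list(lateralised = list(dom = c(8, 1),
                                               nondom = c(1.2, 0.5)),
                            bilateral = list(both = c(6, 1)),
                            inconclusive = list(both = c(0, 0))),
    p_two_sessions = 0)
  noise <- generate_cohort(spec0, seed = seed + 3L)
  # benchmark-style fixed-threshold LI at a high threshold on the mid-ladder ROI
  noise_li <- vapply(noise$cases, function(cs)
    fixed_threshold_li(cs$map, ladder$left_masks[["50"]],
                       ladder$right_masks[["50"]], t = 4), numeric(1))
  pn <- predict(ens4, cohort_feature_store(noise$cases, ladder))

  list(cohort = cohort, ladder = ladder, store = store,
       ens4 = ens4, ens3 = ens3,
       acc4 = mean(p4$label == truth),
       recall_inconclusive = mean(p4$label[truth == "inconclusive"] ==
                                    "inconclusive"),
       acc3_conclusive = mean(p3$label == cohort$label[concl]),
       n_test = sum(te), n_test_conclusive = sum(concl),
       noise_li = noise_li,
       noise_extreme_frac = mean(abs(noise_li) > 0.5, na.rm = TRUE),
       noise_defined = sum(!is.na(noise_li)),
       noise_inconclusive_frac = mean(pn$label == "inconclusive"),
       truth4 = truth, pred4 = p4$label)
}
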