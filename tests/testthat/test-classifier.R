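make_cohort_df <- function(n_per_class, sessions = 1L) {
  classes <- rep(names(n_per_class), n_per_class)
  pid <- sprintf("P%03d", seq_along(classes))
  df <- data.frame(patient_id = rep(pid, each = sessions),
                   label = rep(classes, each = sessions),
                   stringsAsFactors = FALSE)
  df$case_id <- paste0(df$patient_id, "_s", seq_len(sessions))
  df
}

test_that("patient-wise stratified split preserves base rates and patients", {
  co <- make_cohort_df(c(left = 30, bilateral = 30, right = 30))
  sp <- patientwise_stratified_split(co, test_fraction = 1/3, seed = 5)
  expect_equal(sum(sp$split == "test"), 30)
  expect_equal(as.vector(table(sp$label[sp$split == "test"])), c(10, 10, 10))

  # a patient with two sessions lands wholly in one split
  co2 <- make_cohort_df(c(left = 12, right = 6), sessions = 2L)
  sp2 <- patientwise_stratified_split(co2, seed = 9)
  by_pat <- tapply(sp2$split, sp2$patient_id, function(x) length(unique(x)))
  expect_true(all(by_pat == 1))

  # deterministic under the seed, generically different across seeds
  expect_identical(patientwise_stratified_split(co, seed = 5)$split, sp$split)
  expect_false(identical(patientwise_stratified_split(co, seed = 6)$split,
                         sp$split))

  expect_error(patientwise_stratified_split(
    data.frame(case_id = "a", patient_id = "p", label = "left")), "too few")
})

test_that("cell features carry the 2D/1D contract including undefined LIs", {
  maps <- lapply(1:4, function(i) lateralised_map(seed = i, id = paste0("s", i)))
  lad <- cohort_roi_ladder(maps, rep("left", 4))
  cell_lo <- list(threshold = 1, roi_level = 0)
  f <- compute_cell_features(maps[[1]], lad, cell_lo, mode = "2d")
  expect_named(f, c("laterality", "strength"))
  expect_gt(f[["laterality"]], 0)  # strongly left case at moderate threshold

  # empty activation: nothing above a huge threshold
  cell_hi <- list(threshold = 99, roi_level = 0)
  f2 <- compute_cell_features(maps[[1]], lad, cell_hi, mode = "2d")
  expect_equal(unname(f2), c(0, 0))
  expect_true(is.na(compute_cell_features(maps[[1]], lad, cell_hi,
                                          mode = "li1d")))
  expect_error(compute_cell_features(maps[[1]], lad,
                                     list(threshold = 1, roi_level = 33)),
               "roi_level")
})

test_that("grid accuracy is perfect on separable features, chance on shuffled labels", {
  # synthetic feature store with a perfectly separating cell and a noise cell
  set.seed(13)
  n <- 60
  y <- rep(c("left", "bilateral", "right"), each = n / 3)
  lat_sep <- rep(c(0.8, 0, -0.8), each = n / 3) + rnorm(n, sd = 0.02)
  str_sep <- rep(1, n) + rnorm(n, sd = 0.02)
  store <- structure(list(
    cells = data.frame(threshold = c(2, 9), roi_level = c(0, 0)),
    laterality = cbind(lat_sep, rnorm(n, sd = 0.3)),
    strength = cbind(str_sep, abs(rnorm(n, sd = 0.3))),
    li = cbind(lat_sep / str_sep, rnorm(n, sd = 0.5)),
    case_ids = sprintf("c%02d", 1:n), t_grid = c(2, 9), levels = 0),
    class = "li_feature_store")
  co <- data.frame(case_id = store$case_ids, patient_id = store$case_ids,
                   label = y, split = "train")
  g <- grid_accuracy(co, store, mode = "2d", classes = 3, n_splits = 25,
                     seed = 4)
  expect_equal(g$cells$accuracy[1], 1)
  expect_lt(g$cells$accuracy[2], 0.6)

  # deterministic under the seed
  g2 <- grid_accuracy(co, store, mode = "2d", classes = 3, n_splits = 25,
                      seed = 4)
  expect_identical(g$cells$accuracy, g2$cells$accuracy)

  # label shuffling sends even the separable cell to roughly the base rate
  set.seed(99)
  co_sh <- co
  co_sh$label <- sample(co$label)
  g_sh <- grid_accuracy(co_sh, store, mode = "2d", classes = 3, n_splits = 25,
                        seed = 4)
  expect_lt(abs(g_sh$cells$accuracy[1] - g$base_rate), 0.15)

  # significance: the separable cell clears the binomial bar, noise does not
  gs <- significance_mask(g, n_eval = n, alpha = 0.001)
  expect_true(gs$cells$significant[1])
  expect_false(gs$cells$significant[2])
})

test_that("binomial above-chance thresholds match exact tail computation", {
  # printed design constants of the threshold selection rule
  expect_equal(round(100 * min_significant_accuracy(432, 351 / 432, 0.001)), 87)
  expect_equal(round(100 * min_significant_accuracy(521, 351 / 521, 0.001)), 74)
  expect_equal(min_significant_accuracy(10, 0.5, 0.001), 1)

  # agreement with an explicit tail-sum oracle over assorted n
  for (n in c(7, 33, 210, 1000)) {
    p <- 0.61
    alpha <- 0.05
    k_min <- round(n * min_significant_accuracy(n, p, alpha))
    tail_sum <- function(k) sum(dbinom(k:n, n, p))
    expect_lt(tail_sum(k_min), alpha)
    expect_gte(tail_sum(k_min - 1), alpha)
  }
  # unattainable bound: even n/n successes not significant
  expect_identical(min_significant_accuracy(7, 0.61, 0.01), Inf)
  # accuracy equal to the base rate is never significant
  g <- structure(list(cells = data.frame(threshold = 1, roi_level = 0,
                                         accuracy = 0.65, n_undefined = 0L),
                      base_rate = 0.65, n_eval = 200, mode = "2d",
                      classes = 3), class = "accuracy_grid")
  expect_false(significance_mask(g)$cells$significant)
})

test_that("ensemble prediction averages members and respects the tie rule", {
  set.seed(21)
  n <- 48
  y <- rep(c("left", "bilateral", "right", "inconclusive"), each = n / 4)
  lat <- rep(c(0.8, 0, -0.8, 0), each = n / 4) + rnorm(n, sd = 0.03)
  str <- rep(c(1.2, 1.2, 1.2, 0.05), each = n / 4) + rnorm(n, sd = 0.03)
  store <- structure(list(
    cells = data.frame(threshold = c(2, 3), roi_level = c(0, 0)),
    laterality = cbind(lat, lat), strength = cbind(str, str),
    li = cbind(lat / str, lat / str),
    case_ids = sprintf("c%02d", 1:n), t_grid = c(2, 3), levels = 0),
    class = "li_feature_store")
  co <- data.frame(case_id = store$case_ids, patient_id = store$case_ids,
                   label = y, split = "train")
  g <- significance_mask(grid_accuracy(co, store, classes = 4, n_splits = 10,
                                       seed = 2))
  ens <- fit_ensemble(co, store, g)
  expect_s3_class(ens, "li_ensemble")
  expect_gte(length(ens$members), 1)
  pred <- predict(ens, store)
  p <- as.matrix(pred[, paste0("p_", c("left", "bilateral", "right",
                                       "inconclusive"))])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0 & p <= 1))
  # argmax attains the maximum
  expect_equal(pred$label,
               c("left", "bilateral", "right", "inconclusive")[max.col(p, "first")])
  # refit on training-identical cases at least matches the grid accuracy - tol
  expect_gte(mean(pred$label == y), max(g$cells$accuracy) - 0.05)

  # single-member ensemble returns that member's probabilities
  g1 <- g
  g1$cells$significant <- c(TRUE, FALSE)
  ens1 <- fit_ensemble(co, store, g1)
  expect_length(ens1$members, 1)

  # no significant cells -> explicit no-model error
  g0 <- g
  g0$cells$significant <- c(FALSE, FALSE)
  expect_error(fit_ensemble(co, store, g0), "no model")
})

test_that("1D-mode members abstain on undefined LIs and total abstention is handled", {
  y <- rep(c("left", "right"), each = 6)
  lival <- c(rep(0.9, 6), rep(-0.9, 6)) + seq(-0.01, 0.01, length.out = 12)
  store <- structure(list(
    cells = data.frame(threshold = 5, roi_level = 0),
    laterality = matrix(lival, 12), strength = matrix(1, 12),
    li = matrix(lival, 12),
    case_ids = sprintf("c%02d", 1:12), t_grid = 5, levels = 0),
    class = "li_feature_store")
  co <- data.frame(case_id = store$case_ids, patient_id = store$case_ids,
                   label = y, split = "train")
  g <- significance_mask(grid_accuracy(co, store, mode = "li1d", classes = 3,
                                       n_splits = 10, seed = 1), n_eval = 12,
                         alpha = 0.05)
  ens <- fit_ensemble(co, store, g)
  newstore <- store
  newstore$li[1, 1] <- NA  # undefined at the only cell
  pred <- predict(ens, newstore)
  expect_equal(pred$label[1], "unclassifiable")
  expect_equal(pred$n_members_used[1], 0)
  expect_equal(pred$label[12], "right")
})

test_that("mean laterality scores average over significant cells only", {
  lat <- matrix(c(0.5, 0.1, -0.3, 0.7), 1)
  str <- matrix(c(1.0, 0.6, 0.8, 1.2), 1)
  store <- structure(list(
    cells = data.frame(threshold = c(1, 2, 3, 4), roi_level = 0),
    laterality = lat, strength = str, li = lat / str,
    case_ids = "c1", t_grid = 1:4, levels = 0),
    class = "li_feature_store")
  cells <- store$cells[c(1, 3), ]
  sc <- mean_laterality_scores(store, cells = cells, mode = "2d")
  expect_equal(sc$laterality, mean(c(0.5, -0.3)))
  expect_equal(sc$strength, mean(c(1.0, 0.8)))
  # single cell: score equals that cell's feature
  sc1 <- mean_laterality_scores(store, cells = store$cells[2, ], mode = "2d")
  expect_equal(sc1$laterality, 0.1)
  # 1D with all cells undefined: missing score with full undefined count
  store$li[1, ] <- NA
  sc2 <- mean_laterality_scores(store, cells = store$cells, mode = "li1d")
  expect_true(is.nan(sc2$li) || is.na(sc2$li))
  expect_equal(sc2$n_undefined, 4L)
})

test_that("confusion matrices are row-normalised percentages", {
  cm <- confusion_matrix(c("left", "bilateral"), c("left", "left"))
  expect_equal(cm["left", "left"], 50)
  expect_equal(cm["left", "bilateral"], 50)
  expect_equal(unname(rowSums(cm)["left"]), 100)

  perfect <- confusion_matrix(rep(c("left", "right"), 5),
                              rep(c("left", "right"), 5))
  expect_equal(unname(diag(perfect)), c(100, 100))
  expect_error(confusion_matrix(character(0), character(0)))
})

test_that("Clopper-Pearson intervals are exact at the edges and nested", {
  ci <- accuracy_ci(10, 10)
  expect_equal(ci$upper, c(1, 1))
  ci0 <- accuracy_ci(0, 10)
  expect_equal(ci0$lower, c(0, 0))
  for (n in c(1, 7, 23, 50)) {
    for (k in c(0, 1, floor(n / 2), n)) {
      ci <- accuracy_ci(k, n)
      expect_gte(ci$lower[1], ci$lower[2] - 1e-12)  # 84% nested in 95%
      expect_lte(ci$upper[1], ci$upper[2] + 1e-12)
      # matches binom.test at 95%
      bt <- binom.test(k, n)$conf.int
      expect_equal(c(ci$lower[2], ci$upper[2]), as.vector(bt), tolerance = 1e-9)
    }
  }
})

test_that("hybrid prediction excludes inconclusive cases then defers to the base stage", {
  set.seed(31)
  spec <- tiny_spec()
  sim <- generate_cohort(spec, seed = 7)
  cohort <- patientwise_stratified_split(sim$cohort, seed = 2)
  tr <- cohort$split == "train"
  ladder <- cohort_roi_ladder(sim$cases[cohort$case_id[tr]], cohort$label[tr])
  store <- cohort_feature_store(sim$cases, ladder, t_grid = seq(0, 8, 1))
  g4 <- significance_mask(suppressWarnings(
    grid_accuracy(cohort, store, classes = 4, n_splits = 15, seed = 3)))
  ens4 <- fit_ensemble(cohort, store, g4)
  g3 <- significance_mask(suppressWarnings(
    grid_accuracy(cohort, store, classes = 3, n_splits = 15, seed = 3)))
  ens3 <- fit_ensemble(cohort, store, g3)

  te_ids <- cohort$case_id[cohort$split == "test"]
  hyb <- hybrid_predict(ens4, ens3, sim$cases[te_ids], ladder)
  p4 <- predict(ens4, store)
  p3 <- predict(ens3, store)
  for (i in seq_along(te_ids)) {
    id <- te_ids[i]
    if (p4$label[p4$case_id == id] == "inconclusive") {
      expect_equal(hyb$label[i], "inconclusive")
      expect_true(hyb$excluded[i])
    } else {
      expect_equal(hyb$label[i], p3$label[p3$case_id == id])
    }
  }
  # on never-excluded cases the hybrid equals the base classifier by construction
  keep <- !hyb$excluded
  expect_equal(hyb$label[keep], p3$label[match(te_ids[keep], p3$case_id)])
})
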