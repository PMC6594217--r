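class_levels_4 <- c("left", "bilateral", "right", "inconclusive")
class_levels_3 <- c("left", "bilateral", "right")

#' Patient-wise stratified train/test split
#'
#' Assigns whole patients (never single sessions) to either the training or
#' the test split, stratified by class so each split's per-class session
#' base rates stay close to the overall rates. A patient with several
#' sessions contributes all of them to one split.
#'
#' @param cohort data frame with columns `case_id`, `patient_id`, `label`.
#' @param test_fraction fraction of sessions held out (default 1/3).
#' @param seed integer seed.
#' @return The cohort with the `split` column set to `"train"`/`"test"`.
#' @export
patientwise_stratified_split <- function(cohort, test_fraction = 1/3, seed = 1L) {
  stopifnot(all(c("case_id", "patient_id", "label") %in% names(cohort)))
  if (anyNA(cohort$patient_id) || anyNA(cohort$label))
    stop("every case needs a patient id and a label")
  cohort$split <- "train"
  with_local_seed(seed, {
    for (cl in unique(cohort$label)) {
      rows <- which(cohort$label == cl)
      pats <- unique(cohort$patient_id[rows])
      if (length(pats) < 2L)
        stop(sprintf("class '%s' has too few patients to populate both splits", cl))
      sess_per_pat <- table(cohort$patient_id[rows])[pats]
      ord <- sample(seq_along(pats))
      target <- test_fraction * length(rows)
      cum <- cumsum(as.numeric(sess_per_pat[ord]))
      n_test_pat <- max(1L, which.min(abs(cum - target)))
      n_test_pat <- min(n_test_pat, length(pats) - 1L)  # both splits non-empty
      test_pats <- pats[ord[seq_len(n_test_pat)]]
      cohort$split[rows][cohort$patient_id[rows] %in% test_pats] <- "test"
    }
  })
  cohort
}

#' Parameter grid of (t-threshold, ROI level) cells
#'
#' @param t_grid absolute t-value thresholds; default 0 to 12 by 0.5,
#'   covering the informative region of the threshold-ROI accuracy maps.
#' @param levels ROI ladder percentile levels.
#' @return Data frame with one row per cell: `threshold`, `roi_level`.
#' @export
param_cells <- function(t_grid = seq(0, 12, by = 0.5),
                        levels = seq(0, 95, by = 5)) {
  expand.grid(threshold = t_grid, roi_level = levels, KEEP.OUT.ATTRS = FALSE)
}

#' Precompute LI features for a set of cases over a parameter grid
#'
#' Computes, for every case and every (threshold, ROI-level) cell, the
#' above-threshold proportions and the derived laterality, strength and LI.
#' All classifier-facing functions consume this store, so the voxel counting
#' is done once per cohort.
#'
#' @param maps list of [stat_map]s (or `generated_case`s).
#' @param ladder a `roi_ladder`.
#' @param t_grid threshold grid (see [param_cells()]).
#' @return A list of class `li_feature_store`: `cells` (data frame),
#'   `laterality`, `strength`, `li` (case x cell matrices), `case_ids`.
#' @export
cohort_feature_store <- function(maps, ladder, t_grid = seq(0, 12, by = 0.5)) {
  maps <- lapply(maps, function(m) if (inherits(m, "generated_case")) m$map else m)
  cells <- param_cells(t_grid, ladder$levels)
  n_case <- length(maps)
  lat <- str <- matrix(NA_real_, n_case, nrow(cells))
  for (i in seq_len(n_case)) {
    row <- numeric(0)
    for (lv in as.character(ladder$levels)) {
      L <- above_threshold_proportion(maps[[i]], ladder$left_masks[[lv]], t_grid)
      R <- above_threshold_proportion(maps[[i]], ladder$right_masks[[lv]], t_grid)
      idx <- which(cells$roi_level == as.numeric(lv))
      lat[i, idx] <- L - R
      str[i, idx] <- L + R
    }
  }
  li_m <- ifelse(str > 0, lat / str, NA_real_)
  ids <- vapply(maps, function(m) m$id, character(1))
  rownames(lat) <- rownames(str) <- rownames(li_m) <- ids
  structure(list(cells = cells, laterality = lat, strength = str, li = li_m,
                 case_ids = ids, t_grid = t_grid, levels = ladder$levels),
            class = "li_feature_store")
}

#' Feature vector for one case at one parameter cell
#'
#' @param map a [stat_map].
#' @param ladder a `roi_ladder`.
#' @param cell list/row with `threshold` and `roi_level`.
#' @param mode `"2d"` (laterality, strength; always defined) or `"li1d"`
#'   (the LI alone; `NA` when the denominator is zero).
#' @return Named numeric vector.
#' @export
compute_cell_features <- function(map, ladder, cell, mode = c("2d", "li1d")) {
  mode <- match.arg(mode)
  lv <- as.character(cell$roi_level)
  if (!lv %in% names(ladder$left_masks)) stop("roi_level not in ladder")
  L <- above_threshold_proportion(map, ladder$left_masks[[lv]], cell$threshold)
  R <- above_threshold_proportion(map, ladder$right_masks[[lv]], cell$threshold)
  if (mode == "2d") c(laterality = L - R, strength = L + R)
  else c(li = li(L, R))
}

# case x d feature matrix for one cell, from a feature store
cell_feature_matrix <- function(store, cell_idx, mode) {
  if (mode == "2d")
    cbind(laterality = store$laterality[, cell_idx],
          strength = store$strength[, cell_idx])
  else
    cbind(li = store$li[, cell_idx])
}

# Probabilistic linear classifier (linear decision boundaries, class
# probabilities summing to one). method "lda" (default) or "multinom".
# Returns NULL when fitting degenerates (single class, zero variance).
fit_prob_linear <- function(x, y, method = "lda") {
  y <- droplevels(y)
  if (nlevels(y) < 2L) return(NULL)
  tryCatch(suppressWarnings(
    if (method == "lda") {
      fit <- MASS::lda(x, grouping = y)
      list(method = "lda", fit = fit, levels = levels(y))
    } else {
      df <- data.frame(.y = y, x)
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE)
      list(method = "multinom", fit = fit, levels = levels(y))
    }), error = function(e) NULL)
}

# probability matrix (rows = cases) over `all_levels`, zeros for classes the
# member never saw
predict_prob_linear <- function(model, x, all_levels) {
  out <- matrix(0, nrow(x), length(all_levels),
                dimnames = list(NULL, all_levels))
  if (is.null(model)) return(out)
  p <- if (model$method == "lda") {
    predict(model$fit, x)$posterior
  } else {
    pr <- predict(model$fit, newdata = data.frame(x), type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr, deparse.level = 0)
    colnames(pr) <- model$levels
    pr
  }
  out[, colnames(p)] <- p
  out
}

#' Mean half-split accuracy for every parameter cell
#'
#' For each (threshold, ROI-level) cell, the training cases are split into
#' two class-stratified halves `n_splits` times; a probabilistic linear
#' classifier is fitted on one half and its accuracy measured on the other,
#' and the per-cell mean accuracy over splits is returned. In `"li1d"` mode,
#' cases whose LI is undefined at a cell are excluded from both halves at
#' that cell and their count reported. Cells where training degenerates
#' (e.g. a single class present) score the base rate, with a warning.
#'
#' @param cohort cohort data frame; rows with `split == "train"` are used
#'   (all rows if no `split` column).
#' @param store an [cohort_feature_store()] covering the cohort's cases.
#' @param mode `"2d"` or `"li1d"`.
#' @param classes 3 (conclusive cases only) or 4 (inconclusive included).
#' @param n_splits number of random half-splits (default 100).
#' @param seed integer seed.
#' @param method classifier method (`"lda"` or `"multinom"`).
#' @return A list of class `accuracy_grid`: `cells` with columns `threshold`,
#'   `roi_level`, `accuracy`, `n_undefined`; plus `mode`, `classes`,
#'   `base_rate`, `n_train`, `n_eval`, `seed`.
#' @export
grid_accuracy <- function(cohort, store, mode = c("2d", "li1d"),
                          classes = 4, n_splits = 100L, seed = 1L,
                          method = "lda") {
  mode <- match.arg(mode)
  lv <- if (classes == 4) class_levels_4 else class_levels_3
  rows <- if ("split" %in% names(cohort)) cohort$split == "train" else
    rep(TRUE, nrow(cohort))
  rows <- rows & cohort$label %in% lv
  ids <- cohort$case_id[rows]
  y <- factor(cohort$label[rows], levels = lv)
  if (min(table(y)[table(y) > 0]) < 2L) stop("need >= 2 cases per class")
  case_idx <- match(ids, store$case_ids)
  if (anyNA(case_idx)) stop("cohort cases missing from feature store")
  n <- length(ids)
  half_a <- with_local_seed(seed, {
    lapply(seq_len(n_splits), function(s) {
      sel <- logical(n)
      for (cl in levels(y)) {
        k <- which(y == cl)
        sel[sample(k, floor(length(k) / 2))] <- TRUE
      }
      sel
    })
  })
  base_rate <- max(table(y)) / n
  n_cells <- nrow(store$cells)
  acc <- numeric(n_cells)
  n_undef <- integer(n_cells)
  degenerate <- FALSE
  for (ci in seq_len(n_cells)) {
    x <- cell_feature_matrix(store, ci, mode)[case_idx, , drop = FALSE]
    ok <- stats::complete.cases(x)
    n_undef[ci] <- sum(!ok)
    accs <- vapply(half_a, function(sel) {
      tr <- sel & ok
      ev <- !sel & ok
      if (sum(ev) == 0L) return(NA_real_)
      model <- fit_prob_linear(x[tr, , drop = FALSE], y[tr], method)
      if (is.null(model)) {
        degenerate <<- TRUE
        return(base_rate)
      }
      p <- predict_prob_linear(model, x[ev, , drop = FALSE], lv)
      mean(lv[max.col(p, ties.method = "first")] == as.character(y[ev]))
    }, numeric(1))
    acc[ci] <- mean(accs, na.rm = TRUE)
  }
  if (degenerate)
    warning("some cells degenerated to single-class training; base rate recorded")
  cells <- store$cells
  cells$accuracy <- acc
  cells$n_undefined <- n_undef
  structure(list(cells = cells, mode = mode, classes = classes,
                 base_rate = base_rate, n_train = n, n_eval = n,
                 seed = seed, method = method),
            class = "accuracy_grid")
}

# one-sided exact binomial tail P(X >= k | n, p)
binom_tail_geq <- function(k, n, p) stats::pbinom(k - 1, n, p, lower.tail = FALSE)

#' Smallest above-chance accuracy at an exact binomial test
#'
#' The smallest `k/n` whose one-sided exact binomial tail probability under
#' guessing rate `p` falls below `alpha`.
#'
#' @param n evaluation-set size.
#' @param p guessing rate (base rate of the largest class).
#' @param alpha significance level (default 0.001).
#' @return The minimal significant accuracy as a proportion.
#' @export
min_significant_accuracy <- function(n, p, alpha = 0.001) {
  stopifnot(n >= 1, p > 0, p < 1)
  k <- 0:n
  tails <- binom_tail_geq(k, n, p)
  hit <- which(tails < alpha)
  if (!length(hit)) return(Inf)
  k[hit[1]] / n
}

#' Flag parameter cells whose accuracy beats guessing
#'
#' One-sided exact binomial test of each cell's mean accuracy against the
#' guessing rate: a cell is significant iff
#' `P(X >= round(accuracy * n_eval)) < alpha`. No normal approximation is
#' used.
#'
#' @param grid an `accuracy_grid`.
#' @param base_rate guessing rate; defaults to the grid's own base rate.
#' @param n_eval evaluation-set size for the test; defaults to the grid's
#'   full training n.
#' @param alpha significance level (default 0.001).
#' @return The grid with a logical `significant` column added to `cells` and
#'   fields `alpha`, `min_accuracy` recorded.
#' @export
significance_mask <- function(grid, base_rate = grid$base_rate,
                              n_eval = grid$n_eval, alpha = 0.001) {
  stopifnot(base_rate > 0, base_rate < 1)
  k <- round(grid$cells$accuracy * n_eval)
  grid$cells$significant <- binom_tail_geq(k, n_eval, base_rate) < alpha
  grid$alpha <- alpha
  grid$min_accuracy <- min_significant_accuracy(n_eval, base_rate, alpha)
  grid
}

#' Fit the above-chance ensemble
#'
#' Fits one probabilistic linear classifier per significant (threshold,
#' ROI-level) cell on the full training split. Prediction averages the
#' members' probability vectors (winner-take-all on the mean).
#'
#' @param cohort cohort data frame (rows with `split == "train"` are used).
#' @param store feature store covering the training cases.
#' @param grid a significance-masked `accuracy_grid` (see
#'   [significance_mask()]); its mode/classes/method are inherited.
#' @return A list of class `li_ensemble` with `members` (each: `cell`,
#'   `model`), `class_levels`, `mode`, `method`, and training provenance.
#' @export
fit_ensemble <- function(cohort, store, grid) {
  if (is.null(grid$cells$significant))
    stop("grid has no significance mask; run significance_mask() first")
  sig <- which(grid$cells$significant)
  if (!length(sig))
    stop("no model: no parameter cell is significantly above chance; ",
         "review the threshold grid, ROI ladder or alpha")
  lv <- if (grid$classes == 4) class_levels_4 else class_levels_3
  rows <- if ("split" %in% names(cohort)) cohort$split == "train" else
    rep(TRUE, nrow(cohort))
  rows <- rows & cohort$label %in% lv
  ids <- cohort$case_id[rows]
  y <- factor(cohort$label[rows], levels = lv)
  case_idx <- match(ids, store$case_ids)
  members <- lapply(sig, function(ci) {
    x <- cell_feature_matrix(store, ci, grid$mode)[case_idx, , drop = FALSE]
    ok <- stats::complete.cases(x)
    model <- fit_prob_linear(x[ok, , drop = FALSE], y[ok], grid$method)
    list(cell = store$cells[ci, c("threshold", "roi_level")], model = model)
  })
  members <- members[!vapply(members, function(m) is.null(m$model), logical(1))]
  if (!length(members)) stop("no model: every significant cell degenerated")
  structure(list(members = members, class_levels = lv, mode = grid$mode,
                 classes = grid$classes, method = grid$method,
                 n_train = length(ids), base_rate = grid$base_rate,
                 alpha = grid$alpha, seed = grid$seed,
                 t_grid = store$t_grid, levels = store$levels),
            class = "li_ensemble")
}

#' @export
print.li_ensemble <- function(x, ...) {
  cat(sprintf("<li_ensemble> %d members (%s, %d-class, %s), trained on %d cases\n",
              length(x$members), x$mode, x$classes, x$method, x$n_train))
  invisible(x)
}

# resolve newdata (stat_map / list of maps / feature store) into a store
as_feature_store <- function(newdata, ladder, t_grid) {
  if (inherits(newdata, "li_feature_store")) return(newdata)
  if (inherits(newdata, "stat_map") || inherits(newdata, "generated_case"))
    newdata <- list(newdata)
  cohort_feature_store(newdata, ladder, t_grid)
}

#' Predict lateralisation with an above-chance ensemble
#'
#' Each member classifier produces a class-probability vector for every
#' case; the vectors are averaged over members with defined features and
#' the case is assigned to the class with the highest mean probability
#' (winner-take-all). Ties at the argmax fall to the earlier class in the
#' fixed order left, bilateral, right, inconclusive, with a message. In
#' `"li1d"` mode a member abstains wherever the LI is undefined; a case at
#' which every member abstains is labelled `"unclassifiable"` in 3-class
#' mode and inconclusive with probability 1 in 4-class mode.
#'
#' @param object a `li_ensemble`.
#' @param newdata a [stat_map], a list of them, or a prebuilt feature store.
#' @param ladder the `roi_ladder` the ensemble was trained with (required
#'   unless `newdata` is already a feature store).
#' @param ... unused.
#' @return Data frame: `case_id`, one `p_<class>` column per class, `label`,
#'   `n_members_used`.
#' @export
predict.li_ensemble <- function(object, newdata, ladder = NULL, ...) {
  store <- as_feature_store(newdata, ladder, object$t_grid)
  lv <- object$class_levels
  n <- length(store$case_ids)
  p_sum <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
  n_used <- integer(n)
  cell_key <- paste(store$cells$threshold, store$cells$roi_level)
  for (m in object$members) {
    ci <- match(paste(m$cell$threshold, m$cell$roi_level), cell_key)
    if (is.na(ci)) stop("ladder/threshold grid does not match training provenance")
    x <- cell_feature_matrix(store, ci, object$mode)
    ok <- stats::complete.cases(x)
    if (any(ok)) {
      p <- predict_prob_linear(m$model, x[ok, , drop = FALSE], lv)
      p_sum[ok, ] <- p_sum[ok, ] + p
      n_used[ok] <- n_used[ok] + 1L
    }
  }
  probs <- p_sum / pmax(n_used, 1L)
  label <- rep(NA_character_, n)
  defined <- n_used > 0L
  if (any(defined)) {
    win <- max.col(probs[defined, , drop = FALSE], ties.method = "first")
    n_tie <- sum(apply(probs[defined, , drop = FALSE], 1,
                       function(p) sum(p == max(p)) > 1L))
    if (n_tie > 0L)
      message(n_tie, " tie(s) at argmax broken by fixed class order")
    label[defined] <- lv[win]
  }
  if (any(!defined)) {
    if (object$classes == 4) {
      probs[!defined, ] <- 0
      probs[!defined, "inconclusive"] <- 1
      label[!defined] <- "inconclusive"
    } else {
      label[!defined] <- "unclassifiable"
    }
  }
  out <- data.frame(case_id = store$case_ids, probs, label = label,
                    n_members_used = n_used, row.names = NULL,
                    check.names = FALSE)
  names(out)[1 + seq_along(lv)] <- paste0("p_", lv)
  out
}

#' Ensemble-averaged laterality scores for visual spaces
#'
#' The mean per-case feature over all significant cells: in `"li1d"` mode
#' the mean LI over cells where it is defined, in `"2d"` mode the mean
#' laterality and mean strength. The count of cells where the feature was
#' undefined is reported; a case undefined at every cell gets `NA`.
#'
#' @param newdata a [stat_map], list of maps, or feature store.
#' @param ladder a `roi_ladder` (unless `newdata` is a store).
#' @param cells data frame of significant cells (`threshold`, `roi_level`),
#'   e.g. the significant rows of an `accuracy_grid`.
#' @param mode `"2d"` or `"li1d"`.
#' @param t_grid threshold grid used to build a store from raw maps.
#' @return Data frame with `case_id`, the mean score column(s), and
#'   `n_undefined`.
#' @export
mean_laterality_scores <- function(newdata, ladder = NULL, cells,
                                   mode = c("2d", "li1d"),
                                   t_grid = seq(0, 12, by = 0.5)) {
  mode <- match.arg(mode)
  store <- as_feature_store(newdata, ladder, t_grid)
  cell_key <- paste(store$cells$threshold, store$cells$roi_level)
  ci <- match(paste(cells$threshold, cells$roi_level), cell_key)
  if (anyNA(ci)) stop("some cells are not in the feature store grid")
  if (!length(ci)) stop("need at least one cell")
  if (mode == "2d") {
    data.frame(case_id = store$case_ids,
               laterality = rowMeans(store$laterality[, ci, drop = FALSE]),
               strength = rowMeans(store$strength[, ci, drop = FALSE]),
               n_undefined = 0L, row.names = NULL)
  } else {
    m <- store$li[, ci, drop = FALSE]
    data.frame(case_id = store$case_ids,
               li = rowMeans(m, na.rm = TRUE),
               n_undefined = rowSums(is.na(m)), row.names = NULL)
  }
}

#' Row-normalised confusion matrix in percent
#'
#' Rows are true classes, columns predictions; each row sums to 100 save
#' rounding.
#'
#' @param predictions character vector of predicted labels.
#' @param labels character vector of true labels.
#' @param classes class order; defaults to the union in standard order.
#' @return Numeric matrix of row percentages.
#' @export
confusion_matrix <- function(predictions, labels, classes = NULL) {
  stopifnot(length(predictions) == length(labels), length(labels) > 0)
  if (is.null(classes))
    classes <- intersect(c(class_levels_4, "unclassifiable"),
                         unique(c(labels, predictions)))
  tab <- table(factor(labels, levels = classes),
               factor(predictions, levels = classes))
  100 * prop.table(unclass(tab), margin = 1)
}

#' Exact binomial confidence intervals on an accuracy
#'
#' Two-sided Clopper-Pearson intervals for `k` successes out of `n`, at the
#' requested confidence levels (defaults 84% and 95%; the narrower interval
#' is nested in the wider one).
#'
#' @param k number of correct classifications.
#' @param n number of cases.
#' @param levels confidence levels.
#' @return Data frame with `level`, `lower`, `upper` (and the point
#'   estimate as attribute `estimate`).
#' @export
accuracy_ci <- function(k, n, levels = c(0.84, 0.95)) {
  stopifnot(n > 0, k >= 0, k <= n)
  alpha <- 1 - levels
  lower <- if (k == 0) rep(0, length(levels)) else
    stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) rep(1, length(levels)) else
    stats::qbeta(1 - alpha / 2, k + 1, n - k)
  out <- data.frame(level = levels, lower = lower, upper = upper)
  attr(out, "estimate") <- k / n
  out
}

#' Hybrid exclude-then-classify prediction
#'
#' Stage one: a 2-D 4-class ensemble screens each case and any case it
#' labels inconclusive keeps that label. Stage two: the remaining cases are
#' classified by a base 3-class classifier (any object whose `predict`
#' yields a `label` column, typically a 3-class `li_ensemble` or a
#' [single_li_classifier()]).
#'
#' @param exclusion_ensemble a 4-class `"2d"` `li_ensemble`.
#' @param base_classifier the 3-class second-stage classifier.
#' @param newdata maps or feature store.
#' @param ladder the shared `roi_ladder`.
#' @return Data frame: `case_id`, `label`, `excluded` (logical).
#' @export
hybrid_predict <- function(exclusion_ensemble, base_classifier, newdata,
                           ladder = NULL) {
  stopifnot(exclusion_ensemble$classes == 4)
  stage1 <- predict(exclusion_ensemble, newdata, ladder)
  excluded <- stage1$label == "inconclusive"
  stage2 <- predict(base_classifier, newdata, ladder)
  label <- ifelse(excluded, "inconclusive", stage2$label)
  data.frame(case_id = stage1$case_id, label = label, excluded = excluded,
             row.names = NULL)
}

#' Single-score LI classifier (benchmark second stage)
#'
#' Fits a probabilistic linear classifier on one LI value per case (e.g.
#' the fixed-threshold or adaptive benchmark LI). `li_fun(map, ladder)` maps
#' a case to its score at prediction time; cases with an undefined score are
#' labelled `"unclassifiable"`.
#'
#' @param li_values training LI values (may contain `NA`, excluded).
#' @param labels training class labels (3-class).
#' @param li_fun function `(map, ladder) -> scalar LI`.
#' @param method `"lda"` or `"multinom"`.
#' @return An object of class `single_li_classifier` with a `predict`
#'   method.
#' @export
single_li_classifier <- function(li_values, labels, li_fun, method = "lda") {
  ok <- !is.na(li_values)
  y <- factor(labels[ok], levels = class_levels_3)
  model <- fit_prob_linear(cbind(li = li_values[ok]), y, method)
  if (is.null(model)) stop("degenerate training data for single-LI classifier")
  structure(list(model = model, li_fun = li_fun, method = method),
            class = "single_li_classifier")
}

#' @export
predict.single_li_classifier <- function(object, newdata, ladder = NULL, ...) {
  if (inherits(newdata, "stat_map")) newdata <- list(newdata)
  if (inherits(newdata, "li_feature_store"))
    stop("single_li_classifier predicts from raw maps, not a feature store")
  vals <- vapply(newdata, function(m) {
    if (inherits(m, "generated_case")) m <- m$map
    object$li_fun(m, ladder)
  }, numeric(1))
  ids <- vapply(newdata, function(m) {
    if (inherits(m, "generated_case")) m$map$id else m$id
  }, character(1))
  label <- rep("unclassifiable", length(vals))
  ok <- !is.na(vals)
  if (any(ok)) {
    p <- predict_prob_linear(object$model, cbind(li = vals[ok]), class_levels_3)
    label[ok] <- class_levels_3[max.col(p, ties.method = "first")]
  }
  data.frame(case_id = ids, li = vals, label = label, row.names = NULL)
}
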