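#' Laterality index (L - R) / (L + R)
#'
#' The standard laterality index over above-threshold voxel quantities
#' (counts or proportions) in homologous left and right ROIs: +1 is fully
#' left-lateralised, -1 fully right-lateralised. When both quantities are
#' zero the index is undefined and `NA` is returned rather than an error:
#' undefined LIs are first-class values that propagate through the pipeline.
#'
#' @param L,R non-negative above-threshold voxel counts or proportions
#'   (vectorised).
#' @return `(L - R) / (L + R)`, or `NA` where `L + R == 0`.
#' @export
li <- function(L, R) {
  if (any(L < 0 | R < 0, na.rm = TRUE)) stop("L and R must be non-negative")
  s <- L + R
  ifelse(s > 0, (L - R) / s, NA_real_)
}

#' Deconstruct the LI into laterality and strength
#'
#' Splits the laterality index into its numerator `L - R` (laterality) and
#' denominator `L + R` (activation strength). Unlike the ratio, both
#' components are defined for every input, including the zero-activation
#' case `(0, 0)`.
#'
#' @param L,R above-threshold proportions in `[0, 1]` (vectorised).
#' @return A list with numeric fields `laterality` and `strength`.
#' @export
deconstruct <- function(L, R) {
  if (any(L < -1e-12 | L > 1 + 1e-12 | R < -1e-12 | R > 1 + 1e-12))
    stop("L and R must be proportions in [0, 1]")
  list(laterality = L - R, strength = L + R)
}

#' Proportion of in-mask voxels above a threshold
#'
#' Counts voxels with value strictly greater than `t` (so at a threshold at
#' or above the map maximum the proportion is exactly 0) and divides by the
#' mask size.
#'
#' @param map a [stat_map].
#' @param mask non-empty logical array on the map's grid.
#' @param t threshold in map units (vectorised).
#' @return Proportion(s) in `[0, 1]`, one per threshold.
#' @export
above_threshold_proportion <- function(map, mask, t) {
  v <- map$values[mask]
  n <- length(v)
  if (n == 0L) stop("empty mask")
  sv <- sort(v)
  (n - findInterval(t, sv)) / n
}

# counts rather than proportions, same strict-> convention
above_threshold_count <- function(map, mask, t) {
  v <- map$values[mask]
  if (length(v) == 0L) stop("empty mask")
  sv <- sort(v)
  length(v) - findInterval(t, sv)
}

#' LI curve across the map's full threshold range
#'
#' Sweeps evenly spaced thresholds from the map minimum to the map maximum
#' and records, at each, the above-threshold proportions L and R in the two
#' ROIs together with the derived laterality `L - R`, strength `L + R`, and
#' LI. L and R are non-increasing in the threshold; at the minimum both are
#' 1, above the maximum both are 0 and the LI is undefined.
#'
#' @param map a [stat_map].
#' @param left_mask,right_mask non-empty logical ROI masks.
#' @param n_thresholds number of evenly spaced thresholds (default 101).
#' @return A data frame with columns `threshold`, `L`, `R`, `laterality`,
#'   `strength`, `li`.
#' @export
li_curve <- function(map, left_mask, right_mask, n_thresholds = 101L) {
  rng <- range(map$values)
  if (rng[1] == rng[2]) {
    warning("constant map: curve degenerates to a single threshold")
    thr <- rng[1]
  } else {
    thr <- seq(rng[1], rng[2], length.out = n_thresholds)
  }
  L <- above_threshold_proportion(map, left_mask, thr)
  R <- above_threshold_proportion(map, right_mask, thr)
  data.frame(threshold = thr, L = L, R = R,
             laterality = L - R, strength = L + R, li = li(L, R))
}

#' Fixed-threshold benchmark LI
#'
#' The classical benchmark: count voxels above a fixed threshold (default
#' t = 3) in each ROI and apply the LI formula to the raw counts. Undefined
#' (`NA`) when no voxel in either ROI exceeds the threshold. Because the
#' left and right ladder masks are mirrored and equal-sized, counts and
#' proportions give the identical LI; counts are retained to match the
#' benchmark's voxel-count definition.
#'
#' @param map a [stat_map].
#' @param left_mask,right_mask non-empty logical ROI masks.
#' @param t fixed threshold (default 3).
#' @return The LI, or `NA` if undefined.
#' @export
fixed_threshold_li <- function(map, left_mask, right_mask, t = 3) {
  li(above_threshold_count(map, left_mask, t),
     above_threshold_count(map, right_mask, t))
}

#' Adaptive-threshold benchmark LI
#'
#' Sets the threshold to the mean intensity of the positive in-mask voxels,
#' pooled across both hemisphere ROIs so left and right are treated
#' symmetrically, then computes the count-based LI at that threshold.
#'
#' @param map a [stat_map].
#' @param left_mask,right_mask non-empty logical ROI masks.
#' @param pool how to compute the adaptive mean: `"positive"` (default,
#'   mean of pooled positive in-mask values) or `"all"` (mean of all pooled
#'   in-mask values).
#' @return The LI, or `NA` when no positive in-mask voxels exist (the
#'   threshold is undefined).
#' @export
adaptive_li <- function(map, left_mask, right_mask, pool = c("positive", "all")) {
  pool <- match.arg(pool)
  v <- c(map$values[left_mask], map$values[right_mask])
  if (length(v) == 0L) stop("empty masks")
  if (pool == "positive") {
    v <- v[v > 0]
    if (length(v) == 0L) return(NA_real_)
  }
  fixed_threshold_li(map, left_mask, right_mask, t = mean(v))
}

#' Tidy LI feature table for a case across ladder levels and thresholds
#'
#' @param map a [stat_map].
#' @param ladder a `roi_ladder`.
#' @param thresholds numeric vector of t thresholds.
#' @return A data frame with one row per (roi_level, threshold): `case_id`,
#'   `roi_level`, `threshold`, `L`, `R`, `laterality`, `strength`, `li`
#'   (`NA` for undefined).
#' @export
li_feature_table <- function(map, ladder, thresholds) {
  out <- lapply(as.character(ladder$levels), function(lv) {
    L <- above_threshold_proportion(map, ladder$left_masks[[lv]], thresholds)
    R <- above_threshold_proportion(map, ladder$right_masks[[lv]], thresholds)
    data.frame(case_id = map$id, roi_level = as.numeric(lv),
               threshold = thresholds, L = L, R = R,
               laterality = L - R, strength = L + R, li = li(L, R))
  })
  do.call(rbind, out)
}
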