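#' Mirror right-lateralised cases so the dominant hemisphere lies left
#'
#' Right-labelled maps are flipped across the mid-sagittal plane;
#' left-labelled maps pass through unchanged. Bilateral or inconclusive
#' labels are rejected: only conclusive, lateralised cases enter group ROI
#' construction and the caller must pre-filter.
#'
#' @param maps list of [stat_map]s.
#' @param labels character vector, one of `"left"`/`"right"` per map.
#' @return List of [stat_map]s, dominant hemisphere on the left.
#' @export
align_dominant_left <- function(maps, labels) {
  stopifnot(length(maps) == length(labels))
  maps <- lapply(maps, function(m) if (inherits(m, "generated_case")) m$map else m)
  bad <- setdiff(unique(labels), c("left", "right"))
  if (length(bad))
    stop("labels must be 'left' or 'right'; pre-filter other classes (got: ",
         paste(bad, collapse = ", "), ")")
  mapply(function(m, lab) if (lab == "right") mirror_map(m) else m,
         maps, labels, SIMPLIFY = FALSE)
}

#' Left-right difference map
#'
#' Subtracts the mirrored map from the map itself, giving each voxel a
#' left-vs-right difference value. The result is exactly antisymmetric in
#' world x: `d(x, y, z) = -d(-x, y, z)`.
#'
#' @param map a [stat_map] on a symmetric grid.
#' @return A [stat_map] of differences.
#' @export
left_right_difference <- function(map) {
  out <- map
  out$values <- map$values - mirror_map(map)$values
  out
}

#' Voxel-wise one-sample t-test across subjects
#'
#' For each voxel, computes `t = mean / (sd / sqrt(n))` across subjects with
#' the sample (n-1) standard deviation. Voxels with zero variance across
#' subjects are flagged and given t = 0 rather than +/-Inf, which keeps them
#' out of any positive-t base set downstream.
#'
#' @param diffs list of >= 2 [stat_map]s on identical grids.
#' @return A list of class `group_t_map` with `tvalues` (3-D array),
#'   `n_subjects`, `affine`, and `zero_variance` (logical array of flagged
#'   voxels).
#' @export
voxelwise_one_sample_t <- function(diffs) {
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 subjects")
  dm <- dim(diffs[[1]]$values)
  for (m in diffs)
    if (!identical(dim(m$values), dm)) stop("grid mismatch across subjects")
  x <- vapply(diffs, function(m) as.vector(m$values), numeric(prod(dm)))
  mu <- rowMeans(x)
  sd_v <- sqrt(rowSums((x - mu)^2) / (n - 1))
  zv <- sd_v == 0
  tv <- numeric(length(mu))
  tv[!zv] <- mu[!zv] / (sd_v[!zv] / sqrt(n))
  structure(list(tvalues = array(tv, dim = dm),
                 n_subjects = n,
                 affine = diffs[[1]]$affine,
                 zero_variance = array(zv, dim = dm)),
            class = "group_t_map")
}

#' Build the nested ROI ladder from a group difference t-map
#'
#' The base set contains every left-hemisphere voxel with t > 0. Twenty
#' nested binary masks are generated at percentile levels 0, 5, ..., 95 of
#' the in-base t-values: level 0 keeps the whole base set and each
#' subsequent level drops the lowest-scoring 5%, until only the top 5%
#' remain at level 95. Percentiles are computed over the base set only, and
#' ties at a boundary are all retained, so membership is deterministic and
#' independent of voxel order. Each left mask is paired with its mirrored
#' right-hemisphere twin.
#'
#' @param group a `group_t_map` from [voxelwise_one_sample_t()].
#' @param levels percentile levels; default `seq(0, 95, by = 5)`.
#' @param midline_eps passed to [hemisphere_partition()].
#' @return A list of class `roi_ladder` with `levels`, `left_masks`,
#'   `right_masks` (lists of logical arrays named by level), `affine`,
#'   `n_subjects`, `base_size`.
#' @export
build_roi_ladder <- function(group, levels = seq(0, 95, by = 5),
                             midline_eps = NULL) {
  gmap <- stat_map(group$tvalues, group$affine, id = "group")
  hemi <- hemisphere_partition(gmap, midline_eps = midline_eps)
  base <- hemi$left & (group$tvalues > 0)
  if (!any(base)) stop("empty base set: no positive-t voxels in the left hemisphere")
  tb <- sort(group$tvalues[base])
  nb <- length(tb)
  # level p drops the floor(p% * n) lowest-scoring voxels; ties at the cut
  # are retained, so masks can slightly exceed the nominal fraction
  cut_at <- tb[pmin(floor(levels / 100 * nb) + 1L, nb)]
  left_masks <- lapply(seq_along(levels), function(i) base & (group$tvalues >= cut_at[i]))
  right_masks <- lapply(left_masks, mirror_mask, map = gmap)
  names(left_masks) <- names(right_masks) <- as.character(levels)
  structure(list(levels = levels, left_masks = left_masks,
                 right_masks = right_masks, affine = group$affine,
                 n_subjects = group$n_subjects, base_size = sum(base)),
            class = "roi_ladder")
}

#' @export
print.roi_ladder <- function(x, ...) {
  cat(sprintf("<roi_ladder> %d levels (%s...%s), base set %d voxels, n = %d subjects\n",
              length(x$levels), x$levels[1], x$levels[length(x$levels)],
              x$base_size, x$n_subjects))
  invisible(x)
}

#' Build an ROI ladder from a labelled cohort of maps
#'
#' Convenience wrapper for the full group pathway: keep conclusive
#' lateralised cases, mirror the right-lateralised ones so the dominant
#' hemisphere lies left, form per-case left-right difference maps, run the
#' voxel-wise one-sample t-test, and threshold into the percentile ladder.
#'
#' @param maps list of [stat_map]s.
#' @param labels character labels per map; only `"left"` and `"right"` cases
#'   are used, others are dropped.
#' @inheritParams build_roi_ladder
#' @return A `roi_ladder`.
#' @export
cohort_roi_ladder <- function(maps, labels, levels = seq(0, 95, by = 5),
                              midline_eps = NULL) {
  keep <- labels %in% c("left", "right")
  if (sum(keep) < 2L) stop("need at least 2 conclusive lateralised cases")
  aligned <- align_dominant_left(maps[keep], labels[keep])
  diffs <- lapply(aligned, left_right_difference)
  build_roi_ladder(voxelwise_one_sample_t(diffs), levels = levels,
                   midline_eps = midline_eps)
}

#' Persist an ROI ladder as NIfTI masks plus a JSON manifest
#'
#' Writes one left and one right mask per level (40 files) and a
#' `manifest.json` recording levels, subject count and base-set size.
#'
#' @param ladder a `roi_ladder`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_roi_ladder <- function(ladder, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lv in as.character(ladder$levels)) {
    write_mask(ladder$left_masks[[lv]], ladder$affine,
               file.path(dir, sprintf("roi_left_%s.nii.gz", lv)))
    write_mask(ladder$right_masks[[lv]], ladder$affine,
               file.path(dir, sprintf("roi_right_%s.nii.gz", lv)))
  }
  manifest <- list(levels = ladder$levels, n_subjects = ladder$n_subjects,
                   base_size = ladder$base_size)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an ROI ladder written by [write_roi_ladder()]
#' @param dir directory containing the mask files and manifest.
#' @return A `roi_ladder`.
#' @export
read_roi_ladder <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  levels <- manifest$levels
  left_masks <- lapply(as.character(levels), function(lv)
    read_mask(file.path(dir, sprintf("roi_left_%s.nii.gz", lv))))
  right_masks <- lapply(as.character(levels), function(lv)
    read_mask(file.path(dir, sprintf("roi_right_%s.nii.gz", lv))))
  aff <- attr(left_masks[[1]], "affine")
  names(left_masks) <- names(right_masks) <- as.character(levels)
  structure(list(levels = levels, left_masks = left_masks,
                 right_masks = right_masks, affine = aff,
                 n_subjects = manifest$n_subjects,
                 base_size = manifest$base_size),
            class = "roi_ladder")
}
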