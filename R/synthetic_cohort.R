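#' Specification for a synthetic t-map cohort
#'
#' Defines the conditions under which synthetic per-case t-maps are drawn.
#' Each case is Gaussian background noise plus homotopic Gaussian activation
#' blobs at a set of left-hemisphere language-network nodes and their
#' mirrored right twins. The left and right peak amplitudes `a_L`, `a_R`
#' (t-units) are drawn from a per-class regime and control the case's true
#' laterality `lambda = (a_L - a_R) / (a_L + a_R)` and strength
#' `s = a_L + a_R`:
#'
#' * `left` / `right`: dominant amplitude ~ N(8, 1), non-dominant
#'   ~ N(1.2, 0.5) — strong laterality, moderate-to-high strength;
#' * `bilateral`: both ~ N(6, 1) — laterality near 0, high strength;
#' * `inconclusive`: both ~ N(0.6, 0.3) — low strength.
#'
#' All draws are truncated at 0. Default class counts (134/20/12/34 at
#' n = 200) mirror a referral-population base rate of roughly 67% left, 10%
#' bilateral, 6% right and 17% inconclusive. Optional task-negative blobs
#' emulate default-mode regions more active during rest. Maps are generated
#' directly in t-units on a coarse 4 mm grid (32 x 38 x 32, mid-sagittally
#' symmetric, RAS affine, no voxel column on x = 0).
#'
#' @param n_per_class named counts for `left`, `bilateral`, `right`,
#'   `inconclusive`.
#' @param grid_shape lattice dimensions.
#' @param voxel_mm isotropic voxel size in mm.
#' @param node_centres matrix of left-hemisphere node centres (world mm, one
#'   row per node); defaults mimic inferior-frontal, medial-superior and
#'   ventral-posterior language nodes.
#' @param node_weights relative peak weight of each node.
#' @param blob_sd spatial standard deviation of each activation blob, mm.
#' @param amplitude_params list of per-class `c(mean, sd)` pairs for the
#'   dominant and non-dominant amplitudes (fields `dom`, `nondom` for
#'   lateralised classes; `both` for bilateral/inconclusive).
#' @param noise_sd background noise standard deviation in t-units.
#' @param smooth_fwhm Gaussian smoothing FWHM in mm applied to the finished
#'   map; 0 (default) leaves the map unsmoothed — the blobs are already
#'   spatially smooth and the map is constructed directly in t-units.
#' @param task_negative if `TRUE` (default) add symmetric negative blobs at
#'   midline default-mode sites (precuneus, medial-orbitofrontal).
#' @param p_two_sessions probability that a patient contributes two
#'   sessions; repeat sessions share the patient's class and laterality
#'   regime but get an independent lognormal strength jitter.
#' @param session_jitter_sdlog sdlog of the per-session lognormal amplitude
#'   factor.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(left = 134, bilateral = 20,
                                        right = 12, inconclusive = 34),
                        grid_shape = c(32L, 38L, 32L),
                        voxel_mm = 4,
                        node_centres = rbind(ifg = c(-46, 24, 10),
                                             sma = c(-6, 8, 56),
                                             vwfa = c(-42, -54, -14)),
                        node_weights = c(1, 0.7, 0.8),
                        blob_sd = 8,
                        amplitude_params = list(
                          lateralised = list(dom = c(8, 1), nondom = c(1.2, 0.5)),
                          bilateral = list(both = c(6, 1)),
                          inconclusive = list(both = c(0.6, 0.3))),
                        noise_sd = 1,
                        smooth_fwhm = 0,
                        task_negative = TRUE,
                        p_two_sessions = 0.1,
                        session_jitter_sdlog = 0.2) {
  stopifnot(all(c("left", "bilateral", "right", "inconclusive") %in%
                  names(n_per_class)),
            nrow(node_centres) == length(node_weights),
            grid_shape[1] %% 2L == 0L)  # even x-dim: symmetric, no x = 0 column
  structure(list(n_per_class = n_per_class, grid_shape = as.integer(grid_shape),
                 voxel_mm = voxel_mm, node_centres = node_centres,
                 node_weights = node_weights, blob_sd = blob_sd,
                 amplitude_params = amplitude_params, noise_sd = noise_sd,
                 smooth_fwhm = smooth_fwhm, task_negative = task_negative,
                 p_two_sessions = p_two_sessions,
                 session_jitter_sdlog = session_jitter_sdlog),
            class = "cohort_spec")
}

# RAS affine placing the grid symmetrically about world x = 0
spec_affine <- function(spec) {
  d <- spec$grid_shape
  v <- spec$voxel_mm
  aff <- diag(c(v, v, v, 1))
  aff[1:3, 4] <- -v * (d - 1) / 2
  aff
}

# world coordinates of every voxel along one axis
axis_world <- function(n, v) v * (seq_len(n) - 1) - v * (n - 1) / 2

# additive Gaussian blob field for one (left-centre, aL, aR) homotopic pair
blob_field <- function(spec, centre, a_left, a_right) {
  d <- spec$grid_shape
  wx <- axis_world(d[1], spec$voxel_mm)
  wy <- axis_world(d[2], spec$voxel_mm)
  wz <- axis_world(d[3], spec$voxel_mm)
  s2 <- 2 * spec$blob_sd^2
  gy <- exp(-(wy - centre[2])^2 / s2)
  gz <- exp(-(wz - centre[3])^2 / s2)
  gxl <- exp(-(wx - centre[1])^2 / s2)
  gxr <- exp(-(wx + centre[1])^2 / s2)
  gx <- a_left * gxl + a_right * gxr
  outer(gx, outer(gy, gz))  # separable: a_L*G(c) + a_R*G(mirror(c))
}

# truncated-at-zero normal draw
rnorm_pos <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

draw_amplitudes <- function(class, spec) {
  ap <- spec$amplitude_params
  switch(class,
    left = c(rnorm_pos(1, ap$lateralised$dom[1], ap$lateralised$dom[2]),
             rnorm_pos(1, ap$lateralised$nondom[1], ap$lateralised$nondom[2])),
    right = rev(c(rnorm_pos(1, ap$lateralised$dom[1], ap$lateralised$dom[2]),
                  rnorm_pos(1, ap$lateralised$nondom[1], ap$lateralised$nondom[2]))),
    bilateral = rnorm_pos(2, ap$bilateral$both[1], ap$bilateral$both[2]),
    inconclusive = rnorm_pos(2, ap$inconclusive$both[1], ap$inconclusive$both[2]),
    stop("invalid class: ", class))
}

# separable Gaussian smoothing; fwhm in mm
smooth_volume <- function(vol, fwhm, voxel_mm) {
  if (fwhm <= 0) return(vol)
  sd_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(3 * sd_vox))
  k <- stats::dnorm(-r:r, sd = sd_vox)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (off in -r:r) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      out <- out + k[off + r + 1L] * m[idx, , drop = FALSE]
    }
    aperm(array(out, dim = d[perm]), order(perm))
  }
  for (ax in 1:3) vol <- conv_axis(vol, ax)
  vol
}

#' Generate one synthetic case
#'
#' Draws per-class left/right peak amplitudes, builds the homotopic blob
#' field plus background noise (and optional task-negative midline blobs),
#' and records the ground truth. The map emulates a single-subject
#' "task > rest" t-map.
#'
#' @param class one of `"left"`, `"bilateral"`, `"right"`, `"inconclusive"`.
#' @param spec a [cohort_spec()].
#' @param seed integer seed for this case.
#' @param case_id,patient_id identifiers.
#' @param amplitude_factor multiplicative session-level strength jitter
#'   (1 = none).
#' @return A list of class `generated_case`: `map` ([stat_map]), `label`,
#'   `true_lambda`, `true_s`, `a_left`, `a_right`, `patient_id`, `seed`.
#' @export
generate_case <- function(class, spec, seed, case_id = "case",
                          patient_id = case_id, amplitude_factor = 1) {
  aff <- spec_affine(spec)
  vals <- with_local_seed(seed, {
    a <- draw_amplitudes(class, spec) * amplitude_factor
    vol <- array(stats::rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
                 dim = spec$grid_shape)
    for (i in seq_len(nrow(spec$node_centres))) {
      w <- spec$node_weights[i]
      vol <- vol + blob_field(spec, spec$node_centres[i, ], w * a[1], w * a[2])
    }
    if (spec$task_negative) {
      vol <- vol + blob_field(spec, c(0, -64, 40), -1.5, -1.5)   # precuneus
      vol <- vol + blob_field(spec, c(0, 48, -8), -1.5, -1.5)    # med-orbitofrontal
    }
    list(vol = smooth_volume(vol, spec$smooth_fwhm, spec$voxel_mm), a = a)
  })
  a <- vals$a
  structure(list(map = stat_map(vals$vol, aff, id = case_id), label = class,
                 true_lambda = if (sum(a) > 0) (a[1] - a[2]) / sum(a) else 0,
                 true_s = sum(a), a_left = a[1], a_right = a[2],
                 patient_id = patient_id, seed = seed),
            class = "generated_case")
}

#' Generate a labelled synthetic cohort
#'
#' Honours the per-class counts exactly (counts are session counts); a
#' fraction of patients contribute two sessions that share the class and
#' laterality regime but differ in overall strength by a lognormal factor.
#' Byte-identical under the same seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer master seed.
#' @return A list with `cases` (list of `generated_case`) and `cohort`
#'   (data frame: `case_id`, `patient_id`, `label`, `split` = "unassigned").
#' @export
generate_cohort <- function(spec, seed = 1L) {
  classes <- c("left", "bilateral", "right", "inconclusive")
  n_tot <- sum(spec$n_per_class[classes])
  if (n_tot == 0L) stop("zero total cases")
  plan <- with_local_seed(seed, {
    rows <- list()
    pid <- 0L
    for (cl in classes) {
      remaining <- spec$n_per_class[[cl]]
      while (remaining > 0L) {
        pid <- pid + 1L
        n_sess <- if (remaining >= 2L &&
                      stats::runif(1) < spec$p_two_sessions) 2L else 1L
        for (s in seq_len(n_sess)) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = sprintf("P%03d", pid), label = cl, session = s,
            case_seed = sample.int(2^30, 1),
            jitter = stats::rlnorm(1, 0, spec$session_jitter_sdlog))
        }
        remaining <- remaining - n_sess
      }
    }
    do.call(rbind, rows)
  })
  plan$case_id <- sprintf("%s_s%d", plan$patient_id, plan$session)
  cases <- lapply(seq_len(nrow(plan)), function(i)
    generate_case(plan$label[i], spec, seed = plan$case_seed[i],
                  case_id = plan$case_id[i], patient_id = plan$patient_id[i],
                  amplitude_factor = plan$jitter[i]))
  names(cases) <- plan$case_id
  cohort <- data.frame(case_id = plan$case_id, patient_id = plan$patient_id,
                       label = plan$label, split = "unassigned",
                       stringsAsFactors = FALSE)
  list(cases = cases, cohort = cohort)
}

#' Mirror a list of generated cases
#'
#' Flips every map across the mid-sagittal plane, swaps left/right labels,
#' and negates the true laterality; bilateral and inconclusive labels are
#' unchanged. Supports mirror-equivariance property checks.
#'
#' @param cases list of `generated_case` objects.
#' @return The mirrored list.
#' @export
mirror_cohort <- function(cases) {
  lapply(cases, function(cs) {
    cs$map <- mirror_map(cs$map)
    cs$label <- switch(cs$label, left = "right", right = "left", cs$label)
    cs$true_lambda <- -cs$true_lambda
    tmp <- cs$a_left; cs$a_left <- cs$a_right; cs$a_right <- tmp
    cs
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
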