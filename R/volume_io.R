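#' Construct a statistic map
#'
#' A `stat_map` bundles a 3-D lattice of voxel-wise statistics (t-units)
#' with its 4x4 voxel-index-to-world-mm affine and a case identifier. It is
#' the atomic unit every downstream stage consumes. World coordinates follow
#' the RAS convention: negative world x is the LEFT hemisphere. The sign is
#' always taken from the affine, never from array storage order.
#'
#' @param values numeric 3-D array of voxel statistics.
#' @param affine numeric 4x4 invertible matrix mapping 0-based voxel indices
#'   `(i, j, k, 1)` to world mm `(x, y, z, 1)`.
#' @param id case identifier string.
#' @return An object of class `stat_map` with fields `values`, `affine`, `id`.
#' @export
stat_map <- function(values, affine, id = "case") {
  values <- as.array(values)
  if (length(dim(values)) == 4L && dim(values)[4] == 1L)
    dim(values) <- dim(values)[1:3]
  if (length(dim(values)) != 3L)
    stop("stat_map values must be a 3-D lattice (or 4-D with singleton last dimension)")
  if (any(dim(values) < 1L)) stop("all lattice dimensions must be >= 1")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) stop("affine is not invertible")
  n_bad <- sum(!is.finite(values))
  if (n_bad > 0L) {
    warning(sprintf("%d non-finite voxel(s) replaced by 0", n_bad))
    values[!is.finite(values)] <- 0
  }
  structure(list(values = values, affine = affine, id = as.character(id)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map '%s'> %s lattice, t in [%.3g, %.3g]\n", x$id,
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read a statistic map from a NIfTI file
#'
#' Reads a NIfTI-1/2 volume (gzip accepted) as a [stat_map]. Non-finite
#' voxels are replaced by 0 with a warning giving their count. A trailing
#' singleton fourth dimension is dropped; true 4-D volumes are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param id case identifier; defaults to the file name without extension.
#' @return A [stat_map].
#' @export
read_stat_map <- function(path, id = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) > 3L) {
    extra <- dm[-(1:3)]
    if (any(extra != 1L))
      stop(sprintf("'%s' has %d non-singleton dimensions; expected a 3-D map",
                   path, sum(c(dm[1:3], extra) > 1L)))
    img <- array(as.numeric(img), dim = dm[1:3])
  }
  aff <- unclass(RNifti::xform(img))
  if (is.null(id))
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  stat_map(array(as.numeric(img), dim = dim(img)[1:3]), aff, id = id)
}

#' Write a statistic map to a NIfTI file
#'
#' @param map a [stat_map].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- sqrt(colSums(map$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(map$affine, code = 2L)
  RNifti::sform(img) <- structure(map$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write a binary mask to a NIfTI file
#'
#' Stores the mask as an integer 0/1 volume so a read-back reproduces the
#' input exactly.
#'
#' @param mask logical 3-D array.
#' @param affine 4x4 voxel-to-world affine.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, affine, path) {
  stopifnot(length(dim(mask)) == 3L)
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  affine <- as.matrix(affine)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#' @param path path to a mask volume.
#' @return logical 3-D array with the affine attached as attribute `affine`.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  m <- array(as.numeric(img) != 0, dim = dim(img)[1:3])
  attr(m, "affine") <- aff
  m
}

# World x-coordinate of each first-dimension lattice index (0-based voxel
# indices). Requires world x to depend on the first index only, i.e. no
# rotation/shear mixing x with j or k; oblique grids cannot be mirrored by a
# lattice permutation.
world_x_axis <- function(map) {
  aff <- map$affine
  nx <- dim(map$values)[1]
  jk <- max(abs(aff[1, 2:3]))
  if (jk > 1e-6 * max(abs(aff[1, 1]), 1))
    stop("grid is oblique in x: world x must depend on the first lattice index only")
  aff[1, 1] * (seq_len(nx) - 1) + aff[1, 4]
}

# Index permutation sending each x-slab to its mirror partner (world x -> -x).
# Errors if the grid is not mid-sagittally symmetric within tolerance.
mirror_permutation <- function(map, tol = NULL) {
  wx <- world_x_axis(map)
  step <- abs(map$affine[1, 1])
  if (is.null(tol)) tol <- 0.01 * step
  perm <- vapply(wx, function(x) {
    j <- which(abs(wx + x) <= tol)
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1))
  if (anyNA(perm))
    stop("grid is not mid-sagittally symmetric: some voxels have no mirror partner")
  perm
}

#' Partition a lattice into hemispheres by world x-coordinate
#'
#' Assigns each voxel to the left (world x < 0) or right (world x > 0)
#' hemisphere; voxels with `|x| < midline_eps` form a midline band excluded
#' from both. The default band is half a voxel width, so grids with a voxel
#' column exactly on x = 0 exclude that column.
#'
#' @param map a [stat_map] on a mid-sagittally symmetric grid.
#' @param midline_eps half-width of the midline exclusion band in mm;
#'   default half the voxel width in x.
#' @return A list with logical arrays `left`, `right`, `midline`
#'   (pairwise disjoint, covering the lattice), class `hemisphere_partition`.
#' @export
hemisphere_partition <- function(map, midline_eps = NULL) {
  mirror_permutation(map)  # reject asymmetric grids
  wx <- world_x_axis(map)
  if (is.null(midline_eps)) midline_eps <- abs(map$affine[1, 1]) / 2
  dm <- dim(map$values)
  side <- ifelse(abs(wx) < midline_eps, 0L, sign(wx))
  expand <- function(s) array(rep(side == s, times = prod(dm[2:3])), dim = dm)
  structure(list(left = expand(-1L), right = expand(1L), midline = expand(0L)),
            class = "hemisphere_partition")
}

#' Mirror a map across the mid-sagittal plane
#'
#' Returns the map whose value at world `(x, y, z)` equals the input value at
#' `(-x, y, z)`; the affine is unchanged, so mirroring is a pure lattice
#' permutation. Mirroring twice recovers the input exactly.
#'
#' @param map a [stat_map] on a mid-sagittally symmetric grid.
#' @return The mirrored [stat_map].
#' @export
mirror_map <- function(map) {
  perm <- mirror_permutation(map)
  out <- map
  out$values <- map$values[perm, , , drop = FALSE]
  out
}

#' Mirror a logical mask across the mid-sagittal plane
#' @param mask logical 3-D array.
#' @param map the [stat_map] (or any map on the same grid) supplying the affine.
#' @return The mirrored logical array.
#' @export
mirror_mask <- function(mask, map) {
  perm <- mirror_permutation(map)
  mask[perm, , , drop = FALSE]
}
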