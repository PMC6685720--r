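#' Scalar FA volume and binary ROI mask containers
#'
#' Lightweight containers for 3-D scalar fractional-anisotropy fields and
#' binary region masks on a shared voxel grid in a common standard space.
#' The affine maps zero-based voxel indices to world (mm) coordinates,
#' with left-right along world x (RAS convention: +x is the right side).
#'
#' @param data A 3-D numeric array. For `fa_volume()`, values must lie in
#'   \[0, 1\]; for `roi_mask()`, values are binarized at `threshold`
#'   (probabilistic atlas masks are thresholded at 0.5 by default).
#' @param affine A 4x4 voxel-to-world affine matrix. Defaults to 2 mm
#'   isotropic voxels centered on the grid, so the world-x midline runs
#'   through the grid center.
#' @param label Free-text label.
#' @param space Space label (default `"MNI152"`).
#' @return An object of class `fa_volume` or `roi_mask`: a list with
#'   elements `data`, `affine`, `label`, `space`.
#' @export
fa_volume <- function(data, affine = default_affine(dim(data)),
                      label = "FA", space = "MNI152") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(!is.finite(data))) abort("FA volume contains non-finite values")
  if (any(data < 0 | data > 1)) {
    abort("FA values must lie in [0, 1]")
  }
  check_affine(affine)
  structure(list(data = data, affine = affine, label = label, space = space),
            class = "fa_volume")
}

#' @rdname fa_volume
#' @param threshold Binarization cut for non-binary (probabilistic) input
#'   (default 0.5): voxels with `data >= threshold` enter the mask.
#' @export
roi_mask <- function(data, affine = default_affine(dim(data)),
                     label = "ROI", space = "MNI152", threshold = 0.5) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(!is.finite(data))) abort("mask contains non-finite values")
  bin <- array(as.numeric(data >= threshold), dim = dim(data))
  check_affine(affine)
  structure(list(data = bin, affine = affine, label = label, space = space),
            class = "roi_mask")
}

#' @keywords internal
#' @noRd
default_affine <- function(grid_shape, voxel_mm = 2) {
  stopifnot(length(grid_shape) == 3)
  aff <- diag(c(rep(voxel_mm, 3), 1))
  # center the grid so the world origin sits mid-volume
  aff[1:3, 4] <- -voxel_mm * (grid_shape - 1) / 2
  aff
}

#' @keywords internal
#' @noRd
check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)) ||
      any(!is.finite(affine))) {
    abort("affine must be a finite 4x4 matrix")
  }
  invisible(affine)
}

#' @export
print.fa_volume <- function(x, ...) {
  cat("<fa_volume> ", paste(dim(x$data), collapse = " x "),
      " grid, label: ", x$label, ", space: ", x$space, "\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$data), collapse = " x "),
      " grid, ", sum(x$data), " voxels, label: ", x$label, "\n", sep = "")
  invisible(x)
}

#' @keywords internal
#' @noRd
check_same_grid <- function(a, b, tol = 1e-6) {
  if (!all(dim(a$data) == dim(b$data))) {
    abort(sprintf("grid shapes differ: %s vs %s",
                  paste(dim(a$data), collapse = "x"),
                  paste(dim(b$data), collapse = "x")))
  }
  if (max(abs(a$affine - b$affine)) > tol) {
    abort("voxel-to-world transforms differ beyond tolerance")
  }
  invisible(TRUE)
}

#' Intersect two binary masks
#'
#' Voxelwise logical AND (equivalently, the product of the binary masks):
#' the standard construction of a tract-within-structure ROI, e.g. the
#' corticospinal tract restricted to the midbrain.
#'
#' @param a,b `roi_mask` objects on identical grids.
#' @return A `roi_mask` whose voxels are 1 where both inputs are 1.
#' @export
intersect_masks <- function(a, b) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  check_same_grid(a, b)
  out <- a
  out$data <- a$data * b$data
  out$label <- paste(a$label, b$label, sep = " & ")
  out
}

#' Split a mask into left and right hemispheres
#'
#' Classifies voxels by their world x coordinate: `x < midline` is left,
#' `x > midline` is right. Voxels exactly on the midline plane are
#' excluded from both hemispheres (their count is reported as an
#' attribute) to avoid double counting.
#'
#' @param mask A `roi_mask`.
#' @param midline_world_x World x coordinate (mm) of the mid-sagittal
#'   plane (default 0).
#' @return A list with elements `left`, `right` (both `roi_mask`) and
#'   `n_midline`, the count of in-mask voxels dropped on the midline.
#' @export
hemisphere_split <- function(mask, midline_world_x = 0) {
  stopifnot(inherits(mask, "roi_mask"))
  d <- dim(mask$data)
  A <- mask$affine
  if (all(abs(A[1, 1:3]) < 1e-12)) {
    abort("degenerate transform: world x does not vary across the grid")
  }
  i <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  j <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  wx <- A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4]
  left <- right <- mask
  left$data <- array(mask$data * (wx < midline_world_x), dim = d)
  right$data <- array(mask$data * (wx > midline_world_x), dim = d)
  left$label <- paste(mask$label, "(left)")
  right$label <- paste(mask$label, "(right)")
  n_mid <- sum(mask$data[abs(wx - midline_world_x) == 0] > 0)
  list(left = left, right = right, n_midline = n_mid)
}

#' Mean FA within a mask
#'
#' Arithmetic mean of the volume's values over the mask's voxels — the
#' per-participant ROI summary used for all downstream statistics.
#'
#' @param volume An `fa_volume`.
#' @param mask A non-empty `roi_mask` on the same grid.
#' @return A scalar mean FA.
#' @export
mean_in_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "fa_volume"), inherits(mask, "roi_mask"))
  check_same_grid(volume, mask)
  n <- sum(mask$data)
  if (n == 0) {
    abort("mask is empty: ROI definition or registration likely failed")
  }
  sum(volume$data * mask$data) / n
}

#' FA change score
#'
#' Signed post-minus-pre difference: negative values indicate loss of
#' white-matter integrity. Vectorized over cohorts.
#'
#' @param pre,post FA values in \[0, 1\].
#' @return `post - pre`.
#' @export
delta_fa <- function(pre, post) {
  stopifnot(all(pre >= 0 & pre <= 1, na.rm = TRUE),
            all(post >= 0 & post <= 1, na.rm = TRUE))
  post - pre
}

#' Extract per-hemisphere mean FA for one participant
#'
#' @param volume An `fa_volume`.
#' @param left_mask,right_mask Hemisphere `roi_mask` objects (e.g. from
#'   [hemisphere_split()]).
#' @param player_id,timepoint Identifiers copied into the output.
#' @return A tibble with one row per hemisphere: `player_id`,
#'   `timepoint`, `hemisphere`, `mean_fa`, `n_voxels`.
#' @export
extract_roi_fa <- function(volume, left_mask, right_mask,
                           player_id = NA_character_,
                           timepoint = NA_character_) {
  tibble(
    player_id = player_id,
    timepoint = timepoint,
    hemisphere = c("left", "right"),
    mean_fa = c(mean_in_mask(volume, left_mask),
                mean_in_mask(volume, right_mask)),
    n_voxels = c(sum(left_mask$data), sum(right_mask$data))
  )
}

#' Read / write NIfTI volumes and masks
#'
#' Thin wrappers around RNifti for volumes already registered to a common
#' standard space.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param label Label attached to the returned object.
#' @return `read_fa_volume()` returns an `fa_volume`; `read_roi_mask()` a
#'   `roi_mask`.
#' @export
read_fa_volume <- function(path, label = basename(path)) {
  img <- RNifti::readNifti(path)
  fa_volume(array(as.numeric(img), dim = dim(img)),
            affine = unclass(RNifti::xform(img)), label = label)
}

#' @rdname read_fa_volume
#' @param threshold Binarization cut for probabilistic masks (default 0.5).
#' @export
read_roi_mask <- function(path, label = basename(path), threshold = 0.5) {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img), dim = dim(img)),
           affine = unclass(RNifti::xform(img)), label = label,
           threshold = threshold)
}

#' @rdname read_fa_volume
#' @param x An `fa_volume` or `roi_mask`.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "fa_volume") || inherits(x, "roi_mask"))
  img <- RNifti::asNifti(x$data)
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
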