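#' Connected-threshold region growing
#'
#' Grows the set of voxels connected to any seed through voxels whose HU is
#' strictly below `threshold_hu`. A seed whose own HU is at or above the
#' threshold contributes nothing. Default connectivity is 6 (faces), which
#' resists diagonal leakage through one-voxel wall gaps; 26 is available.
#'
#' @param ct a [ct_volume].
#' @param seeds 1-based voxel index triple, or a matrix with one ijk triple
#'   per row.
#' @param threshold_hu inclusion threshold: voxels with `HU < threshold_hu`
#'   are eligible.
#' @param connectivity 6 or 26.
#' @return logical 3D array (the label map).
#' @export
grow_region <- function(ct, seeds, threshold_hu, connectivity = 6) {
  stopifnot_ct(ct)
  seeds <- rbind(seeds)
  if (nrow(seeds) == 0L) stop("empty seed list", call. = FALSE)
  storage.mode(seeds) <- "integer"
  d <- ct_dim(ct)
  for (r in seq_len(nrow(seeds)))
    if (!in_bounds(ct, seeds[r, ])) stop("seed out of bounds", call. = FALSE)
  res <- .rg_grow_cpp(as.numeric(ct$voxels), d, seeds,
                      as.numeric(threshold_hu), as.integer(connectivity))
  array(res, dim = d)
}

#' Growth ratio between two consecutive segmentations
#'
#' `g = n_voxels / n_voxels_prev`, the relative increase of the segmented
#' voxel count between two consecutive thresholds; a sudden jump signals
#' leakage into the parenchyma.
#'
#' @param n_voxels voxel count of the current segmentation.
#' @param n_voxels_prev voxel count of the previous accepted segmentation;
#'   must be positive.
#' @export
growth_ratio <- function(n_voxels, n_voxels_prev) {
  if (n_voxels_prev <= 0)
    stop("growth ratio undefined: previous segmentation is empty", call. = FALSE)
  n_voxels / n_voxels_prev
}

#' Growth-ratio leakage test
#'
#' Flags leakage when the growth ratio strictly exceeds `g_max` (default 1.6);
#' a ratio of exactly `g_max` is not flagged.
#'
#' @param g growth ratio from [growth_ratio()].
#' @param g_max leak cut-off.
#' @export
is_ratio_leak <- function(g, g_max = 1.6) {
  g > g_max
}

#' Reconstruction-kernel group
#'
#' Maps a kernel label (case-insensitive) to one of four groups used by the
#' voxel-budget lookup: `smooth_std` (GE Standard, Siemens B20f/B30f,
#' Philips B/C, Toshiba FC10/FC12), `lung_sharp` (GE Lung, Siemens B50f,
#' Toshiba FC50/FC52), `very_sharp` (Siemens B60f/B70f/B70s, Philips D) and
#' `other` for anything else, including an empty/unknown kernel.
#'
#' @param kernel_name kernel label, e.g. `"B30f"`.
#' @export
kernel_group <- function(kernel_name) {
  k <- tolower(trimws(as.character(kernel_name)[1]))
  if (k %in% c("standard", "std", "b20f", "b30f", "b", "c", "fc10", "fc12"))
    "smooth_std"
  else if (k %in% c("lung", "b50f", "fc50", "fc52"))
    "lung_sharp"
  else if (k %in% c("b60f", "b70f", "b70s", "d"))
    "very_sharp"
  else "other"
}

# Percentage table: per kernel group, per slice-count band, a step function
# of the trachea voxel count N. Bands are upper-inclusive: the entry
# (breaks = b, pct = p) means pct = p[m] for the smallest m with N <= b[m],
# and p[length(p)] when N exceeds every break.
.pct_table <- list(
  smooth_std = list(
    list(smax = 300, breaks = c(2e4, 5e4),   pct = c(0.9, 0.75, 0.5)),
    list(smax = 400, breaks = c(8.5e4, 1e5), pct = c(0.9, 0.75, 0.5)),
    list(smax = Inf, breaks = c(14e4, 17e4), pct = c(0.9, 0.75, 0.5))
  ),
  lung_sharp = list(
    list(smax = 300, breaks = c(1e4, 3.5e4, 7.5e4, 8.5e4),
         pct = c(0.8, 0.5, 0.35, 0.3, 0.2)),
    list(smax = 400, breaks = c(8.5e4, 1e5, 12e4),
         pct = c(0.7, 0.5, 0.35, 0.2)),
    list(smax = Inf, breaks = c(8e4, 11.5e4, 14e4),
         pct = c(0.75, 0.5, 0.35, 0.2))
  ),
  very_sharp = list(
    list(smax = 300, breaks = c(3e4, 6e4, 9e4), pct = c(0.8, 0.6, 0.5, 0.35)),
    list(smax = Inf, breaks = c(5e4, 8e4, 12e4), pct = c(0.8, 0.6, 0.4, 0.25))
  ),
  other = list(
    list(smax = 300, breaks = c(4e4, 9e4),  pct = c(0.8, 0.55, 0.35)),
    list(smax = Inf, breaks = c(7e4, 13e4), pct = c(0.8, 0.55, 0.3))
  )
)

#' Trachea-voxel percentage for the per-lung budget
#'
#' Looks up the percentage of trachea voxels allotted to one lung's
#' segmentation, as a function of the reconstruction kernel group, the number
#' of axial slices S, and the trachea voxel count N. Band boundaries are
#' inclusive on the upper side (e.g. N = 5e4 still falls in the
#' "N <= 5e4" band). Unknown kernels fall back to the generic group.
#'
#' @param kernel_name reconstruction-kernel label.
#' @param slice_count number of axial slices S (>= 1).
#' @param n_trachea trachea voxel count N (>= 0).
#' @return the percentage as a fraction in (0, 1).
#' @export
trachea_percentage <- function(kernel_name, slice_count, n_trachea) {
  if (slice_count < 1) stop("slice_count must be >= 1", call. = FALSE)
  if (n_trachea < 0) stop("n_trachea must be >= 0", call. = FALSE)
  bands <- .pct_table[[kernel_group(kernel_name)]]
  row <- NULL
  for (b in bands) if (slice_count <= b$smax) { row <- b; break }
  m <- findInterval(n_trachea, row$breaks, left.open = TRUE) + 1L
  row$pct[m]
}

#' Maximum allowed voxels for one lung's segmentation
#'
#' The per-lung voxel budget: `round(trachea_percentage(...) * n_trachea)`.
#'
#' @inheritParams trachea_percentage
#' @export
max_voxels_allowed <- function(kernel_name, slice_count, n_trachea) {
  round(trachea_percentage(kernel_name, slice_count, n_trachea) * n_trachea)
}

#' Bounding-box extents of a label
#'
#' Extents (in voxels) of the set voxels along each axis, optionally
#' restricted to a crop window.
#'
#' @param label logical 3D array.
#' @param window optional [crop_region] restricting the measurement.
#' @return named numeric vector `c(width_i, length_j, height_k)`.
#' @export
label_extent <- function(label, window = NULL) {
  if (!is.null(window)) label <- crop_array(label, window)
  w <- which(label, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty label", call. = FALSE)
  ext <- unname(apply(w, 2, function(v) diff(range(v)) + 1L))
  c(width_i = ext[1], length_j = ext[2], height_k = ext[3])
}

#' Morphological hole filling
#'
#' Sets every background voxel that is not 6-connected to the grid border
#' through background. Idempotent; never decreases the voxel count.
#'
#' @param label logical 3D array.
#' @export
fill_holes <- function(label) {
  array(.fill_holes_cpp(as.logical(label), dim(label)), dim = dim(label))
}

#' Morphological dilation by a Euclidean ball
#'
#' `radius_vox = 1` uses the 6-neighbour cross (a single voxel dilates to 7);
#' `radius_vox = 0` is the identity.
#'
#' @param label logical 3D array.
#' @param radius_vox ball radius in voxels (>= 0).
#' @export
dilate <- function(label, radius_vox = 1) {
  if (radius_vox < 0) stop("radius_vox must be >= 0", call. = FALSE)
  if (radius_vox == 0) return(label)
  array(.dilate_cpp(as.logical(label), dim(label), as.integer(radius_vox)),
        dim = dim(label))
}

# connected components, internal wrappers -----------------------------------

cc_label <- function(mask, connectivity = 26) {
  array(.cc_label_cpp(as.logical(mask), dim(mask), as.integer(connectivity)),
        dim = dim(mask))
}

# 2D 8-connectivity components of one axial slice, as a matrix of labels
slice_components <- function(label, k) {
  sl <- label[, , k, drop = FALSE]
  lab <- .cc_label_cpp(as.logical(sl), dim(sl), 26L)
  matrix(lab, nrow = dim(label)[1])
}
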