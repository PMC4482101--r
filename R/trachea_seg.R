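#' Crop region
#'
#' Axis-aligned box of voxel indices, 1-based with inclusive bounds.
#'
#' @param lo,hi integer triples, `lo <= hi` component-wise.
#' @export
crop_region <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(lo > hi)) stop("crop region with lo > hi", call. = FALSE)
  if (any(lo < 1L)) stop("crop region outside grid", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "crop_region")
}

#' @export
print.crop_region <- function(x, ...) {
  cat(sprintf("<crop_region> i %d..%d, j %d..%d, k %d..%d\n",
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3]))
  invisible(x)
}

crop_extent <- function(crop) crop$hi - crop$lo + 1L

crop_array <- function(arr, crop) {
  arr[crop$lo[1]:crop$hi[1], crop$lo[2]:crop$hi[2], crop$lo[3]:crop$hi[3],
      drop = FALSE]
}

crop_ct <- function(ct, crop) {
  sub <- crop_array(ct$voxels, crop)
  out <- ct
  out$voxels <- sub
  out$origin <- as.numeric(ijk_to_physical(ct, crop$lo))
  out$meta$slice_count <- dim(sub)[3]
  out
}

# embed a label computed on a crop back into the full grid
uncrop_label <- function(label, crop, full_dim) {
  out <- array(FALSE, dim = full_dim)
  out[crop$lo[1]:crop$hi[1], crop$lo[2]:crop$hi[2], crop$lo[3]:crop$hi[3]] <-
    label
  out
}

contains_point <- function(crop, ijk) all(ijk >= crop$lo) && all(ijk <= crop$hi)

#' Initial trachea crop
#'
#' Crops the volume around the trachea before the first segmentation: full
#' extent along `i` (the volume width), a fixed physical extent (default
#' 40 mm) centered on the seed along `j` (an average tracheal caliber with
#' margin), and along `k` from the seed's slice through a configurable
#' fraction of the remaining inferior extent. Clipped to the grid.
#'
#' @param ct a [ct_volume].
#' @param seed 1-based seed voxel index (inside the trachea).
#' @param config an [airway_config].
#' @return a [crop_region] containing the seed.
#' @export
initial_crop <- function(ct, seed, config = airway_config()) {
  stopifnot_ct(ct)
  seed <- resolve_seed(ct, seed)
  d <- ct_dim(ct)
  half_j <- ceiling(config$crop_length_mm / 2 / ct$spacing[2])
  j_lo <- max(1L, seed[2] - half_j)
  j_hi <- min(d[2], seed[2] + half_j)
  k_lo <- seed[3]
  k_hi <- min(d[3], seed[3] +
                as.integer(floor(config$crop_height_fraction * (d[3] - seed[3]))))
  crop_region(c(1L, j_lo, k_lo), c(d[1], j_hi, k_hi))
}

# width/length of a label near the seed: bounding-box extents within an
# axial slab of guard_slab_slices slices centered on the seed slice
.guard_sizes <- function(label, seed_k, slab) {
  half <- slab %/% 2L
  nk <- dim(label)[3]
  ks <- max(1L, seed_k - half):min(nk, seed_k + half)
  sub <- label[, , ks, drop = FALSE]
  w <- which(sub, arr.ind = TRUE)
  if (nrow(w) == 0L) return(c(0L, 0L))
  c(diff(range(w[, 1])) + 1L, diff(range(w[, 2])) + 1L)
}

.new_step <- function(threshold_hu, n_voxels, g = NA_real_, accepted, reason) {
  data.frame(threshold_hu = threshold_hu, n_voxels = n_voxels, g = g,
             accepted = accepted, reason = reason)
}

.mk_trace <- function(steps, final_threshold_hu, final_label) {
  steps <- do.call(rbind, steps)
  rownames(steps) <- NULL
  structure(list(steps = steps, final_threshold_hu = final_threshold_hu,
                 final_label = final_label),
            class = "threshold_trace")
}

#' @export
print.threshold_trace <- function(x, ...) {
  cat(sprintf("<threshold_trace> %d steps, final threshold %d HU, %d voxels\n",
              nrow(x$steps), x$final_threshold_hu, sum(x$final_label)))
  print(x$steps)
  invisible(x)
}

#' Iterative-threshold trachea segmentation
#'
#' Implements the trachea schedule on the cropped volume. Starting at
#' `start_hu` (-900 HU), the label's width (along `i`) and length (along
#' `j`) are measured near the seed; leakage is declared when the length
#' reaches 2/3 of the crop length or the width 1/4 of the crop width, in
#' which case the threshold is lowered in 20 HU steps until clean. An empty
#' grow first retries each of the seed's 26 neighbours, then raises the
#' threshold in 50 HU steps. The improvement loop then raises the threshold
#' (+50 HU, or +10 HU once leakage has occurred), subtracts old from new
#' label, and compares the difference's width/length against the stored
#' clean sizes; an oversized difference is a leak answered by 10 HU
#' decrements, and a difference shorter than 1/3 of the crop height ends the
#' loop as converged. The threshold never exceeds `cap_hu` (-800 HU).
#'
#' @param ct the full [ct_volume].
#' @param crop a [crop_region] from [initial_crop()] or [refine_crop()].
#' @param seed 1-based seed voxel index, inside `crop`.
#' @param config an [airway_config].
#' @return a `threshold_trace`; its `final_label` is on the full grid.
#' @export
segment_trachea <- function(ct, crop, seed, config = airway_config()) {
  stopifnot_ct(ct)
  seed <- resolve_seed(ct, seed)
  if (!contains_point(crop, seed)) stop("seed outside crop", call. = FALSE)
  sub <- crop_ct(ct, crop)
  sd_loc <- seed - crop$lo + 1L
  ext <- crop_extent(crop)
  len_limit <- 2 / 3 * ext[2]
  wid_limit <- 1 / 4 * ext[1]
  steps <- list()
  fail <- function(thr)
    stop(sprintf("trachea segmentation failed: no clean non-empty label (last threshold %d HU)",
                 thr), call. = FALSE)
  grow <- function(thr, at = sd_loc)
    grow_region(sub, at, thr, config$connectivity)

  # --- initial non-empty segmentation -------------------------------------
  thr <- config$start_hu
  lab <- NULL
  repeat {
    lab <- grow(thr)
    if (sum(lab) > 0L) break
    # retry from the 26 neighbours of the seed
    found <- FALSE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- sd_loc + c(dx, dy, dz)
      if (any(nb < 1L) || any(nb > dim(sub$voxels))) next
      lab <- grow(thr, nb)
      if (sum(lab) > 0L) { found <- TRUE; break }
    }
    if (found) break
    steps[[length(steps) + 1L]] <- .new_step(thr, 0L, NA, FALSE, "empty")
    if (thr >= config$cap_hu) fail(thr)
    thr <- min(thr + config$step_up_clean, config$cap_hu)
  }

  # --- geometric leak check at the initial threshold ----------------------
  leak_seen <- FALSE
  repeat {
    gs <- .guard_sizes(lab, sd_loc[3], config$guard_slab_slices)
    if (gs[2] >= len_limit || gs[1] >= wid_limit) {
      steps[[length(steps) + 1L]] <- .new_step(thr, sum(lab), NA, FALSE,
                                               "leak_geometry")
      leak_seen <- TRUE
      thr <- thr - config$step_down_initial
      if (thr < config$floor_hu) fail(thr)
      lab <- grow(thr)
      if (sum(lab) == 0L) fail(thr)
    } else {
      steps[[length(steps) + 1L]] <- .new_step(thr, sum(lab), NA, TRUE, "ok")
      break
    }
  }
  stored <- .guard_sizes(lab, sd_loc[3], config$guard_slab_slices)

  finalize <- function(thr, lab) {
    full <- uncrop_label(lab, crop, ct_dim(ct))
    .mk_trace(steps, thr, full)
  }

  # --- improvement loop ---------------------------------------------------
  while (thr < config$cap_hu) {
    step <- if (leak_seen) config$step_up_after_leak else config$step_up_clean
    thr2 <- min(thr + step, config$cap_hu)
    lab2 <- grow(thr2)
    diff <- lab2 & !lab
    if (!any(diff)) {
      steps[[length(steps) + 1L]] <- .new_step(thr2, sum(lab2), NA, TRUE,
                                               "converged")
      return(finalize(thr2, lab2))
    }
    dext <- label_extent(diff)
    if (dext[1] > stored[1] || dext[2] > stored[2]) {
      # leak: decrement by 10 HU until a clean difference is found
      steps[[length(steps) + 1L]] <- .new_step(thr2, sum(lab2), NA, FALSE,
                                               "leak_geometry")
      leak_seen <- TRUE
      thrf <- thr2 - config$step_down_final
      while (thrf > thr) {
        labf <- grow(thrf)
        difff <- labf & !lab
        ok <- TRUE
        if (any(difff)) {
          de <- label_extent(difff)
          ok <- !(de[1] > stored[1] || de[2] > stored[2])
        }
        if (ok) {
          steps[[length(steps) + 1L]] <- .new_step(thrf, sum(labf), NA, TRUE,
                                                   "ok")
          return(finalize(thrf, labf))
        }
        steps[[length(steps) + 1L]] <- .new_step(thrf, sum(labf), NA, FALSE,
                                                 "leak_geometry")
        thrf <- thrf - config$step_down_final
      }
      return(finalize(thr, lab))
    }
    if (dext[3] < crop_extent(crop)[3] / 3 &&
        identical(config$height_rule, "converge")) {
      steps[[length(steps) + 1L]] <- .new_step(thr2, sum(lab2), NA, TRUE,
                                               "converged")
      return(finalize(thr2, lab2))
    }
    if (dext[3] < crop_extent(crop)[3] / 3 &&
        identical(config$height_rule, "leak")) {
      steps[[length(steps) + 1L]] <- .new_step(thr2, sum(lab2), NA, FALSE,
                                               "leak_geometry")
      return(finalize(thr, lab))
    }
    # accepted improvement: update stored sizes and continue
    steps[[length(steps) + 1L]] <- .new_step(thr2, sum(lab2), NA, TRUE, "ok")
    lab <- lab2
    thr <- thr2
    stored <- .guard_sizes(lab, sd_loc[3], config$guard_slab_slices)
  }
  steps[[length(steps) + 1L]] <- .new_step(thr, sum(lab), NA, TRUE,
                                           "cap_reached")
  finalize(thr, lab)
}

#' Locate the carina on a trachea label
#'
#' Scans axial slices from the seed towards the feet and returns the first
#' slice index at which the label's cross-section splits into at least two
#' 8-connected components of at least `min_component_area` voxels, the
#' previous slice having had exactly one.
#'
#' @param label logical 3D array (trachea label).
#' @param seed 1-based seed voxel index used for the segmentation.
#' @param config an [airway_config].
#' @return integer slice index `k`.
#' @export
find_carina <- function(label, seed, config = airway_config()) {
  seed <- as.integer(round(seed))
  nk <- dim(label)[3]
  if (!any(label[, , seed[3]]))
    stop("label empty at the seed slice", call. = FALSE)
  prev <- NA_integer_
  for (k in seed[3]:nk) {
    lab <- slice_components(label, k)
    cnt <- sum(tabulate(lab[lab > 0]) >= config$min_component_area)
    if (k > seed[3] && cnt >= 2L && identical(prev, 1L)) return(k)
    prev <- cnt
  }
  stop("carina not found: label never splits below the seed", call. = FALSE)
}

#' Refine the trachea crop using the carina position
#'
#' Shortens the crop along `k` to end a small margin below the carina and,
#' wherever the label's bounding box touches the crop's anterior/posterior
#' faces, enlarges the crop along `j` (by `refine_pad_mm` per side,
#' repeatedly) to accommodate bent tracheas.
#'
#' @param ct a [ct_volume] (for bounds and spacing).
#' @param crop the [crop_region] of the first segmentation.
#' @param carina_k carina slice from [find_carina()].
#' @param label the first-pass trachea label (full grid).
#' @param config an [airway_config].
#' @export
refine_crop <- function(ct, crop, carina_k, label, config = airway_config()) {
  stopifnot_ct(ct)
  if (carina_k < crop$lo[3] || carina_k > crop$hi[3])
    stop("carina outside crop", call. = FALSE)
  d <- ct_dim(ct)
  k_hi <- min(d[3], carina_k + config$carina_margin_slices)
  lo <- crop$lo; hi <- crop$hi
  hi[3] <- k_hi
  # label bbox within the shortened k range
  sub <- label[, , lo[3]:k_hi, drop = FALSE]
  w <- which(sub, arr.ind = TRUE)
  pad_j <- as.integer(ceiling(config$refine_pad_mm / ct$spacing[2]))
  if (nrow(w) > 0L) {
    jr <- range(w[, 2])                # label is on the full grid in i and j
    while (jr[1] <= lo[2] && lo[2] > 1L) lo[2] <- max(1L, lo[2] - pad_j)
    while (jr[2] >= hi[2] && hi[2] < d[2]) hi[2] <- min(d[2], hi[2] + pad_j)
  }
  crop_region(lo, hi)
}

#' Automatic bronchial seed placement
#'
#' On the carina slice, takes the two largest label components and returns
#' the voxel closest to each centroid within its component (the centroid of
#' a concave component may fall outside it). Seeds are ordered
#' (right lung, left lung) by increasing `i` (the `i` axis runs towards the
#' patient's left).
#'
#' @param label trachea label (full grid).
#' @param carina_k carina slice index.
#' @param config an [airway_config].
#' @return list with `right` and `left` 1-based voxel index triples.
#' @export
place_bronchial_seeds <- function(label, carina_k, config = airway_config()) {
  lab <- slice_components(label, carina_k)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= config$min_component_area)
  if (length(keep) < 2L)
    stop("label does not split into two components at the carina slice",
         call. = FALSE)
  keep <- keep[order(sizes[keep], decreasing = TRUE)][1:2]
  centers <- lapply(keep, function(cid) {
    w <- which(lab == cid, arr.ind = TRUE)
    ctr <- colMeans(w)
    d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2
    best <- w[which.min(d2), ]
    c(best[1], best[2], carina_k)
  })
  ord <- order(vapply(centers, `[`, 0, 1))
  list(right = as.integer(centers[[ord[1]]]),
       left = as.integer(centers[[ord[2]]]))
}

#' Full trachea stage: crop, segment, find carina, refine, re-segment
#'
#' Runs the four cropping/segmentation steps and the automatic bronchial
#' seed placement, returning everything the lung stage needs.
#'
#' @param ct a [ct_volume].
#' @param seed 1-based seed voxel index inside the trachea, above the carina.
#' @param config an [airway_config].
#' @return object of class `trachea_result`: `label` (full grid),
#'   `threshold_hu`, `carina_k`, `right_seed`, `left_seed`, `n_trachea`,
#'   `trace` (final pass), `first_trace`, `crop` (refined).
#' @export
segment_trachea_stage <- function(ct, seed, config = airway_config()) {
  seed <- resolve_seed(ct, seed)
  crop0 <- initial_crop(ct, seed, config)
  tr1 <- segment_trachea(ct, crop0, seed, config)
  carina_k <- find_carina(tr1$final_label, seed, config)
  crop1 <- refine_crop(ct, crop0, carina_k, tr1$final_label, config)
  tr2 <- segment_trachea(ct, crop1, seed, config)
  seeds <- place_bronchial_seeds(tr2$final_label, carina_k, config)
  structure(list(
    label = tr2$final_label,
    threshold_hu = tr2$final_threshold_hu,
    carina_k = carina_k,
    right_seed = seeds$right,
    left_seed = seeds$left,
    n_trachea = sum(tr2$final_label),
    trace = tr2,
    first_trace = tr1,
    crop = crop1
  ), class = "trachea_result")
}

#' @export
print.trachea_result <- function(x, ...) {
  cat(sprintf("<trachea_result> %d voxels at %d HU, carina at slice %d\n",
              x$n_trachea, x$threshold_hu, x$carina_k))
  cat(sprintf("  bronchial seeds: right (%s), left (%s)\n",
              paste(x$right_seed, collapse = ","),
              paste(x$left_seed, collapse = ",")))
  invisible(x)
}
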