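#' Mask half of the trachea and close the opposite main bronchus
#'
#' Returns a copy of the CT in which every trachea-label voxel on the half
#' distal from the lung being segmented (split by the sagittal plane through
#' the trachea centroid's `i`, rounded half-up) is set to 0 HU, and a
#' spherical plug of 0 HU blocks the opposite main bronchus a little below
#' the opposite bronchial seed. The plug radius adapts to the opposite
#' bronchus: equivalent-area radius of its carina-slice component plus
#' `plug_margin_vox` voxels, so the lumen is always fully covered. Growth
#' from the ipsilateral seed can thus climb the unmasked trachea half (and
#' reach any supra-carinal branch) but cannot enter the other lung.
#'
#' @param ct a [ct_volume].
#' @param trachea a `trachea_result` from [segment_trachea_stage()].
#' @param side_to_segment `"right"` or `"left"`.
#' @param config an [airway_config].
#' @return a [ct_volume] copy with the masked voxels at 0 HU.
#' @export
mask_half_trachea <- function(ct, trachea, side_to_segment = c("right", "left"),
                              config = airway_config()) {
  stopifnot_ct(ct)
  side_to_segment <- match.arg(side_to_segment)
  label <- trachea$label
  if (!any(label)) stop("empty trachea label", call. = FALSE)
  w <- which(label, arr.ind = TRUE)
  split_i <- floor(mean(w[, 1]) + 0.5)          # round half-up
  mask <- label
  if (side_to_segment == "right") {
    mask[w[w[, 1] <= split_i, , drop = FALSE]] <- FALSE  # keep left half set
  } else {
    mask[w[w[, 1] > split_i, , drop = FALSE]] <- FALSE   # keep right half set
  }
  out <- ct
  out$voxels[mask] <- 0
  # plug the opposite main bronchus
  opp <- if (side_to_segment == "right") trachea$left_seed else trachea$right_seed
  lab <- slice_components(label, trachea$carina_k)
  cid <- lab[opp[1], opp[2]]
  if (cid == 0L) {
    w2 <- which(lab > 0, arr.ind = TRUE)
    d2 <- (w2[, 1] - opp[1])^2 + (w2[, 2] - opp[2])^2
    cid <- lab[w2[which.min(d2), , drop = FALSE]]
  }
  area <- sum(lab == cid)
  r_vox <- sqrt(area / pi) + config$plug_margin_vox
  ctr <- c(opp[1], opp[2], opp[3] + config$plug_offset_slices)
  d <- ct_dim(ct)
  ctr[3] <- min(ctr[3], d[3])
  rr <- ceiling(r_vox)
  ir <- max(1L, ctr[1] - rr):min(d[1], ctr[1] + rr)
  jr <- max(1L, ctr[2] - rr):min(d[2], ctr[2] + rr)
  kr <- max(1L, ctr[3] - rr):min(d[3], ctr[3] + rr)
  for (k in kr) for (j in jr) for (i in ir) {
    if ((i - ctr[1])^2 + (j - ctr[2])^2 + (k - ctr[3])^2 <= r_vox^2)
      out$voxels[i, j, k] <- 0
  }
  out
}

#' Segment one lung's airway tree under leakage control
#'
#' Region growing from the bronchial seed on the masked volume, with an
#' iteratively increased threshold starting at `start_hu_lung` (-1100 HU;
#' empty grows raise it in 50 HU steps). A step is accepted iff the growth
#' ratio against the previous accepted step is at most `g_max` and the voxel
#' count stays within the budget; accepted steps raise the threshold by
#' 50 HU (10 HU once a rejection has occurred), capped at `cap_hu`. On a
#' rejection the threshold rolls back and is lowered in 10 HU steps until a
#' clean label is found, which becomes final.
#'
#' @param masked_ct the output of [mask_half_trachea()].
#' @param seed ipsilateral bronchial seed (1-based ijk).
#' @param budget maximum allowed voxels from [max_voxels_allowed()].
#' @param config an [airway_config].
#' @return a `threshold_trace` with `g` filled in for every tested step.
#' @export
segment_lung <- function(masked_ct, seed, budget, config = airway_config()) {
  stopifnot_ct(masked_ct)
  seed <- resolve_seed(masked_ct, seed)
  if (budget <= 0) stop("voxel budget must be positive", call. = FALSE)
  steps <- list()
  grow <- function(thr) grow_region(masked_ct, seed, thr, config$connectivity)
  clean <- function(n, n_prev) {
    g <- if (is.na(n_prev)) NA_real_ else growth_ratio(n, n_prev)
    reason <- "ok"
    if (!is.na(g) && is_ratio_leak(g, config$g_max)) reason <- "leak_ratio"
    else if (n > budget) reason <- "leak_budget"
    list(g = g, reason = reason, ok = reason == "ok")
  }
  mk <- function(thr, lab) .mk_trace(steps, thr, lab)

  # initial non-empty, in-budget segmentation
  thr <- config$start_hu_lung
  lab <- NULL
  repeat {
    lab <- grow(thr)
    n <- sum(lab)
    if (n == 0L) {
      steps[[length(steps) + 1L]] <- .new_step(thr, 0L, NA, FALSE, "empty")
      if (thr >= config$cap_hu)
        stop("lung segmentation failed: seed never grows below the cap",
             call. = FALSE)
      thr <- min(thr + config$step_up_clean, config$cap_hu)
      next
    }
    if (n > budget) {
      steps[[length(steps) + 1L]] <- .new_step(thr, n, NA, FALSE, "leak_budget")
      thr <- thr - config$step_down_final
      if (thr < config$floor_hu)
        stop("lung segmentation failed: no label within the voxel budget",
             call. = FALSE)
      next
    }
    steps[[length(steps) + 1L]] <- .new_step(thr, n, NA, TRUE, "ok")
    break
  }

  leak_seen <- FALSE
  while (thr < config$cap_hu) {
    step <- if (leak_seen) config$step_up_after_leak else config$step_up_clean
    thr2 <- min(thr + step, config$cap_hu)
    lab2 <- grow(thr2)
    v <- clean(sum(lab2), sum(lab))
    if (v$ok) {
      reason <- if (thr2 >= config$cap_hu) "cap_reached" else "ok"
      steps[[length(steps) + 1L]] <- .new_step(thr2, sum(lab2), v$g, TRUE,
                                               reason)
      lab <- lab2; thr <- thr2
      next
    }
    # rejection: roll back, decrement by 10 HU until clean, then stop
    steps[[length(steps) + 1L]] <- .new_step(thr2, sum(lab2), v$g, FALSE,
                                             v$reason)
    leak_seen <- TRUE
    thrf <- thr2 - config$step_down_final
    while (thrf > thr) {
      labf <- grow(thrf)
      vf <- clean(sum(labf), sum(lab))
      if (vf$ok) {
        steps[[length(steps) + 1L]] <- .new_step(thrf, sum(labf), vf$g, TRUE,
                                                 "ok")
        return(mk(thrf, labf))
      }
      steps[[length(steps) + 1L]] <- .new_step(thrf, sum(labf), vf$g, FALSE,
                                               vf$reason)
      thrf <- thrf - config$step_down_final
    }
    return(mk(thr, lab))
  }
  if (!nrow(do.call(rbind, steps)) ||
      tail(do.call(rbind, steps)$reason, 1) != "cap_reached")
    steps[[length(steps) + 1L]] <- .new_step(thr, sum(lab), NA, TRUE,
                                             "cap_reached")
  mk(thr, lab)
}

#' Merge the three labels into one airway label
#'
#' Voxelwise union of trachea, right-lung and left-lung labels, followed by
#' hole filling and a dilation (default radius 1) that reconnects parts
#' separated by thin gaps, yielding a single airway label.
#'
#' @param trachea_label,right_label,left_label logical 3D arrays on one grid.
#' @param config an [airway_config].
#' @return list with `union` (pre-dilation, after hole filling) and `merged`
#'   (final label).
#' @export
merge_and_close <- function(trachea_label, right_label, left_label,
                            config = airway_config()) {
  if (!identical(dim(trachea_label), dim(right_label)) ||
      !identical(dim(trachea_label), dim(left_label)))
    stop("label grids do not match", call. = FALSE)
  u <- trachea_label | right_label | left_label
  u <- fill_holes(u)
  merged <- dilate(u, config$dilate_radius_vox)
  ncomp <- max(cc_label(merged, 26))
  if (ncomp > 1L)
    warning(sprintf("merged airway label has %d disconnected components",
                    ncomp), call. = FALSE)
  list(union = u, merged = merged)
}
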