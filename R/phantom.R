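#' Parametric specification of a synthetic airway phantom
#'
#' Describes a symmetric dichotomous airway tree (trachea = generation 0)
#' embedded in noisy lung parenchyma inside a body shell, rasterized on a
#' regular HU grid. The defaults describe a desk-scale, three-level tree
#' (trachea and two bronchial generations) with adult-like tracheal caliber
#' (15 mm lumen diameter) on a 128x128x128 grid at 0.7 mm isotropic spacing,
#' reconstructed with a smooth standard kernel. Tree proportions are chosen
#' so that each lung-side region (half trachea plus one bronchial subtree)
#' stays inside the voxel budget that the kernel/slice lookup assigns to a
#' trachea of this size; the geometry is deliberately not Weibel-realistic.
#'
#' @param generations number of bifurcation levels below the trachea (>= 1).
#' @param root_radius_mm trachea lumen radius.
#' @param radius_ratio child/parent lumen radius factor per generation.
#' @param branch_length_mm per-generation branch length, recycled to
#'   `generations + 1` values (trachea first).
#' @param branch_angle_deg half-angle between the two children of a branch.
#' @param lumen_hu,wall_hu,parenchyma_hu,body_hu tissue HU model.
#' @param wall_thickness_mm airway wall thickness (>= 1 voxel after
#'   rasterization).
#' @param parenchyma_noise_sd Gaussian noise SD added to parenchyma voxels.
#' @param body_margin_vox thickness of the body shell at the grid border.
#' @param spacing,shape voxel spacing (mm) and grid extents.
#' @param defects list of `list(center = c(i, j, k), radius_mm = r)` spheres
#'   in which airway-wall voxels are replaced by parenchyma, opening
#'   threshold-dependent leakage channels (see [defect_on_branch()]).
#' @param supra_carinal add an accessory branch leaving the trachea above the
#'   carina, as in pig anatomy.
#' @param azimuth_deg rotation of the branching plane about the body axis.
#' @param kernel_name reconstruction-kernel label stored in the metadata.
#' @param rng_seed seed for the parenchyma noise field.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(generations = 2,
                         root_radius_mm = 7.5,
                         radius_ratio = 0.55,
                         branch_length_mm = c(30, 20, 12),
                         branch_angle_deg = 35,
                         lumen_hu = -1000,
                         wall_hu = -100,
                         wall_thickness_mm = 1.5,
                         parenchyma_hu = -850,
                         parenchyma_noise_sd = 30,
                         body_hu = 40,
                         body_margin_vox = 4,
                         spacing = c(0.7, 0.7, 0.7),
                         shape = c(128, 128, 128),
                         defects = list(),
                         supra_carinal = FALSE,
                         azimuth_deg = 0,
                         kernel_name = "B30f",
                         rng_seed = 1) {
  if (generations < 1) stop("generations must be >= 1", call. = FALSE)
  if (!(lumen_hu < parenchyma_hu && parenchyma_hu < body_hu))
    stop("HU model must satisfy lumen < parenchyma < body", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (wall_thickness_mm < max(spacing))
    stop("wall_thickness_mm must be at least one voxel", call. = FALSE)
  lens <- rep_len(branch_length_mm, generations + 1)
  structure(list(
    generations = as.integer(generations),
    root_radius_mm = root_radius_mm,
    radius_ratio = radius_ratio,
    branch_length_mm = lens,
    branch_angle_deg = branch_angle_deg,
    lumen_hu = lumen_hu, wall_hu = wall_hu,
    wall_thickness_mm = wall_thickness_mm,
    parenchyma_hu = parenchyma_hu,
    parenchyma_noise_sd = parenchyma_noise_sd,
    body_hu = body_hu, body_margin_vox = as.integer(body_margin_vox),
    spacing = spacing, shape = as.integer(shape),
    defects = defects,
    supra_carinal = isTRUE(supra_carinal),
    azimuth_deg = azimuth_deg,
    kernel_name = kernel_name,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
}

# supra-carinal accessory branch geometry (pig-like tracheal bronchus)
.acc_junction_frac <- 0.2
.acc_tilt_rad <- -75 * pi / 180
.acc_length_mm <- 10

# internal mm coordinates: x = (i-1)*sx, y = (j-1)*sy, z = (k-1)*sz
.phantom_root_mm <- function(spec) {
  ci <- floor(spec$shape[1] / 2)          # voxel index of the tree axis
  cj <- floor(spec$shape[2] / 2)
  k_top <- 6L
  c((ci - 1) * spec$spacing[1], (cj - 1) * spec$spacing[2],
    (k_top - 1) * spec$spacing[3])
}

#' Build the centerline tree of a phantom
#'
#' Constructs the symmetric binary tree of centerline segments described by a
#' [phantom_spec]. The trachea runs along `+k` (towards the feet); each
#' branch splits into two children tilted by `branch_angle_deg` to either
#' side within the branching plane. The accessory supra-carinal branch, when
#' requested, leaves the trachea laterally towards the patient's right, above
#' the carina.
#'
#' @param spec a [phantom_spec].
#' @return object of class `airway_tree`: a list with `branches` (data frame
#'   with one centerline segment per row: generation, side, endpoints in mm,
#'   radius and length) and `spec`.
#' @export
build_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  az <- spec$azimuth_deg * pi / 180
  a <- spec$branch_angle_deg * pi / 180
  dir_of <- function(tilt) c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))
  rows <- list()
  add <- function(id, parent, gen, side, p0, tilt, radius, len, type = "tree") {
    p1 <- p0 + dir_of(tilt) * len
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, parent = parent, generation = gen, side = side, type = type,
      x0 = p0[1], y0 = p0[2], z0 = p0[3],
      x1 = p1[1], y1 = p1[2], z1 = p1[3],
      tilt = tilt, radius_mm = radius, length_mm = len)
    p1
  }
  root0 <- .phantom_root_mm(spec)
  tip <- add(1L, NA_integer_, 0L, "T", root0, 0,
             spec$root_radius_mm, spec$branch_length_mm[1])
  queue <- list(list(id = 1L, gen = 0L, tilt = 0, tip = tip, side = "T"))
  next_id <- 2L
  while (length(queue)) {
    b <- queue[[1]]; queue <- queue[-1]
    if (b$gen >= spec$generations) next
    g <- b$gen + 1L
    r <- spec$root_radius_mm * spec$radius_ratio^g
    len <- spec$branch_length_mm[g + 1]
    for (sgn in c(-1, 1)) {
      side <- if (b$side == "T") (if (sgn < 0) "R" else "L") else b$side
      tilt <- b$tilt + sgn * a
      tip2 <- add(next_id, b$id, g, side, b$tip, tilt, r, len)
      queue[[length(queue) + 1L]] <- list(id = next_id, gen = g, tilt = tilt,
                                          tip = tip2, side = side)
      next_id <- next_id + 1L
    }
  }
  if (spec$supra_carinal) {
    # near-horizontal branch high on the trachea, towards the patient's
    # right, staying well above the recommended seed slice
    p0 <- root0 + c(0, 0, .acc_junction_frac * spec$branch_length_mm[1])
    add(next_id, 1L, 1L, "R", p0, .acc_tilt_rad,
        0.35 * spec$root_radius_mm, .acc_length_mm, type = "accessory")
  }
  branches <- do.call(rbind, rows)
  # bounds check: every tube (plus wall) must stay clear of the body shell;
  # the trachea's flat-cut superior end only needs room for its wall plate
  margin_mm <- (spec$body_margin_vox + 1) * spec$spacing +
    spec$wall_thickness_mm
  hi_mm <- (spec$shape - 1) * spec$spacing
  for (r in seq_len(nrow(branches))) {
    reach <- branches$radius_mm[r] + margin_mm
    zlo_reach <- if (is.na(branches$parent[r]))
      spec$wall_thickness_mm + spec$spacing[3] else reach[3]
    p <- rbind(c(branches$x0[r], branches$y0[r], branches$z0[r]),
               c(branches$x1[r], branches$y1[r], branches$z1[r]))
    lo_req <- c(reach[1], reach[2], zlo_reach)
    if (any(t(p) < lo_req) || any(t(p) > hi_mm - reach))
      stop(sprintf("phantom tree exceeds grid bounds at generation %d",
                   branches$generation[r]), call. = FALSE)
  }
  structure(list(branches = branches, spec = spec), class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  cat(sprintf("<airway_tree> %d branches (%d generations), total length %.1f mm\n",
              nrow(x$branches), max(x$branches$generation),
              sum(x$branches$length_mm)))
  invisible(x)
}

#' Analytic total tube volume of a phantom tree, in mm^3
#'
#' Sum of cylinder volumes `pi r^2 L` over all branches; junction overlap is
#' not subtracted, so the rasterized lumen is expected to fall slightly
#' below this value.
#'
#' @param tree an `airway_tree` from [build_tree()].
#' @export
analytic_tree_volume <- function(tree) {
  b <- tree$branches
  sum(pi * b$radius_mm^2 * b$length_mm)
}

# fill all voxels within `radius` mm of segment p0-p1 with material `code`
# (optionally only where the current material is in `only`)
.fill_capsule <- function(mat, spec, p0, p1, radius, code, only = NULL,
                          zmin = NULL, flat_end = FALSE) {
  sp <- spec$spacing; d <- dim(mat)
  lo <- pmax(1L, floor(pmin(p0, p1) / sp - radius / sp) + 1L)
  hi <- pmin(d, ceiling(pmax(p0, p1) / sp + radius / sp) + 1L)
  nx <- hi[1] - lo[1] + 1L; ny <- hi[2] - lo[2] + 1L; nz <- hi[3] - lo[3] + 1L
  xs <- (seq.int(lo[1], hi[1]) - 1) * sp[1]
  ys <- (seq.int(lo[2], hi[2]) - 1) * sp[2]
  zs <- (seq.int(lo[3], hi[3]) - 1) * sp[3]
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)
  v <- p1 - p0; L2 <- sum(v^2)
  if (L2 < 1e-12) {
    d2 <- (X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2
    traw <- 0
  } else {
    traw <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] +
               (Z - p0[3]) * v[3]) / L2
    t <- pmin(1, pmax(0, traw))
    d2 <- (X - p0[1] - t * v[1])^2 + (Y - p0[2] - t * v[2])^2 +
      (Z - p0[3] - t * v[3])^2
  }
  inside <- d2 <= radius^2
  if (flat_end) inside <- inside & traw <= 1
  if (!is.null(zmin)) inside <- inside & Z >= zmin - 1e-9
  sub <- mat[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  if (is.null(only)) sub[inside] <- code
  else sub[inside & (sub %in% only)] <- code
  mat[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  mat
}

#' Rasterize a phantom to a CT volume with ground truth
#'
#' Materials are laid down in order: parenchyma everywhere, a body shell at
#' the grid border, airway-wall capsules, then lumen capsules (so lumen wins
#' at junctions); finally each defect sphere converts wall voxels back to
#' parenchyma. Gaussian noise (`parenchyma_noise_sd`, seeded by `rng_seed`)
#' is added to parenchyma voxels only, so lumen and wall HU are exact and the
#' zero-noise phantom is fully deterministic tissue by tissue.
#'
#' @param spec a [phantom_spec].
#' @param tree optional pre-built [build_tree()] result.
#' @return list with `ct` (a [ct_volume]) and `truth` (class
#'   `airway_truth`: `graph`, `lumen_label`, `carina_slice`,
#'   `trachea_voxels`, `seed_ijk`).
#' @export
rasterize_phantom <- function(spec, tree = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(tree)) tree <- build_tree(spec)
  d <- spec$shape
  # materials: 0 parenchyma, 1 body, 2 wall, 3 lumen
  mat <- array(0L, dim = d)
  m <- spec$body_margin_vox
  if (m > 0) {
    idx_i <- c(seq_len(m), seq.int(d[1] - m + 1L, d[1]))
    idx_j <- c(seq_len(m), seq.int(d[2] - m + 1L, d[2]))
    mat[idx_i, , ] <- 1L
    mat[, idx_j, ] <- 1L
    mat[, , c(seq_len(min(2L, d[3])), seq.int(d[3] - 1L, d[3]))] <- 1L
  }
  b <- tree$branches
  # the trachea is cut flat at its superior end and sealed by a wall plate,
  # as in a scan that crops the airway; all other tube ends are rounded
  is_root <- is.na(b$parent)
  for (r in seq_len(nrow(b)))
    mat <- .fill_capsule(mat, spec,
                         c(b$x0[r], b$y0[r], b$z0[r]),
                         c(b$x1[r], b$y1[r], b$z1[r]),
                         b$radius_mm[r] + spec$wall_thickness_mm, 2L,
                         zmin = if (is_root[r])
                           b$z0[r] - spec$wall_thickness_mm else NULL)
  # terminal branch lumens are cut flat at the tip (the rounded wall capsule
  # seals them), so the rasterized branch length matches the analytic one
  is_terminal <- !(b$id %in% b$parent)
  for (r in seq_len(nrow(b)))
    mat <- .fill_capsule(mat, spec,
                         c(b$x0[r], b$y0[r], b$z0[r]),
                         c(b$x1[r], b$y1[r], b$z1[r]),
                         b$radius_mm[r], 3L,
                         zmin = if (is_root[r]) b$z0[r] else NULL,
                         flat_end = is_terminal[r])
  for (df in spec$defects) {
    ctr <- (as.numeric(df$center) - 1) * spec$spacing
    mat <- .fill_capsule(mat, spec, ctr, ctr, df$radius_mm, 0L, only = 2L)
  }
  hu <- array(spec$parenchyma_hu, dim = d)
  hu[mat == 1L] <- spec$body_hu
  hu[mat == 2L] <- spec$wall_hu
  hu[mat == 3L] <- spec$lumen_hu
  if (spec$parenchyma_noise_sd > 0) {
    # draw over the full grid so that two phantoms differing only in their
    # defect lists share the same noise realization voxel by voxel
    noise <- with_seed(spec$rng_seed,
                       function() rnorm(length(hu), 0, spec$parenchyma_noise_sd))
    noisy <- mat == 0L
    hu[noisy] <- hu[noisy] + noise[noisy]
  }
  hu <- pmin(pmax(hu, -3024), 3071)
  ct <- ct_volume(hu, spec$spacing, origin = c(0, 0, (d[3] - 1) * spec$spacing[3]),
                  kernel_name = spec$kernel_name, source = "synthetic")
  lumen <- mat == 3L
  carina <- .scan_first_split(lumen)
  k_seed <- if (spec$supra_carinal) {
    # below the accessory branch's inferior reach, above the carina
    jk <- 6 + .acc_junction_frac * spec$branch_length_mm[1] / spec$spacing[3]
    drop_mm <- .acc_length_mm * cos(.acc_tilt_rad) +
      0.35 * spec$root_radius_mm + spec$wall_thickness_mm
    as.integer(ceiling(jk + drop_mm / spec$spacing[3]) + 2L)
  } else 9L
  truth <- structure(list(
    graph = tree,
    lumen_label = lumen,
    carina_slice = carina,
    trachea_voxels = sum(lumen[, , seq_len(carina)]),
    seed_ijk = c(floor(d[1] / 2), floor(d[2] / 2), k_seed)
  ), class = "airway_truth")
  list(ct = ct, truth = truth)
}

# first axial slice at which the mask splits into >= 2 components while the
# previous occupied slice had exactly one
.scan_first_split <- function(mask, min_area = 1L) {
  nk <- dim(mask)[3]
  prev <- 0L
  for (k in seq_len(nk)) {
    lab <- slice_components(mask, k)
    cnt <- sum(tabulate(lab[lab > 0]) >= min_area)
    if (cnt >= 2L && prev == 1L) return(k)
    if (cnt >= 1L) prev <- cnt
  }
  NA_integer_
}

#' Place a leakage defect on a main bronchus wall
#'
#' Returns a defect descriptor (for `phantom_spec(defects = ...)`) centered
#' on the wall of the generation-1 branch of the requested side, at the given
#' fraction of its length, offset posteriorly to the wall mid-thickness.
#'
#' @param spec a [phantom_spec] (defects ignored).
#' @param side `"left"` or `"right"` main bronchus.
#' @param frac position along the branch, 0 (carina) to 1 (tip).
#' @param radius_mm defect sphere radius; should exceed `wall_thickness_mm`
#'   to open a through-wall channel.
#' @export
defect_on_branch <- function(spec, side = c("left", "right"), frac = 0.4,
                             radius_mm = 2.5) {
  side <- match.arg(side)
  tree <- build_tree(spec)
  b <- tree$branches
  want <- if (side == "left") "L" else "R"
  row <- b[b$generation == 1L & b$side == want & b$type == "tree", ][1, ]
  p0 <- c(row$x0, row$y0, row$z0); p1 <- c(row$x1, row$y1, row$z1)
  ctr <- p0 + frac * (p1 - p0) +
    c(0, row$radius_mm + spec$wall_thickness_mm / 2, 0)
  list(center = round(ctr / spec$spacing) + 1, radius_mm = radius_mm)
}

#' Degrade a CT volume (slice thickness, dose, kernel surrogates)
#'
#' Emulates thicker reconstruction by mean-pooling along `k` (slice count
#' divided, z-spacing multiplied by `slice_factor`), lower dose by adding
#' Gaussian noise, and a smoother kernel by Gaussian blurring.
#'
#' @param ct a [ct_volume].
#' @param slice_factor integer >= 1; axial downsampling factor.
#' @param noise_sd_add SD of additional Gaussian noise in HU.
#' @param smooth_sigma_mm Gaussian sigma in mm (0 = off).
#' @param rng_seed seed for the added-noise stream.
#' @export
degrade_ct <- function(ct, slice_factor = 1, noise_sd_add = 0,
                       smooth_sigma_mm = 0, rng_seed = 1) {
  stopifnot_ct(ct)
  f <- as.integer(slice_factor)
  d <- ct_dim(ct)
  if (f < 1 || f > d[3]) stop("slice_factor out of range", call. = FALSE)
  arr <- ct$voxels
  spacing <- ct$spacing
  if (f > 1) {
    nk2 <- d[3] %/% f
    a <- arr[, , seq_len(nk2 * f), drop = FALSE]
    pooled <- Reduce(`+`, lapply(seq_len(f), function(mm)
      a[, , seq(mm, nk2 * f, by = f), drop = FALSE])) / f
    arr <- pooled
    spacing[3] <- spacing[3] * f
  }
  if (noise_sd_add > 0) {
    n <- length(arr)
    arr <- arr + array(
      with_seed(rng_seed, function() rnorm(n, 0, noise_sd_add)),
      dim = dim(arr))
  }
  if (smooth_sigma_mm > 0) {
    sig <- smooth_sigma_mm / spacing
    arr <- array(.gauss_smooth_cpp(as.numeric(arr), dim(arr), sig),
                 dim = dim(arr))
  }
  arr <- pmin(pmax(arr, -3024), 3071)
  ct_volume(arr, spacing, ct$origin, kernel_name = ct$meta$kernel_name,
            source = "synthetic")
}
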