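# Shared fixtures, built once per test run (everything is deterministic).

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# the standard study phantom: 3 airway levels, 128^3, 0.7 mm, noise sd 30
std_phantom <- function() memo("std_phantom", function() {
  rasterize_phantom(phantom_spec())
})

std_segmentation <- function() memo("std_seg", function() {
  ph <- std_phantom()
  run_airway_pipeline(ph$ct, ph$truth$seed_ijk)
})

# same phantom with one wall defect behind the left main bronchus
defect_phantom <- function() memo("defect_phantom", function() {
  d <- defect_on_branch(phantom_spec(), "left", frac = 0.4, radius_mm = 2.5)
  rasterize_phantom(phantom_spec(defects = list(d)))
})

defect_segmentation <- function() memo("defect_seg", function() {
  ph <- defect_phantom()
  run_airway_pipeline(ph$ct, ph$truth$seed_ijk)
})

# small, fast phantom for module-level tests (two airway levels, 80^3)
small_spec <- function(...) {
  args <- utils::modifyList(
    list(generations = 1, root_radius_mm = 5, branch_length_mm = c(18, 12),
         radius_ratio = 0.6, shape = c(80, 80, 80)),
    list(...))
  do.call(phantom_spec, args)
}

small_phantom <- function() memo("small_phantom", function() {
  rasterize_phantom(small_spec())
})

# independent breadth-first flood-fill oracle for grow_region, pure R
bfs_grow_oracle <- function(vol, seed, thr, connectivity = 6) {
  d <- dim(vol)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  out <- array(FALSE, d)
  seed <- as.integer(seed)
  if (vol[seed[1], seed[2], seed[3]] >= thr) return(out)
  out[seed[1], seed[2], seed[3]] <- TRUE
  queue <- list(seed)
  while (length(queue)) {
    c0 <- queue[[1]]; queue <- queue[-1]
    for (r in seq_len(nrow(offs))) {
      p <- c0 + offs[r, ]
      if (any(p < 1L) || any(p > d)) next
      if (!out[p[1], p[2], p[3]] && vol[p[1], p[2], p[3]] < thr) {
        out[p[1], p[2], p[3]] <- TRUE
        queue[[length(queue) + 1L]] <- p
      }
    }
  }
  out
}

# tiny ct_volume from a bare array
as_ct <- function(arr, spacing = c(1, 1, 1), kernel = "") {
  ct_volume(arr, spacing, kernel_name = kernel)
}

# rasterize one solid tube into a logical array (for metric tests)
tube_label <- function(dim3, p0, p1, radius, spacing = c(1, 1, 1)) {
  lab <- array(FALSE, dim3)
  w <- as.matrix(expand.grid(i = seq_len(dim3[1]), j = seq_len(dim3[2]),
                             k = seq_len(dim3[3])))
  x <- sweep(w - 1, 2, spacing, "*")
  v <- (p1 - p0)
  tt <- pmin(1, pmax(0, ((x[, 1] - p0[1]) * v[1] + (x[, 2] - p0[2]) * v[2] +
                           (x[, 3] - p0[3]) * v[3]) / sum(v^2)))
  d2 <- (x[, 1] - p0[1] - tt * v[1])^2 + (x[, 2] - p0[2] - tt * v[2])^2 +
    (x[, 3] - p0[3] - tt * v[3])^2
  lab[w[d2 <= radius^2, , drop = FALSE]] <- TRUE
  lab
}
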