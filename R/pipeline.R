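#' Run the full airway segmentation pipeline
#'
#' End-to-end orchestration: optional Gaussian pre-smoothing, initial crop,
#' first trachea segmentation, carina detection, crop refinement, final
#' trachea segmentation, automatic bronchial seed placement, masked
#' right-lung and left-lung segmentation under growth-ratio and voxel-budget
#' leakage control, merge with hole filling and dilation, and metric
#' computation. The whole pipeline is deterministic: identical inputs give
#' identical results.
#'
#' @param ct a [ct_volume] (or a path readable by [read_ct()]).
#' @param seed seed in the trachea: 1-based ijk triple, or physical LPS mm
#'   with `seed_physical = TRUE`.
#' @param config an [airway_config].
#' @param seed_physical interpret `seed` as LPS coordinates.
#' @param outdir optional directory: writes `airway.nrrd` (merged label),
#'   per-region labels, `report.json` and `trace.csv`.
#' @param verbose log every threshold step to stderr.
#' @return object of class `airway_segmentation`: `trachea`, `right`,
#'   `left` (per-lung results with traces and budgets), `union`
#'   (pre-dilation label), `merged`, and `report` (see
#'   [airway_report()]).
#' @export
run_airway_pipeline <- function(ct, seed, config = airway_config(),
                                seed_physical = FALSE, outdir = NULL,
                                verbose = FALSE) {
  if (is.character(ct)) ct <- read_ct(ct)
  stopifnot_ct(ct)
  seed <- resolve_seed(ct, seed, physical = seed_physical)
  say <- function(...) if (verbose) message(sprintf(...))
  if (config$presmooth_sigma_mm > 0) {
    say("pre-smoothing with sigma %.2f mm", config$presmooth_sigma_mm)
    sig <- config$presmooth_sigma_mm / ct$spacing
    ct$voxels <- array(.gauss_smooth_cpp(as.numeric(ct$voxels), ct_dim(ct), sig),
                       dim = ct_dim(ct))
  }
  say("trachea stage: seed (%s)", paste(seed, collapse = ","))
  trachea <- segment_trachea_stage(ct, seed, config)
  say("trachea: %d voxels at %d HU, carina slice %d",
      trachea$n_trachea, trachea$threshold_hu, trachea$carina_k)
  budget <- max_voxels_allowed(ct$meta$kernel_name, ct$meta$slice_count,
                               trachea$n_trachea)
  say("per-lung voxel budget: %d (kernel '%s', S = %d, N = %d)",
      budget, ct$meta$kernel_name, ct$meta$slice_count, trachea$n_trachea)
  lungs <- list()
  for (side in c("right", "left")) {
    masked <- mask_half_trachea(ct, trachea, side, config)
    sd2 <- if (side == "right") trachea$right_seed else trachea$left_seed
    tr <- segment_lung(masked, sd2, budget, config)
    say("%s lung: %d voxels at %d HU (%d steps)", side, sum(tr$final_label),
        tr$final_threshold_hu, nrow(tr$steps))
    lungs[[side]] <- structure(list(
      side = side, label = tr$final_label,
      threshold_hu = tr$final_threshold_hu,
      trace = tr, budget = budget), class = "lung_result")
  }
  mc <- merge_and_close(trachea$label, lungs$right$label, lungs$left$label,
                        config)
  graph <- extract_centerline(mc$merged, ct$spacing, config$min_spur_mm)
  report <- list(
    volume_mm3 = airway_volume(mc$union, ct$spacing),
    volume_dilated_mm3 = airway_volume(mc$merged, ct$spacing),
    branch_count = branch_count(graph),
    total_branch_length_mm = total_branch_length(graph),
    thresholds = list(trachea = trachea$threshold_hu,
                      right = lungs$right$threshold_hu,
                      left = lungs$left$threshold_hu),
    carina_k = trachea$carina_k,
    n_trachea = trachea$n_trachea,
    budget = budget
  )
  res <- structure(list(trachea = trachea, right = lungs$right,
                        left = lungs$left, union = mc$union,
                        merged = mc$merged, graph = graph,
                        report = report, config = config),
                   class = "airway_segmentation")
  if (!is.null(outdir)) write_segmentation(res, ct, outdir)
  res
}

#' @export
print.airway_segmentation <- function(x, ...) {
  r <- x$report
  cat("<airway_segmentation>\n")
  cat(sprintf("  thresholds (HU): trachea %d, right %d, left %d\n",
              r$thresholds$trachea, r$thresholds$right, r$thresholds$left))
  cat(sprintf("  airway volume: %.1f mm^3 (%.1f after dilation)\n",
              r$volume_mm3, r$volume_dilated_mm3))
  cat(sprintf("  branches: %d, total length %.1f mm\n",
              r$branch_count, r$total_branch_length_mm))
  cat(sprintf("  carina slice %d, trachea voxels %d, per-lung budget %d\n",
              r$carina_k, r$n_trachea, r$budget))
  invisible(x)
}

#' Combined threshold trace of a segmentation, as one data frame
#'
#' @param seg an `airway_segmentation`.
#' @export
trace_table <- function(seg) {
  tt <- function(trace, region) cbind(region = region, trace$steps)
  rbind(tt(seg$trachea$first_trace, "trachea_pass1"),
        tt(seg$trachea$trace, "trachea"),
        tt(seg$right$trace, "right"),
        tt(seg$left$trace, "left"))
}

#' Metric report of a segmentation as a one-row data frame
#'
#' @param seg an `airway_segmentation`.
#' @export
airway_report <- function(seg) {
  r <- seg$report
  data.frame(volume_mm3 = r$volume_mm3,
             volume_dilated_mm3 = r$volume_dilated_mm3,
             branch_count = r$branch_count,
             total_branch_length_mm = r$total_branch_length_mm,
             threshold_trachea_hu = r$thresholds$trachea,
             threshold_right_hu = r$thresholds$right,
             threshold_left_hu = r$thresholds$left,
             carina_k = r$carina_k,
             n_trachea = r$n_trachea,
             budget = r$budget)
}

write_segmentation <- function(seg, ct, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_label(seg$merged, ct, file.path(outdir, "airway.nrrd"))
  write_label(seg$trachea$label, ct, file.path(outdir, "trachea.nrrd"))
  write_label(seg$right$label, ct, file.path(outdir, "right_lung.nrrd"))
  write_label(seg$left$label, ct, file.path(outdir, "left_lung.nrrd"))
  jsonlite::write_json(seg$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(trace_table(seg), file.path(outdir, "trace.csv"),
                   row.names = FALSE)
  utils::write.csv(airway_report(seg), file.path(outdir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(branch_graph_table(seg$graph, ct$spacing),
                   file.path(outdir, "branches.csv"), row.names = FALSE)
  invisible(outdir)
}

#' Dice overlap between two labels
#'
#' @param a,b logical 3D arrays on the same grid.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grids differ", call. = FALSE)
  2 * sum(a & b) / (sum(a) + sum(b))
}
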