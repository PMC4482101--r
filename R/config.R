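#' Pipeline configuration
#'
#' Collects every tunable constant of the segmentation pipeline with its
#' default. Thresholds are in HU; the region-growing inclusion rule is
#' strict (`HU < threshold`).
#'
#' @param ... overrides for any default, by name.
#' @return named list of class `airway_config`.
#'
#' @details Keys:
#' \describe{
#'   \item{connectivity}{growing connectivity, 6 (default) or 26.}
#'   \item{g_max}{growth-ratio leak cut-off (1.6); leak iff `g > g_max`.}
#'   \item{crop_length_mm}{anterior-posterior extent of the trachea crop
#'     (40 mm, an average trachea caliber with margin).}
#'   \item{crop_height_fraction}{fraction of the inferior extent below the
#'     seed kept in the initial crop (0.85).}
#'   \item{guard_slab_slices}{axial slab (slices, centered on the seed)
#'     within which the trachea label's width/length guard is measured (5).}
#'   \item{start_hu, cap_hu}{trachea threshold schedule start (-900) and
#'     cap (-800).}
#'   \item{step_down_initial, step_up_clean, step_up_after_leak,
#'     step_down_final}{HU increments of the trachea schedule
#'     (20 / 50 / 10 / 10).}
#'   \item{floor_hu}{hard lower bound terminating decrement loops (-1024).}
#'   \item{carina_margin_slices}{slices kept below the carina in the refined
#'     crop (3).}
#'   \item{refine_pad_mm}{anterior-posterior enlargement applied while the
#'     label touches the crop faces (10 mm per side).}
#'   \item{min_component_area}{minimum axial component area (voxels) for the
#'     carina split and seed placement (5).}
#'   \item{height_rule}{"converge" (default): a difference label shorter
#'     than 1/3 of the crop height ends the improvement loop; "leak" treats
#'     it as leakage instead.}
#'   \item{start_hu_lung}{lung threshold schedule start (-1100).}
#'   \item{plug_offset_slices}{slices below the opposite bronchial seed at
#'     which the blocking plug is centered (2).}
#'   \item{plug_margin_vox}{margin added to the opposite bronchus
#'     equivalent radius when sizing the plug (2).}
#'   \item{dilate_radius_vox}{final merge dilation radius (1).}
#'   \item{presmooth_sigma_mm}{optional Gaussian pre-smoothing of the whole
#'     volume before any stage (0 = off).}
#'   \item{min_spur_mm}{centerline spur-pruning length (2 mm).}
#' }
#' @export
airway_config <- function(...) {
  cfg <- list(
    connectivity = 6,
    g_max = 1.6,
    crop_length_mm = 40,
    crop_height_fraction = 0.85,
    guard_slab_slices = 5,
    start_hu = -900,
    cap_hu = -800,
    step_down_initial = 20,
    step_up_clean = 50,
    step_up_after_leak = 10,
    step_down_final = 10,
    floor_hu = -1024,
    carina_margin_slices = 3,
    refine_pad_mm = 10,
    min_component_area = 5,
    height_rule = "converge",
    start_hu_lung = -1100,
    plug_offset_slices = 2,
    plug_margin_vox = 2,
    dilate_radius_vox = 1,
    presmooth_sigma_mm = 0,
    min_spur_mm = 2
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(ov)] <- ov
  # start_hu_lung may sit below floor_hu: the floor only terminates
  # decrement loops, while the lung schedule starts below any plausible
  # lumen HU and climbs
  if (cfg$start_hu > cfg$cap_hu || cfg$start_hu_lung > cfg$cap_hu ||
      cfg$floor_hu > cfg$cap_hu)
    stop("HU bounds must satisfy start <= cap and floor <= cap", call. = FALSE)
  if (cfg$floor_hu > cfg$start_hu)
    stop("floor_hu must not exceed start_hu", call. = FALSE)
  if (any(unlist(cfg[c("step_down_initial", "step_up_clean",
                       "step_up_after_leak", "step_down_final")]) <= 0))
    stop("threshold steps must be positive", call. = FALSE)
  structure(cfg, class = "airway_config")
}

#' @export
print.airway_config <- function(x, ...) {
  cat("<airway_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
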