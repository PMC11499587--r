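#' Count panicle detections above a score threshold
#'
#' @param detections a [detection_set] (panicle-labeled instances)
#' @param score_threshold minimum score, inclusive
#' @param label count only this category (`NULL` counts everything)
#' @return integer count
#' @export
count_panicles <- function(detections, score_threshold = 0.5,
                           label = "panicle") {
  insts <- detections$instances
  if (!is.null(label))
    insts <- Filter(function(i) identical(i$label, label), insts)
  sum(vapply(insts, `[[`, numeric(1), "score") >= score_threshold)
}

#' Panicle number per unit area from a plot crop
#'
#' The reference area is the ground footprint of the square crop:
#' `(crop_px * gsd / 1000)^2` square meters.
#'
#' @param count panicle count inside the crop
#' @param crop_px crop side length, pixels (e.g. 700 or 400)
#' @param gsd_mm_per_px ground sample distance, mm/pixel
#' @param plot_id,stage carried through to the record
#' @return a `pnpa_record`: `plot_id, panicle_count, reference_area_m2,
#'   pnpa, stage`
#' @export
pnpa_from_crop <- function(count, crop_px = 700, gsd_mm_per_px = 1.9,
                           plot_id = NA, stage = NA) {
  stopifnot(count >= 0, crop_px > 0, gsd_mm_per_px > 0)
  area <- (crop_px * gsd_mm_per_px / 1000)^2
  structure(list(plot_id = plot_id, panicle_count = count,
                 reference_area_m2 = area, pnpa = count / area,
                 stage = stage),
            class = "pnpa_record")
}

#' @export
print.pnpa_record <- function(x, ...) {
  cat(sprintf("<pnpa_record> plot %s: %d panicles / %.3f m2 = %.1f per m2\n",
              x$plot_id, x$panicle_count, x$reference_area_m2, x$pnpa))
  invisible(x)
}

#' Traditional plant-sampling PNpA estimator
#'
#' Emulates the field practice of counting panicles on a handful of plants
#' and scaling by plant density: draw `k` plants without replacement, take
#' the mean panicle count, multiply by plants per square meter. With 20 cm
#' x 20 cm plant spacing the density is 25 plants/m2; with 13 cm x 13 cm
#' spacing about 59 plants/m2.
#'
#' @param per_plant_panicles panicle counts of every plant in the plot
#' @param plants_per_m2 planting density
#' @param k number of plants sampled (field practice: 6)
#' @param seed sampling seed
#' @param plot_id,stage carried through
#' @return a `pnpa_record`
#' @export
pnpa_from_plant_sample <- function(per_plant_panicles, plants_per_m2 = 25,
                                   k = 6L, seed = 1L, plot_id = NA,
                                   stage = NA) {
  n <- length(per_plant_panicles)
  if (k > n) stop("cannot sample ", k, " plants from ", n)
  stopifnot(all(per_plant_panicles >= 0), plants_per_m2 > 0)
  idx <- if (k == n) seq_len(n) else sample_ids(seed, "plant_sample", n, k)
  est <- mean(per_plant_panicles[idx]) * plants_per_m2
  structure(list(plot_id = plot_id,
                 panicle_count = sum(per_plant_panicles[idx]),
                 reference_area_m2 = k / plants_per_m2,
                 pnpa = est, stage = stage),
            class = "pnpa_record")
}

#' Plant density from a square planting spacing
#'
#' @param spacing_m plant spacing in meters (e.g. 0.2 or 0.13)
#' @return plants per square meter
#' @export
plants_per_m2_from_spacing <- function(spacing_m) {
  stopifnot(spacing_m > 0)
  1 / spacing_m^2
}

#' Panicle angle classes
#'
#' Panicle curvature is scored by the angle between the panicle and the
#' vertical: the four classes are 0, 15, 45 and 90 degrees. An angle maps
#' to the nearest class center; the bin edges sit at the midpoints 7.5, 30
#' and 67.5 degrees and assign upward (7.5 -> deg15).
#'
#' @param angle_deg angle(s) in `[0, 90]` degrees
#' @return factor with levels `deg0, deg15, deg45, deg90`
#' @export
angle_to_class <- function(angle_deg) {
  if (any(angle_deg < 0 | angle_deg > 90))
    stop("panicle angle must lie in [0, 90] degrees")
  idx <- findInterval(angle_deg, c(7.5, 30, 67.5)) + 1L
  factor(angle_class_levels()[idx], levels = angle_class_levels())
}

#' @rdname angle_to_class
#' @export
angle_class_centers <- function() {
  c(deg0 = 0, deg15 = 15, deg45 = 45, deg90 = 90)
}

#' Plot-level panicle class from per-panicle classes
#'
#' The modal class; ties break toward the larger angle (the more curved
#' type).
#'
#' @param classes vector (character or factor) of per-panicle classes
#' @return single factor level
#' @export
predict_plot_class <- function(classes) {
  if (length(classes) == 0) stop("no panicle classes supplied")
  lv <- angle_class_levels()
  counts <- table(factor(as.character(classes), levels = lv))
  winners <- which(counts == max(counts))
  factor(lv[max(winners)], levels = lv)
}
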