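#' Declarative run configuration
#'
#' Nested defaults mirror the published workflow values where they exist:
#' 1600 px tiles with 1/4 overlap, 0.6 merge threshold, 700 px (large
#' plots) and 400 px (small plots) quantification crops, 1.9 mm/px GSD.
#' Everything is overridable with a nested list, and a config survives a
#' serialize/parse round trip unchanged.
#'
#' @param ... nested overrides, e.g. `tiling = list(tile_size = 800)`
#' @param seed global seed; all stage randomness derives from it through
#'   named substreams
#' @return class `run_config` (a nested list)
#' @export
run_config <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    simulator = list(rows = 5L, cols = 5L, plot_width_m = 2.4,
                     plot_height_m = 2.0, interplot_gap_m = 0.4,
                     plant_spacing_m = 0.2, gsd_mm_per_px = 10,
                     rotation_deg = 5, center_jitter_frac = 0.01,
                     panicle_density_per_m2 = 300,
                     stage = "second_third"),
    tiling = list(tile_size = 1600L, overlap_fraction = 0.25),
    detector = list(name = "baseline", score_threshold = 0,
                    min_area_px = 1000, exg_offset = 0, se_radius = 10L),
    merge = list(threshold = 0.6, measure = "min_area_fraction"),
    grid = list(claim_factor = 0.5, uniform_boundaries = FALSE,
                dropout_rate = 0),
    staging = list(acq_days = c(98, 104, 111, 125)),
    quantification = list(crop_px = 700L, crop_px_small = 400L,
                          gsd_mm_per_px = 1.9,
                          panicle_score_threshold = 0.5),
    evaluation = list(iou_thresholds = c(0.5, 0.75)))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param cfg a [run_config]
#' @param path JSON path
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, c(raw[setdiff(names(raw), "seed")],
                        list(seed = raw$seed)))
}

#' Run the end-to-end workflow into a run directory
#'
#' simulate -> segment -> stage -> count -> evaluate. Produces
#' `grid.json`, `stages.csv`, `pnpa.csv`, `metrics.json`, `truth_plots.json`
#' (COCO), `config.json`, and `log.txt` with stage timings; identical
#' config + seed gives identical outputs. Stage failures are reported with
#' the stage name; completed outputs are left intact.
#'
#' @param cfg a [run_config]
#' @param out_dir run directory (created)
#' @param mosaic_path optional PNM mosaic to segment instead of simulating
#'   (the simulator section is then only used for staging/quantification)
#' @param write_mosaic also write the simulated mosaic as PNM (large)
#' @return invisibly, a list with the in-memory stage results
#' @export
run_pipeline <- function(cfg = run_config(), out_dir, mosaic_path = NULL,
                         write_mosaic = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  log_line("run started; seed=%d", cfg$seed)
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    log_line("stage %s ok (%.2f s)", name, proc.time()[["elapsed"]] - t0)
    out
  }
  write_run_config(cfg, file.path(out_dir, "config.json"))

  sim <- cfg$simulator
  field <- timed("simulate", {
    fc <- field_config(rows = sim$rows, cols = sim$cols,
                       plot_width_m = sim$plot_width_m,
                       plot_height_m = sim$plot_height_m,
                       interplot_gap_m = sim$interplot_gap_m,
                       plant_spacing_m = sim$plant_spacing_m,
                       gsd_mm_per_px = sim$gsd_mm_per_px,
                       rotation_deg = sim$rotation_deg,
                       center_jitter_frac = sim$center_jitter_frac,
                       panicle_density_per_m2 = sim$panicle_density_per_m2,
                       stage = sim$stage, seed = cfg$seed)
    generate_field(fc)
  })
  mos <- if (!is.null(mosaic_path)) {
    timed("read_mosaic", mosaic(read_pnm(mosaic_path), sim$gsd_mm_per_px))
  } else field$mosaic
  if (write_mosaic && is.null(mosaic_path))
    timed("write_mosaic", write_pnm(mos, file.path(out_dir, "mosaic.ppm")))
  timed("write_truth", {
    write_truth(field$truth, "coco", file.path(out_dir, "truth_plots.json"),
                what = "plot")
    write_calendar(field$truth, file.path(out_dir, "calendar.csv"))
  })

  seg <- timed("segment", {
    det <- cfg$detector
    segment_plots(mos,
                  detector = detect_plots_baseline,
                  tile_size = cfg$tiling$tile_size,
                  overlap_fraction = cfg$tiling$overlap_fraction,
                  params = merge_params(cfg$merge$threshold, cfg$merge$measure),
                  detector_args = list(min_area_px = det$min_area_px,
                                       exg_offset = det$exg_offset,
                                       se_radius = det$se_radius),
                  score_threshold = det$score_threshold,
                  dropout_rate = cfg$grid$dropout_rate,
                  dropout_seed = cfg$seed,
                  claim_factor = cfg$grid$claim_factor,
                  uniform_boundaries = cfg$grid$uniform_boundaries)
  })
  timed("write_grid", write_plot_grid(seg, file.path(out_dir, "grid.json")))

  stages <- timed("stage", {
    st <- stage_table(field$truth$calendar, cfg$staging$acq_days)
    write.csv(st, file.path(out_dir, "stages.csv"), row.names = FALSE)
    st
  })

  pnpa <- timed("count", {
    # panicle counts from the simulated truth inside the central crop of
    # each plot, at the crop footprint of the configured size
    crop_px <- cfg$quantification$crop_px
    gsd <- sim$gsd_mm_per_px
    half <- crop_px / 2
    tr <- field$truth
    recs <- lapply(seq_len(nrow(tr$boxes)), function(i) {
      b <- tr$boxes[i, ]
      cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
      p <- tr$panicles[tr$panicles$plot_id == i, ]
      inside <- abs(p$x - cx) <= half & abs(p$y - cy) <= half
      stg <- assign_stage(tr$calendar$fhs_day[i], tr$calendar$ms_day[i],
                          cfg$staging$acq_days[1])
      r <- pnpa_from_crop(sum(inside), crop_px, gsd, plot_id = i,
                          stage = as.character(stg))
      data.frame(plot_id = i, stage = r$stage, count = r$panicle_count,
                 area_m2 = r$reference_area_m2, pnpa = r$pnpa)
    })
    df <- do.call(rbind, recs)
    write.csv(df, file.path(out_dir, "pnpa.csv"), row.names = FALSE)
    df
  })

  metrics <- timed("evaluate", {
    truth_work <- t(apply(field$truth$boxes, 1, function(b)
      at_apply_box(at_compose(seg$transform, field$truth$transform), b)))
    ga <- grid_agreement(seg, truth_work)
    m <- list(grid_agreement = list(
      mean_distance_px = ga$mean_distance, sd_distance_px = ga$sd_distance,
      mean_iou = ga$mean_iou, sd_iou = ga$sd_iou,
      n_paired = ga$n_paired, n_missing = ga$n_missing),
      estimated_rotation_deg = seg$angle_deg)
    jsonlite::write_json(m, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(agreement_markdown(ga), file.path(out_dir, "metrics.md"))
    m
  })

  manifest <- list(outputs = c("config.json", "truth_plots.json",
                               "calendar.csv", "grid.json", "stages.csv",
                               "pnpa.csv", "metrics.json", "metrics.md",
                               "log.txt"),
                   seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("run complete")
  invisible(list(field = field, segmentation = seg, stages = stages,
                 pnpa = pnpa, metrics = metrics))
}

agreement_markdown <- function(ga) {
  c("| Method | Euclidean distance (px) | SD (px) | IoU (%) | SD (%) |",
    "|---|---|---|---|---|",
    sprintf("| grid segmentation | %.2f | %.2f | %.2f | %.2f |",
            ga$mean_distance, ga$sd_distance,
            100 * ga$mean_iou, 100 * ga$sd_iou))
}

#' Serialize a plot grid (or segmentation result) to JSON
#'
#' @param x a `plot_grid` or `plot_seg_result`
#' @param path JSON path
#' @export
write_plot_grid <- function(x, path) {
  res <- NULL
  if (inherits(x, "plot_seg_result")) {
    res <- x; x <- x$grid
  }
  line_json <- function(l) list(orientation = l$orientation,
                                slope = l$slope, intercept = l$intercept,
                                member_ids = l$member_ids, rms = l$rms)
  doc <- list(
    row_lines = lapply(x$row_lines, line_json),
    col_lines = lapply(x$col_lines, line_json),
    centers = x$centers,
    mean_size = as.list(x$mean_size),
    boundaries = unname(apply(x$boundaries, 1, as.list)))
  if (!is.null(res)) {
    doc$angle_deg <- res$angle_deg
    doc$transform <- unname(apply(res$transform, 1, as.list))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
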