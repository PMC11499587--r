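#' Synthetic field configuration
#'
#' Describes a rectangular breeding-trial layout to be rendered as a
#' UAV-style mosaic: a `rows x cols` grid of rectangular plots separated by
#' an interplot gap, imaged at a given ground sample distance and rotated
#' relative to the raster axes. Defaults follow the first trial layout the
#' toolkit targets: 2.4 m x 2 m plots on a 40 cm interplot spacing with
#' 20 cm plant spacing, imaged at 1.9 mm/px.
#'
#' @param rows,cols grid dimensions (plots)
#' @param plot_width_m,plot_height_m plot size, meters
#' @param interplot_gap_m gap between adjacent plots (and field margin), m
#' @param plant_spacing_m within-plot plant spacing, m
#' @param gsd_mm_per_px ground sample distance, mm/pixel
#' @param rotation_deg rotation of the field grid relative to raster axes
#' @param center_jitter_frac plot-center jitter amplitude as a fraction of
#'   the plot pitch (uniform in +/- frac * pitch per axis)
#' @param dropout_rate fraction of plots omitted from simulated detections
#'   (never from the rendered truth), in `[0, 1)`
#' @param panicle_density_per_m2 expected panicles per square meter; per-plot
#'   counts are Poisson with mean density x plot area. 300/m2 is a typical
#'   paddy-rice panicle density at heading.
#' @param stage growth stage controlling canopy appearance: one of
#'   `"first_third"`, `"second_third"`, `"final_third"` of the
#'   full-heading-to-maturity interval
#' @param angle_class_mix proportions of the four panicle angle classes
#'   (0, 15, 45, 90 degrees), summing to 1
#' @param seed integer seed; identical config + seed gives identical output
#' @param max_pixels guard against accidental huge renders
#' @return an object of class `field_config`
#' @export
field_config <- function(rows = 5L, cols = 5L,
                         plot_width_m = 2.4, plot_height_m = 2.0,
                         interplot_gap_m = 0.4, plant_spacing_m = 0.2,
                         gsd_mm_per_px = 1.9, rotation_deg = 0,
                         center_jitter_frac = 0, dropout_rate = 0,
                         panicle_density_per_m2 = 300,
                         stage = c("second_third", "first_third", "final_third"),
                         angle_class_mix = c(0.25, 0.25, 0.25, 0.25),
                         seed = 1L, max_pixels = 1e8) {
  stage <- match.arg(stage)
  stopifnot(rows >= 1, cols >= 1,
            plot_width_m > 0, plot_height_m > 0, interplot_gap_m > 0,
            plant_spacing_m > 0, gsd_mm_per_px > 0,
            center_jitter_frac >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            panicle_density_per_m2 >= 0,
            length(angle_class_mix) == 4L,
            abs(sum(angle_class_mix) - 1) <= 1e-9)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 plot_width_m = plot_width_m, plot_height_m = plot_height_m,
                 interplot_gap_m = interplot_gap_m,
                 plant_spacing_m = plant_spacing_m,
                 gsd_mm_per_px = gsd_mm_per_px, rotation_deg = rotation_deg,
                 center_jitter_frac = center_jitter_frac,
                 dropout_rate = dropout_rate,
                 panicle_density_per_m2 = panicle_density_per_m2,
                 stage = stage, angle_class_mix = angle_class_mix,
                 seed = as.integer(seed), max_pixels = max_pixels),
            class = "field_config")
}

#' Layout presets
#'
#' `field_config_small()` is the second trial layout: approximately 1 m x
#' 1 m plots, 30 cm interplot spacing, 13 cm plant spacing.
#'
#' @param ... overrides passed to [field_config()]
#' @export
field_config_small <- function(...) {
  args <- list(plot_width_m = 1.0, plot_height_m = 1.0,
               interplot_gap_m = 0.3, plant_spacing_m = 0.13)
  args[names(list(...))] <- list(...)
  do.call(field_config, args)
}

angle_class_levels <- function() c("deg0", "deg15", "deg45", "deg90")

# Canopy / background palettes per growth stage. The pipeline under test is
# geometric, so these are flat colors plus per-pixel noise and speckles; no
# radiometric realism is attempted (see the methods vignette).
stage_palette <- function(stage) {
  switch(stage,
    first_third = list(canopy = c(0.22, 0.52, 0.18), speck = c(0.55, 0.70, 0.35),
                       speck_rate = 0.01),
    second_third = list(canopy = c(0.24, 0.55, 0.20), speck = c(0.80, 0.82, 0.55),
                        speck_rate = 0.04),
    final_third = list(canopy = c(0.52, 0.48, 0.22), speck = c(0.85, 0.72, 0.30),
                       speck_rate = 0.05))
}

soil_color <- c(0.16, 0.13, 0.11)

#' Generate the exact ground truth of a synthetic field
#'
#' Truth alone is cheap; rendering is done separately by [render_field()]
#' so statistical tests over many plots need not touch pixels. All truth
#' geometry is in the unrotated grid frame; `transform` maps it to the
#' rendered mosaic frame.
#'
#' @param config a [field_config]
#' @return an object of class `field_truth` with elements `boxes`
#'   (`n x 4` matrix, `(xmin, ymin, xmax, ymax)` px, row-major plot order),
#'   `centers` (data frame with `plot_id, row, col, cx, cy`), `panicles`
#'   (data frame with `plot_id, x, y, a_px, b_px, angle_class`), `calendar`
#'   (data frame with `plot_id, fhs_day, ms_day`), `dropout_ids`,
#'   `transform`, and the generating `config`
#' @export
generate_field_truth <- function(config) {
  stopifnot(inherits(config, "field_config"))
  px_per_m <- 1000 / config$gsd_mm_per_px
  pw <- config$plot_width_m * px_per_m
  ph <- config$plot_height_m * px_per_m
  gap <- config$interplot_gap_m * px_per_m
  pitch_x <- pw + gap
  pitch_y <- ph + gap
  W <- ceiling(config$cols * pitch_x + gap)
  H <- ceiling(config$rows * pitch_y + gap)
  if (as.numeric(W) * H > config$max_pixels)
    stop("raster dimension overflow: ", W, " x ", H, " exceeds max_pixels")

  rng <- make_rng(config$seed, "truth")
  n <- config$rows * config$cols
  grid <- expand.grid(col = seq_len(config$cols), row = seq_len(config$rows))
  cx0 <- gap + (grid$col - 1) * pitch_x + pw / 2
  cy0 <- gap + (grid$row - 1) * pitch_y + ph / 2
  jx <- config$center_jitter_frac * pitch_x
  jy <- config$center_jitter_frac * pitch_y
  cx <- cx0 + rng(n, -jx, jx)
  cy <- cy0 + rng(n, -jy, jy)
  boxes <- cbind(xmin = cx - pw / 2, ymin = cy - ph / 2,
                 xmax = cx + pw / 2, ymax = cy + ph / 2)
  centers <- data.frame(plot_id = seq_len(n), row = grid$row, col = grid$col,
                        cx = cx, cy = cy)

  # per-plot Poisson panicle counts at the stated density
  area_m2 <- config$plot_width_m * config$plot_height_m
  counts <- rpois_seeded(config$seed, "panicle_counts", n,
                         config$panicle_density_per_m2 * area_m2)
  total <- sum(counts)
  pan <- NULL
  if (total > 0) {
    prng <- make_rng(config$seed, "panicles")
    pid <- rep.int(seq_len(n), counts)
    # panicles sit inside the plot with a small inset so blobs stay inside
    a_px <- pmax(1, 0.06 * px_per_m + prng(total, -0.01, 0.01) * px_per_m)
    b_px <- pmax(1, 0.025 * px_per_m + prng(total, -0.005, 0.005) * px_per_m)
    inset <- pmax(a_px, b_px)
    px_ <- boxes[pid, "xmin"] + inset +
      prng(total, 0, 1) * (boxes[pid, "xmax"] - boxes[pid, "xmin"] - 2 * inset)
    py_ <- boxes[pid, "ymin"] + inset +
      prng(total, 0, 1) * (boxes[pid, "ymax"] - boxes[pid, "ymin"] - 2 * inset)
    cls <- sample_classes(config$seed, "angle_classes", total,
                          config$angle_class_mix)
    pan <- data.frame(plot_id = pid, x = px_, y = py_,
                      a_px = a_px, b_px = b_px,
                      angle_class = angle_class_levels()[cls])
  } else {
    pan <- data.frame(plot_id = integer(0), x = numeric(0), y = numeric(0),
                      a_px = numeric(0), b_px = numeric(0),
                      angle_class = character(0))
  }

  # calendars drawn so a typical campaign spans all three stage thirds:
  # full heading 85-95 d after sowing, maturity 25-35 d later
  crng <- make_rng(config$seed, "calendar")
  fhs <- round(crng(n, 85, 95))
  ms <- fhs + round(crng(n, 25, 35))
  calendar <- data.frame(plot_id = seq_len(n), fhs_day = fhs, ms_day = ms)

  n_drop <- round(config$dropout_rate * n)
  dropout_ids <- sample_ids(config$seed, "dropout", n, n_drop)

  structure(list(boxes = boxes, centers = centers, panicles = pan,
                 calendar = calendar, dropout_ids = dropout_ids,
                 width_px = W, height_px = H,
                 transform = at_identity(), config = config),
            class = "field_truth")
}

#' Render a synthetic field mosaic
#'
#' Plots are textured rectangles on a dark soil background: green canopy in
#' the first third, green with bright emerging-panicle speckles in the
#' second, yellow-brown with golden speckles in the final third. Panicles
#' are small elliptical blobs whose orientation encodes the angle class
#' (visual sanity check only). The raster is rendered in the grid frame and
#' then rotated by `rotation_deg` about its center with canvas expansion.
#'
#' @param truth a [generate_field_truth()] result
#' @return a [mosaic]; its `transform` (also copied into `truth$transform`
#'   by [generate_field()]) maps grid-frame truth to mosaic pixels
#' @export
render_field <- function(truth) {
  config <- truth$config
  W <- truth$width_px; H <- truth$height_px
  pal <- stage_palette(config$stage)
  nrng <- make_rng(config$seed, "noise")
  noise <- matrix(nrng(H * W, -0.02, 0.02), nrow = H)
  ras <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) ras[, , ch] <- soil_color[ch] + noise

  # canopy rectangles
  for (k in seq_len(nrow(truth$boxes))) {
    b <- truth$boxes[k, ]
    rows <- (floor(b[2]) + 1):min(H, ceiling(b[4]))
    cols <- (floor(b[1]) + 1):min(W, ceiling(b[3]))
    for (ch in 1:3)
      ras[rows, cols, ch] <- pal$canopy[ch] + noise[rows, cols]
    # speckles
    n_px <- length(rows) * length(cols)
    n_sp <- round(pal$speck_rate * n_px)
    if (n_sp > 0) {
      srng <- make_rng(config$seed, paste0("speck", k))
      ri <- rows[ceiling(srng(n_sp, 0, 1) * length(rows))]
      ci <- cols[ceiling(srng(n_sp, 0, 1) * length(cols))]
      for (ch in 1:3) {
        idx <- cbind(ri, ci, ch)
        ras[idx] <- pal$speck[ch]
      }
    }
  }

  # panicle blobs: a short thick segment of length ~a_px oriented by class
  if (nrow(truth$panicles) > 0) {
    ang <- c(deg0 = 90, deg15 = 75, deg45 = 45, deg90 = 0)[truth$panicles$angle_class]
    th <- ang * pi / 180
    steps <- 5L
    col_pan <- pal$speck
    for (s in seq(-0.5, 0.5, length.out = steps)) {
      xs <- round(truth$panicles$x + s * truth$panicles$a_px * cos(th)) + 1L
      ys <- round(truth$panicles$y + s * truth$panicles$a_px * sin(th)) + 1L
      ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
      for (ch in 1:3) ras[cbind(ys[ok], xs[ok], ch)] <- col_pan[ch]
    }
  }

  m <- mosaic(ras, config$gsd_mm_per_px)
  if (config$rotation_deg != 0) m <- rotate_mosaic(m, config$rotation_deg)
  m
}

#' Generate a synthetic field: mosaic plus exact ground truth
#'
#' @param config a [field_config]
#' @return list with elements `mosaic` ([mosaic]) and `truth`
#'   ([generate_field_truth()] result with `transform` set to the grid-to-
#'   mosaic affine)
#' @export
generate_field <- function(config) {
  truth <- generate_field_truth(config)
  m <- render_field(truth)
  truth$transform <- m$transform
  list(mosaic = m, truth = truth)
}

#' Simulate plot detections from ground truth
#'
#' A fast detector stand-in that bypasses imagery: truth boxes perturbed by
#' centered uniform jitter, with a fixed fraction dropped and a fixed
#' fraction split into two overlapping fragments emulating cross-tile
#' duplicates (75% left + 75% right, min-area overlap 2/3 > 0.6).
#'
#' @param truth a `field_truth` (or an `n x 4` box matrix)
#' @param jitter_px center jitter amplitude, uniform in `+/- jitter_px`
#' @param dropout_rate fraction of boxes deleted (exactly `round(rate * n)`)
#' @param split_rate fraction of surviving boxes emitted as two fragments
#' @param seed integer seed
#' @return a [detection_set] in the frame of the truth boxes
#' @export
simulate_detections <- function(truth, jitter_px = 0, dropout_rate = 0,
                                split_rate = 0, seed = 1L) {
  stopifnot(jitter_px >= 0, dropout_rate >= 0, dropout_rate < 1,
            split_rate >= 0, split_rate <= 1)
  boxes <- if (inherits(truth, "field_truth")) truth$boxes else truth
  n <- nrow(boxes)
  keep <- seq_len(n)
  n_drop <- round(dropout_rate * n)
  if (n_drop > 0) keep <- setdiff(keep, sample_ids(seed, "det_dropout", n, n_drop))
  rng <- make_rng(seed, "det_jitter")
  out <- list()
  n_split <- round(split_rate * length(keep))
  split_set <- if (n_split > 0)
    keep[match(sample_ids(seed, "det_split", length(keep), n_split),
               seq_along(keep))] else integer(0)
  for (i in keep) {
    dx <- rng(1, -jitter_px, jitter_px)
    dy <- rng(1, -jitter_px, jitter_px)
    b <- boxes[i, ] + c(dx, dy, dx, dy)
    if (i %in% split_set) {
      w <- b[3] - b[1]
      f1 <- c(b[1], b[2], b[1] + 0.75 * w, b[4])
      f2 <- c(b[1] + 0.25 * w, b[2], b[3], b[4])
      out[[length(out) + 1L]] <- detection_instance(f1, score = 0.9, label = "plot")
      out[[length(out) + 1L]] <- detection_instance(f2, score = 0.9, label = "plot")
    } else {
      out[[length(out) + 1L]] <- detection_instance(b, score = 1, label = "plot")
    }
  }
  detection_set(out, frame = "mosaic")
}

#' Write ground truth to an annotation file
#'
#' Plots become rectangles, panicles become 16-gon ellipse approximations;
#' category names are `"plot"` and `"panicle"`.
#'
#' @param truth a `field_truth`
#' @param format `"coco"` or `"labelme"`
#' @param path output path
#' @param what which categories to include
#' @export
write_truth <- function(truth, format = c("coco", "labelme"), path,
                        what = c("plot", "panicle")) {
  format <- match.arg(format)
  insts <- truth_instances(truth, what)
  set <- detection_set(insts, frame = "mosaic", image_id = 1L)
  switch(format,
         coco = write_coco(set, path,
                           image_size = c(truth$width_px, truth$height_px)),
         labelme = write_labelme(set, path,
                                 image_size = c(truth$width_px, truth$height_px)))
  invisible(path)
}

ellipse_polygon <- function(cx, cy, a, b, theta = 0, n = 16L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- cx + a / 2 * cos(t) * cos(theta) - b / 2 * sin(t) * sin(theta)
  y <- cy + a / 2 * cos(t) * sin(theta) + b / 2 * sin(t) * cos(theta)
  cbind(x, y)
}

truth_instances <- function(truth, what = c("plot", "panicle")) {
  insts <- list()
  if ("plot" %in% what) {
    for (i in seq_len(nrow(truth$boxes)))
      insts[[length(insts) + 1L]] <-
        detection_instance(truth$boxes[i, ], score = 1, label = "plot")
  }
  if ("panicle" %in% what && nrow(truth$panicles) > 0) {
    ang <- c(deg0 = 90, deg15 = 75, deg45 = 45, deg90 = 0)
    for (i in seq_len(nrow(truth$panicles))) {
      p <- truth$panicles[i, ]
      poly <- ellipse_polygon(p$x, p$y, p$a_px, p$b_px,
                              ang[[p$angle_class]] * pi / 180)
      box <- c(min(poly[, 1]), min(poly[, 2]), max(poly[, 1]), max(poly[, 2]))
      insts[[length(insts) + 1L]] <-
        detection_instance(box, score = 1, label = "panicle", polygon = poly)
    }
  }
  insts
}

#' Write / read a per-plot calendar CSV
#'
#' Columns `plot_id, fhs_day, ms_day` (days after sowing of full heading
#' and maturity).
#'
#' @param calendar data frame (or a `field_truth`, whose `calendar` is used)
#' @param path CSV path
#' @export
write_calendar <- function(calendar, path) {
  if (inherits(calendar, "field_truth")) calendar <- calendar$calendar
  write.csv(calendar, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calendar
#' @export
read_calendar <- function(path) {
  cal <- read.csv(path)
  stopifnot(all(c("plot_id", "fhs_day", "ms_day") %in% names(cal)))
  cal
}
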