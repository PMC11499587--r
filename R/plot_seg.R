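#' Merge parameters for cross-tile detections
#'
#' Two detections whose overlap exceeds `threshold` are assumed to be parts
#' of the same plot and merged. The default measure is intersection over
#' the smaller area, because tile-boundary fragments of one plot are
#' partial: they are almost fully contained in the full detection (high
#' containment) while their IoU can be low. Plain IoU is available.
#'
#' @param threshold overlap fraction above which detections merge
#'   (default 0.60)
#' @param measure `"min_area_fraction"` or `"iou"`
#' @export
merge_params <- function(threshold = 0.60,
                         measure = c("min_area_fraction", "iou")) {
  measure <- match.arg(measure)
  stopifnot(threshold > 0, threshold <= 1)
  structure(list(threshold = threshold, measure = measure),
            class = "merge_params")
}

box_intersection_area <- function(a, b) {
  w <- min(a[3], b[3]) - max(a[1], b[1])
  h <- min(a[4], b[4]) - max(a[2], b[2])
  if (w <= 0 || h <= 0) 0 else w * h
}

# overlap between two instances: masks when both carry one, else boxes
instance_overlap <- function(a, b, measure) {
  if (!is.null(a$mask) && !is.null(b$mask)) {
    ib <- c(max(a$box[1], b$box[1]), max(a$box[2], b$box[2]),
            min(a$box[3], b$box[3]), min(a$box[4], b$box[4]))
    if (ib[1] >= ib[3] || ib[2] >= ib[4]) {
      inter <- 0
    } else {
      ma <- mask_window(a, ib); mb <- mask_window(b, ib)
      inter <- sum(ma & mb)
    }
    aa <- sum(a$mask); ab <- sum(b$mask)
  } else {
    inter <- box_intersection_area(a$box, b$box)
    aa <- (a$box[3] - a$box[1]) * (a$box[4] - a$box[2])
    ab <- (b$box[3] - b$box[1]) * (b$box[4] - b$box[2])
  }
  if (measure == "min_area_fraction") {
    if (min(aa, ab) <= 0) 0 else inter / min(aa, ab)
  } else {
    u <- aa + ab - inter
    if (u <= 0) 0 else inter / u
  }
}

# extract the sub-mask of instance `inst` covering integer window `win`
mask_window <- function(inst, win) {
  x0 <- round(inst$box[1]); y0 <- round(inst$box[2])
  r <- (floor(win[2]) - y0 + 1):(ceiling(win[4]) - y0)
  c <- (floor(win[1]) - x0 + 1):(ceiling(win[3]) - x0)
  r <- r[r >= 1 & r <= nrow(inst$mask)]
  c <- c[c >= 1 & c <= ncol(inst$mask)]
  inst$mask[r, c, drop = FALSE]
}

#' Merge cross-tile plot detections
#'
#' Builds a graph with an edge between any two instances whose overlap
#' exceeds the threshold; each connected component collapses to a single
#' instance whose mask is the union of member masks, whose box bounds the
#' union, and whose score is the member maximum. The output is independent
#' of input order (components are emitted by their minimum original index
#' after sorting canonically).
#'
#' @param detections a [detection_set] in the mosaic frame
#' @param params a [merge_params]
#' @return a [detection_set] of merged instances
#' @export
merge_detections <- function(detections, params = merge_params()) {
  stopifnot(inherits(detections, "detection_set"))
  if (detections$frame != "mosaic")
    stop("merge_detections expects detections in the mosaic frame")
  insts <- detections$instances
  n <- length(insts)
  if (n <= 1) return(detections)
  # canonical order so the result is permutation-invariant
  boxes <- do.call(rbind, lapply(insts, `[[`, "box"))
  ord <- order(boxes[, 1], boxes[, 2], boxes[, 3], boxes[, 4],
               -vapply(insts, `[[`, numeric(1), "score"))
  insts <- insts[ord]
  boxes <- boxes[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (boxes[j, 1] > boxes[i, 3] || boxes[j, 3] < boxes[i, 1] ||
          boxes[j, 2] > boxes[i, 4] || boxes[j, 4] < boxes[i, 2]) next
      if (instance_overlap(insts[[i]], insts[[j]], params$measure) >
          params$threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(sort(unique(roots)), function(r) {
    members <- insts[roots == r]
    if (length(members) == 1) return(members[[1]])
    merge_instance_group(members)
  })
  detection_set(merged, frame = "mosaic", image_id = detections$image_id)
}

merge_instance_group <- function(members) {
  bb <- do.call(rbind, lapply(members, `[[`, "box"))
  box <- c(min(bb[, 1]), min(bb[, 2]), max(bb[, 3]), max(bb[, 4]))
  score <- max(vapply(members, `[[`, numeric(1), "score"))
  label <- members[[1]]$label
  mask <- NULL
  if (all(!vapply(members, function(m) is.null(m$mask), logical(1)))) {
    x0 <- round(box[1]); y0 <- round(box[2])
    h <- round(box[4]) - y0; w <- round(box[3]) - x0
    mask <- matrix(FALSE, h, w)
    for (m in members) {
      mx0 <- round(m$box[1]) - x0; my0 <- round(m$box[2]) - y0
      rr <- my0 + seq_len(nrow(m$mask)); cc <- mx0 + seq_len(ncol(m$mask))
      mask[rr, cc] <- mask[rr, cc] | m$mask
    }
  }
  detection_instance(box, mask = mask, score = score, label = label)
}

#' Group plot centers into grid rows and columns
#'
#' 1-D gap clustering of the y (rows) and x (columns) coordinates: sort,
#' estimate the grid pitch as the median of the consecutive differences
#' that exceed a quarter of the largest difference (which discards the
#' near-zero within-row differences), and split wherever a difference
#' exceeds `gap_factor` times the pitch.
#'
#' @param centers `n x 2` matrix of `(x, y)` centers
#' @param gap_factor split threshold as a fraction of the pitch
#' @return list with `rows` and `cols`: lists of integer index vectors,
#'   ordered by position; every center belongs to exactly one of each
#' @export
cluster_rows_cols <- function(centers, gap_factor = 0.5) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  if (nrow(centers) < 4)
    stop("insufficient grid: need at least 4 centers, got ", nrow(centers))
  list(rows = gap_cluster(centers[, 2], gap_factor),
       cols = gap_cluster(centers[, 1], gap_factor))
}

gap_cluster <- function(v, gap_factor) {
  ord <- order(v)
  sv <- v[ord]
  d <- diff(sv)
  if (length(d) == 0 || max(d) <= 1e-9)
    return(list(ord))
  big <- d[d > 0.25 * max(d)]
  pitch <- median(big)
  breaks <- which(d > gap_factor * pitch)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(sv))
  lapply(seq_along(starts), function(k) ord[starts[k]:ends[k]])
}

#' Fit grid lines through grouped centers
#'
#' Ordinary least squares per group: row lines are `y = a x + b` over the
#' member centers, column lines `x = a y + b`. A singleton group yields the
#' axis-parallel line through its point. The residual RMS is reported per
#' line.
#'
#' @param groups index groups from [cluster_rows_cols()] (`rows` or `cols`)
#' @param centers the `n x 2` center matrix the groups index into
#' @param orientation `"row"` or `"col"`
#' @return list of `grid_line` objects with `orientation`, `slope`,
#'   `intercept`, `member_ids`, `rms`
#' @export
fit_grid_lines <- function(groups, centers, orientation = c("row", "col")) {
  orientation <- match.arg(orientation)
  lapply(groups, function(ids) {
    if (orientation == "row") {
      x <- centers[ids, 1]; y <- centers[ids, 2]
    } else {
      x <- centers[ids, 2]; y <- centers[ids, 1]
    }
    if (length(ids) == 1 || diff(range(x)) < 1e-9) {
      slope <- 0; intercept <- mean(y)
    } else {
      f <- lm.fit(cbind(1, x), y)
      intercept <- f$coefficients[1]; slope <- f$coefficients[2]
    }
    res <- y - (slope * x + intercept)
    structure(list(orientation = orientation, slope = unname(slope),
                   intercept = unname(intercept), member_ids = ids,
                   rms = sqrt(mean(res^2))),
              class = "grid_line")
  })
}

line_position <- function(line) line$intercept

# intersection of a row line (y = a1 x + b1) and a col line (x = a2 y + b2)
line_intersection <- function(row_line, col_line) {
  a1 <- row_line$slope; b1 <- row_line$intercept
  a2 <- col_line$slope; b2 <- col_line$intercept
  den <- 1 - a1 * a2
  if (abs(den) < 1e-9) stop("grid undetermined: degenerate line pair")
  x <- (a2 * b1 + b2) / den
  y <- a1 * x + b1
  c(x, y)
}

#' Complete the plot grid from fitted lines
#'
#' Grid centers are the pairwise intersections of row and column lines. A
#' cell is `"detected"` when a merged detection centroid lies within
#' `claim_factor * min(mean width, mean height)` of its intersection;
#' claims are resolved nearest-first and each detection claims at most one
#' cell. Remaining cells are `"completed"`. Final boundaries are the
#' detected box for detected cells (or mean-size boxes everywhere when
#' `uniform_boundaries`) and `center +/- (mean size) / 2` for completed
#' cells, where the mean is over detected plots only.
#'
#' @param row_lines,col_lines [fit_grid_lines()] output
#' @param detections the merged [detection_set]
#' @param claim_factor claiming radius as a fraction of the smaller mean
#'   plot dimension
#' @param uniform_boundaries give every cell the mean-size boundary
#' @return an object of class `plot_grid`: `row_lines`, `col_lines`,
#'   `centers` (data frame `row, col, x, y, provenance, det_id`),
#'   `mean_size` `(w, h)`, `boundaries` (`n x 4` matrix, row-major cells)
#' @export
complete_grid <- function(row_lines, col_lines, detections,
                          claim_factor = 0.5, uniform_boundaries = FALSE) {
  if (length(row_lines) < 1 || length(col_lines) < 1)
    stop("grid undetermined: need at least one row and one column line")
  row_lines <- row_lines[order(vapply(row_lines, line_position, numeric(1)))]
  col_lines <- col_lines[order(vapply(col_lines, line_position, numeric(1)))]
  nr <- length(row_lines); nc <- length(col_lines)
  cells <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  pts <- t(mapply(function(r, c) line_intersection(row_lines[[r]], col_lines[[c]]),
                  cells$row, cells$col))
  insts <- detections$instances
  boxes <- detection_boxes(detections)
  n_det <- length(insts)
  cents <- if (n_det) cbind((boxes[, 1] + boxes[, 3]) / 2,
                            (boxes[, 2] + boxes[, 4]) / 2) else
    matrix(numeric(0), ncol = 2)

  # provisional mean size over all detections sets the claiming radius
  if (n_det == 0) stop("grid undetermined: no detections to size plots from")
  w_all <- boxes[, 3] - boxes[, 1]
  h_all <- boxes[, 4] - boxes[, 2]
  radius <- claim_factor * min(mean(w_all), mean(h_all))

  # nearest-first greedy claiming: ties by smallest distance then lowest id
  d <- sqrt(outer(cents[, 1], pts[, 1], "-")^2 +
            outer(cents[, 2], pts[, 2], "-")^2)
  det_id <- rep(NA_integer_, nrow(pts))
  if (n_det) {
    cand <- which(d <= radius, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], cand[, 1])
      used_det <- logical(n_det); used_cell <- logical(nrow(pts))
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_det[i] || used_cell[j]) next
        used_det[i] <- TRUE; used_cell[j] <- TRUE
        det_id[j] <- i
      }
    }
  }
  detected <- !is.na(det_id)
  if (!any(detected)) stop("grid undetermined: no detection claims any cell")
  mean_w <- mean(w_all[det_id[detected]])
  mean_h <- mean(h_all[det_id[detected]])

  boundaries <- matrix(NA_real_, nrow(pts), 4)
  for (j in seq_len(nrow(pts))) {
    if (detected[j] && !uniform_boundaries) {
      boundaries[j, ] <- boxes[det_id[j], ]
    } else {
      boundaries[j, ] <- c(pts[j, 1] - mean_w / 2, pts[j, 2] - mean_h / 2,
                           pts[j, 1] + mean_w / 2, pts[j, 2] + mean_h / 2)
    }
  }
  colnames(boundaries) <- c("xmin", "ymin", "xmax", "ymax")
  centers <- data.frame(row = cells$row, col = cells$col,
                        x = pts[, 1], y = pts[, 2],
                        provenance = ifelse(detected, "detected", "completed"),
                        det_id = det_id)
  structure(list(row_lines = row_lines, col_lines = col_lines,
                 centers = centers, mean_size = c(w = mean_w, h = mean_h),
                 boundaries = boundaries),
            class = "plot_grid")
}

#' @export
print.plot_grid <- function(x, ...) {
  cat(sprintf("<plot_grid> %d x %d cells (%d detected, %d completed), mean size %.1f x %.1f px\n",
              length(x$row_lines), length(x$col_lines),
              sum(x$centers$provenance == "detected"),
              sum(x$centers$provenance == "completed"),
              x$mean_size[1], x$mean_size[2]))
  invisible(x)
}

#' End-to-end plot-grid segmentation
#'
#' Orchestrates the full pipeline: estimate the grid orientation, rotate
#' the mosaic to axis alignment, tile it, run the detector per tile, map
#' detections to the mosaic frame, merge cross-tile duplicates, cluster
#' centers into rows and columns, fit grid lines, and complete missed
#' cells from line intersections.
#'
#' @param mos a [mosaic]
#' @param detector function `(tile, ...) -> detection_set` in tile frame
#' @param tile_size,overlap_fraction tiling geometry (defaults 1600, 1/4)
#' @param params a [merge_params]
#' @param detector_args extra arguments passed to the detector
#' @param score_threshold detections below this score are discarded before
#'   merging (0 keeps everything; raise for external scored detectors)
#' @param dropout_rate,dropout_seed robustness injection: fraction of
#'   merged plot detections deleted (seeded) before grid fitting, to
#'   exercise completion the way real detector misses would
#' @param claim_factor,uniform_boundaries forwarded to [complete_grid()]
#' @return class `plot_seg_result`: the `grid` (in the rotated working
#'   frame), `angle_deg`, `transform` (input-mosaic frame to working
#'   frame), `transform_back`, and the merged `detections`
#' @export
segment_plots <- function(mos, detector = detect_plots_baseline,
                          tile_size = 1600L, overlap_fraction = 0.25,
                          params = merge_params(), detector_args = list(),
                          score_threshold = 0,
                          dropout_rate = 0, dropout_seed = 1L,
                          claim_factor = 0.5, uniform_boundaries = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  angle <- stage("orientation", estimate_orientation(mos))
  work <- stage("rotation", rotate_mosaic(mos, -angle))
  tiles <- stage("tiling", tile_mosaic(work, tile_size, overlap_fraction))
  dets <- stage("detection", {
    per_tile <- lapply(tiles, function(tl) {
      ds <- do.call(detector, c(list(tl), detector_args))
      to_mosaic_frame(ds, tl)
    })
    all_insts <- do.call(c, lapply(per_tile, `[[`, "instances"))
    if (score_threshold > 0)
      all_insts <- Filter(function(i) i$score >= score_threshold, all_insts)
    detection_set(all_insts, frame = "mosaic")
  })
  merged <- stage("merge", merge_detections(dets, params))
  if (dropout_rate > 0 && length(merged) > 0) {
    n <- length(merged$instances)
    drop <- sample_ids(dropout_seed, "segment_dropout", n,
                       round(dropout_rate * n))
    merged$instances <- merged$instances[setdiff(seq_len(n), drop)]
  }
  if (length(merged) < 4) stop("[cluster] insufficient grid: fewer than 4 merged detections")
  boxes <- detection_boxes(merged)
  cents <- cbind((boxes[, 1] + boxes[, 3]) / 2, (boxes[, 2] + boxes[, 4]) / 2)
  groups <- stage("cluster", cluster_rows_cols(cents))
  row_lines <- stage("fit", fit_grid_lines(groups$rows, cents, "row"))
  col_lines <- stage("fit", fit_grid_lines(groups$cols, cents, "col"))
  grid <- stage("complete",
                complete_grid(row_lines, col_lines, merged,
                              claim_factor = claim_factor,
                              uniform_boundaries = uniform_boundaries))
  tf <- at_compose(work$transform, at_invert(mos$transform))
  structure(list(grid = grid, angle_deg = angle,
                 transform = tf, transform_back = at_invert(tf),
                 detections = merged, working_size = dim(work$raster)[1:2]),
            class = "plot_seg_result")
}

#' @export
print.plot_seg_result <- function(x, ...) {
  cat(sprintf("<plot_seg_result> angle %.2f deg\n", x$angle_deg))
  print(x$grid)
  invisible(x)
}

#' Crop a square image centered on a plot boundary
#'
#' @param mos a [mosaic] (in the same frame as `boundary`)
#' @param boundary `(xmin, ymin, xmax, ymax)` of the plot
#' @param out_size_px output side length, px (e.g. 700 or 400)
#' @return list with `raster` (`out x out x 3`, zero-padded at mosaic
#'   edges) and `offset` (`(x0, y0)` of the crop in the mosaic frame,
#'   possibly negative when padded)
#' @export
crop_plot <- function(mos, boundary, out_size_px = 700L) {
  stopifnot(out_size_px >= 1)
  H <- mosaic_height(mos); W <- mosaic_width(mos)
  cx <- (boundary[1] + boundary[3]) / 2
  cy <- (boundary[2] + boundary[4]) / 2
  if (cx < 0 || cx > W || cy < 0 || cy > H)
    stop("crop center lies outside the mosaic")
  x0 <- round(cx - out_size_px / 2)
  y0 <- round(cy - out_size_px / 2)
  out <- array(0, dim = c(out_size_px, out_size_px, 3))
  sx <- max(0, x0); ex <- min(W, x0 + out_size_px)
  sy <- max(0, y0); ey <- min(H, y0 + out_size_px)
  if (ex > sx && ey > sy) {
    out[(sy - y0 + 1):(ey - y0), (sx - x0 + 1):(ex - x0), ] <-
      mos$raster[(sy + 1):ey, (sx + 1):ex, , drop = FALSE]
  }
  list(raster = out, offset = c(x0, y0))
}
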