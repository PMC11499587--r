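test_that("merge rule follows the 60% min-area-fraction threshold", {
  # identical boxes collapse to one
  s <- boxes_to_set(rbind(c(0, 0, 100, 100), c(0, 0, 100, 100)))
  m <- merge_detections(s)
  expect_length(m$instances, 1)
  expect_box_equal(m$instances[[1]]$box, c(0, 0, 100, 100))

  # contained box: intersection = min area, fraction 1 > 0.6 -> merged
  s <- boxes_to_set(rbind(c(0, 0, 100, 100), c(10, 10, 90, 90)))
  m <- merge_detections(s)
  expect_length(m$instances, 1)
  expect_box_equal(m$instances[[1]]$box, c(0, 0, 100, 100))

  # half overlap: fraction 0.5 <= 0.6 -> kept apart
  s <- boxes_to_set(rbind(c(0, 0, 100, 100), c(50, 0, 150, 100)))
  expect_length(merge_detections(s)$instances, 2)

  # same pair under IoU measure with a permissive threshold merges
  m2 <- merge_detections(s, merge_params(0.3, "iou"))
  expect_length(m2$instances, 1)
})

test_that("merged instances union masks and keep the max score", {
  mk <- function(box, score) {
    w <- box[3] - box[1]; h <- box[4] - box[2]
    detection_instance(box, mask = matrix(TRUE, h, w), score = score)
  }
  s <- detection_set(list(mk(c(0, 0, 10, 10), 0.4), mk(c(2, 0, 12, 10), 0.9)),
                     frame = "mosaic")
  m <- merge_detections(s)
  expect_length(m$instances, 1)
  expect_box_equal(m$instances[[1]]$box, c(0, 0, 12, 10))
  expect_equal(m$instances[[1]]$score, 0.9)
  expect_equal(sum(m$instances[[1]]$mask), 120)  # full union, no holes
})

test_that("merge is idempotent and permutation-invariant", {
  set.seed(31)
  base <- rbind(c(0, 0, 100, 100), c(80, 0, 180, 100), c(90, 5, 170, 95),
                c(300, 300, 400, 380), c(305, 310, 395, 375),
                c(600, 0, 700, 90))
  s <- boxes_to_set(base, scores = runif(nrow(base)))
  m1 <- merge_detections(s)
  m2 <- merge_detections(m1)
  expect_equal(detection_boxes(m2), detection_boxes(m1))
  for (k in 1:20) {
    perm <- sample(length(s$instances))
    sp <- detection_set(s$instances[perm], frame = "mosaic")
    mp <- merge_detections(sp)
    expect_equal(detection_boxes(mp), detection_boxes(m1),
                 label = paste("shuffle", k))
  }
  expect_error(merge_detections(detection_set(frame = "tile")), "mosaic")
})

test_that("row/col clustering recovers grid groups", {
  # perfect 3x3 grid, pitch 100
  g <- expand.grid(x = c(100, 200, 300), y = c(50, 150, 250))
  cl <- cluster_rows_cols(cbind(g$x, g$y))
  expect_length(cl$rows, 3)
  expect_length(cl$cols, 3)
  expect_true(all(lengths(cl$rows) == 3))
  expect_true(all(lengths(cl$cols) == 3))

  # jitter sigma 3 px leaves the grouping unchanged
  set.seed(5)
  cj <- cluster_rows_cols(cbind(g$x + rnorm(9, 0, 3), g$y + rnorm(9, 0, 3)))
  for (k in 1:3) {
    expect_setequal(cj$rows[[k]], cl$rows[[k]])
    expect_setequal(cj$cols[[k]], cl$cols[[k]])
  }

  # collinear centers: one row, n columns
  cc <- cluster_rows_cols(cbind(c(10, 110, 210, 310), rep(40, 4)))
  expect_length(cc$rows, 1)
  expect_length(cc$cols, 4)

  expect_error(cluster_rows_cols(cbind(1:3, 1:3)), "insufficient")
})

test_that("grid line fitting matches closed-form least squares", {
  centers <- rbind(c(0, 10), c(100, 12), c(200, 14))
  l <- fit_grid_lines(list(1:3), centers, "row")[[1]]
  expect_equal(l$slope, 0.02, tolerance = 1e-12)
  expect_equal(l$intercept, 10, tolerance = 1e-12)
  expect_equal(l$rms, 0, tolerance = 1e-9)

  # singleton group: axis-parallel line through the point
  ls <- fit_grid_lines(list(1L), rbind(c(50, 80)), "row")[[1]]
  expect_equal(ls$slope, 0)
  expect_equal(ls$intercept, 80)

  # column line x = a y + b through vertical centers
  vc <- rbind(c(20, 0), c(22, 100), c(24, 200))
  lc <- fit_grid_lines(list(1:3), vc, "col")[[1]]
  expect_equal(lc$slope, 0.02, tolerance = 1e-12)
  expect_equal(lc$intercept, 20, tolerance = 1e-12)
})

test_that("grid completion recovers dropped plots from line intersections", {
  cfg <- small_field_config(rows = 3, cols = 3, gsd = 10, seed = 12)
  tr <- generate_field_truth(cfg)
  dets <- simulate_detections(tr)
  # delete the center plot (row 2, col 2 -> id 5)
  dets$instances <- dets$instances[-5]
  cents <- detection_boxes(dets)
  cents <- cbind((cents[, 1] + cents[, 3]) / 2, (cents[, 2] + cents[, 4]) / 2)
  cl <- cluster_rows_cols(cents)
  grid <- complete_grid(fit_grid_lines(cl$rows, cents, "row"),
                        fit_grid_lines(cl$cols, cents, "col"), dets)
  expect_equal(nrow(grid$boundaries), 9)
  expect_equal(sum(grid$centers$provenance == "completed"), 1)
  comp <- grid$centers[grid$centers$provenance == "completed", ]
  expect_lt(euclidean_distance(c(comp$x, comp$y),
                               c(tr$centers$cx[5], tr$centers$cy[5])), 2)
  # mean size equals the detected boxes' arithmetic mean exactly
  bb <- detection_boxes(dets)
  expect_equal(unname(grid$mean_size["w"]), mean(bb[, 3] - bb[, 1]))
  expect_equal(unname(grid$mean_size["h"]), mean(bb[, 4] - bb[, 2]))
})

test_that("without dropouts every cell is detected and keeps its box", {
  cfg <- small_field_config(rows = 3, cols = 3, gsd = 10, seed = 13)
  tr <- generate_field_truth(cfg)
  dets <- simulate_detections(tr)
  cents <- t(vapply(dets$instances,
                    function(i) fieldplotr:::box_centroid(i$box), numeric(2)))
  cl <- cluster_rows_cols(cents)
  grid <- complete_grid(fit_grid_lines(cl$rows, cents, "row"),
                        fit_grid_lines(cl$cols, cents, "col"), dets)
  expect_true(all(grid$centers$provenance == "detected"))
  # row-major cell order matches truth order for the jitter-free grid
  expect_equal(unname(grid$boundaries), unname(tr$boxes), tolerance = 1e-6)
  # uniform_boundaries gives every cell the mean-size box instead
  gu <- complete_grid(fit_grid_lines(cl$rows, cents, "row"),
                      fit_grid_lines(cl$cols, cents, "col"), dets,
                      uniform_boundaries = TRUE)
  w <- gu$boundaries[, 3] - gu$boundaries[, 1]
  expect_equal(unname(w), rep(unname(grid$mean_size["w"]), 9))
})

test_that("completion tolerates several dropouts under jitter", {
  cfg <- small_field_config(rows = 5, cols = 5, gsd = 10, seed = 14)
  tr <- generate_field_truth(cfg)
  dets <- simulate_detections(tr, jitter_px = 3, dropout_rate = 4 / 25,
                              seed = 21)
  cents <- t(vapply(dets$instances,
                    function(i) fieldplotr:::box_centroid(i$box), numeric(2)))
  cl <- cluster_rows_cols(cents)
  grid <- complete_grid(fit_grid_lines(cl$rows, cents, "row"),
                        fit_grid_lines(cl$cols, cents, "col"), dets)
  expect_equal(nrow(grid$boundaries), 25)
  # all cell centers within 10 px of truth
  ord <- order(grid$centers$row, grid$centers$col)
  errs <- sqrt((grid$centers$x[ord] - tr$centers$cx)^2 +
               (grid$centers$y[ord] - tr$centers$cy)^2)
  expect_lt(max(errs), 10)
})

test_that("grid completion recovers all cells over seeds (property)", {
  for (seed in 1:10) {
    cfg <- small_field_config(rows = 4, cols = 4, gsd = 10,
                              center_jitter_frac = 0.02, seed = seed)
    tr <- generate_field_truth(cfg)
    dets <- simulate_detections(tr, jitter_px = 3, dropout_rate = 0.2,
                                seed = seed)
    cents <- t(vapply(dets$instances,
                      function(i) fieldplotr:::box_centroid(i$box), numeric(2)))
    cl <- cluster_rows_cols(cents)
    grid <- complete_grid(fit_grid_lines(cl$rows, cents, "row"),
                          fit_grid_lines(cl$cols, cents, "col"), dets)
    expect_equal(nrow(grid$boundaries), 16, label = paste("seed", seed))
  }
})

test_that("segment_plots runs the whole pipeline deterministically", {
  cfg <- small_field_config(rows = 3, cols = 3, gsd = 10, rotation_deg = 5,
                            center_jitter_frac = 0.01, seed = 17)
  f <- generate_field(cfg)
  seg1 <- segment_plots(f$mosaic, detector_args = list(min_area_px = 5000))
  seg2 <- segment_plots(f$mosaic, detector_args = list(min_area_px = 5000))
  expect_equal(seg1$grid$boundaries, seg2$grid$boundaries)
  expect_equal(nrow(seg1$grid$boundaries), 9)
  tw <- truth_boxes_in_working_frame(seg1, f$truth)
  ga <- grid_agreement(seg1, tw)
  expect_equal(ga$n_missing, 0)
  expect_gt(ga$mean_iou, 0.85)

  # a field with no plots fails in a named stage
  bare <- mosaic(array(0.12, dim = c(200, 200, 3)), 10)
  expect_error(segment_plots(bare), "\\[orientation\\]")
})

test_that("crop_plot centers, clips and pads", {
  ras <- array(runif(2000 * 2000 * 3), dim = c(2000, 2000, 3))
  m <- mosaic(ras, 1.9)
  cr <- crop_plot(m, c(900, 900, 1100, 1100), 700)
  expect_equal(cr$offset, c(650, 650))
  expect_equal(dim(cr$raster), c(700, 700, 3))
  expect_equal(cr$raster[1, 1, ], ras[651, 651, ])

  # near the left edge: padded, offset recorded
  cr2 <- crop_plot(m, c(50, 900, 150, 1100), 700)
  expect_equal(cr2$offset, c(-250, 650))
  expect_true(all(cr2$raster[, 1:250, ] == 0))
  expect_equal(cr2$raster[1, 251, ], ras[651, 1, ])

  expect_error(crop_plot(m, c(-500, -500, -100, -100), 700), "outside")
})

test_that("plot crops contain the plot's panicles", {
  cfg <- small_field_config(rows = 2, cols = 2, gsd = 10, seed = 19)
  f <- generate_field(cfg)
  tr <- f$truth
  b <- tr$boxes[1, ]
  side <- ceiling(max(b[3] - b[1], b[4] - b[2])) + 10
  cr <- crop_plot(f$mosaic, b, side)
  pan <- tr$panicles[tr$panicles$plot_id == 1, ]
  inside <- pan$x >= cr$offset[1] & pan$x <= cr$offset[1] + side &
            pan$y >= cr$offset[2] & pan$y <= cr$offset[2] + side
  expect_gte(mean(inside), 0.95)
})
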