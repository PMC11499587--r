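# Shared fixtures: coarse-GSD fields keep renders small and tests fast.

small_field_config <- function(rows = 3, cols = 3, gsd = 20, ...) {
  field_config(rows = rows, cols = cols, gsd_mm_per_px = gsd, ...)
}

# detection set from a plain box matrix
boxes_to_set <- function(boxes, scores = rep(1, nrow(boxes)),
                         label = "plot", frame = "mosaic") {
  insts <- lapply(seq_len(nrow(boxes)), function(i)
    detection_instance(boxes[i, ], score = scores[i], label = label))
  detection_set(insts, frame = frame)
}

# map truth boxes into the working frame of a plot_seg_result
truth_boxes_in_working_frame <- function(seg, truth) {
  tf <- at_compose(seg$transform, truth$transform)
  t(apply(truth$boxes, 1, function(b) {
    corners <- rbind(c(b[1], b[2]), c(b[3], b[2]), c(b[3], b[4]), c(b[1], b[4]))
    p <- at_apply(tf, corners)
    c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
  }))
}

expect_box_equal <- function(a, b, tol = 1e-6) {
  expect_equal(as.numeric(a), as.numeric(b), tolerance = tol)
}
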