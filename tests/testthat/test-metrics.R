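# Independent oracles used throughout this file:
#  - brute-force maximum-bipartite matching for TP counts
#  - midpoint Riemann integration of the precision envelope for AP

# maximum matching via augmenting paths on the IoU >= threshold graph
oracle_max_tp <- function(iou_mat, threshold) {
  np <- nrow(iou_mat); ng <- ncol(iou_mat)
  match_gt <- rep(0L, ng)
  try_assign <- function(i, seen, env) {
    for (j in seq_len(ng)) {
      if (iou_mat[i, j] >= threshold && !env$seen[j]) {
        env$seen[j] <- TRUE
        if (env$match_gt[j] == 0L ||
            try_assign(env$match_gt[j], seen, env)) {
          env$match_gt[j] <- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  env <- new.env()
  env$match_gt <- match_gt
  total <- 0L
  for (i in seq_len(np)) {
    env$seen <- rep(FALSE, ng)
    if (try_assign(i, NULL, env)) total <- total + 1L
  }
  total
}

random_box <- function(n, span = 60, size = c(8, 25)) {
  x <- runif(n, 0, span); y <- runif(n, 0, span)
  w <- runif(n, size[1], size[2]); h <- runif(n, size[1], size[2])
  cbind(x, y, x + w, y + h)
}

test_that("euclidean distance and IoU match hand arithmetic", {
  expect_equal(euclidean_distance(c(3, 7), c(3, 7)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 1), c(4, 5)), 5)
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150,
               tolerance = 1e-12)
})

test_that("mask IoU is used when both instances carry masks", {
  mk <- function(box, keep_frac) {
    h <- box[4] - box[2]; w <- box[3] - box[1]
    m <- matrix(FALSE, h, w)
    m[seq_len(round(h * keep_frac)), ] <- TRUE
    detection_instance(box, mask = m)
  }
  a <- mk(c(0, 0, 10, 10), 1)
  b <- mk(c(0, 0, 10, 10), 0.5)
  expect_equal(iou(a, b), 0.5)
})

test_that("greedy matching follows score order and claims best IoU", {
  gt <- boxes_to_set(rbind(c(0, 0, 10, 10)))
  pred <- boxes_to_set(rbind(c(0, 2, 10, 12)), scores = 0.9)
  m <- match_detections(pred, gt, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))

  # two predictions on one gt: highest score claims it, other is FP
  pred2 <- boxes_to_set(rbind(c(0, 1, 10, 11), c(0, 0, 10, 10)),
                        scores = c(0.9, 0.8))
  m2 <- match_detections(pred2, gt, 0.5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 1, 0))
  expect_equal(m2$matches$pred_id, 1)

  expect_error(match_detections(boxes_to_set(rbind(c(0, 0, 1, 1)),
                                             frame = "tile"), gt),
               "frame")
})

test_that("greedy TP equals brute-force optimal TP on random small cases", {
  set.seed(123)
  for (case in 1:200) {
    np <- sample(0:5, 1); ng <- sample(1:5, 1)
    preds <- if (np > 0) boxes_to_set(random_box(np), scores = runif(np))
             else detection_set(frame = "mosaic")
    gts <- boxes_to_set(random_box(ng))
    thr <- sample(c(0.3, 0.5, 0.75), 1)
    got <- match_detections(preds, gts, thr)$tp
    want <- if (np == 0) 0L else
      oracle_max_tp(fieldplotr:::box_iou_matrix(detection_boxes(preds),
                                                detection_boxes(gts)), thr)
    expect_equal(got, want, label = paste("case", case))
  }
})

test_that("precision/recall formulas and degenerate warnings", {
  pr <- precision_recall(list(tp = 5, fp = 0, fn = 0))
  expect_equal(unname(pr), c(1, 1))
  pr2 <- precision_recall(list(tp = 3, fp = 1, fn = 2))
  expect_equal(unname(pr2), c(0.75, 0.6))
  expect_warning(pr3 <- precision_recall(list(tp = 0, fp = 0, fn = 4)),
                 "precision")
  expect_equal(unname(pr3[1]), 0)
})

test_that("AP matches hand-enumerated and numerically integrated values", {
  gt <- boxes_to_set(rbind(c(0, 0, 10, 10)))
  # single matching prediction
  expect_equal(average_precision(boxes_to_set(rbind(c(0, 0, 10, 10)),
                                              scores = 0.9), gt, 0.5), 1)
  # FP ranked first, TP second: envelope gives AP = 0.5
  preds <- boxes_to_set(rbind(c(40, 40, 50, 50), c(0, 0, 10, 10)),
                        scores = c(0.9, 0.8))
  expect_equal(average_precision(preds, gt, 0.5), 0.5)
  expect_error(average_precision(preds, detection_set(frame = "mosaic")),
               "AP undefined")
})

test_that("AP equals Riemann integration of the precision envelope", {
  set.seed(99)
  for (case in 1:20) {
    ng <- sample(2:4, 1); np <- sample(2:6, 1)
    gts <- boxes_to_set(random_box(ng))
    preds <- boxes_to_set(random_box(np), scores = runif(np))
    ap <- average_precision(preds, gts, 0.5)
    # oracle: rebuild the ranked PR points, integrate the envelope on a
    # 1e-6 midpoint grid
    tp <- fieldplotr:::ranked_tp_flags(preds, gts, 0.5)
    cum <- cumsum(tp)
    prec <- cum / seq_along(tp); rec <- cum / ng
    envelope <- function(r) {
      vals <- vapply(r, function(ri) {
        ok <- rec >= ri - 1e-12
        if (any(ok)) max(prec[ok]) else 0
      }, numeric(1))
      vals
    }
    oracle <- if (max(rec) == 0) 0 else {
      grid <- seq(0.5e-6, max(rec) - 0.5e-6, by = 1e-6)
      sum(envelope(grid)) * 1e-6
    }
    expect_equal(ap, oracle, tolerance = 1e-5, label = paste("case", case))
  }
})

test_that("AP is monotone non-increasing in the IoU threshold", {
  set.seed(7)
  gts <- boxes_to_set(random_box(5))
  preds <- boxes_to_set(random_box(8), scores = runif(8))
  aps <- vapply(c(0.3, 0.5, 0.75, 0.9),
                function(t) average_precision(preds, gts, t), numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
  expect_true(all(aps >= 0 & aps <= 1))
})

test_that("AR counts recalls at the stated thresholds", {
  gts <- boxes_to_set(rbind(c(0, 0, 10, 10), c(20, 0, 30, 10),
                            c(40, 0, 50, 10), c(60, 0, 70, 10)))
  preds <- boxes_to_set(rbind(c(0, 0, 10, 10), c(20, 0, 30, 10),
                              c(40, 0, 50, 10)), scores = c(0.9, 0.8, 0.7))
  expect_equal(average_recall(preds, gts, 0.5), 0.75)
  expect_equal(average_recall(gts, gts, 0.5), 1)
  # explicit two-threshold average: mean of per-threshold recalls
  shifted <- boxes_to_set(rbind(c(0, 3, 10, 13), c(20, 3, 30, 13),
                                c(40, 3, 50, 13), c(60, 3, 70, 13)),
                          scores = rep(0.9, 4))
  r50 <- average_recall(shifted, gts, 0.5)
  r75 <- average_recall(shifted, gts, 0.75)
  expect_equal(average_recall(shifted, gts, c(0.5, 0.75)),
               mean(c(r50, r75)))
  # max_detections truncates by score
  expect_equal(average_recall(preds, gts, 0.5, max_detections = 1), 0.25)
})

test_that("regression metrics match the worked example and scale law", {
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$rrmse_pct, 0)

  m <- regression_metrics(c(100, 200, 300), c(110, 190, 310))
  expect_equal(m$rmse, 10)
  expect_equal(m$r2, 0.985)
  expect_equal(m$rrmse_pct, 5)

  m2 <- regression_metrics(3 * c(100, 200, 300), 3 * c(110, 190, 310))
  expect_equal(m2$r2, m$r2)
  expect_equal(m2$rrmse_pct, m$rrmse_pct)
  expect_equal(m2$rmse, 3 * m$rmse)

  expect_error(regression_metrics(c(5, 5, 5), c(5, 6, 5)), "R2 undefined")
  # R2 <= 1 always
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(10); yh <- rnorm(10)
    expect_lte(regression_metrics(y, yh)$r2, 1)
  }
})

test_that("classification metrics reduce one-vs-rest correctly", {
  d <- diag(c(3, 4, 5))
  md <- classification_metrics(d)
  expect_equal(md$accuracy, 1)
  expect_true(all(md$per_class$f1 == 1))

  cm <- matrix(c(8, 1, 2, 9), 2)  # rows truth, cols predicted
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$per_class$precision[1], 8 / 9)
  expect_equal(m$per_class$recall[1], 0.8)
  expect_equal(m$per_class$f1[1], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(round(m$per_class$f1[1], 3), 0.842)

  # permuting class order permutes per-class metrics, macro unchanged
  perm <- c(2, 1)
  mp <- classification_metrics(cm[perm, perm])
  expect_equal(mp$macro, m$macro)
  expect_equal(mp$per_class$f1, m$per_class$f1[perm])

  # accuracy equals the recall mean weighted by true-class counts
  set.seed(11)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    cmr <- matrix(rpois(k * k, 5), k)
    mr <- classification_metrics(cmr)
    expect_equal(mr$accuracy,
                 sum(mr$per_class$recall * rowSums(cmr)) / sum(cmr))
  }
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
})

test_that("relative improvement reproduces published deltas", {
  expect_equal(relative_improvement(5, 5), 0)
  expect_equal(round(relative_improvement(0.652, 0.541), 1), 20.5)
  expect_equal(round(relative_improvement(0.282, 0.161), 1), 75.2)
  expect_error(relative_improvement(1, 0), "zero base")
})

test_that("sampling stability reports shift and correlation laws", {
  x <- c(3, 5, 7, 9, 12, 4, 8)
  same <- sampling_stability(x, x)
  expect_equal(same$mean1, same$mean2)
  expect_equal(same$correlation, 1)
  expect_gt(same$p_value, 0.9)

  shifted <- sampling_stability(x, x + 2)
  expect_equal(shifted$correlation, 1)
  expect_equal(shifted$mean2 - shifted$mean1, 2)
  # sample SD uses the n-1 denominator
  expect_equal(shifted$sd1, sd(x))

  expect_error(sampling_stability(rep(1, 5), x[1:5]), "zero variance")
})

test_that("rank-sum test holds its nominal type-I error", {
  set.seed(2024)
  rejections <- 0
  for (i in 1:500) {
    a <- rnorm(50); b <- rnorm(50)
    if (sampling_stability(a, b)$p_value < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / 500
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("grid agreement pairs by nearest centroid and reports moments", {
  truth <- rbind(c(0, 0, 100, 80), c(200, 0, 300, 80), c(0, 200, 100, 280))
  same <- grid_agreement(truth, truth)
  expect_equal(same$n_missing, 0)
  expect_equal(same$mean_distance, 0)
  expect_equal(same$mean_iou, 1)

  shifted <- truth + matrix(rep(c(3, 4, 3, 4), each = 3), nrow = 3)
  ga <- grid_agreement(shifted, truth)
  expect_equal(ga$mean_distance, 5, tolerance = 1e-9)
  expect_equal(ga$sd_distance, 0, tolerance = 1e-9)

  # unpaired plots are reported missing, not averaged in
  ga2 <- grid_agreement(truth[1:2, ], truth)
  expect_equal(ga2$n_paired, 2)
  expect_equal(ga2$n_missing, 1)
  expect_equal(ga2$mean_distance, 0)
})
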