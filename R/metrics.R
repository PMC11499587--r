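#' Euclidean distance between two points
#'
#' @param p,q length-2 `(x, y)` vectors, pixels
#' @return distance in pixels
#' @export
euclidean_distance <- function(p, q) {
  stopifnot(is.finite(p), is.finite(q))
  sqrt(sum((as.numeric(q) - as.numeric(p))^2))
}

#' Intersection over union
#'
#' Masks are used when both instances carry one, otherwise boxes. Returned
#' in `[0, 1]`; reports conventionally print it times 100.
#'
#' @param a,b [detection_instance]s, or length-4 boxes
#' @return IoU fraction
#' @export
iou <- function(a, b) {
  if (!inherits(a, "detection_instance")) a <- detection_instance(a)
  if (!inherits(b, "detection_instance")) b <- detection_instance(b)
  instance_overlap(a, b, "iou")
}

box_iou_matrix <- function(pa, pb) {
  n <- nrow(pa); m <- nrow(pb)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    w <- pmin(pa[i, 3], pb[, 3]) - pmax(pa[i, 1], pb[, 1])
    h <- pmin(pa[i, 4], pb[, 4]) - pmax(pa[i, 2], pb[, 2])
    inter <- pmax(w, 0) * pmax(h, 0)
    areas <- (pa[i, 3] - pa[i, 1]) * (pa[i, 4] - pa[i, 2]) +
      (pb[, 3] - pb[, 1]) * (pb[, 4] - pb[, 2]) - inter
    out[i, ] <- ifelse(areas > 0, inter / areas, 0)
  }
  out
}

iou_matrix <- function(preds, gts) {
  use_masks <- length(preds$instances) && length(gts$instances) &&
    all(vapply(preds$instances, function(i) !is.null(i$mask), logical(1))) &&
    all(vapply(gts$instances, function(i) !is.null(i$mask), logical(1)))
  if (!use_masks)
    return(box_iou_matrix(detection_boxes(preds), detection_boxes(gts)))
  out <- matrix(0, length(preds$instances), length(gts$instances))
  for (i in seq_along(preds$instances))
    for (j in seq_along(gts$instances))
      out[i, j] <- instance_overlap(preds$instances[[i]],
                                    gts$instances[[j]], "iou")
  out
}

#' Greedy detection matching
#'
#' Predictions are visited in descending score order; each claims the
#' still-unmatched ground truth with the highest IoU at or above the
#' threshold. Unmatched predictions are false positives, unmatched ground
#' truths false negatives. This is the standard detection-benchmark
#' protocol.
#'
#' @param preds,gts [detection_set]s in the same frame
#' @param iou_threshold minimum IoU for a valid match
#' @return class `match_result`: `tp, fp, fn` and a `matches` data frame
#'   (`pred_id, gt_id, iou`)
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  if (!identical(preds$frame, gts$frame))
    stop("predictions and ground truth are in different frames")
  np <- length(preds$instances); ng <- length(gts$instances)
  matches <- data.frame(pred_id = integer(0), gt_id = integer(0),
                        iou = numeric(0))
  if (np > 0 && ng > 0) {
    m <- iou_matrix(preds, gts)
    ord <- order(-detection_scores(preds), seq_len(np))
    taken <- logical(ng)
    for (i in ord) {
      cand <- which(!taken & m[i, ] >= iou_threshold)
      if (length(cand) == 0) next
      j <- cand[which.max(m[i, cand])]
      taken[j] <- TRUE
      matches <- rbind(matches,
                       data.frame(pred_id = i, gt_id = j, iou = m[i, j]))
    }
  }
  structure(list(tp = nrow(matches), fp = np - nrow(matches),
                 fn = ng - nrow(matches), matches = matches),
            class = "match_result")
}

#' Precision and recall from a match result
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`; an empty
#' denominator yields 0 with a warning.
#'
#' @param m a `match_result` (or a list with `tp, fp, fn`)
#' @return named vector `c(precision, recall)`
#' @export
precision_recall <- function(m) {
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else {
    warning("precision undefined (no predictions); reporting 0")
    0
  }
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else {
    warning("recall undefined (no ground truth); reporting 0")
    0
  }
  c(precision = p, recall = r)
}

# ranked TP flags: greedy matching in descending score order
ranked_tp_flags <- function(preds, gts, iou_threshold) {
  np <- length(preds$instances); ng <- length(gts$instances)
  ord <- order(-detection_scores(preds), seq_len(np))
  tp <- logical(np)
  if (np > 0 && ng > 0) {
    m <- iou_matrix(preds, gts)
    taken <- logical(ng)
    for (k in seq_along(ord)) {
      i <- ord[k]
      cand <- which(!taken & m[i, ] >= iou_threshold)
      if (length(cand) == 0) next
      j <- cand[which.max(m[i, cand])]
      taken[j] <- TRUE
      tp[k] <- TRUE
    }
  }
  tp
}

#' Average precision (area under the precision-recall curve)
#'
#' Predictions ranked by descending score accumulate precision-recall
#' points; AP is the sum of `(r_i - r_{i-1}) * p~(r_i)` with `p~` the
#' right-continuous precision envelope (all-point interpolation). AP50 and
#' AP75 are this quantity at IoU thresholds 0.50 and 0.75.
#'
#' @param preds,gts [detection_set]s; predictions carry scores
#' @param iou_threshold IoU validity threshold
#' @param interpolation `"all_point"` (default) or `"eleven_point"`
#' @return AP in `[0, 1]`
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5,
                              interpolation = c("all_point", "eleven_point")) {
  interpolation <- match.arg(interpolation)
  ng <- length(gts$instances)
  if (ng == 0) stop("AP undefined: no ground-truth instances")
  if (length(preds$instances) == 0) return(0)
  tp <- ranked_tp_flags(preds, gts, iou_threshold)
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / ng
  if (interpolation == "all_point") {
    env <- rev(cummax(rev(prec)))
    sum(diff(c(0, rec)) * env)
  } else {
    sapply(seq(0, 1, by = 0.1), function(r0) {
      ok <- rec >= r0
      if (any(ok)) max(prec[ok]) else 0
    }) |> mean()
  }
}

#' Average recall at fixed IoU thresholds
#'
#' Recall using the top `max_detections` predictions by score at each
#' stated IoU threshold, averaged over the thresholds (`AR = mean of the
#' per-threshold recalls`; a single threshold collapses to that recall).
#' AR50 / AR75 are the single-threshold values at 0.50 / 0.75.
#'
#' @param preds,gts [detection_set]s
#' @param iou_thresholds one or more IoU thresholds
#' @param max_detections prediction budget (default unlimited)
#' @return AR in `[0, 1]`
#' @export
average_recall <- function(preds, gts, iou_thresholds = 0.5,
                           max_detections = Inf) {
  ng <- length(gts$instances)
  if (ng == 0) stop("AR undefined: no ground-truth instances")
  np <- length(preds$instances)
  if (is.finite(max_detections) && np > max_detections) {
    keep <- order(-detection_scores(preds), seq_len(np))[seq_len(max_detections)]
    preds <- detection_set(preds$instances[sort(keep)], frame = preds$frame)
  }
  recalls <- vapply(iou_thresholds, function(th) {
    sum(ranked_tp_flags(preds, gts, th)) / ng
  }, numeric(1))
  mean(recalls)
}

#' Regression agreement metrics
#'
#' `R2 = 1 - SS_res / SS_tot`, `RMSE = sqrt(mean((y - yhat)^2))`,
#' `rRMSE = RMSE / mean(y)` reported in percent.
#'
#' @param y actual measured values
#' @param yhat predicted values
#' @return named list `r2, rmse, rrmse_pct`
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0 && ss_res > 0)
    stop("R2 undefined: constant observations with nonzero residuals")
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  rmse <- sqrt(mean((y - yhat)^2))
  if (mean(y) == 0) stop("rRMSE undefined: zero mean observation")
  list(r2 = r2, rmse = rmse, rrmse_pct = 100 * rmse / mean(y))
}

#' Classification metrics from a confusion matrix
#'
#' Rows are the true classes, columns the predicted classes. Accuracy is
#' the trace over the total; per-class precision, recall and F1 come from
#' the one-vs-rest reduction; macro averages are unweighted means.
#'
#' @param cm square numeric matrix of counts (optionally named)
#' @return list with `accuracy`, `per_class` (data frame `class,
#'   precision, recall, f1`) and `macro` (named vector)
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  labels <- rownames(cm)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(cm)))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / total,
       per_class = data.frame(class = labels, precision = unname(prec),
                              recall = unname(rec), f1 = unname(f1)),
       macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)))
}

#' Relative improvement in percent
#'
#' `100 * (new - base) / base`.
#'
#' @param new_value,base_value metric values; `base_value` must be nonzero
#' @export
relative_improvement <- function(new_value, base_value) {
  if (any(base_value == 0)) stop("relative improvement undefined for zero base")
  100 * (new_value - base_value) / base_value
}

#' Sampling-stability report for two repeated samples
#'
#' Means, sample standard deviations (n-1 denominator), the two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction) and
#' the Pearson correlation of the paired values.
#'
#' @param sample1,sample2 equal-length numeric vectors
#' @return list `mean1, mean2, sd1, sd2, p_value, correlation`
#' @export
sampling_stability <- function(sample1, sample2) {
  stopifnot(length(sample1) == length(sample2), length(sample1) >= 3)
  if (sd(sample1) == 0 || sd(sample2) == 0)
    stop("correlation undefined: zero variance sample")
  wt <- suppressWarnings(
    wilcox.test(sample1, sample2, exact = FALSE, correct = FALSE))
  list(mean1 = mean(sample1), mean2 = mean(sample2),
       sd1 = sd(sample1), sd2 = sd(sample2),
       p_value = wt$p.value,
       correlation = cor(sample1, sample2))
}

#' Agreement between a predicted grid and reference boundaries
#'
#' Plots are paired by nearest centroid (greedy, closest pairs first);
#' each pair contributes its centroid Euclidean distance and box IoU, and
#' the report carries their means and sample standard deviations, the
#' standard layout for segmentation-agreement tables. Unpairable plots are
#' counted as missing and excluded from the means.
#'
#' @param predicted a `plot_grid`, `plot_seg_result`, or `n x 4` box matrix
#' @param truth_boxes `m x 4` reference box matrix in the same frame
#' @param max_distance pairing radius in pixels (default: half the mean
#'   reference box diagonal)
#' @return list with `per_plot` data frame (`pred_id, truth_id, distance,
#'   iou`), `mean_distance, sd_distance, mean_iou, sd_iou, n_paired,
#'   n_missing`
#' @export
grid_agreement <- function(predicted, truth_boxes, max_distance = NULL) {
  if (inherits(predicted, "plot_seg_result")) predicted <- predicted$grid
  pred_boxes <- if (inherits(predicted, "plot_grid")) predicted$boundaries
                else predicted
  tb <- truth_boxes
  pc <- cbind((pred_boxes[, 1] + pred_boxes[, 3]) / 2,
              (pred_boxes[, 2] + pred_boxes[, 4]) / 2)
  tc <- cbind((tb[, 1] + tb[, 3]) / 2, (tb[, 2] + tb[, 4]) / 2)
  if (is.null(max_distance)) {
    diag_len <- sqrt((tb[, 3] - tb[, 1])^2 + (tb[, 4] - tb[, 2])^2)
    max_distance <- mean(diag_len) / 2
  }
  d <- sqrt(outer(pc[, 1], tc[, 1], "-")^2 + outer(pc[, 2], tc[, 2], "-")^2)
  cand <- which(d <= max_distance, arr.ind = TRUE)
  per <- data.frame(pred_id = integer(0), truth_id = integer(0),
                    distance = numeric(0), iou = numeric(0))
  if (nrow(cand)) {
    ord <- order(d[cand])
    used_p <- logical(nrow(pc)); used_t <- logical(nrow(tc))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      per <- rbind(per, data.frame(
        pred_id = i, truth_id = j, distance = d[i, j],
        iou = iou(pred_boxes[i, ], tb[j, ])))
    }
  }
  list(per_plot = per,
       mean_distance = mean(per$distance),
       sd_distance = if (nrow(per) > 1) sd(per$distance) else 0,
       mean_iou = mean(per$iou),
       sd_iou = if (nrow(per) > 1) sd(per$iou) else 0,
       n_paired = nrow(per),
       n_missing = nrow(tb) - nrow(per))
}
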