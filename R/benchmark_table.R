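#' Published panicle-detection benchmark table
#'
#' Reference AP/AR values for the two detector backbones (the ResNet-based
#' Mask R-CNN baseline and the multipath-ViT variant) on the four staged
#' UAV panicle datasets, as published alongside the field study this
#' toolkit re-implements the pipeline of. Shipped as data so the
#' relative-improvement arithmetic over the table can be recomputed; the
#' underlying field imagery and trained weights are not redistributable.
#'
#' @return data frame with columns `dataset`, `network`, `ap50`, `ap75`,
#'   `ar50`, `ar75`
#' @export
panicle_benchmark_table <- function() {
  datasets <- c("all_stage", "first_third", "second_third", "final_third")
  data.frame(
    dataset = rep(datasets, 2),
    network = rep(c("mask_rcnn", "panicle_vit"), each = 4),
    ap50 = c(0.600, 0.614, 0.541, 0.616, 0.661, 0.635, 0.652, 0.662),
    ap75 = c(0.152, 0.186, 0.153, 0.161, 0.242, 0.266, 0.205, 0.282),
    ar50 = c(0.660, 0.683, 0.631, 0.683, 0.738, 0.698, 0.730, 0.726),
    ar75 = c(0.273, 0.302, 0.282, 0.303, 0.388, 0.385, 0.344, 0.327))
}

#' Relative improvements across the benchmark table
#'
#' Computes `100 * (vit - baseline) / baseline` for every metric and
#' dataset row of [panicle_benchmark_table()].
#'
#' @param table benchmark table (defaults to the shipped one)
#' @return data frame `dataset, metric, improvement_pct`
#' @export
benchmark_improvements <- function(table = panicle_benchmark_table()) {
  base <- table[table$network == "mask_rcnn", ]
  vit <- table[table$network == "panicle_vit", ]
  vit <- vit[match(base$dataset, vit$dataset), ]
  metrics <- c("ap50", "ap75", "ar50", "ar75")
  out <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(dataset = base$dataset, metric = m,
               improvement_pct = relative_improvement(vit[[m]], base[[m]]))
  }))
  rownames(out) <- NULL
  out
}
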