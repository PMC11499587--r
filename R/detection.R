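#' Detection instances and sets
#'
#' A detection instance is a scored, labeled axis-aligned box with an
#' optional binary mask in the box frame. Boxes are
#' `(xmin, ymin, xmax, ymax)` in 0-based pixels, half-open on the max
#' edges, so a box's area is `(xmax - xmin) * (ymax - ymin)` and the mask
#' (when present) has `round(ymax) - round(ymin)` rows.
#'
#' @param box numeric length-4 `(xmin, ymin, xmax, ymax)`
#' @param mask optional logical matrix in the box frame
#' @param score confidence in `[0, 1]`
#' @param label category name (`"plot"` and `"panicle"` are reserved)
#' @param source_tile optional `(row, col)` index of the originating tile
#' @param polygon optional `n x 2` polygon (mosaic/tile frame) kept for
#'   lossless annotation round trips
#' @return an object of class `detection_instance`
#' @export
detection_instance <- function(box, mask = NULL, score = 1, label = "plot",
                               source_tile = NULL, polygon = NULL) {
  box <- as.numeric(box)
  stopifnot(length(box) == 4L, box[1] < box[3], box[2] < box[4],
            score >= 0, score <= 1)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask),
              nrow(mask) == round(box[4]) - round(box[2]),
              ncol(mask) == round(box[3]) - round(box[1]))
  }
  structure(list(box = box, mask = mask, score = score, label = label,
                 source_tile = source_tile, polygon = polygon),
            class = "detection_instance")
}

#' @rdname detection_instance
#' @param instances list of `detection_instance`
#' @param frame `"tile"` or `"mosaic"`
#' @param image_id identifier used in annotation files
#' @export
detection_set <- function(instances = list(), frame = c("mosaic", "tile"),
                          image_id = 1L) {
  frame <- match.arg(frame)
  stopifnot(all(vapply(instances, inherits, logical(1), "detection_instance")))
  structure(list(instances = instances, frame = frame, image_id = image_id),
            class = "detection_set")
}

#' @export
length.detection_set <- function(x) length(x$instances)

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> %d instances (%s frame)\n",
              length(x$instances), x$frame))
  invisible(x)
}

#' @rdname detection_instance
#' @param x a `detection_set`
#' @export
detection_boxes <- function(x) {
  if (length(x$instances) == 0) return(matrix(numeric(0), ncol = 4))
  do.call(rbind, lapply(x$instances, `[[`, "box"))
}

#' @rdname detection_instance
#' @export
detection_scores <- function(x) {
  vapply(x$instances, `[[`, numeric(1), "score")
}

box_centroid <- function(box) c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)

#' Classical baseline plot detector
#'
#' A deterministic stand-in for a trained instance-segmentation detector,
#' so the full grid pipeline runs without network weights: excess-green
#' index, Otsu threshold shifted by `exg_offset`, morphological closing
#' then opening with a square element of side about the plant spacing,
#' hole filling, and connected components. Components with at least
#' `min_area_px` pixels become instances; the score is the component area
#' divided by the largest component's area (a deterministic proxy, since
#' classical components carry no confidence).
#'
#' @param tile a `tile` or a [mosaic] (detected in place)
#' @param min_area_px minimum component area in pixels squared
#' @param exg_offset additive shift of the automatic threshold
#' @param se_radius structuring-element radius, px; choose about half the
#'   plant spacing in pixels so within-plot gaps close but interplot gaps
#'   survive
#' @return a [detection_set] in the tile frame with masks
#' @export
detect_plots_baseline <- function(tile, min_area_px = 1000, exg_offset = 0,
                                  se_radius = 10L) {
  ras <- if (inherits(tile, "tile")) tile$raster
         else if (inherits(tile, "mosaic")) tile$raster
         else tile
  if (length(dim(ras)) != 3L || dim(ras)[3] != 3L)
    stop("detect_plots_baseline needs an RGB raster")
  exg <- 2 * ras[, , 2] - ras[, , 1] - ras[, , 3]
  mask <- exg > otsu_threshold(exg) + exg_offset
  if (!any(mask)) return(detection_set(list(), frame = "tile"))
  mask <- binary_open(binary_close(mask, se_radius), se_radius)
  mask <- fill_holes(mask)
  lab <- cpp_label_components(mask)
  k <- attr(lab, "n_components")
  if (k == 0) return(detection_set(list(), frame = "tile"))
  st <- cpp_component_stats(lab, k)
  keep <- which(st$area >= min_area_px)
  if (length(keep) == 0) return(detection_set(list(), frame = "tile"))
  amax <- max(st$area[keep])
  insts <- lapply(keep, function(i) {
    rows <- (st$ymin[i] + 1):st$ymax[i]
    cols <- (st$xmin[i] + 1):st$xmax[i]
    detection_instance(
      box = c(st$xmin[i], st$ymin[i], st$xmax[i], st$ymax[i]),
      mask = lab[rows, cols, drop = FALSE] == i,
      score = st$area[i] / amax,
      label = "plot")
  })
  detection_set(insts, frame = "tile")
}

# ---- annotation formats ---------------------------------------------------

#' Read and write COCO / LabelMe annotations
#'
#' COCO instance JSON (`images` / `annotations` / `categories`, bbox as
#' `[x, y, w, h]`, polygon segmentation) and COCO results lists (top-level
#' array with `bbox` and `score`) are supported; polygons are rasterized at
#' read time with the even-odd rule on half-open pixels. LabelMe files hold
#' one image with polygon or rectangle shapes.
#'
#' @param path JSON file path
#' @param rasterize_polygons build masks from polygon segmentations
#' @return a [detection_set] in the mosaic frame
#' @export
read_coco_detections <- function(path, rasterize_polygons = TRUE) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(names(doc))) {
    # results-list format: bbox-only instances, mask absent
    insts <- lapply(doc, function(a) {
      bb <- as.numeric(unlist(a$bbox))
      detection_instance(c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]),
                         score = if (!is.null(a$score)) a$score else 1,
                         label = as.character(
                           if (!is.null(a$category_id)) a$category_id else "plot"))
    })
    return(detection_set(insts, frame = "mosaic"))
  }
  if (is.null(doc$annotations) || is.null(doc$categories))
    stop("malformed COCO file (missing annotations/categories): ", path)
  cats <- setNames(
    vapply(doc$categories, function(c) c$name, character(1)),
    vapply(doc$categories, function(c) as.character(c$id), character(1)))
  insts <- lapply(seq_along(doc$annotations), function(i) {
    a <- doc$annotations[[i]]
    if (is.null(a$bbox) || is.null(a$category_id))
      stop("malformed COCO annotation #", i, " in ", path)
    bb <- as.numeric(unlist(a$bbox))
    box <- c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4])
    mask <- NULL
    poly <- NULL
    if (!is.null(a$segmentation) && length(a$segmentation) > 0 &&
        rasterize_polygons) {
      xy <- as.numeric(unlist(a$segmentation[[1]]))
      poly <- cbind(xy[seq(1, length(xy), 2)], xy[seq(2, length(xy), 2)])
      mask <- polygon_mask(poly, box)
    }
    detection_instance(box, mask = mask,
                       score = if (!is.null(a$score)) a$score else 1,
                       label = cats[[as.character(a$category_id)]],
                       polygon = poly)
  })
  detection_set(insts, frame = "mosaic")
}

# rasterize a polygon into the half-open pixel grid of `box`
polygon_mask <- function(poly, box) {
  x0 <- round(box[1]); y0 <- round(box[2])
  w <- round(box[3]) - x0; h <- round(box[4]) - y0
  if (w < 1 || h < 1) return(NULL)
  cpp_rasterize_polygon(poly[, 1] - x0, poly[, 2] - y0, h, w)
}

#' @rdname read_coco_detections
#' @param set a [detection_set]
#' @param image_size `(width, height)` recorded in the file
#' @param file_name image file name recorded in the file
#' @export
write_coco <- function(set, path, image_size = c(0L, 0L),
                       file_name = "image.png") {
  labs <- unique(c("plot", "panicle",
                   vapply(set$instances, `[[`, character(1), "label")))
  cat_id <- setNames(seq_along(labs), labs)
  anns <- lapply(seq_along(set$instances), function(i) {
    inst <- set$instances[[i]]
    b <- inst$box
    seg <- if (!is.null(inst$polygon)) {
      list(as.numeric(t(inst$polygon)))
    } else {
      list(c(b[1], b[2], b[3], b[2], b[3], b[4], b[1], b[4]))
    }
    list(id = i, image_id = set$image_id,
         category_id = unname(cat_id[[inst$label]]),
         bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
         segmentation = seg,
         area = (b[3] - b[1]) * (b[4] - b[2]),
         iscrowd = 0L, score = inst$score)
  })
  doc <- list(
    images = list(list(id = set$image_id, file_name = file_name,
                       width = image_size[1], height = image_size[2])),
    annotations = anns,
    categories = lapply(labs, function(l)
      list(id = unname(cat_id[[l]]), name = l)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_coco_detections
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$shapes)) stop("malformed LabelMe file (no shapes): ", path)
  insts <- lapply(seq_along(doc$shapes), function(i) {
    s <- doc$shapes[[i]]
    pts <- do.call(rbind, lapply(s$points, as.numeric))
    if (is.null(pts) || nrow(pts) < 2)
      stop("malformed LabelMe shape #", i, " in ", path)
    if (identical(s$shape_type, "rectangle")) {
      box <- c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
      detection_instance(box, label = s$label)
    } else {
      box <- c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
      detection_instance(box, mask = polygon_mask(pts, box),
                         label = s$label, polygon = pts)
    }
  })
  detection_set(insts, frame = "mosaic")
}

#' @rdname read_coco_detections
#' @export
write_labelme <- function(set, path, image_size = c(0L, 0L),
                          file_name = "image.png") {
  shapes <- lapply(set$instances, function(inst) {
    if (!is.null(inst$polygon)) {
      list(label = inst$label,
           points = lapply(seq_len(nrow(inst$polygon)),
                           function(i) as.numeric(inst$polygon[i, ])),
           shape_type = "polygon")
    } else {
      b <- inst$box
      list(label = inst$label,
           points = list(c(b[1], b[2]), c(b[3], b[4])),
           shape_type = "rectangle")
    }
  })
  doc <- list(version = "5.0.1", flags = setNames(list(), character(0)),
              shapes = shapes, imagePath = file_name,
              imageData = NULL,
              imageHeight = image_size[2], imageWidth = image_size[1])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
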