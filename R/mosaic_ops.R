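#' Estimate the dominant grid orientation of a field mosaic
#'
#' Replaces the manual rotation step of desk workflows: vegetation is
#' thresholded with the excess-green index (Otsu), connected-component
#' centroids are extracted, and the circular median (mod 90 degrees) of
#' pairwise nearest-neighbor direction angles gives the grid angle, folded
#' into `(-45, 45]`.
#'
#' @param mos a [mosaic]
#' @param min_area_frac components smaller than this fraction of the
#'   largest component are ignored (specks, panicle blobs)
#' @return grid angle in degrees, in `(-45, 45]`
#' @export
estimate_orientation <- function(mos, min_area_frac = 0.25) {
  exg <- excess_green(mos)
  mask <- exg > otsu_threshold(exg)
  lab <- cpp_label_components(mask)
  k <- attr(lab, "n_components")
  if (k < 1) stop("orientation undetermined: no vegetated regions found")
  st <- cpp_component_stats(lab, k)
  keep <- st$area >= min_area_frac * max(st$area)
  cx <- st$cx[keep]; cy <- st$cy[keep]
  if (length(cx) < 4) stop("orientation undetermined: fewer than 4 vegetated regions")
  d2 <- outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2
  diag(d2) <- Inf
  nn <- apply(d2, 1, which.min)
  ang <- atan2(cy[nn] - cy, cx[nn] - cx) * 180 / pi
  ang <- ang %% 90
  med <- circular_median_mod90(ang)
  if (med > 45) med <- med - 90
  med
}

# circular median on the 90-degree circle: the observed angle minimizing
# the summed wrap-around distance (candidates restricted to observations)
circular_median_mod90 <- function(a) {
  dist <- function(x, y) {
    d <- abs(x - y) %% 90
    pmin(d, 90 - d)
  }
  cost <- vapply(a, function(ai) sum(dist(ai, a)), numeric(1))
  a[which.min(cost)]
}

#' Rotate a mosaic about its center
#'
#' The canvas is expanded so no content is cropped; the mosaic transform is
#' updated so that composing `rotate_mosaic(m, a)` with
#' `rotate_mosaic(., -a)` restores interior points within a pixel.
#'
#' @param mos a [mosaic]
#' @param angle_deg rotation angle, degrees (positive = x toward y)
#' @param fill value for pixels sampled outside the source raster
#' @return the rotated [mosaic]
#' @export
rotate_mosaic <- function(mos, angle_deg, fill = 0) {
  stopifnot(is.finite(angle_deg))
  if (angle_deg %% 360 == 0) return(mos)
  H <- mosaic_height(mos); W <- mosaic_width(mos)
  th <- angle_deg * pi / 180
  W2 <- ceiling(W * abs(cos(th)) + H * abs(sin(th)))
  H2 <- ceiling(W * abs(sin(th)) + H * abs(cos(th)))
  fwd <- at_compose(at_translate((W2 - W) / 2, (H2 - H) / 2),
                    at_rotate_about(angle_deg, W / 2, H / 2))
  inv <- at_invert(fwd)
  ras <- array(0, dim = c(H2, W2, 3))
  for (ch in 1:3)
    ras[, , ch] <- cpp_warp_affine(mos$raster[, , ch], inv, H2, W2, fill)
  mosaic(ras, mos$gsd_mm_per_px, transform = at_compose(fwd, mos$transform))
}

#' Decompose a mosaic into overlapping tiles
#'
#' Tile origins step by `stride = round(tile_size * (1 - overlap_fraction))`
#' along each axis; the final tile is anchored flush to the image edge so
#' coverage is complete. If the mosaic is smaller than the tile along an
#' axis, a single tile clipped to the mosaic covers it.
#'
#' @param mos a [mosaic]
#' @param tile_size tile side, pixels (default 1600)
#' @param overlap_fraction fraction of the tile side shared by adjacent
#'   tiles (default 1/4)
#' @return list of `tile` objects, row-major; each has `raster`, `offset`
#'   (`(x0, y0)` pixels in the mosaic frame) and `index` (`(row, col)`)
#' @export
tile_mosaic <- function(mos, tile_size = 1600L, overlap_fraction = 0.25) {
  stopifnot(tile_size >= 1, overlap_fraction >= 0, overlap_fraction < 1)
  H <- mosaic_height(mos); W <- mosaic_width(mos)
  xs <- tile_origins(W, tile_size, overlap_fraction)
  ys <- tile_origins(H, tile_size, overlap_fraction)
  tiles <- vector("list", length(xs) * length(ys))
  k <- 0L
  for (ti in seq_along(ys)) {
    for (tj in seq_along(xs)) {
      x0 <- xs[tj]; y0 <- ys[ti]
      w <- min(tile_size, W - x0); h <- min(tile_size, H - y0)
      k <- k + 1L
      tiles[[k]] <- structure(
        list(raster = mos$raster[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), , drop = FALSE],
             offset = c(x0, y0), index = c(ti, tj)),
        class = "tile")
    }
  }
  tiles
}

tile_origins <- function(dim, tile_size, overlap_fraction) {
  if (dim <= tile_size) return(0L)
  stride <- max(1L, round(tile_size * (1 - overlap_fraction)))
  xs <- seq.int(0L, dim - tile_size - 1L, by = stride)
  xs <- xs[xs + tile_size <= dim]
  last <- dim - tile_size
  if (length(xs) == 0L || xs[length(xs)] < last) xs <- c(xs, last)
  as.integer(xs)
}

#' @export
print.tile <- function(x, ...) {
  cat(sprintf("<tile> %d x %d px at offset (%d, %d)\n",
              ncol(x$raster), nrow(x$raster), x$offset[1], x$offset[2]))
  invisible(x)
}

#' Translate tile-frame geometry to the mosaic frame
#'
#' @param x a box `(xmin, ymin, xmax, ymax)`, a [detection_instance], or a
#'   [detection_set] in the tile frame
#' @param tile the source `tile`
#' @return the input translated by the tile offset (sets frame `"mosaic"`
#'   and `source_tile` for detection sets)
#' @export
to_mosaic_frame <- function(x, tile) {
  off <- tile$offset
  if (inherits(x, "detection_set")) {
    x$instances <- lapply(x$instances, function(inst) {
      inst$box <- inst$box + c(off, off)
      inst$source_tile <- tile$index
      inst
    })
    x$frame <- "mosaic"
    return(x)
  }
  if (inherits(x, "detection_instance")) {
    x$box <- x$box + c(off, off)
    x$source_tile <- tile$index
    return(x)
  }
  x + c(off, off)
}
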