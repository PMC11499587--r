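#' Mosaic container
#'
#' A mosaic is an RGB raster (numeric `H x W x 3` array with channel values
#' in `[0, 1]`) together with its ground sample distance and the accumulated
#' affine transform from the original acquisition frame to the current
#' raster frame.
#'
#' @param raster numeric `H x W x 3` array, values in `[0, 1]`
#' @param gsd_mm_per_px ground sample distance, mm per pixel
#' @param transform 2x3 affine from the original frame to this raster frame
#' @return an object of class `mosaic`
#' @export
mosaic <- function(raster, gsd_mm_per_px, transform = at_identity()) {
  stopifnot(is.array(raster), length(dim(raster)) == 3L, dim(raster)[3] == 3L,
            dim(raster)[1] >= 1L, dim(raster)[2] >= 1L,
            is.numeric(gsd_mm_per_px), gsd_mm_per_px > 0)
  structure(list(raster = raster, gsd_mm_per_px = gsd_mm_per_px,
                 transform = transform),
            class = "mosaic")
}

#' @export
print.mosaic <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<mosaic> %d x %d px, gsd %.3f mm/px\n", d[2], d[1],
              x$gsd_mm_per_px))
  invisible(x)
}

#' @export
dim.mosaic <- function(x) dim(x$raster)

mosaic_width <- function(m) dim(m$raster)[2]
mosaic_height <- function(m) dim(m$raster)[1]

#' Excess green index
#'
#' `2G - R - B`, a color index separating green vegetation from soil and
#' water background. For the final-third (ripening) canopy the index is
#' lower but remains above the background's.
#'
#' @param raster `H x W x 3` RGB array or a [mosaic]
#' @return numeric `H x W` matrix
#' @export
excess_green <- function(raster) {
  if (inherits(raster, "mosaic")) raster <- raster$raster
  2 * raster[, , 2] - raster[, , 1] - raster[, , 3]
}

#' Otsu threshold
#'
#' Inter-class-variance maximizing threshold of a numeric matrix, computed
#' on a 256-bin histogram over the value range.
#'
#' @param x numeric matrix or vector
#' @param n_bins histogram resolution
#' @return the threshold value; values strictly above it are foreground
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(n_bins, floor((v - r[1]) / diff(r) * n_bins) + 1L), n_bins)
  w <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# ---- PNM raster I/O -------------------------------------------------------
# Portable anymap is the one raster format we can read and write without
# binary dependencies: P6 (binary) for bulk output, P3 (ASCII) for small
# text fixtures. 8-bit depth.

#' Read / write PNM rasters
#'
#' @param path file path; `read_pnm` accepts P3 (ASCII) and P6 (binary) PPM
#' @param raster `H x W x 3` array in `[0, 1]`, or a [mosaic]
#' @param ascii write ASCII P3 instead of binary P6
#' @return `read_pnm` returns an `H x W x 3` array in `[0, 1]`
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P3", "P6")) stop("not a P3/P6 PPM file: ", path)
  tokens <- character(0)
  buf <- character(0)
  # header tokens: width, height, maxval (comments allowed)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PNM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  n <- 3L * w * h
  if (magic == "P6") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, integer(), n = n, quiet = TRUE)
  }
  arr <- array(0, dim = c(h, w, 3))
  # PNM is row-major, interleaved RGB
  for (ch_i in 1:3) {
    arr[, , ch_i] <- matrix(vals[seq(ch_i, n, by = 3)], nrow = h, byrow = TRUE)
  }
  arr / maxval
}

#' @rdname read_pnm
#' @export
write_pnm <- function(raster, path, ascii = FALSE) {
  if (inherits(raster, "mosaic")) raster <- raster$raster
  d <- dim(raster)
  vals <- as.integer(round(pmin(pmax(raster, 0), 1) * 255))
  # interleave channels row-major
  idx <- array(seq_len(d[1] * d[2] * 3), dim = d)
  ord <- as.vector(aperm(idx, c(3, 2, 1)))
  inter <- vals[ord]
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("P3\n%d %d\n255", d[2], d[1]), con)
    writeLines(paste(inter, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n255\n", d[2], d[1]), con, eos = NULL)
    writeBin(as.raw(inter), con)
  }
  invisible(path)
}

# ---- binary morphology via integral-image box sums ------------------------

box_sum <- function(m, r) {
  if (!is.logical(m)) storage.mode(m) <- "logical"
  cpp_box_sum(m, as.integer(r))
}

window_size <- function(r, n, idx) {
  lo <- pmax(idx - r, 1L); hi <- pmin(idx + r, n)
  hi - lo + 1L
}

#' Binary morphology with a square structuring element
#'
#' Dilation, erosion, closing and opening of logical matrices with a square
#' structuring element of side `2 * radius + 1`, computed with integral
#' images (borders are clipped, i.e. the element shrinks at the edges).
#'
#' @param mask logical matrix
#' @param radius structuring-element radius in pixels
#' @name morphology
#' @export
binary_dilate <- function(mask, radius) {
  if (radius < 1) return(mask)
  box_sum(mask, radius) > 0
}

#' @rdname morphology
#' @export
binary_erode <- function(mask, radius) {
  if (radius < 1) return(mask)
  r <- as.integer(radius)
  full <- outer(window_size(r, nrow(mask), seq_len(nrow(mask))),
                window_size(r, ncol(mask), seq_len(ncol(mask))))
  box_sum(mask, r) >= full
}

#' @rdname morphology
#' @export
binary_close <- function(mask, radius) binary_erode(binary_dilate(mask, radius), radius)

#' @rdname morphology
#' @export
binary_open <- function(mask, radius) binary_dilate(binary_erode(mask, radius), radius)

#' @rdname morphology
#' @export
fill_holes <- function(mask) cpp_fill_holes(mask)
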