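#' 2-D affine transforms
#'
#' Affine transforms are plain 2x3 numeric matrices `M` mapping a point
#' `(x, y)` to `(M[1,1] x + M[1,2] y + M[1,3], M[2,1] x + M[2,2] y + M[2,3])`.
#' The package-wide pixel convention is 0-based, origin at the top-left
#' corner, x rightward, y downward; a pixel `(x, y)` covers the half-open
#' square `[x, x+1) x [y, y+1)` and has center `(x + 0.5, y + 0.5)`.
#'
#' @param angle_deg rotation angle in degrees (positive rotates x toward y,
#'   i.e. visually clockwise in image coordinates with y down)
#' @param cx,cy pivot of the rotation, pixels
#' @param dx,dy translation, pixels
#' @name affine
NULL

#' @rdname affine
#' @export
at_identity <- function() {
  matrix(c(1, 0, 0, 1, 0, 0), nrow = 2)
}

#' @rdname affine
#' @export
at_translate <- function(dx, dy) {
  matrix(c(1, 0, 0, 1, dx, dy), nrow = 2)
}

#' @rdname affine
#' @export
at_rotate_about <- function(angle_deg, cx, cy) {
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  # p' = R (p - c) + c
  matrix(c(co, si, -si, co,
           cx - co * cx + si * cy,
           cy - si * cx - co * cy), nrow = 2)
}

#' @rdname affine
#' @param a,b affine transforms; `at_compose(a, b)` applies `b` first
#' @export
at_compose <- function(a, b) {
  l <- a[, 1:2, drop = FALSE]
  cbind(l %*% b[, 1:2, drop = FALSE], l %*% b[, 3] + a[, 3])
}

#' @rdname affine
#' @param m an affine transform
#' @export
at_invert <- function(m) {
  l <- m[, 1:2, drop = FALSE]
  det <- l[1, 1] * l[2, 2] - l[1, 2] * l[2, 1]
  if (abs(det) < 1e-12) stop("affine transform is singular")
  li <- matrix(c(l[2, 2], -l[2, 1], -l[1, 2], l[1, 1]), nrow = 2) / det
  cbind(li, -li %*% m[, 3])
}

#' @rdname affine
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) points
#' @export
at_apply <- function(m, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  t(m[, 1:2] %*% t(pts) + m[, 3])
}

# Map an axis-aligned box through an affine and return the axis-aligned
# bounding box of its four transformed corners.
at_apply_box <- function(m, box) {
  corners <- rbind(c(box[1], box[2]), c(box[3], box[2]),
                   c(box[3], box[4]), c(box[1], box[4]))
  p <- at_apply(m, corners)
  c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
}
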