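# Bounding-box geometry in corner (xmin, ymin, xmax, ymax) and normalized
# center (cx, cy, w, h) conventions. Corner boxes live in pixel units at I/O
# boundaries; the detection head works in normalized center form.

#' Intersection-over-union of two corner boxes
#' @param a,b Numeric vectors `(xmin, ymin, xmax, ymax)`.
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7
box_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

#' IoU of one box against many
#' @param a Numeric vector `(xmin, ymin, xmax, ymax)`.
#' @param B Matrix with one corner box per row.
#' @return Numeric vector of IoUs.
#' @keywords internal
#' @export
box_iou_one_many <- function(a, B) {
  iw <- pmax(0, pmin(a[3], B[, 3]) - pmax(a[1], B[, 1]))
  ih <- pmax(0, pmin(a[4], B[, 4]) - pmax(a[2], B[, 2]))
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) +
    (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter
  out <- inter / ua
  out[ua <= 0] <- 0
  out
}

#' Generalized IoU of two corner boxes
#'
#' `GIoU = IoU - (area(hull) - area(union)) / area(hull)`, in `[-1, 1]`; the
#' associated loss term is `1 - GIoU`.
#' @param a,b Numeric vectors `(xmin, ymin, xmax, ymax)` with positive extent.
#' @return GIoU in `[-1, 1]`.
#' @export
#' @examples
#' giou_box(c(0, 0, 2, 2), c(1, 1, 3, 3)) # ~ -0.0794
giou_box <- function(a, b) {
  stopifnot(a[3] > a[1], a[4] > a[2], b[3] > b[1], b[4] > b[2])
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  hull <- (max(a[3], b[3]) - min(a[1], b[1])) * (max(a[4], b[4]) - min(a[2], b[2]))
  inter / union - (hull - union) / hull
}

#' Convert between corner and normalized center box forms
#'
#' `corners_to_cxcywh()` maps pixel corner boxes to normalized
#' `(cx, cy, w, h)` in `[0, 1]`; `cxcywh_to_corners()` inverts it. Conversions
#' are centralized here and round-trip exactly.
#' @param m Matrix with one box per row.
#' @param image_size Pixel side of the (square) frame.
#' @return Matrix of converted boxes.
#' @export
corners_to_cxcywh <- function(m, image_size) {
  m <- matrix(m, ncol = 4)
  cbind((m[, 1] + m[, 3]) / 2, (m[, 2] + m[, 4]) / 2,
        m[, 3] - m[, 1], m[, 4] - m[, 2]) / image_size
}

#' @rdname corners_to_cxcywh
#' @export
cxcywh_to_corners <- function(m, image_size) {
  m <- matrix(m, ncol = 4)
  cbind(m[, 1] - m[, 3] / 2, m[, 2] - m[, 4] / 2,
        m[, 1] + m[, 3] / 2, m[, 2] + m[, 4] / 2) * image_size
}
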