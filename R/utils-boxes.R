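#' Bounding-box conventions
#'
#' All boxes in this package use 0-based pixel indices and half-open
#' intervals: a box covers columns `[x_min, x_max)` and rows
#' `[y_min, y_max)` of its parent image, so its area is
#' `(x_max - x_min) * (y_max - y_min)` pixels with no off-by-one
#' ambiguity. A pixel at (row r, column c) of an image array has
#' coordinates x = c - 1, y = r - 1.
#'
#' @name box-conventions
NULL

#' Intersection over union of axis-aligned boxes
#'
#' Vectorised over rows: `a` and `b` are data frames (or single named
#' lists) with columns `x_min, y_min, x_max, y_max` under the half-open
#' convention. Disjoint boxes score 0; identical boxes score 1.
#'
#' @param a,b boxes; recycled to a common length.
#' @return numeric vector of IoU values in \[0, 1\].
#' @examples
#' iou(
#'   data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10),
#'   data.frame(x_min = 5, y_min = 5, x_max = 15, y_max = 15)
#' ) # 25 / 175
#' @export
iou <- function(a, b) {
  a <- as.data.frame(a)
  b <- as.data.frame(b)
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  un <- area_a + area_b - inter
  ifelse(un > 0, inter / un, 0)
}

# IoU matrix between every row of `a` (rows) and every row of `b` (cols).
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  ia <- rep(seq_len(nrow(a)), times = nrow(b))
  ib <- rep(seq_len(nrow(b)), each = nrow(a))
  matrix(iou(a[ia, , drop = FALSE], b[ib, , drop = FALSE]),
         nrow = nrow(a), ncol = nrow(b))
}

box_area <- function(boxes) {
  (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
}

assert_valid_boxes <- function(boxes, width = NULL, height = NULL,
                               what = "box") {
  need <- c("x_min", "y_min", "x_max", "y_max")
  missing <- setdiff(need, names(boxes))
  if (length(missing)) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(boxes$x_max < boxes$x_min) || any(boxes$y_max < boxes$y_min)) {
    stop(sprintf("%s has negative extent (max < min)", what), call. = FALSE)
  }
  if (!is.null(width) &&
      (any(boxes$x_min < 0) || any(boxes$x_max > width) ||
       any(boxes$y_min < 0) || any(boxes$y_max > height))) {
    stop(sprintf("%s extends outside the %dx%d image", what, width, height),
         call. = FALSE)
  }
  invisible(boxes)
}
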