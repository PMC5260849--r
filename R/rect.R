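#' Rectangle in pixel coordinates
#'
#' Rectangles address a north-up raster by half-open pixel ranges
#' `[r0, r1) x [c0, c1)` with 0-based indices, row 0 being the northernmost
#' row. A rectangle `rect(50, 160, 50, 160)` therefore covers 110 x 110
#' pixels.
#'
#' @param r0,r1 First row (inclusive) and last row (exclusive), 0-based.
#' @param c0,c1 First column (inclusive) and last column (exclusive), 0-based.
#' @return An object of class `fc_rect`.
#' @export
rect <- function(r0, r1, c0, c1) {
  vals <- c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
  if (any(vals != round(vals))) stop("rectangle bounds must be integers")
  if (r1 <= r0 || c1 <= c0) stop("rectangle must have positive extent")
  structure(list(r0 = as.integer(r0), r1 = as.integer(r1),
                 c0 = as.integer(c0), c1 = as.integer(c1)),
            class = "fc_rect")
}

as_rect <- function(x) {
  if (inherits(x, "fc_rect")) return(x)
  if (is.numeric(x) && length(x) == 4L) return(rect(x[[1]], x[[2]], x[[3]], x[[4]]))
  if (is.list(x) && all(c("r0", "r1", "c0", "c1") %in% names(x)))
    return(rect(x$r0, x$r1, x$c0, x$c1))
  stop("cannot interpret object as a rectangle")
}

#' @export
print.fc_rect <- function(x, ...) {
  cat(sprintf("<rect rows [%d,%d) cols [%d,%d): %d px>\n",
              x$r0, x$r1, x$c0, x$c1, rect_ncell(x)))
  invisible(x)
}

# 1-based R index vectors for a rectangle
rect_rows <- function(r) seq.int(r$r0 + 1L, r$r1)
rect_cols <- function(r) seq.int(r$c0 + 1L, r$c1)

rect_ncell <- function(r) (r$r1 - r$r0) * (r$c1 - r$c0)

rect_in_grid <- function(r, ny, nx) {
  r$r0 >= 0L && r$c0 >= 0L && r$r1 <= ny && r$c1 <= nx
}

rect_inside <- function(inner, outer) {
  inner$r0 >= outer$r0 && inner$r1 <= outer$r1 &&
    inner$c0 >= outer$c0 && inner$c1 <= outer$c1
}

# centre of a rectangle in (row, col) pixel units
rect_centroid <- function(r) {
  c(row = (r$r0 + r$r1 - 1) / 2, col = (r$c0 + r$c1 - 1) / 2)
}
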