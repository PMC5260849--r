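#' Build a categorical land-cover map with named analysis boxes
#'
#' Constructs an abstract north-up land-cover raster (1 pixel = `pixel_km`
#' km, no map projection) holding a large contiguous forest block surrounded
#' by non-forest, optionally with open water and a storm-damage sub-zone of
#' the forest. Named rectangular analysis boxes (conventionally `"forest"`,
#' `"nonforest_1"`, `"nonforest_2"`) are registered for the box statistics
#' downstream.
#'
#' @param nx,ny Grid size in pixels (columns, rows). Row 0 is north.
#' @param forest_rect Rectangle ([rect()]) of forest pixels.
#' @param boxes Named list of rectangles used as analysis boxes. When `NULL`,
#'   default boxes are derived: a `"forest"` box centred in the forest and two
#'   non-forest boxes flanking it to the west and east.
#' @param damage_rect Optional rectangle of storm-damaged forest; must lie
#'   entirely inside `forest_rect`.
#' @param water_rect Optional rectangle of open water (must not intersect the
#'   forest).
#' @param pixel_km Pixel size in km (default 1).
#' @return An object of class `landcover`: list with `classes` (ny x nx
#'   character matrix with values `"forest"`, `"nonforest"`, `"water"`),
#'   `boxes`, `damage_zone`, `pixel_km`, `ny`, `nx`.
#' @examples
#' lc <- build_landcover(200, 200, rect(50, 160, 50, 160))
#' sum(lc$classes == "forest")  # 12100
#' @export
build_landcover <- function(nx, ny, forest_rect, boxes = NULL,
                            damage_rect = NULL, water_rect = NULL,
                            pixel_km = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx > 0L, ny > 0L, pixel_km > 0)
  forest_rect <- as_rect(forest_rect)
  if (!rect_in_grid(forest_rect, ny, nx))
    stop("forest rectangle out of grid bounds")

  classes <- matrix("nonforest", ny, nx)
  classes[rect_rows(forest_rect), rect_cols(forest_rect)] <- "forest"

  if (!is.null(water_rect)) {
    water_rect <- as_rect(water_rect)
    if (!rect_in_grid(water_rect, ny, nx)) stop("water rectangle out of grid bounds")
    if (rects_overlap(water_rect, forest_rect))
      stop("water rectangle is inconsistent: overlaps forest")
    classes[rect_rows(water_rect), rect_cols(water_rect)] <- "water"
  }

  if (!is.null(damage_rect)) {
    damage_rect <- as_rect(damage_rect)
    if (!rect_inside(damage_rect, forest_rect))
      stop("damage rectangle is inconsistent: not contained in forest")
  }

  if (is.null(boxes)) boxes <- default_boxes(forest_rect, ny, nx)
  if (is.null(names(boxes)) || any(names(boxes) == ""))
    stop("analysis boxes must be named")
  boxes <- lapply(boxes, as_rect)
  for (nm in names(boxes)) {
    if (!rect_in_grid(boxes[[nm]], ny, nx))
      stop(sprintf("box '%s' out of grid bounds", nm))
  }

  structure(list(classes = classes, boxes = boxes, damage_zone = damage_rect,
                 forest_rect = forest_rect, pixel_km = pixel_km,
                 ny = ny, nx = nx),
            class = "landcover")
}

rects_overlap <- function(a, b) {
  a$r0 < b$r1 && b$r0 < a$r1 && a$c0 < b$c1 && b$c0 < a$c1
}

# Default analysis boxes: central forest box (inner half of the forest block)
# and two flanking non-forest boxes of the same size, west and east.
default_boxes <- function(forest_rect, ny, nx) {
  fr <- forest_rect
  h <- fr$r1 - fr$r0; w <- fr$c1 - fr$c0
  bh <- max(2L, h %/% 2L); bw <- max(2L, w %/% 2L)
  r0 <- fr$r0 + (h - bh) %/% 2L
  c0 <- fr$c0 + (w - bw) %/% 2L
  fbox <- rect(r0, r0 + bh, c0, c0 + bw)
  west_w <- min(bw, fr$c0); east_w <- min(bw, nx - fr$c1)
  if (west_w < 2L || east_w < 2L)
    stop("forest touches grid edge: cannot derive default non-forest boxes")
  list(
    forest      = fbox,
    nonforest_1 = rect(r0, r0 + bh, fr$c0 - west_w, fr$c0),
    nonforest_2 = rect(r0, r0 + bh, fr$c1, fr$c1 + east_w)
  )
}

#' @export
print.landcover <- function(x, ...) {
  tab <- table(x$classes)
  cat(sprintf("<landcover %d x %d px (%.0f km/px)>\n", x$ny, x$nx, x$pixel_km))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  boxes:", paste(names(x$boxes), collapse = ", "), "\n")
  if (!is.null(x$damage_zone)) cat("  damage zone present\n")
  invisible(x)
}

# logical matrix of pixels belonging to a rectangle
rect_mask <- function(r, ny, nx) {
  m <- matrix(FALSE, ny, nx)
  m[rect_rows(r), rect_cols(r)] <- TRUE
  m
}

#' Look up a named analysis box
#' @param landcover A [build_landcover()] object.
#' @param name Box name.
#' @return The `fc_rect` for that box.
#' @export
get_box <- function(landcover, name) {
  stopifnot(inherits(landcover, "landcover"))
  b <- landcover$boxes[[name]]
  if (is.null(b)) stop(sprintf("no box named '%s'", name))
  b
}
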