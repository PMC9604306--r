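#' Axis-aligned geographic bounding box
#'
#' A rectangle in decimal degrees (WGS84), the unit of both garden definition
#' and null sampling. Boxes must have strictly positive extent on both axes,
#' lie within longitude \[-180, 180\] and latitude \[-90, 90\], and therefore
#' cannot cross the antimeridian; such boxes are rejected at construction.
#'
#' @param min_lon,min_lat,max_lon,max_lat Box edges in decimal degrees.
#'
#' @return An object of class `bbox`: a named list with the four edges.
#' @examples
#' bbox(-112.11, 33.39, -112.09, 33.41)
#' @export
bbox <- function(min_lon, min_lat, max_lon, max_lat) {
  edges <- c(min_lon = min_lon, min_lat = min_lat,
             max_lon = max_lon, max_lat = max_lat)
  if (!is.numeric(edges) || length(edges) != 4L || any(!is.finite(edges))) {
    abort("bbox edges must be four finite numbers.")
  }
  if (min_lon >= max_lon || min_lat >= max_lat) {
    abort("bbox must satisfy min_lon < max_lon and min_lat < max_lat.")
  }
  if (min_lon < -180 || max_lon > 180) {
    abort("bbox longitude out of [-180, 180]: boxes may not cross the antimeridian.")
  }
  if (min_lat < -90 || max_lat > 90) {
    abort("bbox latitude out of [-90, 90].")
  }
  structure(as.list(edges), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox> lon [%g, %g], lat [%g, %g] (%g x %g deg)\n",
              x$min_lon, x$max_lon, x$min_lat, x$max_lat,
              x$max_lon - x$min_lon, x$max_lat - x$min_lat))
  invisible(x)
}

#' Rectangle dimensions in degrees
#'
#' The longitudinal and latitudinal extent of a sampling rectangle. Null
#' rectangles are matched to the garden in degree extent, not projected
#' metres: within one city the degree-to-metre distortion is identical for
#' the garden and every null rectangle, so the comparison is size-matched.
#'
#' @param width_lon Longitudinal extent in decimal degrees (> 0).
#' @param height_lat Latitudinal extent in decimal degrees (> 0).
#'
#' @return An object of class `rect_dims`.
#' @export
rect_dims <- function(width_lon, height_lat) {
  if (!is.numeric(width_lon) || !is.numeric(height_lat) ||
      length(width_lon) != 1L || length(height_lat) != 1L ||
      !is.finite(width_lon) || !is.finite(height_lat) ||
      width_lon <= 0 || height_lat <= 0) {
    abort("rect_dims extents must be single positive finite numbers.")
  }
  structure(list(width_lon = width_lon, height_lat = height_lat),
            class = "rect_dims")
}

#' @export
print.rect_dims <- function(x, ...) {
  cat(sprintf("<rect_dims> %g x %g deg (lon x lat)\n", x$width_lon, x$height_lat))
  invisible(x)
}

#' Extents of a bounding box
#'
#' @param box A [bbox()].
#' @return A [rect_dims()] with the box's longitudinal and latitudinal extent.
#' @export
bbox_dims <- function(box) {
  stopifnot(inherits(box, "bbox"))
  rect_dims(box$max_lon - box$min_lon, box$max_lat - box$min_lat)
}

#' Point-in-box membership (closed bounds)
#'
#' Membership is closed on all four edges: a point lying exactly on any edge
#' is inside. Vectorised over points.
#'
#' @param box A [bbox()].
#' @param lon,lat Numeric vectors of point coordinates in decimal degrees.
#' @return A logical vector.
#' @export
bbox_contains <- function(box, lon, lat) {
  stopifnot(inherits(box, "bbox"))
  lon >= box$min_lon & lon <= box$max_lon &
    lat >= box$min_lat & lat <= box$max_lat
}

#' Centre a rectangle of given dimensions on a point
#'
#' Builds the sampling rectangle for one permutation replicate: a box of the
#' garden's dimensions centred on an observed coordinate. Latitude bounds are
#' clamped to \[-90, 90\]; a rectangle whose longitude bounds would leave
#' \[-180, 180\] (crossing the antimeridian) is a fatal error.
#'
#' @param lat,lon Centroid coordinates in decimal degrees.
#' @param dims A [rect_dims()].
#' @return A [bbox()] centred on the centroid.
#' @export
rectangle_at <- function(lat, lon, dims) {
  stopifnot(inherits(dims, "rect_dims"))
  min_lon <- lon - dims$width_lon / 2
  max_lon <- lon + dims$width_lon / 2
  if (min_lon < -180 || max_lon > 180) {
    abort("sampling rectangle crosses the antimeridian.")
  }
  bbox(min_lon,
       max(lat - dims$height_lat / 2, -90),
       max_lon,
       min(lat + dims$height_lat / 2, 90))
}
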