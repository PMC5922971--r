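# Edge stimuli as line segments, receptor-element activation rules, and the
# chord-displacement geometry used to relate angular to positional change.

#' Physical length (mm) used for "infinite" edges
#'
#' The apparatus edge that spans the whole contact surface is 44 mm long; on a
#' 20 mm skin patch it exceeds the patch diagonal and therefore behaves as an
#' unbounded line.  Edges created with `length = Inf` are realized as segments
#' of this length.
#' @export
INFINITE_EDGE_MM <- 44

#' Create an edge stimulus
#'
#' An edge stimulus is a straight raised edge reduced to a line segment:
#' a center point, a length and an orientation.  Length 0 denotes the raised
#' dot (a degenerate point segment); `Inf` denotes the edge spanning the whole
#' contact area, realized as a [INFINITE_EDGE_MM] (44 mm) segment.
#'
#' Coordinates are in mm with the patch origin at the lower-left corner;
#' orientation is in degrees counter-clockwise from the +x axis.  Because a
#' segment is symmetric under rotation by 180 degrees, orientation is reduced
#' modulo 180 for all geometry.
#'
#' @param center numeric length-2, segment midpoint (mm).
#' @param length edge length in mm (`>= 0`) or `Inf`.
#' @param orientation orientation in degrees (counter-clockwise from +x).
#' @return An object of class `edge_stimulus`.
#' @export
#' @examples
#' edge_stimulus(c(10, 10), length = 4, orientation = 30)
edge_stimulus <- function(center, length, orientation = 0) {
  stopifnot(is.numeric(center), length(center) == 2L, is.finite(center))
  stopifnot(is.numeric(length), length(length) == 1L, length >= 0)
  stopifnot(is.numeric(orientation), length(orientation) == 1L, is.finite(orientation))
  structure(
    list(
      center = as.numeric(center),
      length = length,
      length_mm = if (is.infinite(length)) INFINITE_EDGE_MM else as.numeric(length),
      orientation = orientation %% 180
    ),
    class = "edge_stimulus"
  )
}

#' @export
print.edge_stimulus <- function(x, ...) {
  lab <- if (is.infinite(x$length)) sprintf("infinite (%g mm)", x$length_mm) else
    sprintf("%g mm", x$length)
  cat(sprintf("<edge_stimulus> length %s, orientation %.1f deg, center (%.2f, %.2f) mm\n",
              lab, x$orientation, x$center[1], x$center[2]))
  invisible(x)
}

#' Convert an edge stimulus to a segment
#'
#' @param edge an [edge_stimulus()].
#' @param rotate_by additional rotation (degrees) applied about the edge center.
#' @return 2x2 numeric matrix; rows are the two endpoints (mm).
#' @export
edge_to_segment <- function(edge, rotate_by = 0) {
  stopifnot(inherits(edge, "edge_stimulus"))
  theta <- (edge$orientation + rotate_by) * pi / 180
  h <- edge$length_mm / 2
  u <- c(cos(theta), sin(theta))
  rbind(edge$center - h * u, edge$center + h * u)
}

#' Euclidean distance from points to a closed line segment
#'
#' Vectorized over points.  A degenerate segment (both endpoints equal) gives
#' the distance to that point.
#'
#' @param px,py point coordinates (mm), equal-length numeric vectors.
#' @param seg 2x2 matrix of segment endpoints (rows), as from [edge_to_segment()].
#' @return numeric vector of distances (mm).
#' @export
point_segment_distance <- function(px, py, seg) {
  vx <- seg[2, 1] - seg[1, 1]
  vy <- seg[2, 2] - seg[1, 2]
  l2 <- vx * vx + vy * vy
  dx <- px - seg[1, 1]
  dy <- py - seg[1, 2]
  if (l2 == 0) return(unname(sqrt(dx * dx + dy * dy)))
  t <- pmin(1, pmax(0, (dx * vx + dy * vy) / l2))
  ex <- dx - t * vx
  ey <- dy - t * vy
  unname(sqrt(ex * ex + ey * ey))
}

#' Receptor-element activation by an edge
#'
#' An element is active iff the distance from its center to the edge segment is
#' strictly smaller than the element radius.  For subfield-variant elements the
#' radius is 0.125 mm (250 micron diameter); for uniform-variant elements it
#' equals the unit's receptive-field radius, so activation of the single
#' element is activation of the whole (plate-like) receptive field.
#'
#' @param elements data frame with columns `x`, `y`, `radius` (mm).
#' @param edge an [edge_stimulus()].
#' @param rotate_by extra rotation (degrees) of the edge about its center.
#' @return logical vector, one entry per element.
#' @export
element_active <- function(elements, edge, rotate_by = 0) {
  seg <- edge_to_segment(edge, rotate_by)
  point_segment_distance(elements$x, elements$y, seg) < elements$radius
}

#' Unit activation by an edge
#'
#' A unit is active iff any of its receptor elements is active (logical OR
#' across elements).
#'
#' @param unit a single-unit structure with an `elements` data frame
#'   (columns `x`, `y`, `radius`), e.g. from [get_unit()].
#' @inheritParams element_active
#' @return logical scalar.
#' @export
unit_active <- function(unit, edge, rotate_by = 0) {
  any(element_active(unit$elements, edge, rotate_by))
}

#' Chord displacement of an edge endpoint under rotation
#'
#' The positional change of an edge endpoint when the edge rotates by `delta`
#' degrees about its center: the chord `2 * (length/2) * sin(delta/2)`.  This
#' relates angular discrimination to positional change at the end of the edge
#' (e.g. a 4 mm edge rotated by 5.9 degrees moves its endpoints by 0.21 mm).
#'
#' @param length edge length (mm).
#' @param delta rotation (degrees), `>= 0`.
#' @return displacement (mm).
#' @export
#' @examples
#' endpoint_displacement(4, 5.9)  # 0.21 mm
#' endpoint_displacement(8, 4.0)  # 0.28 mm
endpoint_displacement <- function(length, delta) {
  stopifnot(all(length >= 0), all(delta >= 0))
  2 * (length / 2) * sin(delta / 2 * pi / 180)
}
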