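#' Define a rectangular mapping area
#'
#' The mapping area is the 2-D plane on which the noise map is predicted.
#' Coordinates are in metres with the origin at the lower-left corner; all
#' receiver nodes lie on the implicit 1.5 m measurement plane, so no vertical
#' coordinate is carried.
#'
#' @param width Width of the area in metres (x extent), > 0.
#' @param depth Depth of the area in metres (y extent), > 0.
#' @param grid_spacing Node spacing in metres for the receiver grid
#'   (default 1 m).
#' @param background_level Spatially uniform background noise level in dBA
#'   (must be >= 0).
#' @param working_period Exposure assessment horizon in minutes
#'   (default 480, one 8-hour shift).
#' @return An object of class `nw_area`.
#' @examples
#' mapping_area(100, 70, background_level = 52.2)
#' @export
mapping_area <- function(width, depth, grid_spacing = 1,
                         background_level = 0, working_period = 480) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("`width` must be a single positive number (metres)", call. = FALSE)
  if (!is.numeric(depth) || length(depth) != 1L || !is.finite(depth) || depth <= 0)
    stop("`depth` must be a single positive number (metres)", call. = FALSE)
  if (!is.numeric(grid_spacing) || grid_spacing <= 0)
    stop("`grid_spacing` must be positive", call. = FALSE)
  if (!is.numeric(background_level) || background_level < 0)
    stop("`background_level` must be >= 0 dBA", call. = FALSE)
  if (!is.numeric(working_period) || working_period <= 0)
    stop("`working_period` must be positive (minutes)", call. = FALSE)
  structure(
    list(width = as.numeric(width), depth = as.numeric(depth),
         grid_spacing = as.numeric(grid_spacing),
         background_level = as.numeric(background_level),
         working_period = as.numeric(working_period)),
    class = "nw_area")
}

#' Define an axis-aligned rectangular region
#'
#' Used for moving-machine subareas, worker subareas, and barrier footprints.
#' Boundaries are closed: points on the edge count as inside, so a walker
#' clamped to the edge is still legal.
#'
#' @param x0,y0 Lower-left corner in metres.
#' @param width,depth Extents in metres (>= 0; a zero-size region is a point).
#' @return An object of class `nw_region`.
#' @export
rect_region <- function(x0, y0, width, depth) {
  vals <- c(x0, y0, width, depth)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals)))
    stop("region coordinates must be finite numbers", call. = FALSE)
  if (width < 0 || depth < 0)
    stop("region `width` and `depth` must be >= 0", call. = FALSE)
  structure(
    list(x0 = as.numeric(x0), y0 = as.numeric(y0),
         width = as.numeric(width), depth = as.numeric(depth)),
    class = "nw_region")
}

#' Define a barrier
#'
#' A barrier is a rectangular obstacle (building, wall, stockpile) that
#' screens source-receiver paths crossing its footprint and, when
#' `reflective`, adds a facade reflection to receivers within 1 m of its
#' boundary. Because the model is strictly two-dimensional there is no
#' barrier-top visibility geometry; the screening class is a per-barrier
#' attribute instead.
#'
#' @param region An [rect_region()] footprint.
#' @param screening `"full"` (source hidden from the receiver, -10 dB) or
#'   `"partial"` (source still visible, -5 dB).
#' @param reflective Logical; does the facade reflection (+3 dB within 1 m)
#'   apply to this barrier?
#' @return An object of class `nw_barrier`.
#' @export
barrier <- function(region, screening = c("full", "partial"),
                    reflective = FALSE) {
  if (!inherits(region, "nw_region"))
    stop("`region` must be an nw_region (see rect_region())", call. = FALSE)
  screening <- match.arg(screening)
  structure(
    list(region = region, screening = screening,
         reflective = isTRUE(reflective)),
    class = "nw_barrier")
}

#' Mesh the receiver grid of a mapping area
#'
#' Nodes are laid out at `grid_spacing` intervals starting from the origin,
#' giving `floor(width / spacing) + 1` columns and
#' `floor(depth / spacing) + 1` rows; a 100 m x 70 m area at 1 m spacing
#' meshes to a 101 x 71 node matrix.
#'
#' @param area An [mapping_area()].
#' @return An object of class `nw_grid` with fields `x_coords`, `y_coords`,
#'   `n_cols`, `n_rows`, `spacing`.
#' @export
mesh_grid <- function(area) {
  stopifnot(inherits(area, "nw_area"))
  d <- area$grid_spacing
  n_cols <- floor(area$width / d) + 1L
  n_rows <- floor(area$depth / d) + 1L
  structure(
    list(x_coords = (seq_len(n_cols) - 1L) * d,
         y_coords = (seq_len(n_rows) - 1L) * d,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         spacing = d),
    class = "nw_grid")
}

#' Test whether a point lies inside a region (closed boundary)
#'
#' @param region An [rect_region()].
#' @param p Numeric length-2 point `c(x, y)` in metres.
#' @return `TRUE` iff the point is inside the region or on its edge.
#' @export
region_contains <- function(region, p) {
  stopifnot(inherits(region, "nw_region"), is.numeric(p), length(p) == 2L)
  p[1] >= region$x0 && p[1] <= region$x0 + region$width &&
    p[2] >= region$y0 && p[2] <= region$y0 + region$depth
}

# Liang-Barsky parametric clip of the segment p->q against a rectangle.
# Returns TRUE when the segment (including grazing contact) meets the
# closed rectangle with a parameter interval overlapping (0, 1).
segment_hits_rect <- function(p, q, region) {
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  xmin <- region$x0; xmax <- region$x0 + region$width
  ymin <- region$y0; ymax <- region$y0 + region$depth
  t0 <- 0; t1 <- 1
  for (side in 1:4) {
    if (side == 1L) { den <- -dx; num <- p[1] - xmin }
    else if (side == 2L) { den <- dx; num <- xmax - p[1] }
    else if (side == 3L) { den <- -dy; num <- p[2] - ymin }
    else { den <- dy; num <- ymax - p[2] }
    if (den == 0) {
      if (num < 0) return(FALSE)   # parallel and outside this side
    } else {
      t <- num / den
      if (den < 0) { if (t > t0) t0 <- t } else { if (t < t1) t1 <- t }
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

#' Classify barrier screening along a source-receiver segment
#'
#' Scans all barriers whose footprint intersects the straight segment from
#' source to receiver and returns the strongest screening condition found:
#' `"full"` (source hidden) dominates `"partial"` (source visible behind a
#' low obstacle); `"clear"` when no barrier crosses the path. The result is
#' symmetric in source and receiver.
#'
#' @param src,rcv Numeric length-2 points in metres.
#' @param barriers List of [barrier()] objects (possibly empty).
#' @return One of `"clear"`, `"partial"`, `"full"`.
#' @export
segment_blocked <- function(src, rcv, barriers) {
  if (length(barriers) == 0L) return("clear")
  worst <- "clear"
  for (b in barriers) {
    if (segment_hits_rect(src, rcv, b$region)) {
      if (b$screening == "full") return("full")
      worst <- "partial"
    }
  }
  worst
}

# Distance from a point to a closed rectangle (0 when inside).
dist_to_rect <- function(p, region) {
  dx <- max(region$x0 - p[1], 0, p[1] - (region$x0 + region$width))
  dy <- max(region$y0 - p[2], 0, p[2] - (region$y0 + region$depth))
  sqrt(dx * dx + dy * dy)
}

#' Is a receiver within facade-reflection range of a reflective barrier?
#'
#' Implements the facade-proximity condition of the BS 5228-1 working
#' approximation: a receiver standing within `radius` (default 1 m) of the
#' outside face of a reflective building gains +3 dB. Receivers inside the
#' footprint itself do not qualify.
#'
#' @param rcv Numeric length-2 receiver point.
#' @param barriers List of [barrier()] objects.
#' @param radius Proximity radius in metres, default 1.
#' @return Logical.
#' @export
near_facade <- function(rcv, barriers, radius = 1) {
  for (b in barriers) {
    if (!b$reflective) next
    if (region_contains(b$region, rcv)) next
    if (dist_to_rect(rcv, b$region) <= radius) return(TRUE)
  }
  FALSE
}

#' @export
print.nw_area <- function(x, ...) {
  cat(sprintf("Mapping area: %g m x %g m, grid %g m, background %.1f dBA, working period %g min\n",
              x$width, x$depth, x$grid_spacing, x$background_level,
              x$working_period))
  invisible(x)
}

#' @export
print.nw_region <- function(x, ...) {
  cat(sprintf("Region: (%g, %g) + %g m x %g m\n", x$x0, x$y0, x$width, x$depth))
  invisible(x)
}
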