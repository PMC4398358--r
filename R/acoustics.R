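# Reference quantities: sound intensity 1e-12 W/m^2, sound power 1e-12 W.
I0 <- 1e-12

#' Euclidean distance between two points
#'
#' @param p,q Numeric length-2 points in metres.
#' @return Distance in metres.
#' @export
euclidean_distance <- function(p, q) {
  sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)
}

#' Sound intensity of a hemispherically radiating source
#'
#' Sources sit on a hard, non-absorbing surface and radiate into a
#' half-sphere, so `I = W / (2 * pi * r^2)`. The source-receiver distance is
#' clamped below at `min_r` to avoid the point-source singularity when a
#' receiver node coincides with a source.
#'
#' @param power Emitted sound power in watts (>= 0).
#' @param r Distance in metres (vectorised).
#' @param min_r Minimum effective distance in metres.
#' @return Intensity in W/m^2.
#' @export
source_intensity <- function(power, r, min_r = 1) {
  stopifnot(is.numeric(power), power >= 0)
  r <- pmax(r, min_r)
  power / (2 * pi * r^2)
}

#' Convert a sound intensity to a sound pressure level
#'
#' `L = 10 * log10(I / 1e-12)` dBA.
#'
#' @param i_total Intensity in W/m^2 (vectorised, must be > 0).
#' @return Level in dBA.
#' @export
spl_from_intensity <- function(i_total) {
  if (any(i_total <= 0))
    stop("intensity must be > 0 to express as a level", call. = FALSE)
  10 * log10(i_total / I0)
}

#' Barrier path correction for one source-receiver pair
#'
#' Applies the BS 5228-1 working approximation: -5 dB when the path crosses
#' a partially screening obstacle (source still visible), -10 dB when it
#' crosses a fully screening one (source hidden), and +3 dB reflection when
#' the receiver stands within `facade_radius` of a reflective facade. The
#' screening and reflection corrections can apply simultaneously.
#'
#' @param src,rcv Numeric length-2 points.
#' @param barriers List of [barrier()] objects.
#' @param facade_radius Facade proximity radius in metres, default 1.
#' @return List with `attenuation` (0, -5 or -10 dB) and `reflection`
#'   (0 or +3 dB).
#' @export
path_correction_db <- function(src, rcv, barriers, facade_radius = 1) {
  att <- switch(segment_blocked(src, rcv, barriers),
                clear = 0, partial = -5, full = -10)
  refl <- if (near_facade(rcv, barriers, facade_radius)) 3 else 0
  list(attenuation = att, reflection = refl)
}

# --- vectorised grid helpers -------------------------------------------

# Matrices of node coordinates, [n_rows x n_cols]: rows index y, cols x.
grid_node_matrices <- function(grid) {
  list(x = matrix(grid$x_coords, grid$n_rows, grid$n_cols, byrow = TRUE),
       y = matrix(grid$y_coords, grid$n_rows, grid$n_cols))
}

# Liang-Barsky clip of segments src -> (every node) against one rectangle,
# vectorised over nodes. Returns a logical matrix of hits.
segment_hits_rect_grid <- function(src, nodes, region) {
  dx <- nodes$x - src[1]; dy <- nodes$y - src[2]
  xmin <- region$x0; xmax <- region$x0 + region$width
  ymin <- region$y0; ymax <- region$y0 + region$depth
  t0 <- array(0, dim(dx)); t1 <- array(1, dim(dx))
  miss <- array(FALSE, dim(dx))
  clip <- function(den, num) {
    t <- num / den
    par <- den == 0
    miss <<- miss | (par & num < 0)
    neg <- !par & den < 0
    pos <- !par & den > 0
    t0[neg] <<- pmax(t0[neg], t[neg])
    t1[pos] <<- pmin(t1[pos], t[pos])
  }
  clip(-dx, src[1] - xmin)
  clip(dx, xmax - src[1])
  clip(-dy, src[2] - ymin)
  clip(dy, ymax - src[2])
  !miss & t0 <= t1
}

# Linear attenuation factor (10^(att/10)) from one source to every node.
attenuation_factor_grid <- function(src, nodes, barriers) {
  fac <- array(1, dim(nodes$x))
  if (length(barriers) == 0L) return(fac)
  full <- array(FALSE, dim(nodes$x))
  part <- array(FALSE, dim(nodes$x))
  for (b in barriers) {
    hit <- segment_hits_rect_grid(src, nodes, b$region)
    if (b$screening == "full") full <- full | hit else part <- part | hit
  }
  fac[part] <- 10^(-0.5)
  fac[full] <- 10^(-1)   # full screening dominates partial
  fac
}

# Linear reflection factor per node (receiver property, +3 dB within the
# facade radius of a reflective barrier, outside its footprint).
reflection_factor_grid <- function(nodes, barriers, facade_radius = 1) {
  fac <- array(1, dim(nodes$x))
  for (b in barriers) {
    if (!b$reflective) next
    r <- b$region
    ddx <- pmax(r$x0 - nodes$x, 0, nodes$x - (r$x0 + r$width))
    ddy <- pmax(r$y0 - nodes$y, 0, nodes$y - (r$y0 + r$depth))
    d2 <- ddx^2 + ddy^2
    near <- d2 <= facade_radius^2 & d2 > 0
    fac[near] <- 10^0.3
  }
  fac
}

# Attenuated intensity field of one source over all nodes (linear W/m^2).
source_intensity_grid <- function(position, power, nodes, barriers, min_r) {
  if (power == 0) return(array(0, dim(nodes$x)))
  r2 <- pmax((nodes$x - position[1])^2 + (nodes$y - position[2])^2, min_r^2)
  (power / (2 * pi)) / r2 * attenuation_factor_grid(position, nodes, barriers)
}

#' Compute the instantaneous SPL field over the grid
#'
#' For every node, each active source contributes its hemispherical
#' intensity corrected in the level domain for barrier screening and facade
#' reflection; corrected contributions are summed energetically together
#' with the background intensity `10^(L_BG/10) * 1e-12` and converted back
#' to dBA.
#'
#' @param sources List of active sources, each a list with `position`
#'   (length-2 metres) and `power` (watts, from [effective_power()]).
#' @param grid An [mesh_grid()] result.
#' @param background_level Background noise level, dBA.
#' @param barriers List of [barrier()] objects.
#' @param min_r Source-receiver distance clamp in metres; defaults to the
#'   grid spacing.
#' @return An object of class `nw_field`: list with `levels` (matrix
#'   `n_rows x n_cols`, rows indexing y south to north), `grid`,
#'   `step_index`.
#' @export
compute_field <- function(sources, grid, background_level,
                          barriers = list(), min_r = grid$spacing) {
  stopifnot(inherits(grid, "nw_grid"))
  nodes <- grid_node_matrices(grid)
  i_bg <- if (is.finite(background_level)) 10^(background_level / 10) * I0 else 0
  i_src <- array(0, dim(nodes$x))
  for (s in sources)
    i_src <- i_src + source_intensity_grid(s$position, s$power, nodes,
                                           barriers, min_r)
  refl <- reflection_factor_grid(nodes, barriers)
  total <- i_bg + refl * i_src
  structure(list(levels = spl_from_intensity(total), grid = grid,
                 step_index = NA_integer_),
            class = "nw_field")
}

#' Bilinearly interpolate a gridded level field at an arbitrary point
#'
#' @param field An `nw_field` (or any list with `levels` and `grid`).
#' @param p Numeric length-2 point inside the grid extent.
#' @return Interpolated level in dBA.
#' @export
interpolate_level <- function(field, p) {
  interp_grid_matrix(field$levels, field$grid, p)
}

interp_grid_matrix <- function(levels, grid, p) {
  d <- grid$spacing
  xmax <- grid$x_coords[grid$n_cols]; ymax <- grid$y_coords[grid$n_rows]
  if (p[1] < 0 || p[2] < 0 || p[1] > xmax || p[2] > ymax)
    stop(sprintf("point (%g, %g) lies outside the meshed grid", p[1], p[2]),
         call. = FALSE)
  ix <- min(floor(p[1] / d), grid$n_cols - 2L) + 1L
  iy <- min(floor(p[2] / d), grid$n_rows - 2L) + 1L
  if (grid$n_cols == 1L) ix <- 1L
  if (grid$n_rows == 1L) iy <- 1L
  fx <- (p[1] - grid$x_coords[ix]) / d
  fy <- (p[2] - grid$y_coords[iy]) / d
  ix2 <- min(ix + 1L, grid$n_cols); iy2 <- min(iy + 1L, grid$n_rows)
  (1 - fx) * (1 - fy) * levels[iy,  ix]  +
    fx     * (1 - fy) * levels[iy,  ix2] +
    (1 - fx) * fy     * levels[iy2, ix]  +
    fx     * fy       * levels[iy2, ix2]
}

#' @export
print.nw_field <- function(x, ...) {
  cat(sprintf("SPL field: %d x %d nodes, %.1f-%.1f dBA\n",
              x$grid$n_rows, x$grid$n_cols, min(x$levels), max(x$levels)))
  invisible(x)
}
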