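#' Random-walk parameters
#'
#' Controls the Pearson walk performed by moving machines and workers.
#' Each step moves the walker by `a * (cos(theta), sin(theta))` with the
#' heading `theta` uniform on `[0, 2*pi)` and the step length `a` either
#' uniform on `(0, max_step]` (default) or fixed at `max_step`. The fixed
#' mode exists mainly so the walk can be checked against the Pearson
#' closed form `E|R_n - R_0|^2 = n * a^2`.
#'
#' @param max_step Upper bound (or fixed value) of the step length in
#'   metres; default 5 m per simulation step.
#' @param step_length_dist `"uniform"` or `"fixed"`.
#' @param boundary_policy How a proposed step landing outside the subarea is
#'   handled: `"reject_resample"` (redraw heading and length until inside,
#'   preserving within-area isotropy; falls back to clipping after 1000
#'   redraws) or `"clip"` (clamp the new position to the subarea edge).
#' @return An object of class `nw_walk_params`.
#' @export
walk_params <- function(max_step = 5,
                        step_length_dist = c("uniform", "fixed"),
                        boundary_policy = c("reject_resample", "clip")) {
  if (!is.numeric(max_step) || max_step < 0)
    stop("`max_step` must be >= 0", call. = FALSE)
  structure(
    list(max_step = as.numeric(max_step),
         step_length_dist = match.arg(step_length_dist),
         boundary_policy = match.arg(boundary_policy)),
    class = "nw_walk_params")
}

#' Draw a uniform initial position inside a subarea
#'
#' @param subarea An [rect_region()].
#' @return Numeric length-2 point.
#' @export
initial_position <- function(subarea) {
  stopifnot(inherits(subarea, "nw_region"))
  c(subarea$x0 + stats::runif(1) * subarea$width,
    subarea$y0 + stats::runif(1) * subarea$depth)
}

draw_step_length <- function(params) {
  if (params$step_length_dist == "fixed") params$max_step
  else stats::runif(1) * params$max_step
}

#' Advance a walker by one Pearson step
#'
#' The new position depends only on the previous position, never on the
#' previous heading. Positions never leave the subarea: out-of-bounds
#' proposals are resampled or clipped according to the boundary policy.
#'
#' @param position Current position, numeric length-2, inside `subarea`.
#' @param subarea An [rect_region()] confining the walker.
#' @param params A [walk_params()] object.
#' @return The new position (numeric length-2).
#' @export
walk_step <- function(position, subarea, params) {
  if (params$max_step == 0) return(position)
  xmin <- subarea$x0; xmax <- subarea$x0 + subarea$width
  ymin <- subarea$y0; ymax <- subarea$y0 + subarea$depth
  tries <- if (params$boundary_policy == "reject_resample") 1000L else 1L
  for (i in seq_len(tries)) {
    theta <- stats::runif(1) * 2 * pi
    a <- draw_step_length(params)
    cand <- position + a * c(cos(theta), sin(theta))
    if (cand[1] >= xmin && cand[1] <= xmax &&
        cand[2] >= ymin && cand[2] <= ymax)
      return(cand)
  }
  # budget exhausted (or clip policy): clamp to the subarea edge
  c(min(max(cand[1], xmin), xmax), min(max(cand[2], ymin), ymax))
}
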