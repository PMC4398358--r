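#' Duty-cycle probabilities of a machine
#'
#' Machines operate in three states per simulation step: full power, idle,
#' or off. The three probabilities must sum to one.
#'
#' @param p_on Probability of the full-power state.
#' @param p_off Probability of the off state.
#' @param p_idle Probability of the idle state.
#' @return An object of class `nw_duty`.
#' @examples
#' duty_probs(p_on = 0.9, p_off = 0, p_idle = 0.1)
#' @export
duty_probs <- function(p_on, p_off = 0, p_idle = 0) {
  p <- c(p_on = p_on, p_off = p_off, p_idle = p_idle)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("duty probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("duty probabilities must sum to 1 (got %.10f)", sum(p)),
         call. = FALSE)
  structure(as.list(p), class = "nw_duty")
}

#' Define a stationary machine
#'
#' A fixed noise source characterised by its A-weighted sound power level
#' and its duty-cycle probabilities.
#'
#' @param label Short identifier (e.g. `"S1"`).
#' @param lwa_full A-weighted sound power level at full power, dBA re 1 pW.
#' @param duty A [duty_probs()] object.
#' @param position Numeric length-2 position `c(x, y)` in metres.
#' @param lwa_idle Sound power level in the idle state, dBA. The idle
#'   emission is not a published machine property; by default it is taken
#'   10 dB below `lwa_full`.
#' @return An object of class `nw_machine` with `kind = "stationary"`.
#' @export
stationary_machine <- function(label, lwa_full, duty, position,
                               lwa_idle = lwa_full - 10) {
  new_machine(label, "stationary", lwa_full, lwa_idle, duty,
              position = position)
}

#' Define a moving machine
#'
#' An earth-moving machine that performs a Pearson random walk confined to
#' its working subarea, emitting according to its duty cycle.
#'
#' @inheritParams stationary_machine
#' @param subarea An [rect_region()] the machine is confined to.
#' @param walk A [walk_params()] object controlling step lengths and
#'   boundary handling.
#' @return An object of class `nw_machine` with `kind = "moving"`.
#' @export
moving_machine <- function(label, lwa_full, duty, subarea,
                           walk = walk_params(), lwa_idle = lwa_full - 10) {
  new_machine(label, "moving", lwa_full, lwa_idle, duty,
              subarea = subarea, walk = walk)
}

new_machine <- function(label, kind, lwa_full, lwa_idle, duty,
                        position = NULL, subarea = NULL, walk = NULL) {
  if (!inherits(duty, "nw_duty"))
    stop("`duty` must be a duty_probs() object", call. = FALSE)
  if (!is.numeric(lwa_full) || !is.finite(lwa_full))
    stop("`lwa_full` must be finite (dBA)", call. = FALSE)
  if (!is.numeric(lwa_idle) || !is.finite(lwa_idle) || lwa_idle > lwa_full)
    stop("`lwa_idle` must be finite and <= lwa_full", call. = FALSE)
  if (kind == "stationary") {
    if (is.null(position) || length(position) != 2L || !is.numeric(position))
      stop("stationary machine needs a length-2 `position`", call. = FALSE)
    position <- as.numeric(position)
  } else {
    if (!inherits(subarea, "nw_region"))
      stop("moving machine needs an rect_region() `subarea`", call. = FALSE)
    if (!inherits(walk, "nw_walk_params"))
      stop("moving machine needs walk_params()", call. = FALSE)
  }
  structure(
    list(label = as.character(label), kind = kind,
         lwa_full = as.numeric(lwa_full), lwa_idle = as.numeric(lwa_idle),
         duty = duty, position = position, subarea = subarea, walk = walk),
    class = "nw_machine")
}

#' Sample one duty-cycle state
#'
#' Draws exactly one uniform variate and maps it to `"full"`, `"idle"` or
#' `"off"` with the machine's duty probabilities (thresholds in that order).
#'
#' @param duty A [duty_probs()] object.
#' @return One of `"off"`, `"idle"`, `"full"`.
#' @export
sample_duty_state <- function(duty) {
  if (!inherits(duty, "nw_duty")) duty <- do.call(duty_probs, as.list(duty))
  u <- stats::runif(1)
  if (u < duty$p_on) "full"
  else if (u < duty$p_on + duty$p_idle) "idle"
  else "off"
}

#' Convert an A-weighted sound power level to watts
#'
#' `W = 10^(LWA / 10) * 1e-12`, the reference sound power being 1 pW.
#'
#' @param lwa Sound power level in dBA re 1 pW (vectorised).
#' @return Sound power in watts.
#' @examples
#' sound_power_watts(120)  # 1 W
#' @export
sound_power_watts <- function(lwa) {
  stopifnot(is.numeric(lwa), all(is.finite(lwa)))
  10^(lwa / 10) * 1e-12
}

#' Emitted sound power of a machine in a given duty state
#'
#' Full power uses `lwa_full`, idle uses `lwa_idle`, and an off machine
#' emits nothing (the background field remains).
#'
#' @param machine An `nw_machine`.
#' @param state `"off"`, `"idle"` or `"full"`.
#' @return Sound power in watts.
#' @export
effective_power <- function(machine, state) {
  switch(state,
         off  = 0,
         idle = sound_power_watts(machine$lwa_idle),
         full = sound_power_watts(machine$lwa_full),
         stop(sprintf("unknown duty state '%s'", state), call. = FALSE))
}

#' @export
print.nw_machine <- function(x, ...) {
  where <- if (x$kind == "stationary")
    sprintf("at (%g, %g)", x$position[1], x$position[2])
  else
    sprintf("in subarea (%g, %g) + %g x %g", x$subarea$x0, x$subarea$y0,
            x$subarea$width, x$subarea$depth)
  cat(sprintf("%s machine %s: LWA %.1f dBA (idle %.1f) %s, P(on/off/idle) = %.2f/%.2f/%.2f\n",
              x$kind, x$label, x$lwa_full, x$lwa_idle, where,
              x$duty$p_on, x$duty$p_off, x$duty$p_idle))
  invisible(x)
}
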