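#' Occupational exposure dose convention
#'
#' The dose accumulates as `t / T_allowed(L)` with
#' `T_allowed(L) = criterion_duration * 2^((CL - L) / Q)`: the allowed
#' duration halves for every `Q` dB above the criterion level. The default
#' convention (Q = 3 dB, CL = 90 dBA, 8 h) reproduces dosimeter readings
#' reported for 30-minute workplace measurements; a 5-dB exchange rate can
#' be selected for OSHA-style assessments.
#'
#' @param exchange_rate Exchange rate Q in dB per halving of allowed time.
#' @param criterion_level Criterion level CL in dBA (100% dose for a full
#'   criterion duration at this level).
#' @param criterion_duration Criterion duration in minutes (default 480).
#' @return An object of class `nw_exposure_config`.
#' @export
exposure_config <- function(exchange_rate = 3, criterion_level = 90,
                            criterion_duration = 480) {
  stopifnot(exchange_rate > 0, criterion_duration > 0)
  structure(list(exchange_rate = exchange_rate,
                 criterion_level = criterion_level,
                 criterion_duration = criterion_duration),
            class = "nw_exposure_config")
}

#' Noise dose of an exposure series
#'
#' The series is treated as equal time slices spanning `duration` minutes.
#' For a constant level `L` this reduces to
#' `100 * (duration / criterion_duration) * 2^((L - CL) / Q)`.
#'
#' @param levels Numeric vector of dBA levels (equal step durations).
#' @param duration Total exposure duration in minutes.
#' @param config An [exposure_config()].
#' @return Dose in percent of the allowable daily exposure.
#' @examples
#' dose_percent(85.9, 30)  # 2.4% at Q = 3, CL = 90
#' @export
dose_percent <- function(levels, duration, config = exposure_config()) {
  if (length(levels) == 0L) stop("empty level series", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  t_step <- duration / length(levels)
  q <- config$exchange_rate
  100 * sum(t_step / (config$criterion_duration *
                        2^((config$criterion_level - levels) / q)))
}

#' Time-weighted average level from a dose
#'
#' `TWA = CL + Q * log2(dose / 100)`: the constant level which, sustained
#' for the full criterion duration, accumulates the same dose.
#'
#' @param dose Dose in percent (> 0).
#' @param config An [exposure_config()].
#' @return TWA in dBA.
#' @export
twa_from_dose <- function(dose, config = exposure_config()) {
  if (any(dose <= 0)) stop("`dose` must be > 0", call. = FALSE)
  config$criterion_level + config$exchange_rate * log2(dose / 100)
}

#' Exceedance noise indices L10, L50, L90
#'
#' `Lx` is the level exceeded x% of the time, i.e. the (100 - x)th
#' percentile of the series, computed with linear interpolation between
#' order statistics.
#'
#' @param levels Numeric vector of dBA levels.
#' @return Named numeric vector `c(L10, L50, L90)`.
#' @export
noise_indices <- function(levels) {
  stopifnot(length(levels) >= 1)
  q <- stats::quantile(levels, probs = c(0.9, 0.5, 0.1), names = FALSE,
                       type = 7)
  c(L10 = q[1], L50 = q[2], L90 = q[3])
}

#' Descriptive statistics of a level series
#'
#' @param levels Numeric vector of dBA levels.
#' @param bin_width Histogram bin width in dB (default 1).
#' @return A list of class `nw_level_stats`: `laeq` (energy mean), `std`,
#'   `min`, `max`, `breaks`, `counts`, `pdf` (histogram mass per bin,
#'   summing to 1), `cdf` (empirical distribution function), `L10`, `L50`,
#'   `L90`, `n`.
#' @export
level_statistics <- function(levels, bin_width = 1) {
  stopifnot(length(levels) >= 1, bin_width > 0)
  lo <- floor(min(levels) / bin_width) * bin_width
  hi <- ceiling(max(levels) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(levels, breaks = breaks, plot = FALSE)
  idx <- noise_indices(levels)
  structure(
    list(laeq = aggregate_laeq(levels),
         std = if (length(levels) > 1) stats::sd(levels) else 0,
         min = min(levels), max = max(levels),
         breaks = h$breaks, counts = h$counts,
         pdf = h$counts / length(levels),
         cdf = stats::ecdf(levels),
         L10 = unname(idx["L10"]), L50 = unname(idx["L50"]),
         L90 = unname(idx["L90"]), n = length(levels)),
    class = "nw_level_stats")
}

risk_zone_levels <- c("Safe", "Tolerable", "Low risk", "Moderate risk",
                      "High risk", "Extremely high risk")

#' Classify levels into noise risk zones
#'
#' Risk banding: below 66 dBA Safe, then Tolerable, Low risk, Moderate
#' risk and High risk in 5-dB bands, and Extremely high risk from 86 dBA
#' upward. Bands are left-closed, right-open.
#'
#' @param level Numeric vector of dBA levels.
#' @return Ordered factor over the six zone categories.
#' @examples
#' classify_risk(c(60, 83, 86))
#' @export
classify_risk <- function(level) {
  stopifnot(all(is.finite(level)))
  cut(level, breaks = c(-Inf, 66, 71, 76, 81, 86, Inf),
      labels = risk_zone_levels, right = FALSE, ordered_result = TRUE)
}

#' Risk-zone composition of a noise map
#'
#' @param laeq_grid Numeric matrix of LAeq values.
#' @return A list of class `nw_risk_zones`: `zones` (character matrix of
#'   category names, the grid's shape) and `percentages` (named vector over
#'   the six categories,
#'   summing to 100).
#' @export
risk_zone_percentages <- function(laeq_grid) {
  z <- classify_risk(as.vector(laeq_grid))
  pct <- 100 * table(z) / length(z)
  zones <- matrix(as.character(z), nrow(laeq_grid), ncol(laeq_grid))
  structure(list(zones = zones,
                 percentages = stats::setNames(as.numeric(pct), names(pct))),
            class = "nw_risk_zones")
}

#' Check a noise map against a permissible level
#'
#' @param laeq_grid Numeric matrix of LAeq values.
#' @param limit Permissible level in dBA; a node exceeds when its LAeq is
#'   strictly above the limit.
#' @return List with `mask` (logical matrix) and `percent_exceeding`.
#' @export
check_limit <- function(laeq_grid, limit) {
  stopifnot(all(is.finite(laeq_grid)), is.finite(limit))
  mask <- laeq_grid > limit
  list(mask = mask, percent_exceeding = 100 * mean(mask))
}

#' Personal exposure summary per worker group
#'
#' Computes, for each worker group of a simulation result, the LAeq of its
#' exposure series, the noise dose over the scenario's working period, and
#' the corresponding TWA. With several walkers per group, per-walker
#' results are averaged.
#'
#' @param result An `nw_result` from [run_simulation()].
#' @param config An [exposure_config()]; defaults to the scenario's.
#' @param duration Exposure duration in minutes; defaults to the mapping
#'   area's working period.
#' @return A data.frame with columns `group`, `laeq`, `dose`, `twa`,
#'   `duration`.
#' @export
worker_exposure <- function(result, config = NULL, duration = NULL) {
  sc <- result$scenario
  if (is.null(config)) config <- sc$exposure
  if (is.null(config)) config <- exposure_config()
  if (is.null(duration)) duration <- sc$area$working_period
  groups <- names(result$worker_series)
  rows <- lapply(groups, function(nm) {
    series <- result$worker_series[[nm]]
    laeq <- mean(apply(series, 2, aggregate_laeq))
    dose <- mean(apply(series, 2, dose_percent, duration = duration,
                       config = config))
    data.frame(group = nm, laeq = laeq, dose = dose,
               twa = twa_from_dose(dose, config), duration = duration)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(group = character(), laeq = numeric(), dose = numeric(),
                  twa = numeric(), duration = numeric())
  rownames(out) <- NULL
  out
}

#' @export
print.nw_level_stats <- function(x, ...) {
  cat(sprintf("Level series (n = %d): LAeq %.1f dBA, sd %.2f, range %.1f-%.1f\n",
              x$n, x$laeq, x$std, x$min, x$max))
  cat(sprintf("  L10 %.1f, L50 %.1f, L90 %.1f dBA\n", x$L10, x$L50, x$L90))
  invisible(x)
}

#' @export
print.nw_risk_zones <- function(x, ...) {
  cat("Risk-zone composition (% of area):\n")
  for (nm in names(x$percentages))
    cat(sprintf("  %-20s %6.2f\n", nm, x$percentages[nm]))
  invisible(x)
}
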