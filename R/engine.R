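#' Define a worker group
#'
#' A group of workers moving randomly inside a working subarea; each walker
#' performs an independent Pearson walk and its exposure is read from the
#' current step's field at its position. The group exposure is the mean of
#' its walkers.
#'
#' @param label Group identifier.
#' @param subarea An [rect_region()] the workers stay in.
#' @param n_walkers Number of independent walkers (default 1).
#' @param walk A [walk_params()] object.
#' @return An object of class `nw_worker_group`.
#' @export
worker_group <- function(label, subarea, n_walkers = 1, walk = walk_params()) {
  stopifnot(inherits(subarea, "nw_region"), n_walkers >= 1)
  structure(list(label = as.character(label), subarea = subarea,
                 n_walkers = as.integer(n_walkers), walk = walk),
            class = "nw_worker_group")
}

#' Assemble a workplace scenario
#'
#' @param area An [mapping_area()].
#' @param stationary List of [stationary_machine()] objects.
#' @param moving List of [moving_machine()] objects.
#' @param worker_groups List of [worker_group()] objects.
#' @param barriers List of [barrier()] objects.
#' @param simulation Optional [sim_config()] carried with the scenario
#'   (e.g. from a scenario file).
#' @param exposure Optional [exposure_config()].
#' @return An object of class `nw_scenario`.
#' @export
scenario <- function(area, stationary = list(), moving = list(),
                     worker_groups = list(), barriers = list(),
                     simulation = NULL, exposure = NULL) {
  sc <- structure(
    list(area = area, stationary = stationary, moving = moving,
         worker_groups = worker_groups, barriers = barriers,
         simulation = simulation,
         exposure = if (is.null(exposure)) exposure_config() else exposure),
    class = "nw_scenario")
  msg <- validate_scenario(sc)
  if (length(msg)) stop(paste(msg, collapse = "\n"), call. = FALSE)
  sc
}

#' Validate a scenario
#'
#' Checks types and that every machine position, subarea and barrier lies
#' inside the mapping area. Returns a character vector of problems (empty
#' when valid); [scenario()] and [read_scenario()] raise these as errors.
#'
#' @param sc An `nw_scenario` (or candidate list).
#' @return Character vector of validation messages.
#' @export
validate_scenario <- function(sc) {
  msg <- character()
  if (!inherits(sc$area, "nw_area")) return("`area` is not a mapping_area()")
  whole <- rect_region(0, 0, sc$area$width, sc$area$depth)
  inside <- function(r) {
    r$x0 >= 0 && r$y0 >= 0 && r$x0 + r$width <= sc$area$width &&
      r$y0 + r$depth <= sc$area$depth
  }
  for (m in sc$stationary) {
    if (!inherits(m, "nw_machine") || m$kind != "stationary") {
      msg <- c(msg, "stationary machine entry is not a stationary_machine()")
    } else if (!region_contains(whole, m$position)) {
      msg <- c(msg, sprintf("machine %s: position (%g, %g) outside mapping area",
                            m$label, m$position[1], m$position[2]))
    }
  }
  for (m in sc$moving) {
    if (!inherits(m, "nw_machine") || m$kind != "moving") {
      msg <- c(msg, "moving machine entry is not a moving_machine()")
    } else if (!inside(m$subarea)) {
      msg <- c(msg, sprintf("machine %s: subarea outside mapping area", m$label))
    }
  }
  for (g in sc$worker_groups) {
    if (!inherits(g, "nw_worker_group")) {
      msg <- c(msg, "worker group entry is not a worker_group()")
    } else if (!inside(g$subarea)) {
      msg <- c(msg, sprintf("worker group %s: subarea outside mapping area",
                            g$label))
    }
  }
  for (b in sc$barriers) {
    if (!inherits(b, "nw_barrier")) msg <- c(msg, "barrier entry is not a barrier()")
    else if (!inside(b$region)) msg <- c(msg, "barrier region outside mapping area")
  }
  msg
}

#' Simulation run configuration
#'
#' @param n_steps Number of walk steps (>= 1). Each step represents an
#'   equal slice of the working period, `working_period / n_steps` minutes.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param repeats Number of independent repeats for experiment sweeps.
#' @param record_fields Keep every per-step SPL field in the result
#'   (memory-heavy; default `FALSE`).
#' @return An object of class `nw_sim_config`.
#' @export
sim_config <- function(n_steps = 1500, seed = 1L, repeats = 1L,
                       record_fields = FALSE) {
  stopifnot(n_steps >= 1, repeats >= 1)
  structure(list(n_steps = as.integer(n_steps), seed = as.integer(seed),
                 repeats = as.integer(repeats),
                 record_fields = isTRUE(record_fields)),
            class = "nw_sim_config")
}

#' Aggregate a level series into an equivalent continuous level
#'
#' `LAeq = 10 * log10(mean(10^(L/10)))` with equal weight per element
#' (steps are equal time slices).
#'
#' @param levels Numeric vector of dBA levels.
#' @return LAeq in dBA.
#' @examples
#' aggregate_laeq(c(80, 90))  # 87.40 dBA
#' @export
aggregate_laeq <- function(levels) {
  if (length(levels) == 0L) stop("empty level series", call. = FALSE)
  10 * log10(mean(10^(levels / 10)))
}

#' Run the random-walk noise-mapping simulation
#'
#' Executes the step loop: per step (a) a duty state is sampled for every
#' machine, (b) every moving machine advances one Pearson step inside its
#' subarea, (c) the instantaneous SPL field is computed over the grid,
#' (d) every worker advances one step and reads its exposure from the
#' current field by bilinear interpolation. After the loop the per-node
#' LAeq, standard deviation, minimum and maximum of the step levels are
#' returned together with the per-group exposure series.
#'
#' One seeded RNG stream drives the run; the draw order is: initial
#' positions of moving machines then workers, then per step duty states
#' (stationary machines first, then moving), moving-machine steps, worker
#' steps. Identical seeds give bit-identical results.
#'
#' @param sc An [scenario()].
#' @param config A [sim_config()]; defaults to the scenario's own
#'   `simulation` entry if present.
#' @return An object of class `nw_result` with elements `laeq_grid`,
#'   `std_grid`, `min_grid`, `max_grid` (matrices, rows = y from the south
#'   edge), `grid`, `worker_series` (list per group: matrix steps x
#'   walkers), `worker_positions`, `config`, `scenario`, and optionally
#'   `fields`.
#' @export
run_simulation <- function(sc, config = NULL) {
  stopifnot(inherits(sc, "nw_scenario"))
  if (is.null(config)) config <- sc$simulation
  if (is.null(config)) config <- sim_config()
  msg <- validate_scenario(sc)
  if (length(msg)) stop(paste(msg, collapse = "\n"), call. = FALSE)
  if (length(sc$stationary) + length(sc$moving) < 1L)
    stop("scenario needs at least one machine", call. = FALSE)

  set.seed(config$seed)
  grid <- mesh_grid(sc$area)
  nodes <- grid_node_matrices(grid)
  n_nodes <- grid$n_rows * grid$n_cols
  min_r <- grid$spacing
  i_bg <- 10^(sc$area$background_level / 10) * I0
  refl <- as.vector(reflection_factor_grid(nodes, sc$barriers))

  # Stationary geometry never changes: precompute, per machine, the linear
  # transfer factor from emitted watts to received intensity at each node
  # (spreading x screening), so each step is a matrix-vector product.
  m <- length(sc$stationary)
  G <- if (m) vapply(sc$stationary, function(mc) {
    as.vector(source_intensity_grid(mc$position, 1, nodes, sc$barriers, min_r))
  }, numeric(n_nodes)) else NULL

  mov_pos <- lapply(sc$moving, function(mc) initial_position(mc$subarea))
  wrk_pos <- lapply(sc$worker_groups, function(g)
    lapply(seq_len(g$n_walkers), function(i) initial_position(g$subarea)))

  n_steps <- config$n_steps
  sum_lin <- numeric(n_nodes); sum_l <- numeric(n_nodes)
  sum_l2 <- numeric(n_nodes)
  min_l <- rep(Inf, n_nodes); max_l <- rep(-Inf, n_nodes)
  worker_series <- lapply(sc$worker_groups, function(g)
    matrix(NA_real_, n_steps, g$n_walkers))
  worker_xy <- lapply(sc$worker_groups, function(g)
    array(NA_real_, c(n_steps, g$n_walkers, 2L)))
  duty_log <- matrix(NA_character_, n_steps, m + length(sc$moving))
  fields <- if (config$record_fields) vector("list", n_steps) else NULL

  for (step in seq_len(n_steps)) {
    states <- character(m + length(sc$moving))
    for (k in seq_len(m)) states[k] <- sample_duty_state(sc$stationary[[k]]$duty)
    for (k in seq_along(sc$moving))
      states[m + k] <- sample_duty_state(sc$moving[[k]]$duty)
    duty_log[step, ] <- states

    for (k in seq_along(sc$moving))
      mov_pos[[k]] <- walk_step(mov_pos[[k]], sc$moving[[k]]$subarea,
                                sc$moving[[k]]$walk)

    i_tot <- rep(i_bg, n_nodes)
    if (m) {
      w <- vapply(seq_len(m), function(k)
        effective_power(sc$stationary[[k]], states[k]), numeric(1))
      i_tot <- i_tot + refl * drop(G %*% w)
    }
    for (k in seq_along(sc$moving)) {
      w <- effective_power(sc$moving[[k]], states[m + k])
      if (w > 0)
        i_tot <- i_tot + refl * as.vector(
          source_intensity_grid(mov_pos[[k]], w, nodes, sc$barriers, min_r))
    }
    lev <- 10 * log10(i_tot / I0)
    lev_mat <- matrix(lev, grid$n_rows, grid$n_cols)

    sum_lin <- sum_lin + i_tot
    sum_l <- sum_l + lev; sum_l2 <- sum_l2 + lev^2
    min_l <- pmin(min_l, lev); max_l <- pmax(max_l, lev)
    if (config$record_fields)
      fields[[step]] <- structure(list(levels = lev_mat, grid = grid,
                                       step_index = step), class = "nw_field")

    for (gi in seq_along(sc$worker_groups)) {
      g <- sc$worker_groups[[gi]]
      for (wi in seq_len(g$n_walkers)) {
        wrk_pos[[gi]][[wi]] <- walk_step(wrk_pos[[gi]][[wi]], g$subarea, g$walk)
        worker_xy[[gi]][step, wi, ] <- wrk_pos[[gi]][[wi]]
        worker_series[[gi]][step, wi] <-
          interp_grid_matrix(lev_mat, grid, wrk_pos[[gi]][[wi]])
      }
    }
  }

  as_mat <- function(v) matrix(v, grid$n_rows, grid$n_cols)
  n <- n_steps
  var_l <- pmax(sum_l2 / n - (sum_l / n)^2, 0)
  names(worker_series) <- vapply(sc$worker_groups, `[[`, "", "label")
  names(worker_xy) <- names(worker_series)
  structure(
    list(laeq_grid = as_mat(10 * log10(sum_lin / n / I0)),
         std_grid = as_mat(sqrt(var_l * n / max(n - 1, 1))),
         min_grid = as_mat(min_l), max_grid = as_mat(max_l),
         grid = grid, worker_series = worker_series,
         worker_positions = worker_xy, duty_states = duty_log,
         fields = fields, config = config, scenario = sc),
    class = "nw_result")
}

#' LAeq at an arbitrary point of a simulation result
#'
#' @param result An `nw_result`.
#' @param p Numeric length-2 point.
#' @return LAeq in dBA (bilinear interpolation of the LAeq grid).
#' @export
laeq_at <- function(result, p) {
  interp_grid_matrix(result$laeq_grid, result$grid, p)
}

#' Sweep simulation-step settings with repeats
#'
#' Reruns a scenario at several step settings with several repeats each and
#' reads the predicted LAeq at fixed receiver points, the protocol used to
#' validate convergence of the simulation: each (setting, repeat) pair runs
#' with a seed derived deterministically from the base seed
#' (`seed + 1009 * (setting index - 1) + repeat index - 1`).
#'
#' @param sc An [scenario()].
#' @param step_settings Integer vector of step counts
#'   (e.g. `c(100, 250, 500, 750, 1000, 1250, 1500)`).
#' @param repeats Repeats per setting.
#' @param receiver_points Two-column matrix (or data.frame) of receiver
#'   coordinates in metres.
#' @param base_seed Base integer seed.
#' @return A data.frame with one row per (receiver, setting, repeat):
#'   `receiver`, `x`, `y`, `n_steps`, `repeat_idx`, `seed`, `laeq`.
#' @export
experiment_grid <- function(sc, step_settings, repeats, receiver_points,
                            base_seed = 1L) {
  pts <- as.matrix(receiver_points)
  stopifnot(ncol(pts) == 2L, repeats >= 1)
  rows <- vector("list", length(step_settings) * repeats)
  idx <- 0L
  for (si in seq_along(step_settings)) {
    for (ri in seq_len(repeats)) {
      seed <- as.integer(base_seed + 1009L * (si - 1L) + (ri - 1L))
      res <- run_simulation(sc, sim_config(n_steps = step_settings[si],
                                           seed = seed))
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        receiver = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
        n_steps = step_settings[si], repeat_idx = ri, seed = seed,
        laeq = apply(pts, 1, function(p) laeq_at(res, p)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.nw_scenario <- function(x, ...) {
  cat(sprintf("Noise scenario: %g m x %g m, background %.1f dBA\n",
              x$area$width, x$area$depth, x$area$background_level))
  cat(sprintf("  %d stationary machine(s), %d moving machine(s), %d worker group(s), %d barrier(s)\n",
              length(x$stationary), length(x$moving),
              length(x$worker_groups), length(x$barriers)))
  invisible(x)
}

#' @export
print.nw_result <- function(x, ...) {
  cat(sprintf("Simulation result: %d steps, seed %d\n",
              x$config$n_steps, x$config$seed))
  cat(sprintf("  LAeq grid %d x %d nodes: %.1f-%.1f dBA\n",
              x$grid$n_rows, x$grid$n_cols, min(x$laeq_grid), max(x$laeq_grid)))
  if (length(x$worker_series))
    for (nm in names(x$worker_series))
      cat(sprintf("  group %s: LAeq %.1f dBA over %d steps\n", nm,
                  aggregate_laeq(rowMeans(x$worker_series[[nm]])),
                  nrow(x$worker_series[[nm]])))
  invisible(x)
}
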