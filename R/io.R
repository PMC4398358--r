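SCENARIO_SCHEMA_VERSION <- 1L

scenario_to_list <- function(sc) {
  reg <- function(r) list(x0 = r$x0, y0 = r$y0, width = r$width,
                          depth = r$depth)
  list(
    version = SCENARIO_SCHEMA_VERSION,
    area = list(width = sc$area$width, depth = sc$area$depth,
                grid_spacing = sc$area$grid_spacing,
                background_level = sc$area$background_level,
                working_period = sc$area$working_period),
    barriers = lapply(sc$barriers, function(b)
      c(reg(b$region), list(screening = b$screening,
                            reflective = b$reflective))),
    stationary_machines = lapply(sc$stationary, function(m)
      list(label = m$label, lwa_full = m$lwa_full, lwa_idle = m$lwa_idle,
           p_on = m$duty$p_on, p_off = m$duty$p_off, p_idle = m$duty$p_idle,
           x = m$position[1], y = m$position[2])),
    moving_machines = lapply(sc$moving, function(m)
      list(label = m$label, lwa_full = m$lwa_full, lwa_idle = m$lwa_idle,
           p_on = m$duty$p_on, p_off = m$duty$p_off, p_idle = m$duty$p_idle,
           subarea = reg(m$subarea), max_step = m$walk$max_step,
           step_length_dist = m$walk$step_length_dist,
           boundary_policy = m$walk$boundary_policy)),
    worker_groups = lapply(sc$worker_groups, function(g)
      list(label = g$label, subarea = reg(g$subarea),
           n_walkers = g$n_walkers, max_step = g$walk$max_step,
           step_length_dist = g$walk$step_length_dist,
           boundary_policy = g$walk$boundary_policy)),
    simulation = if (!is.null(sc$simulation))
      list(n_steps = sc$simulation$n_steps, seed = sc$simulation$seed,
           repeats = sc$simulation$repeats),
    exposure = list(exchange_rate = sc$exposure$exchange_rate,
                    criterion_level = sc$exposure$criterion_level,
                    criterion_duration = sc$exposure$criterion_duration))
}

need_field <- function(entry, field, entity) {
  if (is.null(entry[[field]]))
    stop(sprintf("scenario file: %s is missing field `%s`", entity, field),
         call. = FALSE)
  entry[[field]]
}

list_to_scenario <- function(x) {
  a <- need_field(x, "area", "document")
  area <- mapping_area(
    width = need_field(a, "width", "area"),
    depth = need_field(a, "depth", "area"),
    grid_spacing = a$grid_spacing %||% 1,
    background_level = a$background_level %||% 0,
    working_period = a$working_period %||% 480)
  reg <- function(r, entity) rect_region(
    need_field(r, "x0", entity), need_field(r, "y0", entity),
    need_field(r, "width", entity), need_field(r, "depth", entity))
  duty_of <- function(e, entity) {
    tryCatch(duty_probs(p_on = e$p_on %||% 0, p_off = e$p_off %||% 0,
                        p_idle = e$p_idle %||% 0),
             error = function(err) stop(sprintf("%s: %s", entity,
                                                conditionMessage(err)),
                                        call. = FALSE))
  }
  walk_of <- function(e) walk_params(
    max_step = e$max_step %||% 5,
    step_length_dist = e$step_length_dist %||% "uniform",
    boundary_policy = e$boundary_policy %||% "reject_resample")
  stationary <- lapply(x$stationary_machines %||% list(), function(e) {
    ent <- sprintf("stationary machine %s", e$label %||% "?")
    stationary_machine(
      label = need_field(e, "label", ent),
      lwa_full = need_field(e, "lwa_full", ent),
      lwa_idle = e$lwa_idle %||% (e$lwa_full - 10),
      duty = duty_of(e, ent),
      position = {
        # YAML 1.1 parses a bare `y` key as a boolean; accept that spelling
        yy <- e$y %||% e[["TRUE"]]
        if (is.null(yy)) stop(sprintf("scenario file: %s is missing field `y`",
                                      ent), call. = FALSE)
        c(need_field(e, "x", ent), yy)
      })
  })
  moving <- lapply(x$moving_machines %||% list(), function(e) {
    ent <- sprintf("moving machine %s", e$label %||% "?")
    moving_machine(
      label = need_field(e, "label", ent),
      lwa_full = need_field(e, "lwa_full", ent),
      lwa_idle = e$lwa_idle %||% (e$lwa_full - 10),
      duty = duty_of(e, ent),
      subarea = reg(need_field(e, "subarea", ent), ent),
      walk = walk_of(e))
  })
  workers <- lapply(x$worker_groups %||% list(), function(e) {
    ent <- sprintf("worker group %s", e$label %||% "?")
    worker_group(label = need_field(e, "label", ent),
                 subarea = reg(need_field(e, "subarea", ent), ent),
                 n_walkers = e$n_walkers %||% 1, walk = walk_of(e))
  })
  barriers <- lapply(x$barriers %||% list(), function(e)
    barrier(reg(e, "barrier"), screening = e$screening %||% "full",
            reflective = isTRUE(e$reflective)))
  sim <- if (!is.null(x$simulation))
    sim_config(n_steps = x$simulation$n_steps %||% 1500,
               seed = x$simulation$seed %||% 1L,
               repeats = x$simulation$repeats %||% 1L)
  expo <- if (!is.null(x$exposure))
    exposure_config(exchange_rate = x$exposure$exchange_rate %||% 3,
                    criterion_level = x$exposure$criterion_level %||% 90,
                    criterion_duration = x$exposure$criterion_duration %||% 480)
  scenario(area, stationary = stationary, moving = moving,
           worker_groups = workers, barriers = barriers,
           simulation = sim, exposure = expo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scenario file
#'
#' Scenario files are versioned YAML (or JSON) documents with sections
#' `area`, `barriers`, `stationary_machines`, `moving_machines`,
#' `worker_groups`, `simulation` and `exposure`. All geometry and
#' probability invariants are validated on read; violations raise an error
#' naming the offending entity and field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return An [scenario()] object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  list_to_scenario(x)
}

#' Write a scenario file
#'
#' Serialisation round-trips losslessly: reading the written file yields a
#' scenario equal to the one written.
#'
#' @param sc An [scenario()].
#' @param path Destination path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "nw_scenario"))
  x <- scenario_to_list(sc)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  else yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Generate a random but valid scenario
#'
#' Draws machine sound power levels uniformly in 95-120 dBA (the span of
#' field-surveyed machinery), random duty-cycle probabilities, and random
#' positions, subareas and barriers inside the area. Reproducible from the
#' seed; useful for property testing and benchmarking.
#'
#' @param seed Integer seed.
#' @param n_stationary,n_moving,n_worker_groups,n_barriers Entity counts.
#' @param width,depth Mapping-area dimensions in metres.
#' @param grid_spacing Grid spacing in metres.
#' @return An [scenario()] object.
#' @export
generate_synthetic_scenario <- function(seed = 1L, n_stationary = 3,
                                        n_moving = 1, n_worker_groups = 1,
                                        n_barriers = 0, width = 100,
                                        depth = 70, grid_spacing = 1) {
  set.seed(seed)
  rand_duty <- function() {
    p <- stats::rexp(3)
    p <- p / sum(p)
    duty_probs(p_on = p[1], p_off = p[2], p_idle = p[3])
  }
  rand_region <- function() {
    w <- stats::runif(1, 0.05, 0.4) * width
    d <- stats::runif(1, 0.05, 0.4) * depth
    rect_region(stats::runif(1, 0, width - w), stats::runif(1, 0, depth - d),
                w, d)
  }
  area <- mapping_area(width, depth, grid_spacing = grid_spacing,
                       background_level = stats::runif(1, 40, 55))
  stationary <- lapply(seq_len(n_stationary), function(i)
    stationary_machine(sprintf("S%d", i), stats::runif(1, 95, 120),
                       rand_duty(),
                       c(stats::runif(1, 0, width), stats::runif(1, 0, depth))))
  moving <- lapply(seq_len(n_moving), function(i)
    moving_machine(sprintf("D%d", i), stats::runif(1, 95, 120), rand_duty(),
                   rand_region()))
  workers <- lapply(seq_len(n_worker_groups), function(i)
    worker_group(sprintf("G%d", i), rand_region()))
  barriers <- lapply(seq_len(n_barriers), function(i)
    barrier(rand_region(),
            screening = sample(c("full", "partial"), 1),
            reflective = stats::runif(1) < 0.5))
  scenario(area, stationary = stationary, moving = moving,
           worker_groups = workers, barriers = barriers)
}

#' Surveyed machine inventory
#'
#' The machinery inventory surveyed across the three validation workplaces
#' (an oil palm mill, a piling site, and a drainage excavation): A-weighted
#' sound power levels and duty-cycle probabilities per machine, with labels
#' S1-S7 (stationary) and D1-D3 (earth-moving).
#'
#' @return A data.frame with columns `case_study`, `machine`,
#'   `characteristic` (`"S"` stationary / `"EM"` earth-moving), `lwa`,
#'   `p_on`, `p_off`, `p_idle`, `label`.
#' @export
machine_inventory <- function() {
  utils::read.csv(system.file("extdata", "machine_inventory.csv",
                              package = "noisewalk"),
                  stringsAsFactors = FALSE)
}

#' Dosimeter exposure reference table
#'
#' Measured and predicted personal noise exposure for the three worker
#' groups of the oil-palm-mill survey: dosimeter LAeq (dBA) and noise dose
#' (%) over 30-minute measurements, alongside the simulation predictions
#' at 1500 steps. Shipped as printed reference values for comparison
#' exercises.
#'
#' @return A data.frame with columns `group`, `measured_laeq`,
#'   `measured_dose`, `predicted_laeq`, `predicted_dose`.
#' @export
exposure_reference <- function() {
  utils::read.csv(system.file("extdata", "exposure_reference.csv",
                              package = "noisewalk"),
                  stringsAsFactors = FALSE)
}

#' Bundled case-study scenarios
#'
#' Ready-made scenario files for the three surveyed workplaces. Machine
#' sound powers and duty cycles are the surveyed values; machine positions
#' and subareas are synthetic approximations of the published site layouts
#' (the survey reports them only graphically), so they illustrate the
#' workflow rather than reproduce the sites exactly.
#'
#' @param case Case-study number, 1, 2 or 3.
#' @return An [scenario()] object.
#' @export
case_study_scenario <- function(case = 1) {
  stopifnot(case %in% 1:3)
  read_scenario(system.file("extdata",
                            sprintf("case_study_%d.yaml", case),
                            package = "noisewalk"))
}

grid_header <- function(what) {
  sprintf("# %s; row 1 = y = 0 (south edge), columns west to east, metres/dBA",
          what)
}

write_grid_csv <- function(mat, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(grid_header(what), con)
  # 17 significant digits so that re-reading restores the doubles exactly
  txt <- apply(mat, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  writeLines(txt, con)
}

#' Read back a grid CSV written by [export_results()]
#'
#' @param path Path to the CSV file.
#' @return Numeric matrix (rows = y from the south edge).
#' @export
read_grid_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", comment.char = "#",
                              header = FALSE))
}

#' Plot a noise map with 5-dBA contour bands
#'
#' Filled contours at 5-dBA intervals over the LAeq grid (or any gridded
#' field), the standard presentation of a strategic noise map.
#'
#' @param x An `nw_result` or `nw_field`.
#' @param main Plot title.
#' @param interval Contour interval in dBA (default 5).
#' @export
plot_noise_map <- function(x, main = "Strategic noise map (LAeq)",
                           interval = 5) {
  levels <- if (inherits(x, "nw_result")) x$laeq_grid else x$levels
  grid <- x$grid
  lo <- floor(min(levels) / interval) * interval
  hi <- ceiling(max(levels) / interval) * interval
  if (hi <= lo) hi <- lo + interval
  breaks <- seq(lo, hi, by = interval)
  graphics::filled.contour(
    grid$x_coords, grid$y_coords, t(levels), levels = breaks,
    color.palette = function(n) grDevices::hcl.colors(n, "YlOrRd", rev = TRUE),
    xlab = "x (m)", ylab = "y (m)", main = main, asp = 1,
    key.title = graphics::title(main = "dBA", cex.main = 0.9))
  invisible(x)
}

#' Plot the noise risk zones as a coloured raster
#'
#' @param x An `nw_result`, or an `nw_risk_zones` (then `grid` is required).
#' @param grid The [mesh_grid()] the zones were computed on.
#' @param main Plot title.
#' @export
plot_risk_zones <- function(x, grid = NULL, main = "Noise risk zones") {
  if (inherits(x, "nw_result")) {
    grid <- x$grid
    x <- risk_zone_percentages(x$laeq_grid)
  }
  stopifnot(inherits(x, "nw_risk_zones"), inherits(grid, "nw_grid"))
  z <- matrix(match(x$zones, risk_zone_levels), nrow(x$zones))
  cols <- c("#2c7bb6", "#abd9e9", "#ffffbf", "#fdae61", "#d7191c", "#7f0000")
  graphics::image(grid$x_coords, grid$y_coords, t(z), zlim = c(1, 6),
                  col = cols, xlab = "x (m)", ylab = "y (m)", main = main,
                  asp = 1, useRaster = TRUE)
  graphics::legend("topright", legend = risk_zone_levels, fill = cols,
                   cex = 0.7, bg = "white")
  invisible(x)
}

#' Export simulation results to a directory
#'
#' Writes the LAeq grid, the per-step worker exposure levels, the exposure
#' report, the risk-zone grid and summary, a contour map, and a JSON run
#' manifest sufficient to reproduce the run (seed, configuration, software
#' version, file inventory).
#'
#' @param result An `nw_result` from [run_simulation()].
#' @param outdir Output directory (created if absent).
#' @param contour Also render `noise_map.png` (requires PNG support in the
#'   R build; default tries and warns on failure).
#' @return Invisibly, a character vector of the files written.
#' @export
export_results <- function(result, outdir, contour = TRUE) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory %s", outdir), call. = FALSE)
  files <- character()
  add <- function(f) files <<- c(files, f)

  f <- file.path(outdir, "laeq_grid.csv")
  write_grid_csv(result$laeq_grid, f, "LAeq grid (dBA)")
  add(f)

  f <- file.path(outdir, "worker_levels.csv")
  rows <- list(); i <- 0L
  for (nm in names(result$worker_series)) {
    series <- result$worker_series[[nm]]
    xy <- result$worker_positions[[nm]]
    for (wi in seq_len(ncol(series))) {
      i <- i + 1L
      rows[[i]] <- data.frame(step = seq_len(nrow(series)), group = nm,
                              walker = wi, x = xy[, wi, 1], y = xy[, wi, 2],
                              level_dba = series[, wi])
    }
  }
  wl <- if (length(rows)) do.call(rbind, rows)
  else data.frame(step = integer(), group = character(), walker = integer(),
                  x = numeric(), y = numeric(), level_dba = numeric())
  utils::write.csv(wl, f, row.names = FALSE)
  add(f)

  f <- file.path(outdir, "exposure_report.csv")
  utils::write.csv(worker_exposure(result), f, row.names = FALSE)
  add(f)

  rz <- risk_zone_percentages(result$laeq_grid)
  f <- file.path(outdir, "risk_zones.csv")
  write_grid_csv(matrix(match(rz$zones, risk_zone_levels), nrow(rz$zones)), f,
                 paste("risk zone category index 1-6:",
                       paste(risk_zone_levels, collapse = ", ")))
  add(f)

  if (contour) {
    f <- file.path(outdir, "noise_map.png")
    ok <- tryCatch({
      grDevices::png(f, width = 900, height = 650)
      plot_noise_map(result)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      warning("contour rendering failed: ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    if (ok) add(f)
  }

  manifest <- list(
    package = "noisewalk",
    version = as.character(utils::packageVersion("noisewalk")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = result$config$seed,
    n_steps = result$config$n_steps,
    grid = list(n_rows = result$grid$n_rows, n_cols = result$grid$n_cols,
                spacing = result$grid$spacing),
    risk_zone_percentages = as.list(rz$percentages),
    files = basename(files))
  f <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  add(f)
  invisible(files)
}
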