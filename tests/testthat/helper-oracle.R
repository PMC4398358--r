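# Independent scalar oracle for the SPL field: plain per-node, per-source
# arithmetic with its own geometry code (slab-method segment clipping and
# corner/edge distances), kept free of the package's vectorised routines.

oracle_segment_hits <- function(p, q, reg) {
  lo <- c(reg$x0, reg$y0)
  hi <- c(reg$x0 + reg$width, reg$y0 + reg$depth)
  d <- q - p
  tmin <- 0; tmax <- 1
  for (ax in 1:2) {
    if (d[ax] == 0) {
      if (p[ax] < lo[ax] || p[ax] > hi[ax]) return(FALSE)
    } else {
      tt <- sort(c((lo[ax] - p[ax]) / d[ax], (hi[ax] - p[ax]) / d[ax]))
      tmin <- max(tmin, tt[1]); tmax <- min(tmax, tt[2])
    }
  }
  tmin <= tmax
}

oracle_attenuation <- function(src, rcv, barriers) {
  att <- 0
  for (b in barriers) {
    if (oracle_segment_hits(src, rcv, b$region)) {
      a <- if (b$screening == "full") -10 else -5
      att <- min(att, a)
    }
  }
  att
}

oracle_reflection <- function(rcv, barriers, radius = 1) {
  for (b in barriers) {
    if (!b$reflective) next
    reg <- b$region
    dx <- max(reg$x0 - rcv[1], 0, rcv[1] - (reg$x0 + reg$width))
    dy <- max(reg$y0 - rcv[2], 0, rcv[2] - (reg$y0 + reg$depth))
    d <- sqrt(dx^2 + dy^2)
    if (d > 0 && d <= radius) return(3)
  }
  0
}

# sources: list of list(position, power); returns matrix [n_rows x n_cols]
oracle_field <- function(sources, grid, background_level, barriers = list(),
                         min_r = grid$spacing) {
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  i_bg <- if (is.finite(background_level)) 10^(background_level / 10) * 1e-12 else 0
  for (iy in seq_len(grid$n_rows)) {
    for (ix in seq_len(grid$n_cols)) {
      rcv <- c(grid$x_coords[ix], grid$y_coords[iy])
      refl <- oracle_reflection(rcv, barriers)
      i_tot <- i_bg
      for (s in sources) {
        if (s$power == 0) next
        r <- max(sqrt(sum((rcv - s$position)^2)), min_r)
        ik <- s$power / (2 * pi * r^2)
        lik <- 10 * log10(ik / 1e-12) +
          oracle_attenuation(s$position, rcv, barriers) + refl
        i_tot <- i_tot + 10^(lik / 10) * 1e-12
      }
      out[iy, ix] <- 10 * log10(i_tot / 1e-12)
    }
  }
  out
}

random_sources <- function(n, width, depth) {
  lapply(seq_len(n), function(i)
    list(position = c(runif(1, 0, width), runif(1, 0, depth)),
         power = sound_power_watts(runif(1, 95, 120))))
}

random_barriers <- function(n, width, depth) {
  lapply(seq_len(n), function(i) {
    w <- runif(1, 2, width / 3); d <- runif(1, 2, depth / 3)
    barrier(rect_region(runif(1, 0, width - w), runif(1, 0, depth - d), w, d),
            screening = sample(c("full", "partial"), 1),
            reflective = runif(1) < 0.5)
  })
}
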