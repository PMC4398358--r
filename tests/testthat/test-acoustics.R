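test_that("distance, intensity and level conversions are exact", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(2, 2), c(2, 2)), 0)
  expect_equal(euclidean_distance(c(1, 2), c(4, 6)), 5)

  expect_equal(source_intensity(2 * pi, 1, min_r = 0.1), 1)
  expect_equal(source_intensity(0, 7), 0)
  expect_equal(source_intensity(1, 10) / source_intensity(1, 20), 4)

  expect_equal(spl_from_intensity(1e-12), 0)
  expect_equal(spl_from_intensity(1), 120)
  expect_equal(spl_from_intensity(1e-4), 80)
  expect_error(spl_from_intensity(0), "> 0")
})

test_that("path corrections follow the BS 5228-1 approximation", {
  full <- barrier(rect_region(4, -1, 2, 2), screening = "full")
  part <- barrier(rect_region(4, -1, 2, 2), screening = "partial")
  refl <- barrier(rect_region(20, -0.5, 2, 2), reflective = TRUE)
  src <- c(0, 0); rcv <- c(10, 0)

  pc <- path_correction_db(src, rcv, list())
  expect_equal(c(pc$attenuation, pc$reflection), c(0, 0))
  pc <- path_correction_db(src, rcv, list(full))
  expect_equal(pc$attenuation, -10)
  pc <- path_correction_db(src, rcv, list(part))
  expect_equal(pc$attenuation, -5)
  # receiver 0.5 m from a reflective facade off the propagation path
  pc <- path_correction_db(src, c(19.5, 0.5), list(refl))
  expect_equal(c(pc$attenuation, pc$reflection), c(0, 3))
})

test_that("a source-free field is the uniform background", {
  g <- mesh_grid(mapping_area(20, 10, background_level = 52.2))
  f <- compute_field(list(), g, background_level = 52.2)
  expect_true(all(abs(f$levels - 52.2) < 1e-12))
  expect_equal(dim(f$levels), c(11L, 21L))
})

test_that("a single free-field source follows LWA - 10 log10(2 pi r^2)", {
  g <- mesh_grid(mapping_area(40, 5))
  src <- list(position = c(0, 0), power = sound_power_watts(103.9))
  f <- compute_field(list(src), g, background_level = -Inf)
  at <- function(x, y) f$levels[y + 1, x + 1]
  expect_equal(at(10, 0), 103.9 - 10 * log10(2 * pi * 10^2), tolerance = 1e-12)
  expect_equal(round(at(10, 0), 1), 75.9)
  # 6.02 dB loss per doubling of distance
  expect_equal(at(10, 0) - at(20, 0), 10 * log10(4), tolerance = 1e-12)
  expect_equal(at(20, 0) - at(40, 0), 10 * log10(4), tolerance = 1e-12)
})

test_that("vectorised field matches the scalar per-node oracle", {
  set.seed(21)
  for (i in 1:5) {
    g <- mesh_grid(mapping_area(30, 20, background_level = 48))
    sources <- random_sources(5, 30, 20)
    barriers <- random_barriers(2, 30, 20)
    f <- compute_field(sources, g, background_level = 48, barriers = barriers)
    expect_lt(max(abs(f$levels - oracle_field(sources, g, 48, barriers))),
              1e-9)
  }
})

test_that("removing a source never raises the field", {
  set.seed(22)
  g <- mesh_grid(mapping_area(30, 20))
  sources <- random_sources(4, 30, 20)
  barriers <- random_barriers(1, 30, 20)
  f_all <- compute_field(sources, g, 45, barriers)
  for (k in seq_along(sources)) {
    f_k <- compute_field(sources[-k], g, 45, barriers)
    expect_true(all(f_k$levels <= f_all$levels + 1e-12))
  }
})

test_that("the total field dominates background and every single source", {
  set.seed(23)
  g <- mesh_grid(mapping_area(30, 20))
  sources <- random_sources(4, 30, 20)
  barriers <- random_barriers(2, 30, 20)
  f_all <- compute_field(sources, g, 45, barriers)
  expect_true(all(f_all$levels >= 45 - 1e-12))
  for (k in seq_along(sources)) {
    f_k <- compute_field(sources[k], g, -Inf, barriers)
    expect_true(all(f_all$levels >= f_k$levels - 1e-12))
  }
})

test_that("bilinear interpolation reproduces nodes and cell centres", {
  g <- mesh_grid(mapping_area(1, 1))
  f <- structure(list(levels = rbind(c(70, 70), c(80, 80)), grid = g),
                 class = "nw_field")
  expect_equal(interpolate_level(f, c(0, 0)), 70)
  expect_equal(interpolate_level(f, c(1, 1)), 80)
  expect_equal(interpolate_level(f, c(0.5, 0.5)), 75)
  expect_error(interpolate_level(f, c(2, 0.5)), "outside")

  gu <- mesh_grid(mapping_area(5, 5))
  fu <- compute_field(list(), gu, background_level = 60)
  set.seed(24)
  for (i in 1:10)
    expect_equal(interpolate_level(fu, runif(2, 0, 5)), 60)
})
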