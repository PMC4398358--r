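test_that("noise dose reproduces dosimeter arithmetic", {
  expect_equal(dose_percent(90, 480), 100)
  expect_equal(round(dose_percent(85.9, 30), 1), 2.4)
  expect_equal(round(dose_percent(88.5, 30), 1), 4.4)
  # +3 dB halves the allowed duration at Q = 3
  expect_equal(dose_percent(93, 240), 100)
  # Q = 5 convention
  q5 <- exposure_config(exchange_rate = 5, criterion_level = 90)
  expect_equal(dose_percent(95, 240, q5), 100)
  expect_error(dose_percent(numeric(0), 30), "empty")
  expect_error(dose_percent(90, 0), "positive")
})

test_that("TWA and dose are inverse transforms", {
  expect_equal(twa_from_dose(100), 90)
  expect_equal(twa_from_dose(50), 90 + 3 * log2(0.5))
  expect_equal(round(twa_from_dose(50), 1), 87)
  expect_error(twa_from_dose(0), "> 0")
  set.seed(31)
  for (L in runif(10, 70, 100))
    expect_equal(twa_from_dose(dose_percent(L, 480)), L)
})

test_that("dose is additive over concatenated exposure segments", {
  set.seed(32)
  a <- runif(8, 75, 95); b <- runif(12, 75, 95)
  # equal slice durations: 8 slices of 5 min + 12 slices of 5 min
  expect_equal(dose_percent(c(a, b), 100),
               dose_percent(a, 40) + dose_percent(b, 60))
})

test_that("dose of a series is close to the dose of its LAeq at Q = 3", {
  # 2^(x/3) differs from 10^(x/10) by ~0.4% per 10 dB; fluctuating series
  # doses therefore track the LAeq-based dose within 0.5% relative for
  # moderate spreads
  set.seed(33)
  lv <- runif(200, 84, 92)
  d_series <- dose_percent(lv, 480)
  d_laeq <- dose_percent(aggregate_laeq(lv), 480)
  expect_lt(abs(d_series - d_laeq) / d_laeq, 0.005)
})

test_that("exceedance indices use the (100 - x)th percentile", {
  idx <- noise_indices(rep(77.7, 10))
  expect_equal(unname(idx), rep(77.7, 3))

  idx <- noise_indices(1:100)
  expect_equal(unname(idx["L10"]), 90.1)
  expect_equal(unname(idx["L50"]), 50.5)
  expect_equal(unname(idx["L90"]), 10.9)

  set.seed(34)
  for (i in 1:10) {
    idx <- noise_indices(runif(50, 60, 100))
    expect_true(idx["L90"] <= idx["L50"] && idx["L50"] <= idx["L10"])
  }
})

test_that("level statistics summarise the series correctly", {
  s <- level_statistics(rep(80, 20))
  expect_equal(s$std, 0)
  expect_equal(s$laeq, 80)
  expect_equal(s$cdf(79.999), 0)
  expect_equal(s$cdf(80), 1)

  s <- level_statistics(c(80, 90))
  expect_equal(round(s$laeq, 2), 87.40)
  expect_equal(c(s$min, s$max), c(80, 90))
  expect_equal(sum(s$pdf), 1)
  expect_true(all(diff(s$cdf(seq(75, 95, by = 0.5))) >= 0))
})

test_that("risk zones follow the left-closed 5-dB banding", {
  expect_equal(as.character(classify_risk(60)), "Safe")
  expect_equal(as.character(classify_risk(83)), "High risk")
  expect_equal(as.character(classify_risk(86)), "Extremely high risk")
  expect_equal(as.character(classify_risk(66)), "Tolerable")
  # monotone in level
  z <- classify_risk(seq(50, 100, by = 0.5))
  expect_true(all(diff(as.integer(z)) >= 0))
})

test_that("risk-zone percentages partition the area", {
  rz <- risk_zone_percentages(matrix(60, 10, 10))
  expect_equal(unname(rz$percentages["Safe"]), 100)

  g <- matrix(c(rep(60, 50), rep(90, 50)), 10, 10)
  rz <- risk_zone_percentages(g)
  expect_equal(unname(rz$percentages["Safe"]), 50)
  expect_equal(unname(rz$percentages["Extremely high risk"]), 50)
  expect_equal(sum(rz$percentages), 100, tolerance = 1e-9)
})

test_that("limit checks use a strict exceedance", {
  g <- matrix(c(70, 75, 80, 85), 2, 2)
  expect_equal(check_limit(g, 90)$percent_exceeding, 0)
  expect_equal(check_limit(g, 60)$percent_exceeding, 100)
  expect_equal(check_limit(matrix(85, 3, 3), 85)$percent_exceeding, 0)
  expect_equal(check_limit(g, 77)$percent_exceeding, 50)
})

test_that("worker exposure report is consistent with its own series", {
  area <- mapping_area(30, 20, background_level = 50, working_period = 30)
  sc <- scenario(area,
                 stationary = list(stationary_machine("A", 110,
                                                      duty_probs(1, 0, 0),
                                                      c(15, 10))),
                 worker_groups = list(worker_group("G", rect_region(5, 5, 10, 10))))
  res <- run_simulation(sc, sim_config(n_steps = 50, seed = 77))
  rep <- worker_exposure(res)
  expect_equal(nrow(rep), 1L)
  series <- res$worker_series[["G"]][, 1]
  expect_equal(rep$laeq, aggregate_laeq(series))
  expect_equal(rep$dose, dose_percent(series, 30))
  expect_equal(rep$twa, twa_from_dose(rep$dose))
  expect_equal(rep$duration, 30)
})
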