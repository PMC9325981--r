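test_that("leucine CPM chain reproduces the hand-computed carbon rate", {
  # 900 net CPM at 80% efficiency = 1125 DPM -> 5.07e-15 mol leucine
  expect_equal(bpp_from_counts(1000, 50, 50, 8e4, 1e5, 100),
               0.005237, tolerance = 1e-3)
  expect_equal(bpp_from_counts(100, 60, 40, 8e4, 1e5, 100), 0)
  # linear in net CPM, inverse-linear in volume and duration
  b1 <- bpp_from_counts(1000, 50, 50, 8e4, 1e5, 100)
  expect_equal(bpp_from_counts(1900, 50, 50, 8e4, 1e5, 100), 2 * b1)
  expect_equal(bpp_from_counts(1000, 50, 50, 8e4, 1e5, 100,
                               sample_volume_L = 0.003), b1 / 2)
  expect_equal(bpp_from_counts(1000, 50, 50, 8e4, 1e5, 100,
                               incubation_hours = 2), b1 / 2)
  expect_error(bpp_from_counts(100, 0, 0, 12e4, 1e5, 100), "efficiency")
  expect_warning(bpp_from_counts(50, 40, 40, 8e4, 1e5, 100), "clamped")
})

test_that("oxygen solubility matches published saturation values", {
  expect_equal(o2_saturation_mgL(20), 9.09, tolerance = 1e-3)
  # colder water holds more oxygen; pressure scales linearly
  temps <- seq(1, 35, by = 2)
  expect_true(all(diff(o2_saturation_mgL(temps)) < 0))
  expect_equal(o2_saturation_mgL(20, pressure_hPa = 900),
               o2_saturation_mgL(20) * 900 / 1013.25)
  # salt lowers solubility
  expect_lt(o2_saturation_mgL(20, salinity_psu = 10), o2_saturation_mgL(20))
  expect_error(o2_saturation_mgL(60), "validity")
})

test_that("optode series reduce to the median of the stable tail", {
  expect_equal(as.numeric(o2_concentration(rep(100, 60), 20)),
               o2_saturation_mgL(20), tolerance = 1e-9)
  expect_equal(as.numeric(o2_concentration(rep(0, 20), 20)), 0)
  set.seed(1)
  x <- c(100 + rnorm(50, 0, 2), rep(90, 30))
  v <- o2_concentration(x, 20)
  expect_equal(as.numeric(v), 0.9 * o2_saturation_mgL(20), tolerance = 1e-9)
  expect_true(attr(v, "stable"))
  # never-stable series falls back with a warning
  set.seed(2)
  noisy <- 100 + rnorm(40, 0, 3)
  expect_warning(v2 <- o2_concentration(noisy, 20), "stable")
  expect_false(attr(v2, "stable"))
  expect_error(o2_concentration(rep(100, 5), 20), "10")
})

test_that("respiration converts oxygen drawdown to carbon units", {
  expect_equal(respiration_rate(9.0, 9.0, 72), 0)
  expect_equal(respiration_rate(9.59, 9.09, 72), 2.607, tolerance = 1e-3)
  expect_equal(respiration_rate(9.59, 9.09, 72, rq = 0.8),
               0.8 * respiration_rate(9.59, 9.09, 72))
  expect_warning(r <- respiration_rate(9.0, 9.5, 72), "clamped")
  expect_equal(r, 0)
})

test_that("growth efficiency and carbon budgets obey their identities", {
  expect_equal(growth_efficiency(1, 1), 0.5)
  expect_equal(growth_efficiency(0.1, 0.9), 0.1)
  expect_equal(growth_efficiency(2, 0), 1)
  expect_true(is.na(growth_efficiency(0, 0)))
  # scale invariance
  expect_equal(growth_efficiency(0.3, 0.7), growth_efficiency(3, 7))
  # round trip: processing X at efficiency e yields e*X of growth
  e <- growth_efficiency(0.2, 0.8)
  expect_equal(carbon_processed(e * 123, e), 123)
  expect_equal(carbon_processed(10, 0.5), 20)
  expect_equal(carbon_processed(5, 1), 5)
  expect_error(carbon_processed(1, 0), "bge")
})

test_that("spike volume solves the dosing equation with dilution", {
  expect_equal(spike_volume(0.1, 2.82, 0.125) * 1000, 4.6, tolerance = 0.01)
  v <- spike_volume(0.1, 0.2, 1)
  expect_equal(v, 1 * 0.1 / 0.1)   # v = V t / (L - t)
  expect_equal(spike_volume(0, 2.82, 0.125), 0)
  expect_error(spike_volume(0.3, 0.2, 0.125), "exceed")
})

test_that("noiseless synthetic incubations invert to their true rates", {
  des <- study_design(n_lakes = 4, lakes_with_respiration = 4)
  truth <- expand.grid(replicate = 1:3, treatment = c("control", "plastic"),
                       lake_id = sprintf("lake_%02d", 1:4),
                       stringsAsFactors = FALSE)
  set.seed(5)
  truth$bpp <- runif(nrow(truth), 0.05, 0.3)
  truth$respiration <- ifelse(truth$replicate == 1,
                              runif(nrow(truth), 0.5, 1.5), NA)
  inc <- make_incubation_data(des, truth, noise = FALSE)
  rates <- incubation_rates(inc$scint, inc$oxygen)
  agg <- aggregate(bpp ~ lake_id + treatment, truth, mean)
  i <- match(paste(rates$lake_id, rates$treatment),
             paste(agg$lake_id, agg$treatment))
  expect_equal(rates$bpp, agg$bpp[i], tolerance = 0.02)
  tr <- truth[truth$replicate == 1, ]
  j <- match(paste(rates$lake_id, rates$treatment),
             paste(tr$lake_id, tr$treatment))
  expect_equal(rates$respiration, tr$respiration[j], tolerance = 0.02)
  expect_true(all(rates$bge > 0 & rates$bge < 1))
})
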