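# Supply seasonality, storage tanks, synthetic data, experiment plumbing.

test_that("seasonal supply: constant, periodic, and mean behaviour", {
  m0 <- seasonal_supply_model(baseline = c(10, 20, 30),
                              amplitude = c(0, 0, 0), noise_hw = c(0, 0, 0))
  expect_equal(seasonal_supply(3.7, m0), c(10, 20, 30))
  m1 <- seasonal_supply_model(noise_hw = c(0, 0, 0))
  expect_equal(seasonal_supply(2, m1), seasonal_supply(2 + m1$period, m1))
  m2 <- seasonal_supply_model()
  set.seed(6)
  draws <- t(replicate(10000, seasonal_supply(4, m2)))
  det <- m2$baseline + m2$amplitude * sin(2 * pi * (4 / m2$period + m2$phase))
  tol <- 3 * (m2$noise_hw / sqrt(3)) / sqrt(10000)
  expect_true(all(abs(colMeans(draws) - det) < tol * 1.5))
  expect_true(all(draws >= 0))
})

test_that("tank_update: conservation, saturation, emptying", {
  t0 <- list(holdup = 50, v_max = 100)
  r <- tank_update(t0, inflow = 20, outflow = 20)
  expect_equal(r$tank$holdup, 50); expect_equal(r$overflow, 0)
  full <- tank_update(list(holdup = 100, v_max = 100), inflow = 30, outflow = 10)
  expect_equal(full$overflow, 20)
  expect_equal(full$tank$holdup, 100)
  empty <- tank_update(list(holdup = 5, v_max = 100), inflow = 10, outflow = 50)
  expect_equal(empty$realized_outflow, 15)
  expect_equal(empty$tank$holdup, 0)
  set.seed(9)  # mass bookkeeping property
  tank <- list(holdup = 40, v_max = 80)
  sup <- 0; fed <- 0; ov <- 0
  for (i in 1:50) {
    inn <- runif(1, 0, 30); outt <- runif(1, 0, 30)
    r <- tank_update(tank, inn, outt)
    sup <- sup + inn; fed <- fed + r$realized_outflow; ov <- ov + r$overflow
    tank <- r$tank
  }
  expect_lt(abs((sup - fed - ov) - (tank$holdup - 40)), 1e-9)
})

test_that("synthetic elemental data: round trip, schema, configurability", {
  basis <- build_basis_matrix()
  clean <- generate_synthetic_elemental_data(n = 30, noise_sd = 0, ash = 0,
                                             seed = 5)
  truth <- attr(clean, "truth")
  est <- estimate_dataset(clean, basis)
  expect_lt(max(abs(est$x_sugar - truth$x_sugar)), 1e-6)
  expect_lt(max(abs(est$x_lignin - truth$x_lignin)), 1e-6)
  df <- generate_synthetic_elemental_data(n = 50, seed = 2)
  expect_named(df, c("waste_type", "category", "C", "H", "O", "N", "weight"))
  expect_true(all(rowSums(df[, c("C", "H", "O", "N")]) <= 1))
  expect_true(all(df$weight >= 0))
  # per-type mean lipid ordering is configurable and holds at the default
  big <- generate_synthetic_elemental_data(n = 600, noise_sd = 0, ash = 0,
                                           seed = 3)
  tr <- attr(big, "truth")
  mean_lip <- tapply(tr$x_lipids, tr$waste_type, mean)
  expect_gt(mean_lip[["FW"]], mean_lip[["AW"]])
})

test_that("generator is reproducible and respects n", {
  a <- generate_synthetic_elemental_data(n = 17, seed = 8)
  b <- generate_synthetic_elemental_data(n = 17, seed = 8)
  expect_identical(a, b)
  expect_equal(nrow(a), 17)
})

test_that("sensitivity analysis: degenerate model has ~zero CoV", {
  x0 <- c(0.5, 0.2, 0.2)
  tight <- fit_kde(matrix(x0, 1), bandwidth = 1e-4, waste_type = "FW")
  sa <- sensitivity_analysis(list(FW = tight), flowrates = 80,
                             n_samples = 3, horizon = 3, seed = 2)
  expect_lt(sa$cov[["FW"]], 1e-3)
  expect_equal(nrow(sa$mean_biogas), 3)
})

test_that("perfect-tracking runs give zero MAE and DTW in the report", {
  tgt <- c(rep(5, 4), rep(7, 4))
  runs <- rbind(tgt, tgt)
  rep <- metrics_report(runs, tgt)
  expect_equal(rep$mae_mean, 0)
  expect_equal(rep$dtw_mean, 0)
  expect_equal(rep$cov_mean, 0)
})
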