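test_that("configuration invariants are enforced", {
  expect_error(forecast_config(benchmark_lag = 1, exog_lag = 1),
               "benchmark_lag > exog_lag")
  expect_error(forecast_config(exog_lag = -1), "exog_lag")
  expect_error(forecast_config(initial_training_months = 6),
               "initial_training_months")
  expect_error(forecast_config(horizon = 0), "horizon")
})

test_that("a constant target is predicted exactly", {
  y <- rep(3.5, 40)
  fc <- rolling_forecast(y, config = forecast_config(
    benchmark_lag = 2, exog_lag = 0, initial_training_months = 24,
    order = c(0, 0, 0)))
  expect_true(all(abs(fc$prediction - 3.5) < 1e-8))
  expect_equal(nrow(fc), 40 - 24 - 2 + 1)
})

test_that("a perfectly informative exogenous signal yields near-exact predictions", {
  set.seed(10)
  n <- 60
  x <- cumsum(rnorm(n)) + 20
  # target IS the exogenous signal (up to numerical jitter that keeps the
  # zero-residual likelihood well-behaved), observable with less delay
  y <- x + rnorm(n, 0, 1e-6)
  cfg <- forecast_config(benchmark_lag = 3, exog_lag = 0,
                         initial_training_months = 24, order = c(0, 0, 0))
  aug <- rolling_forecast(y, exog = x, config = cfg)
  expect_true(all(abs(aug$prediction - aug$observed) < 1e-4))
  base <- rolling_forecast(y, exog = NULL, config = cfg)
  # the baseline cannot track changes it has not yet observed
  expect_gt(mean(abs(base$prediction - base$observed)),
            mean(abs(aug$prediction - aug$observed)))
})

test_that("predictions never see target values newer than the benchmark lag", {
  set.seed(20)
  n <- 40
  y <- cumsum(rnorm(n)) + 50
  x <- y + rnorm(n, 0, 0.1)
  cfg <- forecast_config(benchmark_lag = 4, exog_lag = 1,
                         initial_training_months = 24, order = c(1, 0, 0))
  ref <- rolling_forecast(y, exog = x, config = cfg)
  t0 <- 30L  # a forecast month present in the output
  stopifnot(t0 %in% ref$month)
  # perturb target inside the unavailable window (t - 4 + 1 .. t)
  y2 <- y
  y2[(t0 - 3):t0] <- y2[(t0 - 3):t0] + 100
  pert_t <- rolling_forecast(y2, exog = x, config = cfg)
  expect_equal(pert_t$prediction[pert_t$month == t0],
               ref$prediction[ref$month == t0], tolerance = 1e-10)
  # perturb exog after t - 1
  x2 <- x
  x2[t0] <- x2[t0] + 100
  pert_x <- rolling_forecast(y, exog = x2, config = cfg)
  expect_equal(pert_x$prediction[pert_x$month == t0],
               ref$prediction[ref$month == t0], tolerance = 1e-10)
  # perturbing an available target month DOES change the prediction
  y3 <- y
  y3[t0 - 10] <- y3[t0 - 10] + 5
  pert_ok <- rolling_forecast(y3, exog = x, config = cfg)
  expect_false(isTRUE(all.equal(
    pert_ok$prediction[pert_ok$month == t0],
    ref$prediction[ref$month == t0], tolerance = 1e-10)))
})

test_that("evaluation bookkeeping matches brute-force recomputation", {
  set.seed(30)
  n <- 54
  lat <- cumsum(rnorm(n, 0, 0.5)) + 10
  y <- lat + rnorm(n, 0, 0.2)
  x <- lat + rnorm(n, 0, 0.2)
  cfg <- forecast_config(benchmark_lag = 2, exog_lag = 0,
                         initial_training_months = 24, order = c(1, 0, 0))
  ev <- run_forecast_experiment(y, x, cfg)
  pm <- ev$per_month
  expect_equal(ev$mae_baseline, mean(pm$abs_error_baseline))
  expect_equal(ev$mae_augmented, mean(pm$abs_error_augmented))
  expect_equal(pm$abs_error_baseline,
               abs(pm$observed - pm$pred_baseline))
  expect_equal(ev$n_evaluated, n - 24 - 2 + 1)
  expect_true(all(pm$pred_baseline >= 0))
})

test_that("calendar-labelled series round-trip through the forecaster", {
  set.seed(40)
  months <- month_seq("2016-01", 40)
  y <- data.frame(period = months, rate = cumsum(rnorm(40)) + 30)
  x <- data.frame(period = months, rate = cumsum(rnorm(40)) + 5)
  cfg <- forecast_config(benchmark_lag = 2, exog_lag = 1,
                         initial_training_months = 24, order = c(0, 1, 0))
  fc <- rolling_forecast(y, exog = x, config = cfg)
  expect_equal(fc$month, months[(24 + 2):40])
  bad_x <- x[-5, ]
  expect_error(rolling_forecast(y, exog = bad_x, config = cfg),
               "missing")
})

test_that("order selection settles on a plausible ARIMA order for an AR(1)", {
  set.seed(50)
  y <- as.numeric(arima.sim(list(ar = 0.5), 120)) + 10
  cfg <- forecast_config(benchmark_lag = 1, exog_lag = 0,
                         initial_training_months = 80)
  fc <- rolling_forecast(y, config = cfg)
  ord <- attr(fc, "order")
  expect_equal(ord[2], 0)          # stationary: no differencing
  expect_lte(sum(ord[c(1, 3)]), 6) # inside the bounded grid
})
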