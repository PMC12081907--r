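test_that("config validation names the offending field", {
  expect_error(sim_config(n_months = 12), "n_months")
  expect_error(sim_config(p_single_location = 1.2), "p_single_location")
  expect_error(sim_config(p_single_location = 0.7, p_multi_location = 0.5),
               "p_single_location")
  expect_error(sim_config(mention_base_rate = -1), "mention_base_rate")
  expect_error(sim_config(shock_window = list(start = "2020-05",
                                              end = "2020-01",
                                              multiplier = 2)),
               "shock_window")
  expect_error(sim_config(latent_process = list(type = "seasonal")),
               "latent_process")
})

test_that("noise-free random walk with zero drift is constant", {
  cfg <- sim_config(latent_process = list(type = "random_walk", init = 1,
                                          drift = 0, sd = 0),
                    n_months = 24)
  lat <- simulate_latent_intensity(cfg)
  expect_true(all(lat == 1))
  expect_equal(dim(lat), c(24L, 4L))
})

test_that("piecewise latent has constant first differences per segment", {
  cfg <- sim_config(latent_process = list(type = "piecewise", init = 1,
                                          slopes = c(0.02, 0.04),
                                          changepoints = 12, sd = 0),
                    n_months = 24)
  lat <- simulate_latent_intensity(cfg)[, 1]
  d <- diff(lat)
  # the step into the changepoint month already uses the new slope
  expect_equal(unique(round(d[1:10], 12)), 0.02)
  expect_equal(unique(round(d[11:23], 12)), 0.04)
})

test_that("random-walk level matches its analytic mean over replicates", {
  drift <- 0.01; sdv <- 0.001
  levels24 <- vapply(1:400, function(s) {
    cfg <- sim_config(latent_process = list(type = "random_walk", init = 1,
                                            drift = drift, sd = sdv),
                      n_months = 24, seed = s)
    simulate_latent_intensity(cfg)[24, 1]
  }, numeric(1))
  analytic <- 1 + 24 * drift
  se <- sdv * sqrt(24) / sqrt(length(levels24))
  expect_lt(abs(mean(levels24) - analytic), 3 * se)
})

test_that("identical seed and config reproduce the stream exactly", {
  cfg <- sim_config(n_users = 60, n_months = 24, seed = 5)
  a <- simulate_comment_stream(cfg)
  b <- simulate_comment_stream(cfg)
  expect_identical(a$comments, b$comments)
  expect_identical(a$truth$latent_intensity, b$truth$latent_intensity)
  c_ <- simulate_comment_stream(sim_config(n_users = 60, n_months = 24,
                                           seed = 6))
  expect_false(identical(a$comments$body, c_$comments$body))
})

test_that("per-user comment counts are conserved in the stream total", {
  cfg <- sim_config(n_users = 50, n_months = 24, seed = 21)
  sim <- simulate_comment_stream(cfg)
  per_user <- table(sim$comments$user_id)
  expect_equal(sum(per_user), nrow(sim$comments))
  expect_equal(sum(sim$truth$mention_counts$total_comments),
               nrow(sim$comments))
})

test_that("with zero coupling the pooled mention rate matches the base rate", {
  cfg <- sim_config(n_users = 600, n_months = 24, seed = 13,
                    mention_base_rate = 40, mention_coupling = 0,
                    comments_per_user_month = 8)
  sim <- simulate_comment_stream(cfg)
  n_com <- nrow(sim$comments)
  n_drug <- sum(sim$truth$mention_counts$drug_comments)
  p <- 40 / 1e4
  se <- sqrt(p * (1 - p) / n_com)
  expect_lt(abs(n_drug / n_com - p), 3 * se)
})

test_that("p_single_location = 1 puts every user in exactly one location community", {
  cfg <- sim_config(n_users = 150, n_months = 24, seed = 31,
                    p_single_location = 1, p_multi_location = 0,
                    comments_per_user_month = 3)
  sim <- simulate_comment_stream(cfg)
  locmap <- default_location_map()
  loc <- sim$comments[sim$comments$subreddit %in% locmap$community, ]
  n_comm <- tapply(loc$subreddit, loc$user_id,
                   function(s) length(unique(s)))
  expect_equal(length(n_comm), 150L)
  expect_true(all(n_comm == 1L))
})

test_that("zero mortality coupling gives a flat death rate at the base level", {
  cfg <- sim_config(n_users = 30, n_months = 36, seed = 17,
                    mortality_base_rate = 2, mortality_coupling = 0)
  sim <- simulate_comment_stream(cfg)
  b <- simulate_benchmarks(cfg, sim$truth)
  nat <- b$mortality[b$mortality$geography == "national", ]
  # mean per-month national rate within 3 Poisson s.e. of base rate
  lam_month <- cfg$total_population * 2 / 1e4
  se_rate <- sqrt(lam_month / 36) / cfg$total_population * 1e4
  expect_lt(abs(mean(nat$rate) - 2), 3 * se_rate)
})

test_that("noise-free benchmarks are a monotone transform of the latent signal", {
  cfg <- sim_config(n_users = 30, n_months = 36, seed = 23,
                    benchmark_lag_months = 0L, benchmark_noise = "none",
                    latent_process = list(type = "random_walk", init = 1,
                                          drift = 0.02, sd = 0.08))
  sim <- simulate_comment_stream(cfg)
  b <- simulate_benchmarks(cfg, sim$truth)
  wts <- cfg$regions$weight / sum(cfg$regions$weight)
  lat_nat <- as.vector(sim$truth$latent_intensity %*% wts)
  nat <- b$mortality[b$mortality$geography == "national", ]
  nat <- nat[order(nat$month), ]
  expect_equal(cor(nat$rate, lat_nat), 1, tolerance = 1e-10)
})

test_that("the configured lag is recoverable from noise-free channels", {
  for (lag in c(-4L, 0L, 4L)) {
    cfg <- sim_config(n_months = 48, seed = 41, benchmark_lag_months = lag,
                      benchmark_noise = "none", mention_noise = "none",
                      latent_process = list(type = "random_walk", init = 1,
                                            drift = 0.01, sd = 0.1))
    pair <- simulate_signal_pair(cfg)
    xc <- cross_correlate(pair$comment_rate, pair$mortality_rate,
                          max_lag = 6)
    expect_equal(xc$best_lag, lag)
    expect_equal(xc$r_best, 1, tolerance = 1e-8)
  }
})

test_that("semi-annual laboratory counts aggregate the shifted signal by halves", {
  cfg <- sim_config(n_users = 30, n_months = 36, seed = 47,
                    benchmark_lag_months = 0L, benchmark_noise = "none",
                    report_base_rate = 50)
  sim <- simulate_comment_stream(cfg)
  b <- simulate_benchmarks(cfg, sim$truth)
  lab_nat <- b$lab[b$lab$geography == "national", ]
  expect_equal(nrow(lab_nat), 6L)  # 36 months = 6 full halves
  # expected national count for the first half, computed directly
  wts <- cfg$regions$weight / sum(cfg$regions$weight)
  pops <- cfg$total_population * wts
  lam_direct <- sum(vapply(seq_along(pops), function(r) {
    sum(pops[r] * 50 / 1e5 * (1 + sim$truth$latent_intensity[1:6, r]))
  }, numeric(1)))
  expect_equal(lab_nat$count[lab_nat$period == sort(lab_nat$period)[1]],
               lam_direct, tolerance = 1e-10)
})
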