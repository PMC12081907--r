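lx <- tiny_lexicon()
locmap <- default_location_map()

# small hand-built stream: 2 cohort users in Pennsylvania, 1 in Illinois
fixture_stream <- function() {
  months <- month_seq("2019-01", 3)
  com <- rbind(
    make_comments("philly checking in", users = "u1",
                  subreddits = "philadelphia", months = "2019-01"),
    make_comments("also philly", users = "u2",
                  subreddits = "philadelphia", months = "2019-01"),
    make_comments("chicago here", users = "u3", subreddits = "chicago",
                  months = "2019-01"),
    make_comments(c("fentanyl talk", "fentanyl and heroin", "plain talk",
                    "more plain talk"),
                  users = c("u1", "u2", "u1", "u3"),
                  months = c("2019-02", "2019-02", "2019-02", "2019-02")),
    make_comments(c("heroin mention", "nothing"),
                  users = c("u3", "u2"), months = c("2019-03", "2019-03")))
  com$comment_id <- sprintf("c%04d", seq_len(nrow(com)))
  com
}

test_that("a single month's rate is plain normalized arithmetic", {
  com <- make_comments(c(rep("nothing going on", 3998),
                         "fentanyl story", "fentanyl again"),
                       users = rep("u1", 4000),
                       subreddits = c("philadelphia",
                                      rep("news", 3999)),
                       months = rep("2020-03", 4000))
  co <- build_cohort(com, locmap)
  men <- detect_mentions(com, lx)
  rs <- comment_rate_series(men, com, co, lx, "all_opioids",
                            granularity = "monthly", window = "none")
  expect_equal(rs$numerator, 2)
  expect_equal(rs$denominator, 4000)
  expect_equal(rs$rate, 5.0)
})

test_that("category and geography filters pick the right comments", {
  com <- fixture_stream()
  co <- build_cohort(com, locmap)
  men <- detect_mentions(com, lx)
  rs_syn <- comment_rate_series(men, com, co, lx, "synthetic")
  # fentanyl comments: c0004 (u1), c0005 (u2) in 2019-02
  feb <- rs_syn[rs_syn$period == "2019-02", ]
  expect_equal(feb$numerator, 2)
  rs_her <- comment_rate_series(men, com, co, lx, "heroin")
  expect_equal(rs_her[rs_her$period == "2019-02", ]$numerator, 1)
  expect_equal(rs_her[rs_her$period == "2019-03", ]$numerator, 1)
  # comment c0005 names fentanyl and heroin: once in each category,
  # once only under all_opioids
  rs_all <- comment_rate_series(men, com, co, lx, "all_opioids")
  expect_equal(rs_all[rs_all$period == "2019-02", ]$numerator, 2)
  # region filter: only the Illinois user for Midwest
  rs_mw <- comment_rate_series(men, com, co, lx, "all_opioids",
                               geography = "region:Midwest")
  expect_equal(sum(rs_mw$numerator), 1)
  expect_equal(sum(rs_mw$denominator), 3)
})

test_that("constant monthly counts make the trailing window a no-op on the rate", {
  n <- 30L
  months <- month_seq("2018-01", n)
  com <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_comments(c("fentanyl", rep("filler text", 9)),
                  users = rep("u1", 10), months = rep(months[i], 10),
                  subreddits = c("philadelphia", rep("news", 9)))
  }))
  com$comment_id <- sprintf("c%05d", seq_len(nrow(com)))
  co <- build_cohort(com, locmap)
  men <- detect_mentions(com, lx)
  plain <- comment_rate_series(men, com, co, lx, window = "none")
  trail <- comment_rate_series(men, com, co, lx, window = "trailing_12m")
  expect_equal(nrow(trail), n - 11L)
  expect_true(all(abs(trail$rate - plain$rate[1]) < 1e-12))
})

test_that("every trailing entry equals a brute-force windowed recomputation", {
  cfg <- sim_config(n_users = 150, n_months = 48, seed = 77,
                    mention_base_rate = 60, comments_per_user_month = 6)
  sim <- simulate_comment_stream(cfg)
  lxd <- default_lexicon()
  co <- build_cohort(sim$comments, locmap)
  men <- detect_mentions(sim$comments, lxd)
  plain <- comment_rate_series(men, sim$comments, co, lxd, window = "none")
  trail <- comment_rate_series(men, sim$comments, co, lxd,
                               window = "trailing_12m")
  num12 <- oracle_trailing(plain$numerator)
  den12 <- oracle_trailing(plain$denominator)
  keep <- which(!is.na(num12))
  expect_equal(trail$numerator, num12[keep])
  expect_equal(trail$denominator, den12[keep])
  rel_err <- abs(trail$rate - num12[keep] / den12[keep] * 1e4) /
    pmax(abs(trail$rate), 1e-300)
  expect_true(all(rel_err < 1e-12))
})

test_that("rates are invariant to doubling numerator and denominator", {
  rs <- rate_series(month_seq("2020-01", 3), c(2, 4, 6), c(100, 100, 100))
  rs2 <- rate_series(month_seq("2020-01", 3), 2 * c(2, 4, 6),
                     2 * c(100, 100, 100))
  expect_equal(rs$rate, rs2$rate)
})

test_that("national numerators and denominators are the sum of regional ones", {
  cfg <- sim_config(n_users = 300, n_months = 24, seed = 55,
                    mention_base_rate = 60, p_single_location = 1,
                    p_multi_location = 0)
  sim <- simulate_comment_stream(cfg)
  lxd <- default_lexicon()
  co <- build_cohort(sim$comments, locmap)
  men <- detect_mentions(sim$comments, lxd)
  nat <- comment_rate_series(men, sim$comments, co, lxd)
  regional <- lapply(unique(co$region), function(r) {
    comment_rate_series(men, sim$comments, co, lxd,
                        geography = paste0("region:", r))
  })
  num_sum <- Reduce(`+`, lapply(regional, function(r) {
    r$numerator[match(nat$period, r$period)]
  }))
  den_sum <- Reduce(`+`, lapply(regional, function(r) {
    r$denominator[match(nat$period, r$period)]
  }))
  expect_equal(nat$numerator, num_sum)
  expect_equal(nat$denominator, den_sum)
})

test_that("benchmark normalization is count over population times scale", {
  counts <- data.frame(geography = "national",
                       period = month_seq("2020-01", 1),
                       count = 50, stringsAsFactors = FALSE)
  rs <- benchmark_rate_series(counts, c(national = 1e6), scale = 1e4)
  expect_equal(rs$rate, 0.5)
  counts2 <- data.frame(geography = "region:South", period = "2020-H1",
                        count = 120, stringsAsFactors = FALSE)
  rs2 <- benchmark_rate_series(counts2, c(`region:South` = 600000),
                               scale = 1e5, geography = "region:South",
                               granularity = "semiannual")
  expect_equal(rs2$rate, 20.0)
  expect_error(benchmark_rate_series(counts, c(elsewhere = 1), scale = 1e4),
               "missing population.*national")
})

test_that("simulated mortality matches the configured rate in expectation", {
  rates <- vapply(1:40, function(s) {
    cfg <- sim_config(n_users = 30, n_months = 24, seed = s,
                      mortality_base_rate = 1.2, mortality_coupling = 0)
    sim <- simulate_signal_pair(cfg)
    mean(sim$mortality_rate$rate)
  }, numeric(1))
  lam <- 1e7 * 1.2 / 1e4
  se <- sqrt(lam / (24 * 40)) / 1e7 * 1e4
  expect_lt(abs(mean(rates) - 1.2), 3 * se)
})

test_that("semiannual bins are calendar halves", {
  com <- make_comments(rep("fentanyl here", 14),
                       users = rep("u1", 14),
                       months = c(rep("2019-01", 1), rep("2019-06", 5),
                                  rep("2019-07", 4), rep("2019-12", 4)),
                       subreddits = c("philadelphia", rep("news", 13)))
  com$comment_id <- sprintf("c%04d", 1:14)
  co <- build_cohort(com, locmap)
  men <- detect_mentions(com, lx)
  rs <- comment_rate_series(men, com, co, lx, granularity = "semiannual")
  expect_equal(rs$period, c("2019-H1", "2019-H2"))
  expect_equal(rs$denominator, c(6, 8))
})
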