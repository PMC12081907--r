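#' Synthetic comment-stream and benchmark generator
#'
#' The generator encodes the joint structure the downstream analysis
#' assumes: a latent regional drug-use intensity drives both the rate of
#' drug mentions in a comment stream and the rate of overdose deaths (and
#' laboratory drug reports), with the benchmark channels shifted by a
#' configurable lead/lag. Users have home regions and post in zero, one, or
#' several location communities; an optional "discourse shock" inflates
#' non-drug comment volume over a window, diluting normalized mention rates
#' without touching mortality. All randomness flows from a single master
#' seed through per-component substreams, so adding one component does not
#' perturb the draws of another.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_users number of users (>= 1).
#' @param n_months number of calendar months (>= 24; the forecasting
#'   experiment needs a two-year training window).
#' @param start_month first month, `"YYYY-MM"`.
#' @param regions data.frame with columns `region` and `weight` (relative
#'   population weights; normalized internally).
#' @param latent_process list describing the latent intensity: either
#'   `list(type = "random_walk", init, drift, sd)` or
#'   `list(type = "piecewise", init, slopes, changepoints, sd)` where
#'   `slopes` has one entry per segment and `changepoints` are the month
#'   indices at which the slope changes.
#' @param mention_base_rate expected drug mentions per 10,000 comments at
#'   latent intensity zero.
#' @param mention_coupling multiplicative effect of latent intensity on the
#'   mention rate (rate multiplier is `1 + coupling * intensity`).
#' @param mortality_base_rate expected monthly deaths per 10,000 population
#'   at latent intensity zero.
#' @param mortality_coupling multiplicative effect of latent intensity on
#'   the death rate.
#' @param report_base_rate expected monthly laboratory reports per 100,000
#'   population at latent intensity zero (aggregated semi-annually).
#' @param report_coupling multiplicative effect of latent intensity on the
#'   report rate.
#' @param benchmark_lag_months signed integer: months by which the
#'   benchmark channels trail (+) or lead (-) the comment signal.
#' @param comments_per_user_month mean comments per user per month.
#' @param comment_dispersion negative-binomial dispersion (size) of the
#'   per-user-month comment count; smaller means more overdispersed.
#' @param p_single_location probability a user posts in exactly one location
#'   community.
#' @param p_multi_location probability a user posts in two or more location
#'   communities.
#' @param shock_window optional `list(start, end, multiplier)`: months
#'   (inclusive) over which non-drug comment volume is multiplied.
#' @param total_population total population across regions (for benchmark
#'   denominators).
#' @param mention_noise `"binomial"` (sampled) or `"none"` (expected counts).
#' @param benchmark_noise `"poisson"` (sampled) or `"none"` (expected
#'   counts).
#' @param seed master integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_users = 500L,
                       n_months = 48L,
                       start_month = "2015-01",
                       regions = data.frame(
                         region = c("Northeast", "Midwest", "South", "West"),
                         weight = c(0.17, 0.21, 0.38, 0.24)),
                       latent_process = list(type = "random_walk",
                                             init = 1, drift = 0.01,
                                             sd = 0.05),
                       mention_base_rate = 20,
                       mention_coupling = 1,
                       mortality_base_rate = 1.5,
                       mortality_coupling = 1,
                       report_base_rate = 20,
                       report_coupling = 1,
                       benchmark_lag_months = 0L,
                       comments_per_user_month = 10,
                       comment_dispersion = 1,
                       p_single_location = 0.6,
                       p_multi_location = 0.1,
                       shock_window = NULL,
                       total_population = 1e7,
                       mention_noise = c("binomial", "none"),
                       benchmark_noise = c("poisson", "none"),
                       seed = 1L) {
  cfg <- list(n_users = as.integer(n_users), n_months = as.integer(n_months),
              start_month = start_month, regions = regions,
              latent_process = latent_process,
              mention_base_rate = mention_base_rate,
              mention_coupling = mention_coupling,
              mortality_base_rate = mortality_base_rate,
              mortality_coupling = mortality_coupling,
              report_base_rate = report_base_rate,
              report_coupling = report_coupling,
              benchmark_lag_months = as.integer(benchmark_lag_months),
              comments_per_user_month = comments_per_user_month,
              comment_dispersion = comment_dispersion,
              p_single_location = p_single_location,
              p_multi_location = p_multi_location,
              shock_window = shock_window,
              total_population = total_population,
              mention_noise = match.arg(mention_noise),
              benchmark_noise = match.arg(benchmark_noise),
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

cfg_fail <- function(field, why) {
  stop("invalid simulation config: field '", field, "' ", why, call. = FALSE)
}

validate_sim_config <- function(cfg) {
  if (!is.finite(cfg$n_users) || cfg$n_users < 1L)
    cfg_fail("n_users", "must be >= 1")
  if (!is.finite(cfg$n_months) || cfg$n_months < 24L)
    cfg_fail("n_months", "must be >= 24 (minimum training span)")
  ym_check(cfg$start_month)
  rg <- cfg$regions
  if (!is.data.frame(rg) || !all(c("region", "weight") %in% names(rg)) ||
      nrow(rg) < 1L)
    cfg_fail("regions", "must be a data.frame with columns region, weight")
  if (any(rg$weight < 0) || sum(rg$weight) <= 0)
    cfg_fail("regions", "weights must be non-negative with positive sum")
  lp <- cfg$latent_process
  if (!is.list(lp) || is.null(lp$type) ||
      !lp$type %in% c("random_walk", "piecewise"))
    cfg_fail("latent_process", "type must be 'random_walk' or 'piecewise'")
  if (lp$type == "piecewise") {
    ncp <- length(lp$changepoints %||% integer())
    if (length(lp$slopes %||% numeric()) != ncp + 1L)
      cfg_fail("latent_process", "needs length(slopes) == length(changepoints) + 1")
  }
  for (f in c("mention_base_rate", "mention_coupling", "mortality_base_rate",
              "mortality_coupling", "report_base_rate", "report_coupling",
              "comments_per_user_month", "comment_dispersion",
              "total_population")) {
    if (!is.numeric(cfg[[f]]) || !is.finite(cfg[[f]]) || cfg[[f]] < 0)
      cfg_fail(f, "must be a non-negative number")
  }
  for (f in c("p_single_location", "p_multi_location")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      cfg_fail(f, "must be a probability in [0, 1]")
  }
  if (cfg$p_single_location + cfg$p_multi_location > 1 + 1e-12)
    cfg_fail("p_single_location", "+ p_multi_location must be <= 1")
  sw <- cfg$shock_window
  if (!is.null(sw)) {
    if (!is.list(sw) || !all(c("start", "end", "multiplier") %in% names(sw)))
      cfg_fail("shock_window", "must be list(start, end, multiplier)")
    ym_check(c(sw$start, sw$end))
    if (ym_to_index(sw$end) < ym_to_index(sw$start))
      cfg_fail("shock_window", "end precedes start")
    if (sw$multiplier < 0) cfg_fail("shock_window", "multiplier must be >= 0")
  }
  if (!is.finite(cfg$seed)) cfg_fail("seed", "must be a finite integer")
  class(cfg) <- "sim_config"
  cfg
}

# Latent intensity over [1 - pad_pre, n_months + pad_post]. The visible
# window (rows pad_pre + 1 .. pad_pre + n_months) is generated from its own
# substream first, then extended backwards/forwards from independent
# substreams, so the visible draw is invariant to the padding requested.
gen_latent <- function(cfg, pad_pre = 0L, pad_post = 0L) {
  n <- cfg$n_months
  R <- nrow(cfg$regions)
  lp <- cfg$latent_process
  sdv <- lp$sd %||% 0

  if (lp$type == "random_walk") {
    drift <- rep(lp$drift %||% 0, n)
  } else {
    ncp <- length(lp$changepoints %||% integer())
    seg <- findInterval(seq_len(n), sort(lp$changepoints %||% integer())) + 1L
    drift <- (lp$slopes)[seg]
  }
  init <- lp$init %||% 1

  core <- with_substream(cfg$seed, "latent", {
    e <- matrix(rnorm(n * R, 0, sdv), n, R)
    apply(e + drift, 2L, cumsum) + init
  })
  core <- matrix(core, n, R)

  pre <- NULL
  if (pad_pre > 0L) {
    d1 <- drift[1L]
    pre <- with_substream(cfg$seed, "latent_pre", {
      e <- matrix(rnorm(pad_pre * R, 0, sdv), pad_pre, R)
      # walk backwards from the first visible value
      out <- matrix(0, pad_pre, R)
      for (r in seq_len(R)) {
        x <- core[1L, r]
        for (i in pad_pre:1L) {
          x <- x - d1 - e[pad_pre - i + 1L, r]
          out[i, r] <- x
        }
      }
      out
    })
  }
  post <- NULL
  if (pad_post > 0L) {
    dn <- drift[n]
    post <- with_substream(cfg$seed, "latent_post", {
      e <- matrix(rnorm(pad_post * R, 0, sdv), pad_post, R)
      out <- matrix(0, pad_post, R)
      for (r in seq_len(R)) {
        x <- core[n, r]
        for (i in seq_len(pad_post)) {
          x <- x + dn + e[i, r]
          out[i, r] <- x
        }
      }
      out
    })
  }
  full <- rbind(pre, core, post)
  full <- pmax(full, 0)
  colnames(full) <- cfg$regions$region
  full
}

#' Simulate the latent regional drug-use intensity
#'
#' @param config a `sim_config`.
#' @return numeric matrix, `n_months` rows by one column per region; all
#'   values non-negative. Reproducible under the config seed.
#' @export
simulate_latent_intensity <- function(config) {
  config <- validate_sim_config(unclass(config))
  gen_latent(config, 0L, 0L)
}

FILLER_TEMPLATES <- c(
  "just another quiet evening thinking about work and weather",
  "anyone else watching the game tonight from downtown",
  "the traffic on the bridge was unreal this morning",
  "looking for a good coffee place near the park",
  "my garden finally survived the late frost this year",
  "that new album is on repeat all week honestly",
  "does anybody have tips for fixing a squeaky door",
  "the farmers market had great tomatoes this weekend")

DRUG_TEMPLATES <- c(
  "heard some talk about %s going around the neighborhood again",
  "a friend of a friend mentioned %s at the clinic yesterday",
  "people keep bringing up %s in these threads lately",
  "the news segment last night was all about %s again")

GENERIC_SUBREDDITS <- c("news", "funny", "music", "sports", "gaming",
                        "movies", "askanything", "pics")

#' Simulate a comment stream with embedded drug mentions
#'
#' Each user gets a home region (sampled by region weight) and a location
#' posting profile: single-location users post in exactly one location
#' community in their home region, multi-location users post in two or
#' three distinct communities, and the rest never post location evidence.
#' Per user-month comment counts are negative binomial; each base comment
#' carries a drug mention with probability
#' `mention_base_rate/10000 * (1 + mention_coupling * intensity)`, with the
#' surface form drawn from the lexicon. A shock window adds extra non-drug
#' comments only.
#'
#' @param config a `sim_config`.
#' @param lexicon an `opioid_lexicon` supplying surface forms.
#' @param locmap a `location_map` supplying location communities.
#' @return list with `comments` (data.frame: `comment_id`, `user_id`,
#'   `subreddit`, `month`, `body`) and `truth` (class `sim_truth`: latent
#'   intensity, configured lag, per-user home assignment, per-region-month
#'   generated counts).
#' @export
simulate_comment_stream <- function(config, lexicon = default_lexicon(),
                                    locmap = default_location_map()) {
  cfg <- validate_sim_config(unclass(config))
  stopifnot(inherits(lexicon, "opioid_lexicon"), inherits(locmap, "location_map"))
  if (nrow(lexicon) == 0L) stop("lexicon is empty", call. = FALSE)

  n <- cfg$n_months
  months <- month_seq(cfg$start_month, n)
  pad <- abs(cfg$benchmark_lag_months)
  latent_full <- gen_latent(cfg, pad, pad)
  latent <- latent_full[pad + seq_len(n), , drop = FALSE]
  regions <- cfg$regions$region
  wts <- cfg$regions$weight / sum(cfg$regions$weight)

  # communities available per region; regions absent from the map can still
  # host users but those users cannot be location posters
  by_region <- split(seq_len(nrow(locmap)), locmap$region)

  users <- with_substream(cfg$seed, "users", {
    home_region <- sample(regions, cfg$n_users, replace = TRUE, prob = wts)
    u <- runif(cfg$n_users)
    loc_type <- ifelse(u < cfg$p_single_location, "single",
                       ifelse(u < cfg$p_single_location + cfg$p_multi_location,
                              "multi", "none"))
    loc_type[!(home_region %in% names(by_region))] <- "none"
    primary <- rep(NA_integer_, cfg$n_users)
    communities <- vector("list", cfg$n_users)
    for (i in seq_len(cfg$n_users)) {
      if (loc_type[i] == "none") next
      cand <- by_region[[home_region[i]]]
      primary[i] <- cand[sample.int(length(cand), 1L)]
      if (loc_type[i] == "single") {
        communities[[i]] <- primary[i]
      } else {
        others <- setdiff(seq_len(nrow(locmap)), primary[i])
        k <- 1L + (runif(1) < 0.5)
        communities[[i]] <- c(primary[i], sample(others, k))
      }
    }
    list(home_region = home_region, loc_type = loc_type, primary = primary,
         communities = communities)
  })
  home_state <- ifelse(is.na(users$primary), NA_character_,
                       locmap$state[users$primary])
  user_id <- sprintf("u%06d", seq_len(cfg$n_users))

  # per user-month comment counts
  grid <- CJ(user = seq_len(cfg$n_users), m = seq_len(n))
  shock_mult <- rep(1, n)
  if (!is.null(cfg$shock_window)) {
    idx <- ym_to_index(months)
    inwin <- idx >= ym_to_index(cfg$shock_window$start) &
             idx <= ym_to_index(cfg$shock_window$end)
    shock_mult[inwin] <- cfg$shock_window$multiplier
  }
  counts <- with_substream(cfg$seed, "comments", {
    base <- rnbinom(nrow(grid), mu = cfg$comments_per_user_month,
                    size = cfg$comment_dispersion)
    extra_mu <- cfg$comments_per_user_month * (shock_mult[grid$m] - 1)
    extra <- integer(nrow(grid))
    pos <- extra_mu > 0
    if (any(pos)) extra[pos] <- rnbinom(sum(pos), mu = extra_mu[pos],
                                        size = cfg$comment_dispersion)
    list(base = base, extra = extra)
  })
  grid[, base := counts$base][, extra := counts$extra]
  grid[, region := users$home_region[user]]

  p_m <- pmin(1, cfg$mention_base_rate / 1e4 *
                   (1 + cfg$mention_coupling *
                        latent[cbind(grid$m, match(grid$region, regions))]))
  grid[, n_drug := if (cfg$mention_noise == "binomial") {
    with_substream(cfg$seed, "mentions", rbinom(.N, base, p_m))
  } else as.integer(round(base * p_m))]
  grid[n_drug > base, n_drug := base]

  # expand user-months to comments; drug comments first within each cell
  tot <- grid$base + grid$extra
  keep <- tot > 0L
  g <- grid[keep]
  totk <- tot[keep]
  rows <- rep.int(seq_len(nrow(g)), totk)
  within <- sequence(totk)
  is_drug <- within <= rep.int(g$n_drug, totk)

  com <- data.table(
    user = rep.int(g$user, totk),
    m = rep.int(g$m, totk),
    is_drug = is_drug)

  # guaranteed location posts: one extra non-drug comment per community
  # membership, placed in the user's first month
  loc_users <- which(users$loc_type != "none")
  loc_extra <- if (length(loc_users)) {
    data.table(
      user = rep.int(loc_users, lengths(users$communities[loc_users])),
      m = 1L,
      is_drug = FALSE,
      subreddit = locmap$community[unlist(users$communities[loc_users])])
  } else NULL

  com[, subreddit := with_substream(cfg$seed, "subreddits",
        sample(GENERIC_SUBREDDITS, .N, replace = TRUE))]
  if (!is.null(loc_extra)) com <- rbind(com, loc_extra)
  setorder(com, user, m)

  com[, body := ""]
  nd <- sum(com$is_drug)
  bodies <- with_substream(cfg$seed, "text", {
    terms <- sample(lexicon$surface_term, nd, replace = TRUE)
    sprintf(sample(DRUG_TEMPLATES, nd, replace = TRUE), terms)
  })
  com[is_drug == TRUE, body := bodies]
  com[is_drug == FALSE,
      body := with_substream(cfg$seed, "filler",
                sample(FILLER_TEMPLATES, .N, replace = TRUE))]

  comments <- data.frame(
    comment_id = sprintf("c%08d", seq_len(nrow(com))),
    user_id = user_id[com$user],
    subreddit = com$subreddit,
    month = months[com$m],
    body = com$body,
    stringsAsFactors = FALSE)

  mention_counts <- com[, .(drug_comments = sum(is_drug),
                            total_comments = .N),
                        by = .(region = users$home_region[user], m)]
  mention_counts[, month := months[m]][, m := NULL]

  truth <- list(
    latent_intensity = latent,
    latent_padded = latent_full,
    pad = pad,
    true_lag = cfg$benchmark_lag_months,
    months = months,
    users = data.frame(user_id = user_id,
                       home_region = users$home_region,
                       home_state = home_state,
                       loc_type = users$loc_type,
                       n_location_communities =
                         lengths(users$communities),
                       stringsAsFactors = FALSE),
    mention_counts = as.data.frame(mention_counts),
    config = cfg)
  class(truth) <- "sim_truth"
  list(comments = comments, truth = truth)
}

#' Simulate benchmark mortality and laboratory series
#'
#' Monthly overdose deaths are Poisson with regional rate tied to the same
#' latent intensity as the comment channel, shifted by
#' `benchmark_lag_months`; semi-annual laboratory report counts aggregate
#' the same shifted signal over calendar halves. Both are returned with
#' population denominators and normalized rates (per 10,000 for mortality,
#' per 100,000 for reports), for each region and nationally.
#'
#' @param config the `sim_config` used to generate `truth`.
#' @param truth a `sim_truth` from [simulate_comment_stream()] (or the
#'   lightweight truth from [simulate_signal_pair()]).
#' @return list with data.frames `mortality` (geography, month, count,
#'   population, rate) and `lab` (geography, period, count, population,
#'   rate).
#' @export
simulate_benchmarks <- function(config, truth) {
  cfg <- validate_sim_config(unclass(config))
  stopifnot(inherits(truth, "sim_truth"))
  n <- cfg$n_months
  months <- truth$months
  lag <- cfg$benchmark_lag_months
  pad <- truth$pad
  stopifnot(pad >= abs(lag))
  latent_shift <- truth$latent_padded[pad + seq_len(n) - lag, , drop = FALSE]

  regions <- cfg$regions$region
  wts <- cfg$regions$weight / sum(cfg$regions$weight)
  pops <- cfg$total_population * wts

  lam_mort <- sweep(cfg$mortality_base_rate / 1e4 *
                      (1 + cfg$mortality_coupling * latent_shift),
                    2L, pops, `*`)
  deaths <- if (cfg$benchmark_noise == "poisson") {
    matrix(with_substream(cfg$seed, "mortality", rpois(n * length(regions),
                                                       lam_mort)),
           n, length(regions))
  } else lam_mort

  mort <- data.table(
    geography = rep(regions, each = n),
    month = rep(months, length(regions)),
    count = as.vector(deaths),
    population = rep(pops, each = n))
  nat <- mort[, .(geography = "national", count = sum(count),
                  population = sum(population)), by = month]
  mort <- rbind(mort, nat[, .(geography, month, count, population)])
  mort[, rate := count / population * 1e4]

  # semi-annual laboratory reports over fully covered calendar halves
  halves <- ym_to_half(months)
  full_halves <- names(which(table(halves) == 6L))
  lam_lab_m <- sweep(cfg$report_base_rate / 1e5 *
                       (1 + cfg$report_coupling * latent_shift),
                     2L, pops, `*`)
  lab_list <- list()
  for (h in full_halves) {
    sel <- which(halves == h)
    lam_h <- colSums(lam_lab_m[sel, , drop = FALSE])
    lab_list[[h]] <- data.table(geography = regions, period = h,
                                expected = lam_h, population = pops)
  }
  lab <- rbindlist(lab_list)
  lab[, count := if (cfg$benchmark_noise == "poisson") {
    with_substream(cfg$seed, "lab", rpois(.N, expected))
  } else expected]
  natl <- lab[, .(geography = "national", count = sum(count),
                  population = sum(population)), by = period]
  lab <- rbind(lab[, .(geography, period, count, population)],
               natl[, .(geography, period, count, population)])
  lab[, rate := count / population * 1e5]
  setorder(lab, geography, period)

  list(mortality = as.data.frame(mort[order(geography, month)]),
       lab = as.data.frame(lab))
}

#' Simulate an aggregate national mention-rate / mortality-rate pair
#'
#' A month-level shortcut past per-comment text generation: monthly national
#' comment totals are fixed at `monthly_comments` (times any shock
#' multiplier), mention counts are Poisson around the latent-driven rate,
#' and mortality follows [simulate_benchmarks()]'s national channel. Used
#' for replicate-heavy experiments (lag recovery, forecast calibration)
#' where the full stream generator would add nothing but runtime; the two
#' paths share the same latent process and coupling structure.
#'
#' @param config a `sim_config`.
#' @param monthly_comments national comment volume per month.
#' @return list with `comment_rate` and `mortality_rate` (both
#'   [rate_series()] data.frames, monthly, no trailing window) and `truth`
#'   (latent series and configured lag).
#' @export
simulate_signal_pair <- function(config, monthly_comments = 2e6) {
  cfg <- validate_sim_config(unclass(config))
  n <- cfg$n_months
  months <- month_seq(cfg$start_month, n)
  pad <- abs(cfg$benchmark_lag_months)
  latent_full <- gen_latent(cfg, pad, pad)
  wts <- cfg$regions$weight / sum(cfg$regions$weight)
  lat_nat_full <- as.vector(latent_full %*% wts)
  lat <- lat_nat_full[pad + seq_len(n)]
  lat_shift <- lat_nat_full[pad + seq_len(n) - cfg$benchmark_lag_months]

  shock_mult <- rep(1, n)
  if (!is.null(cfg$shock_window)) {
    idx <- ym_to_index(months)
    inwin <- idx >= ym_to_index(cfg$shock_window$start) &
             idx <= ym_to_index(cfg$shock_window$end)
    shock_mult[inwin] <- cfg$shock_window$multiplier
  }
  denom <- monthly_comments * shock_mult
  lam_m <- monthly_comments * cfg$mention_base_rate / 1e4 *
    (1 + cfg$mention_coupling * lat)
  mentions <- if (cfg$mention_noise == "binomial") {
    with_substream(cfg$seed, "pair_mentions", rpois(n, lam_m))
  } else lam_m

  lam_d <- cfg$total_population * cfg$mortality_base_rate / 1e4 *
    (1 + cfg$mortality_coupling * lat_shift)
  deaths <- if (cfg$benchmark_noise == "poisson") {
    with_substream(cfg$seed, "pair_mortality", rpois(n, lam_d))
  } else lam_d

  cr <- rate_series(period = months, numerator = mentions,
                    denominator = denom, scale = 1e4,
                    geography = "national", category = "all_opioids",
                    granularity = "monthly", window = "none")
  mr <- rate_series(period = months, numerator = deaths,
                    denominator = rep(cfg$total_population, n), scale = 1e4,
                    geography = "national", category = "all_opioids",
                    granularity = "monthly", window = "none")
  truth <- list(latent = lat, true_lag = cfg$benchmark_lag_months,
                months = months)
  list(comment_rate = cr, mortality_rate = mr, truth = truth)
}
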