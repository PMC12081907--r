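#' End-to-end surveillance pipeline
#'
#' Orchestrates simulate -> mention detection -> cohort -> rates ->
#' benchmark alignment -> forecasting as one configured, reproducible run.
#' All randomness flows from the master seed in the simulation config;
#' rerunning the same configuration reproduces every output file
#' byte-for-byte.
#'
#' @param config a list (or YAML file parsed with [load_pipeline_config()])
#'   with elements:
#'   \describe{
#'     \item{simulation}{arguments for [sim_config()] (synthetic runs), or
#'       `NULL` when `comments_file` points at an existing stream.}
#'     \item{comments_file}{optional path to a comments JSONL (real-data
#'       runs).}
#'     \item{categories}{category labels to compute rates for.}
#'     \item{geographies}{geographies to compute rates for.}
#'     \item{comparison}{list(max_lag, exclude, detrend).}
#'     \item{forecast}{arguments for [forecast_config()].}
#'     \item{stages}{subset of c("simulate", "mentions", "cohort", "rates",
#'       "compare", "forecast"); defaults to all.}
#'   }
#' @param out_dir output directory (created if needed); artifacts are CSV /
#'   JSONL / JSON.
#' @return the run manifest (invisibly a list, also written to
#'   `manifest.json`): per-stage parameters, output files and key results.
#' @export
run_pipeline <- function(config, out_dir) {
  stages_all <- c("simulate", "mentions", "cohort", "rates", "compare",
                  "forecast")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), status = "ok")
  lexicon <- default_lexicon()
  locmap <- default_location_map()

  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$status <<- "failed"
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- res
    res
  }

  comments <- NULL
  truth <- NULL
  benchmarks <- NULL
  scfg <- NULL

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      scfg <<- do.call(sim_config, config$simulation %||% list())
      sim <- simulate_comment_stream(scfg, lexicon, locmap)
      comments <<- sim$comments
      truth <<- sim$truth
      benchmarks <<- simulate_benchmarks(scfg, truth)
      write_comments_jsonl(comments, file.path(out_dir, "comments.jsonl"))
      fwrite(benchmarks$mortality,
             file.path(out_dir, "benchmarks_monthly.csv"))
      fwrite(benchmarks$lab,
             file.path(out_dir, "benchmarks_semiannual.csv"))
      jsonlite::write_json(
        list(true_lag = truth$true_lag,
             n_comments = nrow(comments),
             months = truth$months),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE)
      yaml::write_yaml(unclass(scfg)[setdiff(names(scfg), "regions")],
                       file.path(out_dir, "config_echo.yaml"))
      list(status = "ok", n_comments = nrow(comments),
           true_lag = truth$true_lag,
           files = c("comments.jsonl", "benchmarks_monthly.csv",
                     "benchmarks_semiannual.csv", "truth.json"))
    })
  } else if (!is.null(config$comments_file)) {
    comments <- read_comments_jsonl(config$comments_file)
  }

  mentions <- NULL
  if ("mentions" %in% stages) {
    run_stage("mentions", function() {
      if (is.null(comments)) stop("no comment stream available")
      mentions <<- detect_mentions(comments, lexicon)
      fwrite(mentions, file.path(out_dir, "mentions.csv"))
      summ <- summarize_mentions(mentions, lexicon)
      fwrite(summ$by_drug, file.path(out_dir, "mention_summary.csv"))
      list(status = "ok", n_mentions = sum(mentions$n_occurrences),
           n_comments_with_mentions = length(unique(mentions$comment_id)),
           files = c("mentions.csv", "mention_summary.csv"))
    })
  }

  cohort <- NULL
  if ("cohort" %in% stages) {
    run_stage("cohort", function() {
      if (is.null(comments)) stop("no comment stream available")
      cohort <<- build_cohort(comments, locmap,
                              window = config$cohort_window)
      fwrite(cohort, file.path(out_dir, "cohort.csv"))
      jsonlite::write_json(attr(cohort, "exclusions"),
                           file.path(out_dir, "exclusions.json"),
                           auto_unbox = TRUE)
      list(status = "ok", n_cohort = nrow(cohort),
           exclusions = attr(cohort, "exclusions"),
           files = c("cohort.csv", "exclusions.json"))
    })
  }

  rates <- list()
  if ("rates" %in% stages) {
    run_stage("rates", function() {
      if (is.null(mentions) || is.null(cohort)) {
        stop("rates stage needs mentions and cohort")
      }
      cats <- config$categories %||% "all_opioids"
      geos <- config$geographies %||% "national"
      files <- character()
      for (cat_ in cats) {
        for (geo in geos) {
          rs <- comment_rate_series(mentions, comments, cohort, lexicon,
                                    category = cat_, geography = geo,
                                    granularity = "monthly",
                                    window = "none")
          key <- paste0(gsub(":", "_", geo), "_", cat_)
          f <- paste0("rates_", key, ".csv")
          write_rate_series_csv(rs, file.path(out_dir, f))
          rates[[key]] <<- rs
          files <- c(files, f)
        }
      }
      list(status = "ok", n_series = length(files), files = files)
    })
  }

  comparison <- NULL
  if ("compare" %in% stages) {
    run_stage("compare", function() {
      if (!length(rates) || is.null(benchmarks)) {
        stop("compare stage needs rates and simulated benchmarks")
      }
      cmp_cfg <- config$comparison %||% list()
      max_lag <- cmp_cfg$max_lag %||% 6L
      mort <- benchmark_rate_series(benchmarks$mortality,
                                    populations = NULL, scale = 1e4,
                                    geography = "national",
                                    granularity = "monthly")
      reddit <- rates[[1L]]
      raw <- cross_correlate(reddit, mort, max_lag = max_lag,
                             exclude = cmp_cfg$exclude)
      res <- list(status = "ok",
                  best_lag = raw$best_lag, r_best = raw$r_best,
                  files = "xcorr.csv")
      xcdf <- data.frame(lag = raw$lags, r = raw$r_by_lag,
                         n_pairs = raw$n_by_lag)
      if (isTRUE(cmp_cfg$detrend %||% TRUE)) {
        det <- detrend_and_correlate(reddit, mort, max_lag = max_lag,
                                     exclude = cmp_cfg$exclude)
        res$detrended_best_lag <- det$best_lag
        res$detrended_r_best <- det$r_best
        res$stationarity_achieved <- det$stationarity_achieved
        res$differencing_order <- det$differencing_order_used
        xcdf$r_detrended <- det$r_by_lag
      }
      fwrite(xcdf, file.path(out_dir, "xcorr.csv"))
      comparison <<- res
      res
    })
  }

  forecast_res <- NULL
  if ("forecast" %in% stages) {
    run_stage("forecast", function() {
      if (!length(rates) || is.null(benchmarks)) {
        stop("forecast stage needs rates and simulated benchmarks")
      }
      fcfg <- do.call(forecast_config, config$forecast %||% list())
      mort <- benchmark_rate_series(benchmarks$mortality,
                                    populations = NULL, scale = 1e4,
                                    geography = "national",
                                    granularity = "monthly")
      reddit <- rates[[1L]]
      shared <- intersect(mort$period, reddit$period)
      mort_s <- mort[mort$period %in% shared, ]
      reddit_s <- reddit[reddit$period %in% shared, ]
      ev <- run_forecast_experiment(
        data.frame(period = mort_s$period, rate = mort_s$rate),
        data.frame(period = reddit_s$period, rate = reddit_s$rate),
        fcfg)
      fwrite(ev$per_month, file.path(out_dir, "forecasts.csv"))
      jsonlite::write_json(
        list(mae_baseline = ev$mae_baseline,
             mae_augmented = ev$mae_augmented,
             statistic = ev$statistic, p.value = ev$p.value,
             n_evaluated = ev$n_evaluated),
        file.path(out_dir, "evaluation.json"), auto_unbox = TRUE,
        digits = NA)
      forecast_res <<- ev
      list(status = "ok", mae_baseline = ev$mae_baseline,
           mae_augmented = ev$mae_augmented, p.value = ev$p.value,
           files = c("forecasts.csv", "evaluation.json"))
    })
  }

  manifest$out_dir <- out_dir
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' @rdname run_pipeline
#' @param path YAML configuration file.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  yaml::read_yaml(path)
}
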