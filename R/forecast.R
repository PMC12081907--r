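#' Rolling-origin ARIMA forecasting with a delayed target and a
#' near-real-time exogenous signal
#'
#' Official mortality series arrive with a publication delay; social-media
#' comment rates arrive almost immediately. The experiment asks whether the
#' fresh exogenous signal improves one-step-ahead prediction of the
#' benchmark: at each origin month t, the model may use target values only
#' up to t - `benchmark_lag` and (for the augmented model) exogenous values
#' up to t - `exog_lag`, then must predict the target at t. The gap between
#' the last target observation and the forecast month is bridged by
#' iterating the fitted model forward `benchmark_lag` steps, with observed
#' exogenous values supplied where available and the last available value
#' held for the remaining steps. Predictions are clipped at zero (rates are
#' non-negative).
#'
#' @name forecasting
NULL

#' Forecast experiment configuration
#'
#' @param benchmark_lag months by which the target (benchmark) input is
#'   delayed at forecast time (default 6).
#' @param exog_lag months by which the exogenous comment-rate input is
#'   delayed (default 1); must be strictly smaller than `benchmark_lag`.
#' @param initial_training_months observed target months required before
#'   the first origin (default 24).
#' @param horizon forecast steps beyond the origin month (default 1).
#' @param order optional fixed ARIMA order `c(p, d, q)`; when `NULL` the
#'   order is selected by AIC over a bounded grid at the first origin.
#' @param max_p,max_q,max_d bounds of the order-selection grid.
#' @param reselect_each_origin re-run order selection at every origin
#'   (default `FALSE`: select once, refit coefficients each origin).
#' @return validated list of class `forecast_config`.
#' @export
forecast_config <- function(benchmark_lag = 6L, exog_lag = 1L,
                            initial_training_months = 24L, horizon = 1L,
                            order = NULL, max_p = 3L, max_q = 3L,
                            max_d = 2L, reselect_each_origin = FALSE) {
  cfg <- list(benchmark_lag = as.integer(benchmark_lag),
              exog_lag = as.integer(exog_lag),
              initial_training_months = as.integer(initial_training_months),
              horizon = as.integer(horizon),
              order = order, max_p = as.integer(max_p),
              max_q = as.integer(max_q), max_d = as.integer(max_d),
              reselect_each_origin = isTRUE(reselect_each_origin))
  if (cfg$exog_lag < 0L || cfg$benchmark_lag <= cfg$exog_lag) {
    stop("invalid forecast config: need benchmark_lag > exog_lag >= 0",
         call. = FALSE)
  }
  if (cfg$initial_training_months < 12L) {
    stop("invalid forecast config: initial_training_months must be >= 12",
         call. = FALSE)
  }
  if (cfg$horizon < 1L) {
    stop("invalid forecast config: horizon must be >= 1", call. = FALSE)
  }
  if (!is.null(order) && (length(order) != 3L || any(order < 0))) {
    stop("invalid forecast config: order must be c(p, d, q)", call. = FALSE)
  }
  class(cfg) <- "forecast_config"
  cfg
}

# AIC order selection over a bounded (p, d, q) grid; d is fixed first by
# repeated ADF testing of the (differenced) training series.
select_arima_order <- function(y, xreg, cfg) {
  d <- 0L
  z <- y
  while (d < cfg$max_d && length(z) >= 10L && sd(z) > 1e-10 &&
         adf_test(z)$p.value >= 0.05) {
    z <- diff(z)
    d <- d + 1L
  }
  best <- NULL
  best_aic <- Inf
  for (p in 0L:cfg$max_p) {
    for (q in 0L:cfg$max_q) {
      fit <- try_arima(y, c(p, d, q), xreg)
      if (!is.null(fit) && is.finite(AIC(fit)) && AIC(fit) < best_aic) {
        best_aic <- AIC(fit)
        best <- c(p, d, q)
      }
    }
  }
  best %||% c(0L, d, 0L)
}

try_arima <- function(y, order, xreg) {
  for (method in c("CSS-ML", "CSS")) {
    fit <- tryCatch(
      suppressWarnings(arima(y, order = order, xreg = xreg,
                             include.mean = order[2L] == 0L,
                             method = method)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      # predict.Arima re-evaluates the xreg expression from the stored
      # call; embed the value so prediction works from any frame
      fit$call$xreg <- xreg
      return(fit)
    }
  }
  NULL
}

# drift fallback when no ARIMA fit converges at an origin
drift_forecast <- function(y, steps) {
  drift <- if (length(y) > 1L) mean(diff(y)) else 0
  tail(y, 1L) + steps * drift
}

as_monthly_series <- function(x, what) {
  if (is.numeric(x) && is.null(dim(x))) {
    return(list(idx = seq_along(x), value = as.numeric(x), periods = NULL))
  }
  s <- series_values(x)
  if (s$granularity != "monthly") {
    stop(what, " must be a monthly series", call. = FALSE)
  }
  list(idx = s$idx, value = s$value, periods = index_to_period(s$idx,
                                                               "monthly"))
}

#' Rolling-origin forecasts
#'
#' @param target monthly target series: a [rate_series()], a data.frame
#'   with `period`/`rate`, or a bare numeric vector.
#' @param exog optional exogenous monthly series aligned on the same
#'   calendar (same length/periods as `target`).
#' @param config a [forecast_config()].
#' @return data.frame of class `rolling_forecast` with columns `month`
#'   (period label or index), `observed`, `prediction`; attributes carry
#'   the ARIMA order(s) used and the number of fallback origins.
#' @export
rolling_forecast <- function(target, exog = NULL,
                             config = forecast_config()) {
  stopifnot(inherits(config, "forecast_config"))
  ts_ <- as_monthly_series(target, "target")
  y <- ts_$value
  n <- length(y)
  xv <- NULL
  if (!is.null(exog)) {
    xs <- as_monthly_series(exog, "exog")
    if (length(xs$value) != n ||
        (!is.null(ts_$periods) && !is.null(xs$periods) &&
         !identical(ts_$periods, xs$periods))) {
      missing_m <- if (!is.null(ts_$periods) && !is.null(xs$periods)) {
        setdiff(ts_$periods, xs$periods)
      } else "length mismatch"
      stop("exog does not cover the target calendar; missing: ",
           paste(head(missing_m, 6L), collapse = ", "), call. = FALSE)
    }
    xv <- xs$value
  }

  L <- config$benchmark_lag
  xl <- config$exog_lag
  h <- config$horizon
  t_first <- config$initial_training_months + L + h - 1L
  if (t_first > n) {
    stop("series too short: first forecastable month is ", t_first,
         " but the series has ", n, " months", call. = FALSE)
  }
  origins <- t_first:n

  order <- config$order
  n_fallback <- 0L
  preds <- numeric(length(origins))
  orders_used <- vector("list", length(origins))

  for (j in seq_along(origins)) {
    t <- origins[j]
    avail <- t - L - h + 1L  # last observed target month at this origin
    ytr <- y[seq_len(avail)]
    xtr <- if (!is.null(xv)) matrix(xv[seq_len(avail)], ncol = 1L,
                                    dimnames = list(NULL, "exog")) else NULL
    steps <- L + h - 1L
    newx <- NULL
    if (!is.null(xv)) {
      fut <- (avail + 1L):t
      known <- fut <= t - xl
      vals <- numeric(length(fut))
      vals[known] <- xv[fut[known]]
      if (any(!known)) vals[!known] <- xv[t - xl]
      newx <- matrix(vals, ncol = 1L, dimnames = list(NULL, "exog"))
    }
    if (is.null(order) || config$reselect_each_origin) {
      order <- select_arima_order(ytr, xtr, config)
    }
    orders_used[[j]] <- order
    fit <- try_arima(ytr, order, xtr)
    if (is.null(fit)) {
      n_fallback <- n_fallback + 1L
      preds[j] <- drift_forecast(ytr, steps)
    } else {
      pr <- predict(fit, n.ahead = steps, newxreg = newx)
      preds[j] <- tail(as.numeric(pr$pred), 1L)
    }
  }
  preds <- pmax(preds, 0)

  out <- data.frame(
    month = if (!is.null(ts_$periods)) ts_$periods[origins] else origins,
    observed = y[origins],
    prediction = preds,
    stringsAsFactors = FALSE)
  attr(out, "order") <- orders_used[[1L]]
  attr(out, "orders_used") <- orders_used
  attr(out, "n_fallback") <- n_fallback
  attr(out, "config") <- config
  class(out) <- c("rolling_forecast", "data.frame")
  out
}

#' Run the paired baseline-vs-augmented forecast experiment
#'
#' Fits the benchmark-only (baseline) and benchmark + exogenous
#' comment-rate (augmented) rolling forecasts over the same origins, pairs
#' their absolute errors by month, and compares them with the signed-rank
#' test.
#'
#' @inheritParams rolling_forecast
#' @param exog the exogenous comment-rate series (required here).
#' @return list of class `forecast_evaluation`: `per_month` (month,
#'   observed, both predictions, both absolute errors), `mae_baseline`,
#'   `mae_augmented`, `statistic`, `p.value`, `n_evaluated`, and the ARIMA
#'   orders used.
#' @export
run_forecast_experiment <- function(target, exog,
                                    config = forecast_config()) {
  base <- rolling_forecast(target, exog = NULL, config = config)
  aug <- rolling_forecast(target, exog = exog, config = config)
  stopifnot(identical(base$month, aug$month))
  per_month <- data.frame(
    month = base$month,
    observed = base$observed,
    pred_baseline = base$prediction,
    pred_augmented = aug$prediction,
    abs_error_baseline = abs(base$observed - base$prediction),
    abs_error_augmented = abs(aug$observed - aug$prediction),
    stringsAsFactors = FALSE)
  cmp <- compare_models(per_month$abs_error_baseline,
                        per_month$abs_error_augmented)
  out <- list(per_month = per_month,
              mae_baseline = cmp$mae_baseline,
              mae_augmented = cmp$mae_augmented,
              statistic = cmp$statistic,
              p.value = cmp$p.value,
              n_evaluated = nrow(per_month),
              order_baseline = attr(base, "order"),
              order_augmented = attr(aug, "order"),
              n_fallback = c(baseline = attr(base, "n_fallback"),
                             augmented = attr(aug, "n_fallback")))
  class(out) <- "forecast_evaluation"
  out
}

#' @export
print.forecast_evaluation <- function(x, ...) {
  cat(sprintf("Rolling-origin forecast evaluation over %d months\n",
              x$n_evaluated))
  cat(sprintf("  baseline  order (%s): MAE %.6g\n",
              paste(x$order_baseline, collapse = ","), x$mae_baseline))
  cat(sprintf("  augmented order (%s): MAE %.6g\n",
              paste(x$order_augmented, collapse = ","), x$mae_augmented))
  cat(sprintf("  signed-rank V = %g, p = %.4g\n", x$statistic, x$p.value))
  invisible(x)
}
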