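#' Lead/lag cross-correlation between rate series
#'
#' Co-movement between a comment rate series and a benchmark rate series is
#' quantified by Pearson correlation at every lead/lag offset in a
#' symmetric window. Sign convention: a *positive* lag k means the
#' benchmark trails the comment series by k periods (the comment value at
#' period t is paired with the benchmark value at t + k). An optional
#' calendar exclusion window (e.g. pandemic years) drops the affected
#' periods from both series; pairs are formed after shifting, so the same
#' calendar periods are removed from each side. The detrended variant
#' first-differences both series, verifies stationarity of each with the
#' augmented Dickey-Fuller test, escalates to second differences if
#' needed, and refuses to report a correlation when stationarity cannot be
#' achieved.
#'
#' @name benchmark_alignment
NULL

series_values <- function(x) {
  if (inherits(x, "rate_series") ||
      (is.data.frame(x) && all(c("period", "rate") %in% names(x)))) {
    g <- rs_granularity(x)
    list(idx = period_to_index(x$period, g), value = x$rate, granularity = g)
  } else if (is.data.frame(x) && all(c("period", "value") %in% names(x))) {
    g <- if (all(grepl("H", x$period, fixed = TRUE))) "semiannual" else "monthly"
    list(idx = period_to_index(x$period, g), value = x$value, granularity = g)
  } else {
    stop("series must be a rate_series or a data.frame with period/rate ",
         "columns", call. = FALSE)
  }
}

exclusion_indices <- function(exclude, granularity) {
  if (is.null(exclude)) return(integer())
  stopifnot(length(exclude) == 2L)
  lo <- period_to_index(exclude[1L], granularity)
  hi <- period_to_index(exclude[2L], granularity)
  if (hi < lo) stop("exclusion window end precedes start", call. = FALSE)
  lo:hi
}

best_lag_of <- function(lags, r) {
  ok <- which(!is.na(r))
  if (!length(ok)) return(list(best_lag = NA_integer_, r_best = NA_real_))
  # maximum correlation magnitude; ties broken toward smallest |lag|,
  # then negative before positive
  score <- abs(r[ok])
  m <- max(score)
  cand <- ok[score >= m - 1e-12]
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  list(best_lag = lags[cand[1L]], r_best = r[cand[1L]])
}

xcorr_core <- function(sa, sb, max_lag, excl_idx) {
  lags <- seq.int(-max_lag, max_lag)
  va <- sa$value; vb <- sb$value
  va[sa$idx %in% excl_idx] <- NA
  vb[sb$idx %in% excl_idx] <- NA
  r <- rep(NA_real_, length(lags))
  n_pairs <- integer(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    # pair a at t with b at t + k
    mi <- match(sa$idx + k, sb$idx)
    ok <- !is.na(mi) & !is.na(va) & !is.na(vb[mi])
    n_pairs[i] <- sum(ok)
    if (n_pairs[i] >= 3L && sd(va[ok]) > 1e-12 && sd(vb[mi][ok]) > 1e-12) {
      r[i] <- cor(va[ok], vb[mi][ok])
    }
  }
  list(lags = lags, r = r, n_pairs = n_pairs)
}

new_xcorr_result <- function(lags, r, n_pairs, d, adf_p, stationary,
                             exclude, granularity, reason = NULL) {
  bl <- best_lag_of(lags, r)
  structure(list(lags = lags, r_by_lag = r, n_by_lag = n_pairs,
                 best_lag = bl$best_lag, r_best = bl$r_best,
                 differencing_order_used = d,
                 adf_p_by_series = adf_p,
                 stationarity_achieved = stationary,
                 excluded_window = exclude,
                 granularity = granularity,
                 failure_reason = reason),
            class = "xcorr_result")
}

#' Raw lead/lag cross-correlation
#'
#' @param a comment-side series (a [rate_series()] or data.frame with
#'   `period` and `rate`).
#' @param b benchmark-side series, same granularity.
#' @param max_lag maximum lead/lag offset in periods (default 6).
#' @param exclude optional `c(start, end)` calendar window to drop.
#' @return an `xcorr_result`: per-lag correlations `r_by_lag`, the
#'   best-correlated lag `best_lag` (maximum |r|, signed r reported), pair
#'   counts, and diagnostics.
#' @export
cross_correlate <- function(a, b, max_lag = 6L, exclude = NULL) {
  sa <- series_values(a)
  sb <- series_values(b)
  if (sa$granularity != sb$granularity) {
    stop("series have different granularities (", sa$granularity, " vs ",
         sb$granularity, ")", call. = FALSE)
  }
  excl <- exclusion_indices(exclude, sa$granularity)
  overlap <- length(setdiff(intersect(sa$idx, sb$idx), excl))
  if (overlap < max_lag + 3L) {
    stop("insufficient overlap after exclusion: need >= ", max_lag + 3L,
         " shared periods, have ", overlap, call. = FALSE)
  }
  cc <- xcorr_core(sa, sb, max_lag, excl)
  new_xcorr_result(cc$lags, cc$r, cc$n_pairs, 0L, NULL, NA, exclude,
                   sa$granularity)
}

#' Detrended (differenced) cross-correlation with stationarity testing
#'
#' @inheritParams cross_correlate
#' @param alpha significance level for the Dickey-Fuller stationarity
#'   check (default 0.05); both differenced series must reject the unit
#'   root for a detrended correlation to be reported.
#' @return an `xcorr_result` with `differencing_order_used` in \{1, 2\},
#'   per-series ADF p-values and `stationarity_achieved`; when neither
#'   first nor second differencing achieves stationarity (or differencing
#'   degenerates to a constant), no correlation is reported.
#' @export
detrend_and_correlate <- function(a, b, max_lag = 6L, exclude = NULL,
                                  alpha = 0.05) {
  sa <- series_values(a)
  sb <- series_values(b)
  if (sa$granularity != sb$granularity) {
    stop("series have different granularities", call. = FALSE)
  }
  if (min(length(sa$value), length(sb$value)) < 12L) {
    stop("series too short to difference twice and test stationarity",
         call. = FALSE)
  }
  excl <- exclusion_indices(exclude, sa$granularity)

  diff_series <- function(s, d) {
    # label a difference by its later period
    list(idx = s$idx[-seq_len(d)], value = diff(s$value, differences = d),
         granularity = s$granularity)
  }

  for (d in 1L:2L) {
    da <- diff_series(sa, d)
    db <- diff_series(sb, d)
    if (sd(da$value) < 1e-10 || sd(db$value) < 1e-10) {
      return(new_xcorr_result(seq.int(-max_lag, max_lag),
                              rep(NA_real_, 2L * max_lag + 1L),
                              rep(0L, 2L * max_lag + 1L),
                              d, NULL, FALSE, exclude, sa$granularity,
                              reason = paste0("order-", d, " differencing ",
                                              "is (numerically) constant; ",
                                              "correlation undefined")))
    }
    pa <- adf_test(da$value)$p.value
    pb <- adf_test(db$value)$p.value
    if (pa < alpha && pb < alpha) {
      # a difference spanning any excluded month is itself contaminated:
      # widen the exclusion so entries straddling the window edge drop too
      excl_d <- unique(as.vector(outer(excl, 0L:d, `+`)))
      overlap <- length(setdiff(intersect(da$idx, db$idx), excl_d))
      if (overlap < max_lag + 3L) {
        stop("insufficient overlap after differencing and exclusion: need ",
             max_lag + 3L, ", have ", overlap, call. = FALSE)
      }
      cc <- xcorr_core(da, db, max_lag, excl_d)
      return(new_xcorr_result(cc$lags, cc$r, cc$n_pairs, d,
                              c(a = pa, b = pb), TRUE, exclude,
                              sa$granularity))
    }
  }
  new_xcorr_result(seq.int(-max_lag, max_lag),
                   rep(NA_real_, 2L * max_lag + 1L),
                   rep(0L, 2L * max_lag + 1L),
                   2L, c(a = pa, b = pb), FALSE, exclude, sa$granularity,
                   reason = paste("stationarity not achieved by first- or",
                                  "second-order differencing"))
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat("Lead/lag cross-correlation (", x$granularity, ")\n", sep = "")
  if (x$differencing_order_used > 0L) {
    cat("  differencing order:", x$differencing_order_used,
        "| stationarity achieved:", x$stationarity_achieved, "\n")
    if (!is.null(x$adf_p_by_series)) {
      cat("  ADF p-values:", paste(sprintf("%s=%.4g",
                                           names(x$adf_p_by_series),
                                           x$adf_p_by_series),
                                   collapse = ", "), "\n")
    }
  }
  if (!is.null(x$failure_reason)) {
    cat("  no correlation reported:", x$failure_reason, "\n")
  } else {
    cat(sprintf("  best lag: %+d (r = %.3f)\n", x$best_lag, x$r_best))
  }
  invisible(x)
}

#' Permutation null band for a cross-correlation
#'
#' Permutes one series `n_perm` times, recomputes the maximum |r| over
#' lags, and returns the null quantile of that maximum — a reference band
#' for judging whether an observed best correlation exceeds chance.
#'
#' @inheritParams cross_correlate
#' @param n_perm number of permutations.
#' @param probs quantile(s) of the null distribution to return.
#' @param seed RNG seed for the permutations.
#' @return named numeric vector of null quantiles of max |r|.
#' @export
xcorr_permutation_band <- function(a, b, max_lag = 6L, n_perm = 1000L,
                                   probs = 0.95, seed = 1L) {
  sa <- series_values(a)
  sb <- series_values(b)
  stats_null <- with_substream(seed, "xcorr_perm", {
    vapply(seq_len(n_perm), function(i) {
      sp <- sb
      sp$value <- sample(sb$value)
      cc <- xcorr_core(sa, sp, max_lag, integer())
      max(abs(cc$r), na.rm = TRUE)
    }, numeric(1))
  })
  stats::quantile(stats_null, probs, names = TRUE)
}
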