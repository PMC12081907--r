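#' Augmented Dickey-Fuller unit-root test
#'
#' Tests the null of a unit root against stationarity using the "drift"
#' specification (regression with a constant, no deterministic trend):
#' \deqn{\Delta y_t = \alpha + \rho y_{t-1} + \sum_{i=1}^{k} \phi_i
#' \Delta y_{t-i} + \epsilon_t}
#' The statistic is the t-ratio of \eqn{\rho}. The augmentation order k is
#' selected by AIC over 0..`max_lags` on a common estimation sample (then
#' the chosen regression is refit on its full sample). P-values come from
#' interpolation of the finite-sample quantiles of the tau_mu distribution
#' (Fuller's tabulation), clamped to [0.01, 0.99]; rejection (small p)
#' indicates stationarity.
#'
#' @param x numeric series.
#' @param lags `"aic"` for AIC selection or a fixed non-negative integer.
#' @param max_lags upper bound for selection; default
#'   `trunc((length(x) - 1)^(1/3))`.
#' @return object of class `htest` with `statistic` (tau), `p.value`,
#'   `parameter` (lag order used).
#' @export
adf_test <- function(x, lags = "aic", max_lags = NULL) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("series contains non-finite values",
                               call. = FALSE)
  n <- length(x)
  if (n < 8L) stop("series too short for an ADF test (need >= 8 points)",
                   call. = FALSE)
  if (sd(x) < 1e-12) stop("series is (numerically) constant; ADF test is ",
                          "undefined", call. = FALSE)
  kmax <- max_lags %||% max(0L, trunc((n - 1)^(1/3)))
  kmax <- min(kmax, n - 5L)

  dy <- diff(x)
  ylag <- x[-n]
  fit_k <- function(k, from) {
    # rows t = from..(n-1) of dy (1-indexed over dy)
    rows <- from:(n - 1L)
    X <- cbind(1, ylag[rows])
    if (k > 0L) {
      for (i in seq_len(k)) X <- cbind(X, dy[rows - i])
    }
    y <- dy[rows]
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    nn <- length(y)
    list(fit = fit, X = X, rss = rss, n = nn, k = k,
         aic = nn * log(rss / nn) + 2 * (k + 2L))
  }

  if (identical(lags, "aic")) {
    # common sample so AICs are comparable
    fits <- lapply(0L:kmax, fit_k, from = kmax + 1L)
    k <- (0L:kmax)[which.min(vapply(fits, `[[`, numeric(1), "aic"))]
  } else {
    k <- as.integer(lags)
    if (k < 0L || k > kmax + 2L) stop("invalid lag order", call. = FALSE)
  }
  final <- fit_k(k, from = k + 1L)
  fit <- final$fit
  res <- fit$residuals
  dfree <- final$n - (k + 2L)
  sigma2 <- sum(res^2) / dfree
  XtXinv <- solve(crossprod(final$X))
  se_rho <- sqrt(sigma2 * XtXinv[2L, 2L])
  tau <- fit$coefficients[2L] / se_rho

  p <- adf_pvalue(tau, final$n)
  structure(list(statistic = c(tau = unname(tau)),
                 parameter = c(`lag order` = k),
                 p.value = p,
                 method = "Augmented Dickey-Fuller test (drift)",
                 data.name = deparse(substitute(x)),
                 alternative = "stationary",
                 sample.size = final$n),
            class = "htest")
}

# Finite-sample quantiles of the Dickey-Fuller tau_mu distribution
# (constant, no trend), interpolated in both sample size and probability.
ADF_TAU_MU <- list(
  n = c(25, 50, 100, 250, 500, 1e5),
  p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  q = rbind(
    c(-3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)))

adf_pvalue <- function(tau, n) {
  tab <- ADF_TAU_MU
  # quantile row for this sample size
  qn <- vapply(seq_along(tab$p), function(j) {
    stats::approx(tab$n, tab$q[, j], xout = n, rule = 2)$y
  }, numeric(1))
  p <- stats::approx(qn, tab$p, xout = tau, rule = 2)$y
  min(max(p, 0.01), 0.99)
}
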