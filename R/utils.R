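#' @importFrom stats aggregate arima cor lm lm.fit pnorm predict rbinom
#'   rnbinom rnorm rpois runif sd setNames AIC coef complete.cases
#' @importFrom utils head read.csv tail
#' @import data.table
NULL

# Calendar months are handled as "YYYY-MM" strings at the interface and as
# integer month indices (years * 12 + month - 1) internally.

ym_check <- function(ym) {
  ok <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", ym)
  if (!all(ok)) {
    stop("malformed month label(s): ", paste(head(ym[!ok], 5L), collapse = ", "),
         " (expected 'YYYY-MM')", call. = FALSE)
  }
  invisible(ym)
}

ym_to_index <- function(ym) {
  ym_check(ym)
  as.integer(substr(ym, 1L, 4L)) * 12L + as.integer(substr(ym, 6L, 7L)) - 1L
}

index_to_ym <- function(i) {
  i <- as.integer(i)
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

#' Sequence of consecutive calendar months
#'
#' @param start first month, `"YYYY-MM"`.
#' @param n number of months.
#' @return character vector of `n` month labels.
#' @export
month_seq <- function(start, n) {
  index_to_ym(ym_to_index(start) + seq_len(n) - 1L)
}

# "YYYY-MM" -> "YYYY-H1" (Jan-Jun) or "YYYY-H2" (Jul-Dec)
ym_to_half <- function(ym) {
  ym_check(ym)
  paste0(substr(ym, 1L, 4L),
         ifelse(as.integer(substr(ym, 6L, 7L)) <= 6L, "-H1", "-H2"))
}

half_to_index <- function(h) {
  ok <- grepl("^[0-9]{4}-H[12]$", h)
  if (!all(ok)) stop("malformed semiannual label(s): ",
                     paste(head(h[!ok], 5L), collapse = ", "), call. = FALSE)
  as.integer(substr(h, 1L, 4L)) * 2L + as.integer(substr(h, 7L, 7L)) - 1L
}

index_to_half <- function(i) {
  i <- as.integer(i)
  sprintf("%04d-H%d", i %/% 2L, i %% 2L + 1L)
}

# Period helpers that dispatch on granularity so the alignment and rate code
# can treat monthly and semiannual series uniformly.
period_to_index <- function(p, granularity) {
  switch(granularity,
         monthly = ym_to_index(p),
         semiannual = half_to_index(p),
         stop("unknown granularity: ", granularity, call. = FALSE))
}

index_to_period <- function(i, granularity) {
  switch(granularity,
         monthly = index_to_ym(i),
         semiannual = index_to_half(i),
         stop("unknown granularity: ", granularity, call. = FALSE))
}

# Derive a per-component seed from one master seed so that adding a component
# to the generator does not perturb draws made by earlier components.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_along(utf8ToInt(label)) + 31)) %% 2147483647
  # keep the product in doubles (exact below 2^53) before reducing
  v <- ((as.numeric(seed) %% 2147483647) * 48271 + h) %% 2147483629
  as.integer(v) + 1L
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
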