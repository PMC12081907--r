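#' Normalized rate series
#'
#' A rate series is an ordered, calendar-contiguous table of
#' (period, numerator, denominator, rate) for one geography and one drug
#' category, at monthly or semiannual granularity, optionally as a
#' 12-month trailing aggregate, scaled per 10,000 or per 100,000.
#'
#' @param period character periods (`"YYYY-MM"` or `"YYYY-H1"`/`"-H2"`),
#'   strictly increasing and contiguous.
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param scale rate scale (10000 or 100000).
#' @param geography,category,granularity,window metadata attributes.
#' @return data.frame of class `rate_series` with columns `period`,
#'   `numerator`, `denominator`, `rate`.
#' @export
rate_series <- function(period, numerator, denominator, scale = 1e4,
                        geography = "national", category = "all_opioids",
                        granularity = c("monthly", "semiannual"),
                        window = c("none", "trailing_12m")) {
  granularity <- match.arg(granularity)
  window <- match.arg(window)
  idx <- period_to_index(period, granularity)
  if (length(idx) > 1L && any(diff(idx) != 1L)) {
    stop("periods must be strictly increasing and contiguous", call. = FALSE)
  }
  if (any(denominator <= 0)) {
    stop("denominator must be positive for every entry", call. = FALSE)
  }
  out <- data.frame(period = period, numerator = as.numeric(numerator),
                    denominator = as.numeric(denominator),
                    rate = as.numeric(numerator) / as.numeric(denominator) *
                      scale,
                    stringsAsFactors = FALSE)
  attr(out, "geography") <- geography
  attr(out, "category") <- category
  attr(out, "granularity") <- granularity
  attr(out, "window") <- window
  attr(out, "scale") <- scale
  class(out) <- c("rate_series", "data.frame")
  out
}

rs_granularity <- function(x) {
  g <- attr(x, "granularity")
  if (!is.null(g)) return(g)
  if (all(grepl("^[0-9]{4}-H[12]$", x$period))) "semiannual" else "monthly"
}

#' Normalized comment rates for a drug category
#'
#' Numerator: unique comments by cohort users (in the requested geography)
#' that mention at least one drug of the category. Denominator: all
#' comments by those cohort users. A comment naming several drugs of the
#' category counts once; a comment naming drugs from two categories counts
#' once in each category. The 12-month trailing window right-aligns: the
#' entry for month m sums months m-11..m, and is emitted only once 12
#' months of history exist; months with no cohort comments contribute zero
#' to both sums.
#'
#' @param mentions mention records from [detect_mentions()].
#' @param comments the full comment stream (cohort filtering happens here).
#' @param cohort a `cohort_assignment` from [build_cohort()].
#' @param lexicon an `opioid_lexicon` (for category resolution).
#' @param category a category label for [resolve_category()].
#' @param geography `"national"`, `"region:<name>"`, or `"state:<name>"`.
#' @param granularity `"monthly"` or `"semiannual"`.
#' @param window `"none"` or `"trailing_12m"` (monthly only).
#' @param scale rate scale; default per 10,000 comments.
#' @return a [rate_series()].
#' @export
comment_rate_series <- function(mentions, comments, cohort, lexicon,
                                category = "all_opioids",
                                geography = "national",
                                granularity = c("monthly", "semiannual"),
                                window = c("none", "trailing_12m"),
                                scale = 1e4) {
  granularity <- match.arg(granularity)
  window <- match.arg(window)
  if (window == "trailing_12m" && granularity != "monthly") {
    stop("trailing_12m window requires monthly granularity", call. = FALSE)
  }
  drugs <- resolve_category(category, lexicon)
  users <- select_geography_users(cohort, geography)

  cdt <- as.data.table(comments)[user_id %in% users]
  if (nrow(cdt) == 0L) {
    stop("no cohort comments in geography '", geography, "'", call. = FALSE)
  }
  mdt <- as.data.table(mentions)[user_id %in% users &
                                 canonical_drug %in% drugs]

  cdt[, midx := ym_to_index(month)]
  rng <- range(cdt$midx)
  grid <- data.table(midx = rng[1L]:rng[2L])
  den <- cdt[, .(denominator = .N), by = midx]
  num <- if (nrow(mdt)) {
    mdt[, midx := ym_to_index(month)][, .(numerator = uniqueN(comment_id)),
                                      by = midx]
  } else data.table(midx = integer(), numerator = integer())
  tab <- num[den[grid, on = "midx"], on = "midx"]
  tab[is.na(numerator), numerator := 0L]
  tab[is.na(denominator), denominator := 0L]
  setorder(tab, midx)

  if (granularity == "semiannual") {
    tab[, hidx := half_to_index(ym_to_half(index_to_ym(midx)))]
    tab <- tab[, .(numerator = sum(numerator),
                   denominator = sum(denominator)), by = hidx]
    setorder(tab, hidx)
    tab <- drop_zero_denominator(tab, "hidx", index_to_half, geography)
    return(rate_series(index_to_half(tab$hidx), tab$numerator,
                       tab$denominator, scale, geography, category,
                       "semiannual", "none"))
  }

  if (window == "trailing_12m") {
    if (nrow(tab) < 12L) {
      stop("trailing_12m window needs at least 12 months of data; have ",
           nrow(tab), call. = FALSE)
    }
    if (any(tab$denominator == 0L)) {
      warning("months with zero cohort comments contribute zero to ",
              "trailing sums (geography '", geography, "')", call. = FALSE)
    }
    n12 <- frollsum(tab$numerator, 12L)
    d12 <- frollsum(tab$denominator, 12L)
    keep <- which(!is.na(d12) & d12 > 0)
    return(rate_series(index_to_ym(tab$midx[keep]), n12[keep], d12[keep],
                       scale, geography, category, "monthly",
                       "trailing_12m"))
  }

  tab <- drop_zero_denominator(tab, "midx", index_to_ym, geography)
  rate_series(index_to_ym(tab$midx), tab$numerator, tab$denominator,
              scale, geography, category, "monthly", "none")
}

# entries with zero denominator are omitted (with a warning); contiguity is
# preserved by trimming at the edges, interior gaps are an error surfaced by
# the rate_series constructor
drop_zero_denominator <- function(tab, key, to_label, geography) {
  z <- tab$denominator == 0
  if (any(z)) {
    warning("omitting ", sum(z), " period(s) with zero cohort comments in ",
            "geography '", geography, "': ",
            paste(head(to_label(tab[[key]][z]), 5L), collapse = ", "),
            call. = FALSE)
    tab <- tab[!z]
  }
  tab
}

select_geography_users <- function(cohort, geography) {
  stopifnot(inherits(cohort, "cohort_assignment"))
  if (identical(geography, "national")) return(cohort$user_id)
  if (grepl("^region:", geography)) {
    r <- sub("^region:", "", geography)
    return(cohort$user_id[cohort$region == r])
  }
  if (grepl("^state:", geography)) {
    s <- sub("^state:", "", geography)
    return(cohort$user_id[cohort$state == s])
  }
  stop("geography must be 'national', 'region:<name>' or 'state:<name>'",
       call. = FALSE)
}

#' Normalized benchmark rates
#'
#' Converts death or laboratory-report counts to population-normalized
#' rates: `rate = count / population * scale`. For monthly mortality a
#' 12-month trailing variant is available (trailing sum of counts over the
#' fixed population, matching the provisional-mortality reporting
#' convention).
#'
#' @param counts data.frame with columns `geography`, `period` (or `month`),
#'   `count`.
#' @param populations named numeric vector (geography -> population) or
#'   data.frame with columns `geography`, `population`.
#' @param scale rate scale (10,000 for mortality, 100,000 for reports).
#' @param geography which geography to extract.
#' @param granularity `"monthly"` or `"semiannual"`.
#' @param window `"none"` or `"trailing_12m"` (monthly only).
#' @param category category label carried as metadata.
#' @return a [rate_series()].
#' @export
benchmark_rate_series <- function(counts, populations, scale = 1e4,
                                  geography = "national",
                                  granularity = c("monthly", "semiannual"),
                                  window = c("none", "trailing_12m"),
                                  category = "all_opioids") {
  granularity <- match.arg(granularity)
  window <- match.arg(window)
  if (is.data.frame(populations)) {
    populations <- setNames(populations$population, populations$geography)
  }
  dt <- as.data.table(counts)
  if ("month" %in% names(dt) && !"period" %in% names(dt)) {
    setnames(dt, "month", "period")
  }
  need <- c("geography", "period", "count")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    stop("counts missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sel <- dt[["geography"]] == geography
  dt <- dt[which(sel)]
  if (nrow(dt) == 0L) {
    stop("no counts for geography '", geography, "'", call. = FALSE)
  }
  if (!geography %in% names(populations)) {
    if ("population" %in% names(dt)) {
      populations <- setNames(dt$population[1L], geography)
    } else {
      stop("missing population for geography '", geography, "'",
           call. = FALSE)
    }
  }
  pop <- populations[[geography]]
  setorderv(dt, "period")

  if (window == "trailing_12m") {
    if (granularity != "monthly") {
      stop("trailing_12m window requires monthly granularity", call. = FALSE)
    }
    c12 <- frollsum(dt$count, 12L)
    keep <- !is.na(c12)
    return(rate_series(dt$period[keep], c12[keep], rep(pop, sum(keep)),
                       scale, geography, category, granularity,
                       "trailing_12m"))
  }
  rate_series(dt$period, dt$count, rep(pop, nrow(dt)), scale, geography,
              category, granularity, "none")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("Rate series: %s / %s, %s, window %s, per %s; %d periods\n",
              attr(x, "geography"), attr(x, "category"),
              attr(x, "granularity"), attr(x, "window"),
              format(attr(x, "scale"), big.mark = ","), nrow(x)))
  NextMethod()
}
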