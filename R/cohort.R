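#' Geolocated user cohort construction
#'
#' Users are located by *community membership*: posting in a location-based
#' community (e.g. a city forum) is taken as a proxy for living there. A
#' user who posted at least once in exactly one distinct location community
#' is assigned that community's state and census region; users who posted in
#' two or more distinct location communities are excluded as ambiguous, and
#' users with no location posts are excluded as unlocatable. Inclusion is
#' agnostic to whether the user ever mentioned a drug.
#'
#' @name cohort
NULL

#' Build the location cohort from a comment stream
#'
#' @param comments data.frame of comment records with columns `user_id`,
#'   `subreddit` (community name), `month`.
#' @param locmap a validated `location_map` (see [load_location_map()]).
#' @param window optional length-2 character vector `c(start, end)` of
#'   `"YYYY-MM"` months limiting which comments count as location evidence
#'   (all of a user's comments still count toward rates downstream).
#' @return data.frame of class `cohort_assignment` with columns `user_id`,
#'   `state`, `region`, one row per cohort user, and an `exclusions`
#'   attribute listing `n_multi_location` and `n_no_location`.
#' @export
build_cohort <- function(comments, locmap, window = NULL) {
  stopifnot(inherits(locmap, "location_map"))
  need <- c("user_id", "subreddit")
  missing <- setdiff(need, names(comments))
  if (length(missing)) {
    stop("comments missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dt <- as.data.table(comments)[, .(user_id = as.character(user_id),
                                    subreddit = tolower(as.character(subreddit)),
                                    month = if ("month" %in% names(comments))
                                      as.character(month) else NA_character_)]
  loc <- dt[subreddit %in% locmap$community]
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    lo <- ym_to_index(window[1L]); hi <- ym_to_index(window[2L])
    loc <- loc[!is.na(month)][ym_to_index(month) >= lo &
                              ym_to_index(month) <= hi]
  }
  all_users <- unique(dt$user_id)
  per_user <- loc[, .(n_communities = uniqueN(subreddit),
                      community = subreddit[1L]), by = user_id]
  single <- per_user[n_communities == 1L]
  mi <- match(single$community, locmap$community)
  out <- data.frame(user_id = single$user_id,
                    state = locmap$state[mi],
                    region = locmap$region[mi],
                    stringsAsFactors = FALSE)
  out <- out[order(out$user_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- list(
    n_multi_location = nrow(per_user) - nrow(single),
    n_no_location = length(all_users) - nrow(per_user))
  class(out) <- c("cohort_assignment", "data.frame")
  out
}

#' Rank concordance between cohort size and state population
#'
#' Kendall's Tau-b between the number of cohort users observed per state and
#' an external population count per state, as a sanity check that the cohort
#' tracks where people actually live.
#'
#' @param cohort a `cohort_assignment` from [build_cohort()].
#' @param populations named numeric vector (state -> population) or a
#'   data.frame with columns `state` and `population`.
#' @return list with `tau` (Kendall's Tau-b), `n_states`, and the per-state
#'   table used.
#' @export
cohort_population_concordance <- function(cohort, populations) {
  if (is.data.frame(populations)) {
    populations <- setNames(populations$population, populations$state)
  }
  counts <- table(cohort$state)
  states <- intersect(names(counts), names(populations))
  if (length(states) < 3L) {
    stop("need at least 3 states present in both cohort and population ",
         "table; got ", length(states), call. = FALSE)
  }
  x <- as.numeric(counts[states])
  y <- as.numeric(populations[states])
  list(tau = as.numeric(cor(x, y, method = "kendall")),
       n_states = length(states),
       table = data.frame(state = states, cohort_users = x, population = y,
                          stringsAsFactors = FALSE))
}
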