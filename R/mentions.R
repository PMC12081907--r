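#' Drug-mention detection in comment text
#'
#' Matching is case-insensitive, token-based and exact: comment text is split
#' into tokens on runs of non-alphanumeric characters, and a mention is a
#' whole-token match of a lexicon surface term (multi-word terms match as a
#' contiguous token sequence). There is no stemming or fuzzy matching —
#' misspellings are caught only if they are explicit lexicon entries. Matches
#' are resolved longest-first, left to right, and a token consumed by a
#' longer term is not re-used by a shorter one, so nested terms are never
#' double counted.
#'
#' @name mentions
NULL

tokenize_lower <- function(x) {
  strsplit(tolower(x), "[^a-z0-9]+")
}

#' Detect lexicon drug mentions in comments
#'
#' @param comments a data.frame of comment records with columns `body` and,
#'   if present, `comment_id`, `user_id`, `month` (carried through to the
#'   output); or a single character string.
#' @param lexicon an `opioid_lexicon` from [load_lexicon()].
#' @return a data.frame of mention records with one row per
#'   (comment, canonical drug) pair: `comment_id`, `user_id`, `month`,
#'   `canonical_drug`, `n_occurrences`. Comments without mentions contribute
#'   no rows; an empty input yields an empty frame.
#' @export
detect_mentions <- function(comments, lexicon) {
  stopifnot(inherits(lexicon, "opioid_lexicon"))
  if (is.character(comments)) {
    comments <- data.frame(body = comments, stringsAsFactors = FALSE)
  }
  if (!"body" %in% names(comments)) {
    stop("comments must have a 'body' column", call. = FALSE)
  }
  n <- nrow(comments)
  empty <- data.frame(comment_id = character(), user_id = character(),
                      month = character(), canonical_drug = character(),
                      n_occurrences = integer(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  comment_id <- if ("comment_id" %in% names(comments)) {
    as.character(comments$comment_id)
  } else sprintf("c%07d", seq_len(n))
  user_id <- if ("user_id" %in% names(comments)) {
    as.character(comments$user_id)
  } else rep(NA_character_, n)
  month <- if ("month" %in% names(comments)) {
    as.character(comments$month)
  } else rep(NA_character_, n)

  toks <- tokenize_lower(comments$body)
  lens <- lengths(toks)
  if (sum(lens) == 0L) return(empty)
  tok_dt <- data.table(
    row = rep.int(seq_len(n), lens),
    pos = unlist(lapply(lens, seq_len), use.names = FALSE),
    token = unlist(toks, use.names = FALSE)
  )
  tok_dt <- tok_dt[token != ""]
  if (nrow(tok_dt) == 0L) return(empty)

  term_toks <- tokenize_lower(lexicon$surface_term)
  term_len <- lengths(term_toks)
  hits <- vector("list", 0L)
  consumed <- rep(FALSE, nrow(tok_dt))
  tok_dt[, idx := .I]

  # multi-token terms first (longest first), then single tokens on whatever
  # was not consumed
  for (L in sort(unique(term_len[term_len > 1L]), decreasing = TRUE)) {
    terms_L <- which(term_len == L)
    first_words <- vapply(term_toks[terms_L], `[`, character(1), 1L)
    cand <- which(tok_dt$token %in% first_words & !consumed)
    for (i in cand) {
      if (consumed[i]) next
      span <- i:(i + L - 1L)
      if (span[L] > nrow(tok_dt)) next
      if (tok_dt$row[span[L]] != tok_dt$row[i]) next
      if (any(consumed[span])) next
      # contiguity within the comment
      if (!all(tok_dt$pos[span] == tok_dt$pos[i] + 0:(L - 1L))) next
      seqs <- tok_dt$token[span]
      m <- which(first_words == seqs[1L])
      matched <- FALSE
      for (j in m) {
        if (identical(term_toks[[terms_L[j]]], seqs)) {
          hits[[length(hits) + 1L]] <- data.table(
            row = tok_dt$row[i],
            canonical_drug = lexicon$canonical_drug[terms_L[j]])
          consumed[span] <- TRUE
          matched <- TRUE
          break
        }
      }
      if (matched) next
    }
  }

  single <- lexicon[term_len == 1L, , drop = FALSE]
  if (nrow(single)) {
    free <- tok_dt[!consumed]
    mi <- match(free$token, single$surface_term)
    got <- !is.na(mi)
    if (any(got)) {
      hits[[length(hits) + 1L]] <- data.table(
        row = free$row[got],
        canonical_drug = single$canonical_drug[mi[got]])
    }
  }

  if (!length(hits)) return(empty)
  rec <- rbindlist(hits)[, .(n_occurrences = .N), by = .(row, canonical_drug)]
  setorder(rec, row, canonical_drug)
  data.frame(comment_id = comment_id[rec$row],
             user_id = user_id[rec$row],
             month = month[rec$row],
             canonical_drug = rec$canonical_drug,
             n_occurrences = rec$n_occurrences,
             stringsAsFactors = FALSE)
}

#' Summarize mention records
#'
#' Per-drug totals (mention occurrences, unique comments, unique users),
#' sorted by mentions descending, plus the same totals aggregated by
#' receptor-activity class and by synthesis class when a lexicon is
#' supplied.
#'
#' @param records mention records from [detect_mentions()].
#' @param lexicon optional `opioid_lexicon` used to attach class labels and
#'   produce by-class aggregates.
#' @return a list of class `mention_summary` with elements `by_drug` and,
#'   when a lexicon is given, `by_receptor_class` and `by_synthesis_class`.
#' @export
summarize_mentions <- function(records, lexicon = NULL) {
  dt <- as.data.table(records)
  if (nrow(dt) == 0L) {
    by_drug <- data.frame(canonical_drug = character(), mentions = integer(),
                          comments = integer(), users = integer(),
                          stringsAsFactors = FALSE)
    out <- list(by_drug = by_drug)
    class(out) <- "mention_summary"
    return(out)
  }
  by_drug <- dt[, .(mentions = sum(n_occurrences),
                    comments = uniqueN(comment_id),
                    users = uniqueN(user_id[!is.na(user_id)])),
                by = canonical_drug]
  setorder(by_drug, -mentions, canonical_drug)
  out <- list(by_drug = as.data.frame(by_drug))
  if (!is.null(lexicon)) {
    stopifnot(inherits(lexicon, "opioid_lexicon"))
    cls <- unique(lexicon[c("canonical_drug", "receptor_class",
                            "synthesis_class")])
    dtc <- merge(dt, as.data.table(cls), by = "canonical_drug")
    for (field in c("receptor_class", "synthesis_class")) {
      agg <- dtc[, .(mentions = sum(n_occurrences),
                     comments = uniqueN(comment_id),
                     users = uniqueN(user_id[!is.na(user_id)])),
                 by = field]
      setorder(agg, -mentions)
      out[[paste0("by_", field)]] <- as.data.frame(agg)
    }
  }
  class(out) <- "mention_summary"
  out
}

#' @export
print.mention_summary <- function(x, ...) {
  cat("Mention summary:", nrow(x$by_drug), "drug(s)\n")
  print(head(x$by_drug, 10L))
  invisible(x)
}
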