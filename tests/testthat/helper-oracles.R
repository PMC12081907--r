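# Independent brute-force oracles used to cross-check the implementation.

# naive regex-per-term mention scan: one lookaround-delimited regex per
# surface term, counted independently, aggregated per canonical drug
oracle_mention_scan <- function(comments, lexicon) {
  body <- tolower(comments$body)
  out <- list()
  for (i in seq_len(nrow(lexicon))) {
    term <- lexicon$surface_term[i]
    # terms are lowercase alphanumeric tokens separated by single spaces
    pat <- paste0("(?<![a-z0-9])", gsub(" +", "[^a-z0-9]+", term),
                  "(?![a-z0-9])")
    hits <- gregexpr(pat, body, perl = TRUE)
    cnt <- vapply(hits, function(h) sum(h > 0L), integer(1))
    idx <- which(cnt > 0L)
    if (length(idx)) {
      out[[length(out) + 1L]] <- data.frame(
        row = idx, canonical_drug = lexicon$canonical_drug[i],
        n = cnt[idx], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(comment_id = character(), canonical_drug = character(),
                      n_occurrences = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  agg <- aggregate(n ~ row + canonical_drug, data = df, FUN = sum)
  cid <- if ("comment_id" %in% names(comments)) {
    as.character(comments$comment_id)
  } else sprintf("c%07d", seq_len(nrow(comments)))
  res <- data.frame(comment_id = cid[agg$row],
                    canonical_drug = agg$canonical_drug,
                    n_occurrences = agg$n, stringsAsFactors = FALSE)
  res[order(res$comment_id, res$canonical_drug), ]
}

# Kendall's tau-b by exhaustive pair enumeration
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - count_tie_pairs(x)) * (n0 - count_tie_pairs(y)))
}

count_tie_pairs <- function(v) {
  tt <- table(v)
  sum(tt * (tt - 1) / 2)
}

# exact two-sided signed-rank p by enumeration of all 2^n sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Pearson r over explicitly retained index pairs
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# trailing 12-month sum by explicit window loop
oracle_trailing <- function(v, w = 12L) {
  n <- length(v)
  out <- rep(NA_real_, n)
  for (m in w:n) out[m] <- sum(v[(m - w + 1L):m])
  out
}

tiny_lexicon <- function() {
  validate_lexicon(data.frame(
    surface_term = c("fentanyl", "fent", "china white", "sufentanil",
                     "heroin", "tramadol", "methadone", "oxycodone"),
    canonical_drug = c("fentanyl", "fentanyl", "fentanyl", "sufentanil",
                       "heroin", "tramadol", "methadone", "oxycodone"),
    receptor_class = c("full_agonist", "full_agonist", "full_agonist",
                       "full_agonist", "heroin", "full_agonist",
                       "full_agonist", "full_agonist"),
    synthesis_class = c("synthetic", "synthetic", "synthetic",
                        "other_opioid", "heroin", "synthetic", "excluded",
                        "natural_semisynthetic"),
    stringsAsFactors = FALSE))
}

make_comments <- function(bodies, users = NULL, months = NULL,
                          subreddits = NULL) {
  n <- length(bodies)
  data.frame(comment_id = sprintf("c%04d", seq_len(n)),
             user_id = users %||% sprintf("u%03d", seq_len(n)),
             subreddit = subreddits %||% rep("news", n),
             month = months %||% rep("2020-01", n),
             body = bodies, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
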