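test_that("occurrences are counted per comment and drug, case-insensitively", {
  lx <- tiny_lexicon()
  m <- detect_mentions("Fentanyl is scary. fentanyl patches too.", lx)
  expect_equal(nrow(m), 1L)
  expect_equal(m$canonical_drug, "fentanyl")
  expect_equal(m$n_occurrences, 2L)
})

test_that("token boundaries prevent nested-term false positives", {
  lx <- tiny_lexicon()
  m <- detect_mentions("sufentanil is not fentanyl", lx)
  m <- m[order(m$canonical_drug), ]
  expect_equal(m$canonical_drug, c("fentanyl", "sufentanil"))
  expect_equal(m$n_occurrences, c(1L, 1L))
  # "fent" must not fire inside "fentanyl" or "sufentanil"
  expect_equal(sum(m$n_occurrences), 2L)
})

test_that("multi-token surface terms match as contiguous sequences only", {
  lx <- tiny_lexicon()
  m <- detect_mentions("they called it china white back then", lx)
  expect_equal(m$canonical_drug, "fentanyl")
  expect_equal(m$n_occurrences, 1L)
  # broken sequence does not match
  expect_equal(nrow(detect_mentions("china is not white", lx)), 0L)
  # punctuation between tokens still separates words, not sequences
  m2 <- detect_mentions("china-white, twice: china white", lx)
  expect_equal(m2$n_occurrences, 2L)
})

test_that("empty or mention-free text yields an empty record set", {
  lx <- tiny_lexicon()
  expect_equal(nrow(detect_mentions("", lx)), 0L)
  expect_equal(nrow(detect_mentions("nothing to see here", lx)), 0L)
  expect_equal(nrow(detect_mentions(data.frame(body = character()), lx)), 0L)
})

test_that("matching is idempotent and order-independent over a stream", {
  lx <- tiny_lexicon()
  set.seed(11)
  bodies <- replicate(50, paste(sample(c("fentanyl", "heroin", "walk",
                                         "china", "white", "china white",
                                         "tram", "tramadol"),
                                       sample(3:8, 1), replace = TRUE),
                                collapse = " "))
  com <- make_comments(bodies)
  a <- detect_mentions(com, lx)
  b <- detect_mentions(com[sample(nrow(com)), ], lx)
  key <- function(d) d[order(d$comment_id, d$canonical_drug),
                       c("comment_id", "canonical_drug", "n_occurrences")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
  expect_equal(key(a), key(detect_mentions(com, lx)), ignore_attr = TRUE)
})

test_that("the matcher agrees with a naive regex-per-term oracle", {
  lx <- tiny_lexicon()
  set.seed(7)
  vocab <- c("the", "fentanyl", "heroin", "sufentanil", "fent", "china",
             "white", "oxycodone", "street", "report", "tramadol",
             "methadone")
  bodies <- replicate(300, paste(sample(vocab, sample(2:12, 1),
                                        replace = TRUE), collapse = " "))
  com <- make_comments(bodies)
  got <- detect_mentions(com, lx)
  got <- got[order(got$comment_id, got$canonical_drug),
             c("comment_id", "canonical_drug", "n_occurrences")]
  want <- oracle_mention_scan(com, lx)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("summaries tally mentions, unique comments, and unique users", {
  rec <- data.frame(
    comment_id = c("c1", "c1", "c2", "c3"),
    user_id = c("u1", "u1", "u1", "u2"),
    month = "2020-01",
    canonical_drug = c("heroin", "fentanyl", "heroin", "heroin"),
    n_occurrences = c(2L, 1L, 1L, 3L), stringsAsFactors = FALSE)
  s <- summarize_mentions(rec)
  her <- s$by_drug[s$by_drug$canonical_drug == "heroin", ]
  expect_equal(her$mentions, 6L)
  expect_equal(her$comments, 3L)
  expect_equal(her$users, 2L)
  # sorted by mentions descending
  expect_equal(s$by_drug$canonical_drug[1], "heroin")
  # invariants: mentions >= comments >= 1, users <= comments
  expect_true(all(s$by_drug$mentions >= s$by_drug$comments))
  expect_true(all(s$by_drug$users <= s$by_drug$comments))

  empty <- summarize_mentions(rec[0, ])
  expect_equal(nrow(empty$by_drug), 0L)
})

test_that("class-level aggregates follow the lexicon annotations", {
  lx <- tiny_lexicon()
  com <- make_comments(c("fentanyl and tramadol", "heroin again",
                         "oxycodone pills"))
  s <- summarize_mentions(detect_mentions(com, lx), lx)
  syn <- s$by_synthesis_class
  expect_equal(syn$mentions[syn$synthesis_class == "synthetic"], 2L)
  expect_equal(syn$mentions[syn$synthesis_class == "heroin"], 1L)
})

test_that("planted mention counts are recovered exactly from a synthetic stream", {
  cfg <- sim_config(n_users = 80, n_months = 24, seed = 303,
                    mention_base_rate = 80, comments_per_user_month = 6)
  sim <- simulate_comment_stream(cfg)
  lx <- default_lexicon()
  rec <- detect_mentions(sim$comments, lx)
  planted <- sum(sim$truth$mention_counts$drug_comments)
  # each planted drug comment embeds exactly one surface-term occurrence
  expect_equal(sum(rec$n_occurrences), planted)
  expect_equal(length(unique(rec$comment_id)), planted)
})
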