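#' Read and write pipeline artifacts
#'
#' Comment streams travel as JSONL (one record per line with `user_id`,
#' `subreddit`, `month` as `"YYYY-MM"`, `body`, and optionally
#' `comment_id`); everything else is plain CSV.
#'
#' @name io
NULL

#' @rdname io
#' @param comments comment data.frame.
#' @param path file path.
#' @export
write_comments_jsonl <- function(comments, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(comments, con, verbose = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_comments_jsonl <- function(path) {
  if (!file.exists(path)) stop("comments file not found: ", path,
                               call. = FALSE)
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  need <- c("user_id", "subreddit", "month", "body")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("comments JSONL missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"comment_id" %in% names(df)) {
    df$comment_id <- sprintf("c%08d", seq_len(nrow(df)))
  }
  df
}

#' @rdname io
#' @param rs a [rate_series()].
#' @export
write_rate_series_csv <- function(rs, path) {
  out <- as.data.frame(rs)
  out$geography <- attr(rs, "geography")
  out$category <- attr(rs, "category")
  out$granularity <- attr(rs, "granularity")
  out$window <- attr(rs, "window")
  out$scale <- attr(rs, "scale")
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname io
#' @export
read_rate_series_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  rate_series(df$period, df$numerator, df$denominator,
              scale = df$scale[1L], geography = df$geography[1L],
              category = df$category[1L],
              granularity = df$granularity[1L], window = df$window[1L])
}
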