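# JSON Lines serialization of a stream chunk (keys id, date, text, lang,
# is_retweet). Strings are escaped minimally (backslash, quote, control
# whitespace), which covers tokenized social-media text.
json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub('"', '\\"', s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  gsub("\t", "\\t", s, fixed = TRUE)
}

stream_to_jsonl <- function(stream) {
  sprintf('{"id":"%s","date":"%s","text":"%s","lang":"%s","is_retweet":%s}',
          json_escape(stream$id), as.character(stream$date),
          json_escape(stream$text), json_escape(stream$lang),
          ifelse(stream$is_retweet, "true", "false"))
}

#' Write / read a message stream as JSON Lines
#'
#' One message per line with keys `id`, `date`, `text`, `lang`,
#' `is_retweet`, UTF-8. Reading tolerates malformed lines: they are
#' skipped with a warning reporting the count, unless their fraction
#' exceeds `max_malformed_frac`, in which case reading aborts. A line
#' missing a required key counts as malformed.
#'
#' @param stream a message stream table.
#' @param path file path.
#' @param max_malformed_frac abort threshold for the malformed-line
#'   fraction (default 0.01).
#' @return `write_stream` returns `path` invisibly; `read_stream` returns
#'   the stream `data.table` with an attribute `malformed` giving the
#'   number of skipped lines.
#' @export
write_stream <- function(stream, path) {
  stream <- as_stream(stream)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(stream_to_jsonl(stream), con)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path, max_malformed_frac = 0.01) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.table(id = character(0), date = as.IDate(integer(0)),
                      text = character(0), lang = character(0),
                      is_retweet = logical(0))
    setattr(out, "malformed", 0L)
    return(out)
  }
  parse_one <- function(ln) {
    x <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    need <- c("id", "date", "text", "lang", "is_retweet")
    if (is.null(x) || !all(need %in% names(x)) ||
        any(vapply(x[need], is.null, logical(1)))) return(NULL)
    x[need]
  }
  # fast path: parse everything as one JSON array; fall back to per-line
  # parsing (to isolate and skip bad lines) only when that fails
  rows <- tryCatch({
    df <- jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"))
    need <- c("id", "date", "text", "lang", "is_retweet")
    if (!all(need %in% names(df)) || anyNA(df$is_retweet)) stop("missing keys")
    list(df = df[need], bad = 0L)
  }, error = function(e) {
    parsed <- lapply(lines, parse_one)
    ok <- !vapply(parsed, is.null, logical(1))
    list(df = rbindlist(parsed[ok]), bad = sum(!ok))
  })
  bad <- rows$bad
  if (bad / length(lines) > max_malformed_frac) {
    stop(sprintf("%d of %d lines malformed (> %.2f%% allowed)", bad,
                 length(lines), 100 * max_malformed_frac), call. = FALSE)
  }
  if (bad > 0L) {
    warning(sprintf("skipped %d malformed line(s) of %d", bad, length(lines)))
  }
  out <- as.data.table(rows$df)
  out[, date := as.IDate(date)]
  out[, is_retweet := as.logical(is_retweet)]
  setattr(out, "malformed", as.integer(bad))
  out[]
}

#' Write / read an n-gram ledger as TSV
#'
#' Tab-separated with header
#' `date  n  ngram  count_total  count_organic  count_retweet`, UTF-8, one
#' row per (date, order, n-gram). Round-trips losslessly.
#'
#' @param ledger ledger table from [count_stream()].
#' @param path file path.
#' @return `write_ledger` returns `path` invisibly; `read_ledger` the
#'   keyed ledger `data.table`.
#' @export
write_ledger <- function(ledger, path) {
  x <- as.data.table(ledger)
  setorder(x, date, n, ngram)
  fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  x <- fread(path, sep = "\t", header = TRUE, encoding = "UTF-8",
             colClasses = list(character = "ngram"))
  x[, date := as.IDate(date)]
  x[, n := as.integer(n)]
  setkey(x, date, n, ngram)
  x[]
}

#' Export helpers for analysis tables
#'
#' Plain TSV writers for the pipeline's table artifacts: ranked
#' distributions (`ngram  count  frequency  rank`), word-shift tables
#' (`word  h  p_ref  p_comp  contribution  class  h_rank_comp
#' usage_rank_comp  in_top_k`), divergence contribution tables
#' (`type  r1  r2  contribution  exclusivity`) and rank-rank histograms
#' (`cell_x  cell_y  band  count`).
#'
#' @param x the object to export.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  if (inherits(x, "shift_table")) x <- x$table
  if (inherits(x, "rtd_result")) x <- x$contributions
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
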