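#' @import data.table
#' @importFrom stats median rbinom runif setNames
NULL

# Coerce a message stream to a validated data.table with columns
# id, date (IDate), text, lang, is_retweet. Extra columns are kept.
as_stream <- function(stream) {
  x <- as.data.table(stream)
  need <- c("date", "text", "is_retweet")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("stream is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(x$date, "IDate")) {
    x <- copy(x)
    x[, date := suppressWarnings(as.IDate(date))]
  }
  if (!is.logical(x$is_retweet)) x[, is_retweet := as.logical(is_retweet)]
  x
}

#' Count n-grams in a message stream, split by organic/retweet
#'
#' Tokenizes every message and accumulates per-day counts of 1-, 2- and
#' 3-grams, partitioned into organic (`is_retweet = FALSE`) and retweeted
#' occurrences. Days follow the UTC calendar dates carried by the stream.
#' Messages without a parseable date are skipped with a warning.
#'
#' @param stream a message stream: data.frame with columns `date`, `text`,
#'   `is_retweet` (`id` and `lang` are carried by streams but not used here).
#' @param orders integer vector of n-gram orders to count, subset of 1:3.
#' @param case_fold passed to [tokenize()].
#' @return an n-gram ledger: a `data.table` with columns `date` (`IDate`),
#'   `n`, `ngram`, `count_total`, `count_organic`, `count_retweet`, keyed by
#'   `(date, n, ngram)`. `count_total = count_organic + count_retweet` for
#'   every row.
#' @export
count_stream <- function(stream, orders = 1:3, case_fold = TRUE) {
  stopifnot(all(orders %in% 1:3), length(orders) >= 1)
  stream <- as_stream(stream)
  bad <- is.na(stream$date)
  if (any(bad)) {
    warning(sum(bad), " message(s) missing a valid date; skipped")
    stream <- stream[!bad]
  }
  ft <- tokenize_flat(stream$text, case_fold = case_fold)
  ledger_from_flat(ft, stream$date, stream$is_retweet, orders)
}

# Core counting on flat-tokenized messages. Uses integer token ids and a
# base-K positional encoding for higher orders so grouping happens on
# numeric keys; n-gram strings are materialized once per unique key.
ledger_from_flat <- function(ft, dates, is_retweet, orders = 1:3) {
  orders <- sort(unique(as.integer(orders)))
  flat <- ft$tokens
  midx <- ft$midx
  if (length(flat) == 0L) {
    return(empty_ledger())
  }
  vocab <- unique(flat)
  K <- length(vocab)
  ids <- match(flat, vocab)
  day <- as.IDate(dates)[midx]
  rt <- as.logical(is_retweet)[midx]
  m <- length(ids)

  pieces <- vector("list", length(orders))
  for (oi in seq_along(orders)) {
    n <- orders[oi]
    if (n == 1L) {
      gid <- as.double(ids)
      sel <- rep(TRUE, m)
    } else if (m < n) {
      pieces[[oi]] <- empty_ledger()
      next
    } else {
      sel <- c(midx[seq_len(m - n + 1L)] == midx[seq_len(m - n + 1L) + (n - 1L)],
               rep(FALSE, n - 1L))
      if (n == 2L) {
        gid <- (as.double(ids) - 1) * K + as.double(c(ids[-1L], 0L))
      } else {
        gid <- ((as.double(ids) - 1) * K + (as.double(c(ids[-1L], 0L)) - 1)) * K +
          as.double(c(ids[-(1:2)], 0L, 0L))
      }
    }
    if (K^n >= 2^53) {  # positional encoding would lose precision; paste instead
      grams <- flat_ngram_strings(flat, midx, n)
      dt <- data.table(date = day[grams$pos], g = grams$str, rt = rt[grams$pos])
      agg <- dt[, .(count_total = .N, count_retweet = sum(rt)), by = .(date, g)]
      setnames(agg, "g", "ngram")
    } else {
      dt <- data.table(date = day[sel], gid = gid[sel], rt = rt[sel])
      agg <- dt[, .(count_total = .N, count_retweet = sum(rt)), by = .(date, gid)]
      ug <- unique(agg$gid)
      dec <- decode_gid(ug, vocab, n)  # decode once per unique id
      agg[, ngram := dec[match(gid, ug)]]
      agg[, gid := NULL]
    }
    agg[, n := n]
    pieces[[oi]] <- agg
  }
  led <- rbindlist(pieces, use.names = TRUE, fill = TRUE)
  if (nrow(led) == 0L) return(empty_ledger())
  led[, count_organic := count_total - as.integer(count_retweet)]
  led[, count_retweet := as.integer(count_retweet)]
  setcolorder(led, c("date", "n", "ngram", "count_total", "count_organic",
                     "count_retweet"))
  setkey(led, date, n, ngram)
  led[]
}

decode_gid <- function(gid, vocab, n) {
  K <- length(vocab)
  if (n == 1L) return(vocab[as.integer(gid)])
  if (n == 2L) {
    a <- (gid - 1) %/% K + 1
    b <- gid - (a - 1) * K
    return(paste(vocab[as.integer(a)], vocab[as.integer(b)]))
  }
  t2 <- (gid - 1) %/% K
  c3 <- gid - t2 * K
  a <- t2 %/% K + 1
  b <- t2 - (a - 1) * K + 1
  paste(vocab[as.integer(a)], vocab[as.integer(b)], vocab[as.integer(c3)])
}

# fallback path: explicit strings for windows of order n
flat_ngram_strings <- function(flat, midx, n) {
  m <- length(flat)
  pos <- seq_len(m - n + 1L)
  keep <- midx[pos] == midx[pos + (n - 1L)]
  pos <- pos[keep]
  str <- switch(as.character(n),
    "1" = flat[pos],
    "2" = paste(flat[pos], flat[pos + 1L]),
    "3" = paste(flat[pos], flat[pos + 1L], flat[pos + 2L]))
  list(pos = pos, str = str)
}

empty_ledger <- function() {
  data.table(date = as.IDate(integer(0)), n = integer(0), ngram = character(0),
             count_total = integer(0), count_organic = integer(0),
             count_retweet = integer(0), key = c("date", "n", "ngram"))
}

#' Rank a count distribution with fractional ties
#'
#' Builds a ranked distribution from ledger rows (or any table with `ngram`
#' and count columns): counts are summed per n-gram, converted to relative
#' frequencies, and ranked by descending count with average (fractional)
#' ranks for ties, so rank 1 is the most frequent type and the rank sum over
#' `N` types is always `N(N+1)/2`.
#'
#' @param ledger ledger rows forming one distribution (one day, or an
#'   aggregate); must contain a single n-gram order if an `n` column is
#'   present.
#' @param which which count column to rank: `"total"`, `"organic"` or
#'   `"retweet"`. Types whose chosen count is zero are dropped before
#'   ranking.
#' @return `data.table` with columns `ngram`, `count`, `frequency`, `rank`,
#'   sorted by rank.
#' @export
rank_distribution <- function(ledger, which = c("total", "organic", "retweet")) {
  which <- match.arg(which)
  x <- as.data.table(ledger)
  if (!"ngram" %in% names(x)) stop("ledger must have an `ngram` column", call. = FALSE)
  if ("n" %in% names(x) && length(unique(x$n)) > 1L) {
    stop("ledger holds several n-gram orders; subset to one before ranking",
         call. = FALSE)
  }
  col <- if (paste0("count_", which) %in% names(x)) paste0("count_", which)
         else if ("count" %in% names(x)) "count"
         else stop("no count column found", call. = FALSE)
  d <- x[, .(count = sum(.SD[[1]])), by = ngram, .SDcols = col][count > 0L]
  if (nrow(d) == 0L) stop("empty distribution: nothing to rank", call. = FALSE)
  d[, frequency := count / sum(count)]
  d[, rank := frank(-count, ties.method = "average")]
  setorder(d, rank, ngram)
  d[]
}

#' Identify messages containing an anchor phrase
#'
#' Matches the anchor as a contiguous run of tokens within each tokenized
#' message, under the same tokenization as [count_stream()], so punctuation
#' and case variants of the phrase match.
#'
#' @param stream a message stream (see [count_stream()]).
#' @param anchor anchor phrase, e.g. `"mental health"`; must tokenize to at
#'   least one token.
#' @param case_fold passed to [tokenize()].
#' @return logical vector, one element per message.
#' @export
anchor_matches <- function(stream, anchor, case_fold = TRUE) {
  stream <- as_stream(stream)
  atoks <- tokenize(anchor, case_fold = case_fold)[[1]]
  if (length(atoks) == 0L) stop("empty anchor phrase", call. = FALSE)
  ft <- tokenize_flat(stream$text, case_fold = case_fold)
  match_token_run(ft, atoks)
}

# contiguous token-run matching on the flat representation
match_token_run <- function(ft, atoks) {
  k <- length(atoks)
  flat <- ft$tokens
  midx <- ft$midx
  out <- rep(FALSE, ft$nmsg)
  m <- length(flat)
  if (m < k) return(out)
  pos <- seq_len(m - k + 1L)
  hit <- midx[pos] == midx[pos + (k - 1L)]
  for (j in seq_len(k)) {
    hit <- hit & (flat[pos + (j - 1L)] == atoks[j])
  }
  if (any(hit)) out[unique(midx[pos[hit]])] <- TRUE
  out
}

#' Extract the anchored sub-corpus
#'
#' Returns exactly the messages whose token sequence contains the anchor
#' phrase as adjacent tokens.
#'
#' @inheritParams anchor_matches
#' @return the matching rows of `stream`.
#' @export
anchor_subset <- function(stream, anchor, case_fold = TRUE) {
  stream <- as_stream(stream)
  stream[anchor_matches(stream, anchor, case_fold = case_fold)]
}

#' Daily rank time series of a target n-gram
#'
#' For each day present in the ledger (at the target's order), computes the
#' target's fractional rank among that day's n-grams. Days where the target
#' is absent are reported as missing (`NA`), never as a sentinel rank.
#'
#' @param ledger an n-gram ledger from [count_stream()].
#' @param target the n-gram of interest (already tokenized text, e.g.
#'   `"mental health"`).
#' @param which count column used for ranking, as in [rank_distribution()].
#' @return list with `series`, a `data.table` (`date`, `count`, `rank`), and
#'   `median`, the median rank over non-missing days (`NA` if the target
#'   never appears).
#' @export
rank_timeseries <- function(ledger, target, which = c("total", "organic", "retweet")) {
  which <- match.arg(which)
  x <- as.data.table(ledger)
  ord <- length(strsplit(target, " ", fixed = TRUE)[[1]])
  col <- paste0("count_", which)
  d <- x[n == ord]
  if (nrow(d) == 0L) stop("ledger has no rows of order ", ord, call. = FALSE)
  ser <- d[, {
    cnt <- .SD[[col]]
    keep <- cnt > 0L
    cnt <- cnt[keep]
    ng <- ngram[keep]
    ct <- cnt[ng == target]
    if (length(ct) == 0L) {
      list(count = NA_integer_, rank = NA_real_)
    } else {
      list(count = ct[1L],
           rank = sum(cnt > ct[1L]) + (sum(cnt == ct[1L]) + 1) / 2)
    }
  }, by = date]
  setorder(ser, date)
  list(series = ser[], median = if (all(is.na(ser$rank))) NA_real_
                                else median(ser$rank, na.rm = TRUE))
}

#' Aggregate daily ledgers into per-year ranked distributions
#'
#' Sums daily counts over each calendar year (partial years are kept and
#' labeled by their year) and ranks the pooled counts per year and order
#' with the tie convention of [rank_distribution()].
#'
#' @inheritParams rank_timeseries
#' @return `data.table` with columns `year`, `n`, `ngram`, `count`,
#'   `frequency`, `rank`.
#' @export
yearly_aggregate <- function(ledger, which = c("total", "organic", "retweet")) {
  which <- match.arg(which)
  x <- as.data.table(ledger)
  col <- paste0("count_", which)
  agg <- x[, .(count = sum(.SD[[1]])), by = .(year = year(date), n, ngram),
           .SDcols = col][count > 0L]
  agg[, frequency := count / sum(count), by = .(year, n)]
  agg[, rank := frank(-count, ties.method = "average"), by = .(year, n)]
  setorder(agg, year, n, rank, ngram)
  agg[]
}

#' Corpus summary statistics for one day
#'
#' Summarizes the 1-gram ledger of a corpus on a given day: number of
#' distinct words, total word count, and total word count excluding
#' retweeted messages.
#'
#' @inheritParams rank_timeseries
#' @param date the day to summarize.
#' @param label corpus label carried into the output.
#' @return one-row `data.table` with `date`, `label`, `unique_1grams`,
#'   `total_1grams`, `total_1grams_no_retweets`. A day inside the ledger
#'   with no rows yields zeros.
#' @export
summarize_corpus <- function(ledger, date, label = "") {
  x <- as.data.table(ledger)
  d1 <- x[n == 1L]
  if (nrow(d1) == 0L) stop("ledger has no 1-gram rows", call. = FALSE)
  day <- as.IDate(date)
  rows <- d1[date == day]
  data.table(date = day, label = label,
             unique_1grams = nrow(rows),
             total_1grams = sum(rows$count_total),
             total_1grams_no_retweets = sum(rows$count_organic))
}

#' Per-day corpus totals for one n-gram order
#'
#' Collapses a ledger to daily total/organic/retweet token counts at one
#' order; used as the background for amplification statistics.
#'
#' @inheritParams rank_timeseries
#' @param n n-gram order to total.
#' @return `data.table` with `date`, `count_total`, `count_organic`,
#'   `count_retweet` (one row per day).
#' @export
ledger_totals <- function(ledger, n = 1L) {
  x <- as.data.table(ledger)
  ord <- as.integer(n)
  x[n == ord, .(count_total = sum(count_total),
                count_organic = sum(count_organic),
                count_retweet = sum(count_retweet)), by = date][order(date)]
}
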