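#' Monthly organic/retweet balance of a target n-gram
#'
#' Sums the target's daily organic and retweeted counts over calendar
#' months and reports the organic and retweet fractions. A month where the
#' target never appears is reported with missing fractions. A month is
#' flagged `amplified` when retweeted use strictly exceeds organic use
#' (`f_rt > 1/2`).
#'
#' @param ledger daily n-gram ledger containing the target's order.
#' @param target the n-gram of interest.
#' @return `data.table` with one row per month spanned by the ledger:
#'   `month` (`"YYYY-MM"`), `c_ot`, `c_rt`, `f_ot`, `f_rt`, `amplified`.
#' @export
monthly_balance <- function(ledger, target) {
  x <- as.data.table(ledger)
  ord <- length(strsplit(target, " ", fixed = TRUE)[[1]])
  d <- x[n == ord & ngram == target]
  months <- month_seq(range(x$date))
  if (nrow(d) == 0L) {
    return(data.table(month = months, c_ot = 0L, c_rt = 0L, f_ot = NA_real_,
                      f_rt = NA_real_, amplified = NA))
  }
  agg <- d[, .(c_ot = sum(count_organic), c_rt = sum(count_retweet)),
           by = .(month = format(date, "%Y-%m"))]
  out <- agg[data.table(month = months), on = "month"]
  out[is.na(c_ot), c_ot := 0L]
  out[is.na(c_rt), c_rt := 0L]
  tot <- out$c_ot + out$c_rt
  out[, f_ot := fifelse(tot > 0, c_ot / tot, NA_real_)]
  out[, f_rt := fifelse(tot > 0, c_rt / tot, NA_real_)]
  out[, amplified := fifelse(tot > 0, f_rt > 0.5, NA)]
  setorder(out, month)
  out[]
}

month_seq <- function(rng) {
  from <- as.Date(paste0(format(rng[1], "%Y-%m"), "-01"))
  to <- as.Date(paste0(format(rng[2], "%Y-%m"), "-01"))
  format(seq(from, to, by = "month"), "%Y-%m")
}

#' Relative retweet amplification heatmap
#'
#' For each (weekday, month) cell, compares the target's retweet/organic
#' odds with the background corpus's odds over the same days:
#' `R = (c_rt / c_ot) / (C_rt / C_ot)`, where lowercase counts are the
#' target's and uppercase the background totals over all n-grams of the
#' same order. Counts are summed over the cell's days before the ratios
#' are formed. `R > 1` marks stronger-than-background social
#' amplification; `R < 1` marks organic-dominant use. Cells where any of
#' the four counts is zero are flagged undefined (missing `R`), never
#' clamped or infinite.
#'
#' @param ledger daily ledger containing the target.
#' @param target the n-gram of interest.
#' @param background either a full ledger (its totals at the target's
#'   order are used) or a precomputed daily totals table from
#'   [ledger_totals()] (columns `date`, `count_organic`, `count_retweet`).
#'   Must cover every date on which the target appears.
#' @return `data.table` with `weekday` (1 = Monday), `month`, the four
#'   summed counts, `R`, and `defined`.
#' @export
amplification_heatmap <- function(ledger, target, background) {
  x <- as.data.table(ledger)
  ord <- length(strsplit(target, " ", fixed = TRUE)[[1]])
  bg <- as.data.table(background)
  if ("ngram" %in% names(bg)) bg <- ledger_totals(bg, n = ord)
  d <- x[n == ord & ngram == target]
  missing_dates <- setdiff(as.character(unique(d$date)),
                           as.character(unique(bg$date)))
  if (length(missing_dates)) {
    stop("background does not cover target dates: ",
         paste(utils::head(missing_dates, 10), collapse = ", "), call. = FALSE)
  }
  bg <- bg[, .(date, C_ot = count_organic, C_rt = count_retweet)]
  tg <- d[, .(date, c_ot = count_organic, c_rt = count_retweet)]
  m <- tg[bg, on = "date"]
  m[is.na(c_ot), c_ot := 0L]
  m[is.na(c_rt), c_rt := 0L]
  cells <- m[, .(c_ot = sum(c_ot), c_rt = sum(c_rt),
                 C_ot = sum(C_ot), C_rt = sum(C_rt)),
             by = .(weekday = as.integer(format(as.Date(date), "%u")),
                    month = format(date, "%Y-%m"))]
  cells[, defined := c_ot > 0 & c_rt > 0 & C_ot > 0 & C_rt > 0]
  cells[, R := fifelse(defined, (c_rt / c_ot) / (C_rt / C_ot), NA_real_)]
  setorder(cells, month, weekday)
  cells[]
}

#' Month-smoothed rank panel with weekly min-max band
#'
#' Prepares the rank panel of a contagiogram: the daily rank series, a
#' trailing mean over `window` days computed on `log10(rank)` and
#' transformed back (ranks are displayed logarithmically), and the
#' minimum and maximum rank within each ISO week.
#'
#' @param series `data.table`/data.frame with columns `date` and `rank`
#'   (missing ranks allowed), e.g. from [rank_timeseries()].
#' @param window smoothing window in days (default 30, month-scale).
#' @return `data.table` with `date`, `rank`, `smoothed`, `week`,
#'   `week_min`, `week_max`.
#' @export
smoothed_rank_panel <- function(series, window = 30L) {
  if (!(length(window) == 1L && window >= 1)) {
    stop("`window` must be a positive integer", call. = FALSE)
  }
  s <- as.data.table(series)[, .(date = as.IDate(date), rank = as.numeric(rank))]
  days <- data.table(date = seq(min(s$date), max(s$date), by = 1L))
  s <- s[days, on = "date"]
  setorder(s, date)
  s[, smoothed := 10^rolling_smooth(log10(rank), window = window)]
  s[, week := format(as.Date(date), "%G-W%V")]
  s[, `:=`(week_min = if (all(is.na(rank))) NA_real_ else min(rank, na.rm = TRUE),
           week_max = if (all(is.na(rank))) NA_real_ else max(rank, na.rm = TRUE)),
    by = week]
  s[]
}

#' Detect the first sustained retweet-balance crossing
#'
#' Finds the earliest month that begins a run of at least `run_length`
#' consecutive amplified months (`f_rt > 1/2`), i.e. the point where
#' retweeted use of the target durably overtakes organic use. Months with
#' no occurrences break a run.
#'
#' @param balance monthly balance table from [monthly_balance()].
#' @param run_length required run of consecutive amplified months
#'   (default 3, guarding against single-month noise).
#' @return the `"YYYY-MM"` month starting the first sustained run, or
#'   `NA_character_` if none exists.
#' @export
detect_crossing <- function(balance, run_length = 3L) {
  b <- as.data.table(balance)
  if (nrow(b) < run_length) return(NA_character_)
  setorder(b, month)
  amp <- !is.na(b$amplified) & b$amplified
  r <- rle(amp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= run_length)
  if (length(ok) == 0L) return(NA_character_)
  b$month[starts[ok[1L]]]
}
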