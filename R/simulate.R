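#' Configuration for the synthetic message stream
#'
#' Builds a validated configuration for [generate_stream()]. The defaults
#' emulate, at desk scale, a decade of a 10%-style public message stream in
#' which an anchor topic grows by two orders of magnitude in prevalence,
#' spikes annually on awareness days and irregularly on tragedies, carries
#' regime-dependent word sentiment, and is increasingly retweeted, with the
#' platform-wide retweet probability rising through 1/2 mid-series.
#'
#' The anchor prevalence schedule is log-linear from `pi_start` to `pi_end`
#' across the window; events boost it multiplicatively (boost decaying
#' exponentially with the event's half-life, capped so probabilities stay
#' in \[0, 1\]). The retweet probability follows
#' `rho(t) = rho_lo + (rho_hi - rho_lo) * (1 + tanh((t - t_cross) / scale)) / 2`,
#' crossing 1/2 at `rho_cross_date` when `rho_lo + rho_hi = 1`. Anchor
#' messages have their retweet odds multiplied by
#' `anchor_retweet_odds_boost`, so their planted amplification ratio
#' against the background is exactly that factor.
#'
#' @param start_date,end_date simulation window (inclusive).
#' @param messages_per_day messages generated per day.
#' @param vocab_size background vocabulary size; chosen much larger than
#'   the daily token flow so that daily rank distributions have the
#'   heavy-tailed dynamic range of real streams.
#' @param zipf_exponent exponent of the background Zipf distribution.
#' @param anchor_phrase two-token anchor phrase planted in topic messages.
#' @param pi_start,pi_end anchor prevalence at the window's ends.
#' @param event_list data.frame with columns `date`, `kind`
#'   (`"awareness"`/`"tragedy"`), `boost` (multiplier >= 1), `half_life`
#'   (days); `NULL` for the default planted decade of events.
#' @param rho_lo,rho_hi,rho_cross_date,rho_scale_days retweet-probability
#'   schedule parameters.
#' @param anchor_retweet_odds_boost multiplicative boost of anchor
#'   messages' retweet odds relative to background.
#' @param sentiment_means named list: mean happiness targeted by the
#'   anchor-topic word distribution in each regime (`baseline`,
#'   `awareness`, `tragedy`) and the Gaussian weighting width `sd`.
#' @param topic_lexicon_frac probability that a non-anchor token of a topic
#'   message is drawn from the (regime-weighted) lexicon rather than the
#'   background vocabulary.
#' @param len_range inclusive range of message lengths in tokens.
#' @param lexicon lexicon table (see [read_lexicon()]); `NULL` for the
#'   bundled synthetic fixture.
#' @param rng_seed integer seed; identical configurations and seeds yield
#'   byte-identical streams.
#' @return object of class `stream_config` (a validated list).
#' @export
stream_config <- function(start_date = "2010-01-01",
                          end_date = "2019-12-31",
                          messages_per_day = 1000L,
                          vocab_size = 50000L,
                          zipf_exponent = 1.0,
                          anchor_phrase = "mental health",
                          pi_start = 1e-4,
                          pi_end = 1e-2,
                          event_list = NULL,
                          rho_lo = 0.25,
                          rho_hi = 0.75,
                          rho_cross_date = "2017-07-01",
                          rho_scale_days = 60,
                          anchor_retweet_odds_boost = 1.5,
                          sentiment_means = list(baseline = 5.5,
                                                 awareness = 6.5,
                                                 tragedy = 4.0,
                                                 sd = 0.75),
                          topic_lexicon_frac = 0.5,
                          len_range = c(5L, 25L),
                          lexicon = NULL,
                          rng_seed = 1L) {
  start_date <- as.IDate(start_date)
  end_date <- as.IDate(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date < start_date) {
    stop("invalid simulation window", call. = FALSE)
  }
  if (messages_per_day < 1L) stop("messages_per_day must be >= 1", call. = FALSE)
  if (zipf_exponent <= 0) stop("zipf_exponent must be positive", call. = FALSE)
  if (pi_start < 0 || pi_start > 1 || pi_end < 0 || pi_end > 1) {
    stop("prevalence endpoints must lie in [0, 1]", call. = FALSE)
  }
  if (rho_lo < 0 || rho_hi > 1 || rho_lo > rho_hi) {
    stop("retweet probability bounds must satisfy 0 <= rho_lo <= rho_hi <= 1",
         call. = FALSE)
  }
  if (anchor_retweet_odds_boost <= 0) {
    stop("anchor_retweet_odds_boost must be positive", call. = FALSE)
  }
  if (is.null(event_list)) event_list <- default_event_list(start_date, end_date)
  ev <- as.data.table(event_list)
  if (nrow(ev)) {
    if (!all(c("date", "kind", "boost", "half_life") %in% names(ev))) {
      stop("event_list needs columns date, kind, boost, half_life", call. = FALSE)
    }
    ev[, date := as.IDate(date)]
    if (any(ev$boost < 1)) stop("event boost must be >= 1", call. = FALSE)
    if (!all(ev$kind %in% c("awareness", "tragedy"))) {
      stop("event kind must be 'awareness' or 'tragedy'", call. = FALSE)
    }
    if (any(ev$date < start_date | ev$date > end_date)) {
      stop("event dates must lie within the simulation window", call. = FALSE)
    }
  }
  if (is.null(lexicon)) lexicon <- read_lexicon(lexicon_fixture_path())
  cfg <- list(start_date = start_date, end_date = end_date,
              messages_per_day = as.integer(messages_per_day),
              vocab_size = as.integer(vocab_size),
              zipf_exponent = zipf_exponent,
              anchor_phrase = anchor_phrase,
              pi_start = pi_start, pi_end = pi_end,
              event_list = ev,
              rho_lo = rho_lo, rho_hi = rho_hi,
              rho_cross_date = as.IDate(rho_cross_date),
              rho_scale_days = rho_scale_days,
              anchor_retweet_odds_boost = anchor_retweet_odds_boost,
              sentiment_means = sentiment_means,
              topic_lexicon_frac = topic_lexicon_frac,
              len_range = as.integer(len_range),
              lexicon = as.data.table(lexicon),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "stream_config"
  cfg
}

# Default planted events: annual awareness days (late January from year 4,
# mid-October from year 5) and irregular tragedies, 20 events over a
# default decade.
default_event_list <- function(start_date, end_date) {
  y0 <- as.integer(format(as.Date(start_date), "%Y"))
  y1 <- as.integer(format(as.Date(end_date), "%Y"))
  ev <- list()
  if (y1 >= y0 + 3L) {
    jan_years <- seq(y0 + 3L, y1)
    ev[[length(ev) + 1L]] <- data.table(
      date = as.IDate(sprintf("%d-01-25", jan_years)),
      kind = "awareness", boost = 25, half_life = 1.5)
  }
  if (y1 >= y0 + 4L) {
    oct_years <- seq(y0 + 4L, y1)
    ev[[length(ev) + 1L]] <- data.table(
      date = as.IDate(sprintf("%d-10-10", oct_years)),
      kind = "awareness", boost = 10, half_life = 1.5)
  }
  trag <- as.IDate(c("2012-12-14", "2014-08-11", "2015-06-17", "2017-04-18",
                     "2018-06-08", "2019-08-03"))
  trag <- trag[trag >= start_date & trag <= end_date]
  if (length(trag)) {
    ev[[3]] <- data.table(date = trag, kind = "tragedy", boost = 15,
                          half_life = 3)
  }
  out <- rbindlist(ev)
  if (nrow(out)) out <- out[date >= as.IDate(start_date) & date <= as.IDate(end_date)]
  if (nrow(out) == 0L) {
    return(data.table(date = as.IDate(integer(0)), kind = character(0),
                      boost = numeric(0), half_life = numeric(0)))
  }
  setorder(out, date)
  out[]
}

# Deterministic schedule pieces -------------------------------------------

# day-by-day scheduled quantities for the whole window
build_schedules <- function(cfg) {
  dates <- seq(cfg$start_date, cfg$end_date, by = 1L)
  nd <- length(dates)
  frac <- if (nd == 1L) 0 else (seq_len(nd) - 1) / (nd - 1)
  pi_base <- if (cfg$pi_start > 0 && cfg$pi_end > 0) {
    # log-linear growth between positive endpoints
    exp(log(cfg$pi_start) + frac * (log(cfg$pi_end) - log(cfg$pi_start)))
  } else {
    # a zero endpoint has no log form; interpolate linearly
    cfg$pi_start + frac * (cfg$pi_end - cfg$pi_start)
  }
  boost <- rep(1, nd)
  regime <- rep("baseline", nd)
  best <- rep(0, nd)
  if (nrow(cfg$event_list)) {
    for (i in seq_len(nrow(cfg$event_list))) {
      e <- cfg$event_list[i]
      dt <- as.numeric(dates - e$date)
      act <- dt >= 0
      a <- ifelse(act, (e$boost - 1) * 2^(-dt / e$half_life), 0)
      boost <- boost * (1 + a)
      take <- a > best & a >= 0.5
      regime[take] <- e$kind
      best <- pmax(best, a)
    }
  }
  pi_eff <- pmin(1, pi_base * boost)
  t_rel <- as.numeric(dates - cfg$rho_cross_date)
  rho <- cfg$rho_lo + (cfg$rho_hi - cfg$rho_lo) *
    (1 + tanh(t_rel / cfg$rho_scale_days)) / 2
  odds <- rho / (1 - rho)
  odds_a <- odds * cfg$anchor_retweet_odds_boost
  rho_anchor <- odds_a / (1 + odds_a)
  rho_anchor[rho >= 1] <- 1
  data.table(date = dates, pi_base = pi_base, pi_eff = pi_eff,
             regime = regime, rho = rho, rho_anchor = rho_anchor)
}

# background vocabulary: a head of common function words (never containing
# the anchor's constituent tokens) followed by synthetic word types
build_vocab <- function(cfg) {
  common <- c("the", "to", "a", "and", "i", "you", "of", "in", "is", "for",
              "on", "my", "it", "me", "that", "with", "be", "this", "have",
              "so", "not", "are", "at", "but", "we", "do", "what", "can",
              "if", "or", "was", "just", "like", "they", "your", "all",
              "get", "when", "out", "up", "about", "how", "will", "one",
              "no", "more", "people", "time", "day", "good", "love", "know",
              "now", "today", "think", "see", "want", "who", "from", "as")
  atoks <- tokenize(cfg$anchor_phrase)[[1]]
  common <- setdiff(common, atoks)
  v <- cfg$vocab_size
  if (length(common) >= v) return(common[seq_len(v)])
  c(common, sprintf("w%06d", seq_len(v - length(common))))
}

#' Generate a synthetic message stream with planted structure
#'
#' Simulates the configured window day by day. Each day emits
#' `messages_per_day` messages; a message is an anchor-topic message with
#' the day's (event-boosted) prevalence, in which case it contains the
#' anchor phrase as an adjacent token pair plus regime-weighted lexicon
#' words, otherwise its tokens are Zipf draws from the background
#' vocabulary (which never contains the anchor tokens, so background
#' messages never match the anchor). Retweet flags are drawn from the
#' day's retweet probability, with boosted odds for anchor messages.
#' All randomness derives from `rng_seed`; two runs with the same
#' configuration are identical.
#'
#' @param config a [stream_config()].
#' @param path optional path: when given, the stream is written as JSON
#'   Lines (keys `id`, `date`, `text`, `lang`, `is_retweet`) instead of
#'   returned in memory.
#' @return list with `stream` (a `data.table`, or `NULL` when `path` is
#'   given) and `truth`, the ground-truth record: per-day scheduled and
#'   realized anchor prevalence and retweet fraction, the regime, the
#'   event list, the sentiment regime means, and the scheduled month of
#'   the anchor's sustained retweet-balance crossing
#'   (`anchor_crossing_month`).
#' @export
generate_stream <- function(config, path = NULL) {
  stopifnot(inherits(config, "stream_config"))
  sched <- build_schedules(config)
  prep <- prepare_generator(config)
  set.seed(config$rng_seed)
  con <- NULL
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
  }
  chunks <- list()
  realized <- vector("list", nrow(sched))
  offset <- 0L
  for (d in seq_len(nrow(sched))) {
    day <- simulate_day(config, prep, sched[d], offset)
    offset <- offset + nrow(day$stream)
    realized[[d]] <- day$realized
    if (is.null(con)) {
      chunks[[d]] <- day$stream
    } else {
      writeLines(stream_to_jsonl(day$stream), con)
    }
  }
  truth <- build_truth(config, sched, rbindlist(realized))
  list(stream = if (is.null(con)) rbindlist(chunks) else NULL, truth = truth)
}

# regime-weighted sampling tables shared across days
prepare_generator <- function(cfg) {
  vocab <- build_vocab(cfg)
  p <- seq_along(vocab)^(-cfg$zipf_exponent)
  cum_bg <- cumsum(p / sum(p))
  sm <- cfg$sentiment_means
  lex <- cfg$lexicon
  regime_cum <- lapply(c(baseline = "baseline", awareness = "awareness",
                         tragedy = "tragedy"), function(rg) {
    w <- stats::dnorm(lex$score, mean = sm[[rg]], sd = sm$sd)
    w <- w + 1e-12
    cumsum(w / sum(w))
  })
  list(vocab = vocab, cum_bg = cum_bg, lex_words = lex$word,
       regime_cum = regime_cum,
       anchor_tokens = tokenize(cfg$anchor_phrase)[[1]])
}

# one simulated day; all RNG happens here, day by day, so output is
# independent of any chunking of the surrounding loop
simulate_day <- function(cfg, prep, s, offset) {
  n <- cfg$messages_per_day
  k <- rbinom(1L, n, s$pi_eff)
  is_anchor <- c(rep(TRUE, k), rep(FALSE, n - k))[sample.int(n)]
  lens <- cfg$len_range[1] + floor(runif(n) * (cfg$len_range[2] - cfg$len_range[1] + 1L))
  texts <- character(n)

  # background tokens for non-anchor messages, drawn in message order
  bg_msgs <- which(!is_anchor)
  if (length(bg_msgs)) {
    tot <- sum(lens[bg_msgs])
    ids <- findInterval(runif(tot), prep$cum_bg) + 1L
    toks <- prep$vocab[ids]
    midx <- rep.int(seq_along(bg_msgs), lens[bg_msgs])
    texts[bg_msgs] <- paste_by_group(toks, midx, length(bg_msgs))
  }

  an_msgs <- which(is_anchor)
  if (length(an_msgs)) {
    cum_rg <- prep$regime_cum[[s$regime]]
    for (i in an_msgs) {
      noth <- lens[i] - 2L
      from_lex <- runif(noth) < cfg$topic_lexicon_frac
      oth <- character(noth)
      nl <- sum(from_lex)
      if (nl) oth[from_lex] <- prep$lex_words[findInterval(runif(nl), cum_rg) + 1L]
      if (noth - nl) {
        oth[!from_lex] <- prep$vocab[findInterval(runif(noth - nl), prep$cum_bg) + 1L]
      }
      pos <- 1L + floor(runif(1) * (noth + 1L))
      texts[i] <- paste(append(oth, prep$anchor_tokens, after = pos - 1L),
                        collapse = " ")
    }
  }

  rho_msg <- ifelse(is_anchor, s$rho_anchor, s$rho)
  is_rt <- runif(n) < rho_msg
  stream <- data.table(id = sprintf("t%09d", offset + seq_len(n)),
                       date = s$date, text = texts, lang = "en",
                       is_retweet = is_rt)
  realized <- data.table(date = s$date,
                         realized_anchor_frac = k / n,
                         realized_retweet_frac = mean(is_rt))
  list(stream = stream, realized = realized)
}

paste_by_group <- function(tokens, group, ngroups) {
  out <- vapply(split(tokens, group), paste, character(1), collapse = " ")
  res <- character(ngroups)
  res[as.integer(names(out))] <- out
  res
}

build_truth <- function(cfg, sched, realized) {
  daily <- merge(sched, realized, by = "date", all.x = TRUE)
  mon <- daily[, .(rho_anchor_mean = mean(rho_anchor)),
               by = .(month = format(date, "%Y-%m"))]
  setorder(mon, month)
  amp <- mon$rho_anchor_mean > 0.5
  cross <- NA_character_
  r <- rle(amp)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= 3L)
  if (length(ok)) cross <- mon$month[starts[ok[1L]]]
  list(daily = daily,
       events = copy(cfg$event_list),
       sentiment_means = cfg$sentiment_means,
       anchor_phrase = cfg$anchor_phrase,
       anchor_crossing_month = cross,
       rng_seed = cfg$rng_seed)
}

#' Write / read a ground-truth record
#'
#' Serializes the ground truth from [generate_stream()] as JSON and reads
#' it back losslessly (dates are restored to `IDate`, tables to
#' `data.table`).
#'
#' @param gt ground-truth list.
#' @param path output file.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns the ground-truth list.
#' @export
write_ground_truth <- function(gt, path) {
  x <- gt
  x$daily <- as.data.frame(x$daily)
  x$daily$date <- as.character(x$daily$date)
  x$events <- as.data.frame(x$events)
  if (nrow(x$events)) x$events$date <- as.character(x$events$date)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$daily <- as.data.table(x$daily)
  x$daily[, date := as.IDate(date)]
  ev <- as.data.table(x$events)
  if (nrow(ev)) {
    ev[, date := as.IDate(date)]
  } else {
    ev <- data.table(date = as.IDate(integer(0)), kind = character(0),
                     boost = numeric(0), half_life = numeric(0))
  }
  x$events <- ev
  if (is.null(x$anchor_crossing_month)) x$anchor_crossing_month <- NA_character_
  x$rng_seed <- as.integer(x$rng_seed)
  x
}
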