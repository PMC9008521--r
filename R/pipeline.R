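#' Configure an end-to-end pipeline run
#'
#' Bundles and validates everything [run_pipeline()] needs: the stream
#' source (a JSON Lines path or a [stream_config()] to simulate), the
#' anchor phrase, lexicon and lens, event dates for word-shift tables,
#' divergence and smoothing parameters, the output directory and the seed.
#'
#' @param source a path to a JSON Lines stream, or a [stream_config()].
#' @param out_dir output directory (created if needed).
#' @param anchor anchor phrase defining the topical sub-corpus.
#' @param lexicon lexicon table or TSV path; `NULL` for the bundled
#'   fixture.
#' @param lens optional neutral-exclusion lens `c(lo, hi)` for ambient
#'   scoring.
#' @param events data.frame with a `date` column (and optionally `kind`)
#'   for which word-shift tables are produced; `NULL` takes the event list
#'   from a synthetic source (or none for a file source).
#' @param alpha rank-turbulence divergence exponent.
#' @param ambient_window trailing window (days) for ambient smoothing.
#' @param rank_window trailing window (days) for rank smoothing.
#' @param divergence_order n-gram order compared by divergence (anchor
#'   3-grams are filtered via [filter_anchor_phrases()] when this is 3).
#' @param divergence_year calendar year compared; `NULL` for the last year
#'   in the stream.
#' @param background_sample_rate fraction of messages kept (by systematic
#'   1-in-k subsampling) as the random background corpus for divergence.
#' @param seed integer seed driving all randomness of the run; for a
#'   synthetic source it replaces the generator's `rng_seed`.
#' @param plots also render basic figures from the exported tables?
#' @param chunk_days days simulated/processed per chunk (memory knob only;
#'   results are independent of it).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(source, out_dir,
                            anchor = "mental health",
                            lexicon = NULL, lens = NULL, events = NULL,
                            alpha = 1 / 3,
                            ambient_window = 7L, rank_window = 30L,
                            divergence_order = 3L, divergence_year = NULL,
                            background_sample_rate = 0.1,
                            seed = 1L, plots = FALSE, chunk_days = 32L) {
  if (!(inherits(source, "stream_config") ||
        (is.character(source) && length(source) == 1L))) {
    stop("`source` must be a file path or a stream_config", call. = FALSE)
  }
  if (is.character(source) && !file.exists(source)) {
    stop("stream file not found: ", source, call. = FALSE)
  }
  if (is.null(lexicon)) {
    lexicon <- read_lexicon(lexicon_fixture_path())
  } else if (is.character(lexicon)) {
    lexicon <- read_lexicon(lexicon)
  } else {
    lexicon <- as.data.table(lexicon)
  }
  if (is.null(events) && inherits(source, "stream_config")) {
    events <- copy(source$event_list)
  }
  if (!is.null(events)) {
    events <- as.data.table(events)
    events[, date := as.IDate(date)]
  }
  if (!(alpha > 0)) stop("alpha must be positive", call. = FALSE)
  if (background_sample_rate <= 0 || background_sample_rate > 1) {
    stop("background_sample_rate must be in (0, 1]", call. = FALSE)
  }
  cfg <- list(source = source, out_dir = out_dir, anchor = anchor,
              lexicon = lexicon, lens = lens, events = events,
              alpha = alpha, ambient_window = as.integer(ambient_window),
              rank_window = as.integer(rank_window),
              divergence_order = as.integer(divergence_order),
              divergence_year = divergence_year,
              background_sample_rate = background_sample_rate,
              seed = as.integer(seed), plots = isTRUE(plots),
              chunk_days = as.integer(chunk_days))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full discourse pipeline
#'
#' Executes the stages end to end, streaming the corpus in date chunks so
#' memory stays flat: n-gram counting with organic/retweet splits, anchored
#' sub-corpus extraction, the anchor's daily rank series, daily corpus
#' summaries, ambient happiness with weekly smoothing, word-shift tables
#' for each configured event, a yearly rank-turbulence divergence of the
#' anchored corpus against a systematic background subsample, and the
#' anchor's contagiogram panels. All table artifacts are written as TSV
#' under `out_dir` together with a `manifest.json` recording the
#' configuration hash, row counts, and headline results; runs with
#' identical configurations are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the principal in-memory results
#'   (`rank_series`, `rank_median_by_year`, `ambient`, `shifts`,
#'   `divergence`, `balance`, `crossing_month`, `truth` for synthetic
#'   sources) and `paths` to the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  atoks <- tokenize(cfg$anchor)[[1]]
  ord <- length(atoks)
  keep_every <- max(1L, as.integer(round(1 / cfg$background_sample_rate)))

  synthetic <- inherits(cfg$source, "stream_config")
  acc <- new.env(parent = emptyenv())
  acc$anchored <- list(); acc$sampled <- list(); acc$anchor_day <- list()
  acc$totals <- list(); acc$summary <- list(); acc$realized <- list()
  acc$n_msgs <- 0L

  process_chunk <- function(chunk) {
    ft <- tokenize_flat(chunk$text)
    hit <- match_token_run(ft, atoks)
    if (any(hit)) acc$anchored[[length(acc$anchored) + 1L]] <- chunk[hit]
    idx <- seq_len(nrow(chunk)) + acc$n_msgs
    sel <- idx %% keep_every == 0L
    if (any(sel)) acc$sampled[[length(acc$sampled) + 1L]] <- chunk[sel]
    st <- chunk_day_stats(ft, chunk$date, chunk$is_retweet, ord, atoks)
    acc$anchor_day[[length(acc$anchor_day) + 1L]] <- st$anchor_day
    acc$totals[[length(acc$totals) + 1L]] <- st$totals
    acc$summary[[length(acc$summary) + 1L]] <- st$summary
    acc$n_msgs <- acc$n_msgs + nrow(chunk)
    invisible(NULL)
  }

  set.seed(cfg$seed)
  truth <- NULL
  if (synthetic) {
    scfg <- cfg$source
    scfg$rng_seed <- cfg$seed
    sched <- build_schedules(scfg)
    prep <- prepare_generator(scfg)
    set.seed(scfg$rng_seed)
    offset <- 0L
    starts <- seq(1L, nrow(sched), by = cfg$chunk_days)
    for (s0 in starts) {
      rows <- s0:min(s0 + cfg$chunk_days - 1L, nrow(sched))
      days <- vector("list", length(rows))
      for (j in seq_along(rows)) {
        day <- simulate_day(scfg, prep, sched[rows[j]], offset)
        offset <- offset + nrow(day$stream)
        acc$realized[[length(acc$realized) + 1L]] <- day$realized
        days[[j]] <- day$stream
      }
      process_chunk(rbindlist(days))
    }
    truth <- build_truth(scfg, sched, rbindlist(acc$realized))
  } else {
    stream <- read_stream(cfg$source)
    if (nrow(stream) == 0L) stop("empty input stream", call. = FALSE)
    setorder(stream, date, id)
    for (piece in split_by_chunk(stream, cfg$chunk_days)) process_chunk(piece)
  }

  out <- list()
  paths <- list()
  anchored <- rbindlist(acc$anchored)
  if (nrow(anchored) == 0L) {
    stop("no messages contain the anchor phrase '", cfg$anchor, "'",
         call. = FALSE)
  }
  anchored_ledger <- count_stream(anchored, orders = 1:3)
  paths$anchored_ledger <- file.path(cfg$out_dir, "anchored_ledger.tsv")
  write_ledger(anchored_ledger, paths$anchored_ledger)

  # anchor rank series + yearly medians
  anchor_day <- rbindlist(acc$anchor_day)
  setorder(anchor_day, date)
  setnames(anchor_day, c("count_total", "count_organic", "count_retweet"),
           c("count", "count_organic", "count_retweet"))
  paths$rank_series <- file.path(cfg$out_dir, "rank_series.tsv")
  fwrite(anchor_day, paths$rank_series, sep = "\t", quote = FALSE, na = "NA")
  out$rank_series <- anchor_day
  out$rank_median_by_year <- anchor_day[!is.na(rank),
    .(median_rank = median(rank), days_present = .N),
    by = .(year = year(date))][order(year)]

  # daily summaries of the full corpus
  summary_tab <- rbindlist(acc$summary)[order(date)]
  paths$summary <- file.path(cfg$out_dir, "summary.tsv")
  fwrite(summary_tab, paths$summary, sep = "\t", quote = FALSE)

  # ambient happiness of the anchored corpus
  out$ambient <- ambient_series(anchored_ledger, cfg$lexicon, lens = cfg$lens,
                                window = cfg$ambient_window)
  paths$ambient <- file.path(cfg$out_dir, "ambient.tsv")
  fwrite(out$ambient, paths$ambient, sep = "\t", quote = FALSE, na = "NA")

  # word shifts per event
  out$shifts <- list()
  if (!is.null(cfg$events) && nrow(cfg$events)) {
    for (i in seq_len(nrow(cfg$events))) {
      ev <- cfg$events$date[i]
      sh <- tryCatch({
        ref <- build_reference(anchored_ledger, ev, mode = "pooled_week")
        comp <- anchored_ledger[n == 1L & date == ev]
        word_shift(ref, comp, cfg$lexicon, lens = cfg$lens,
                   ref_label = paste("week before", ev),
                   comp_label = as.character(ev))
      }, error = function(e) {
        message("shift table skipped for ", ev, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(sh)) {
        out$shifts[[as.character(ev)]] <- sh
        p <- file.path(cfg$out_dir, paste0("shift_", ev, ".tsv"))
        write_table_tsv(sh, p)
        paths$shifts <- c(paths$shifts, p)
      }
    }
  }

  # divergence: anchored vs background subsample, yearly aggregation
  sampled <- rbindlist(acc$sampled)
  dorder <- cfg$divergence_order
  year_pick <- cfg$divergence_year
  if (is.null(year_pick)) year_pick <- max(year(anchored_ledger$date))
  ya <- yearly_aggregate(anchored_ledger[n == dorder])
  sample_ledger <- count_stream(sampled, orders = dorder)
  ys <- yearly_aggregate(sample_ledger)
  rd1 <- ya[year == year_pick, .(ngram, count, frequency, rank)]
  rd2 <- ys[year == year_pick, .(ngram, count, frequency, rank)]
  out$divergence <- NULL
  if (nrow(rd1) && nrow(rd2)) {
    if (dorder == 3L && length(atoks) == 2L) {
      rd1 <- filter_anchor_phrases(rd1, paste(atoks, collapse = " "))
    }
    out$divergence <- rank_turbulence_divergence(rd1, rd2, alpha = cfg$alpha)
    paths$divergence <- file.path(cfg$out_dir, "divergence.tsv")
    write_table_tsv(out$divergence, paths$divergence)
    hist <- rank_rank_histogram(
      out$divergence$contributions[, .(type, r1, r2, exclusivity)])
    paths$divergence_histogram <- file.path(cfg$out_dir,
                                            "divergence_histogram.tsv")
    write_table_tsv(hist, paths$divergence_histogram)
  }

  # contagiogram of the anchor n-gram
  target <- paste(atoks, collapse = " ")
  target_ledger <- anchor_day[!is.na(count),
    .(date, n = ord, ngram = target, count_total = count,
      count_organic, count_retweet)]
  bg_totals <- rbindlist(acc$totals)[order(date)]
  out$balance <- monthly_balance(target_ledger, target)
  paths$balance <- file.path(cfg$out_dir, "balance.tsv")
  fwrite(out$balance, paths$balance, sep = "\t", quote = FALSE, na = "NA")
  out$heatmap <- amplification_heatmap(target_ledger, target, bg_totals)
  paths$heatmap <- file.path(cfg$out_dir, "heatmap.tsv")
  fwrite(out$heatmap, paths$heatmap, sep = "\t", quote = FALSE, na = "NA")
  panel <- smoothed_rank_panel(anchor_day[, .(date, rank)],
                               window = cfg$rank_window)
  paths$rankpanel <- file.path(cfg$out_dir, "rankpanel.tsv")
  fwrite(panel, paths$rankpanel, sep = "\t", quote = FALSE, na = "NA")
  out$crossing_month <- detect_crossing(out$balance)

  if (synthetic) {
    paths$truth <- file.path(cfg$out_dir, "truth.json")
    write_ground_truth(truth, paths$truth)
    out$truth <- truth
  }

  manifest <- list(
    package = "discourselens",
    version = as.character(utils::packageVersion("discourselens")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    anchor = cfg$anchor,
    n_messages = acc$n_msgs,
    n_anchored = nrow(anchored),
    crossing_month = out$crossing_month,
    divergence = if (!is.null(out$divergence)) out$divergence$divergence else NULL,
    rank_median_by_year = out$rank_median_by_year,
    tables = lapply(paths[!names(paths) %in% "truth"], function(p) {
      if (is.character(p) && length(p) == 1L && file.exists(p)) {
        length(readLines(p, warn = FALSE)) - 1L
      } else NULL
    })
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  if (cfg$plots) render_pipeline_plots(paths, cfg$out_dir)

  out$paths <- paths
  invisible(out)
}

# Per-day statistics of one chunk without materializing n-gram strings:
# counts are grouped on integer token ids (positionally encoded for the
# anchor's order), which is all that daily summaries, background totals and
# the anchor's daily tied rank require.
chunk_day_stats <- function(ft, dates, is_retweet, ord, atoks) {
  flat <- ft$tokens
  midx <- ft$midx
  vocab <- unique(flat)
  K <- length(vocab)
  if (K^ord >= 2^53) {  # id encoding would lose precision: count via strings
    led <- ledger_from_flat(ft, dates, is_retweet, orders = unique(c(1L, ord)))
    target <- paste(atoks, collapse = " ")
    anchor_day <- led[n == ord, {
      ct <- count_total[ngram == target]
      if (length(ct)) {
        list(rank = sum(count_total > ct[1L]) + (sum(count_total == ct[1L]) + 1) / 2,
             count_total = ct[1L],
             count_organic = count_organic[ngram == target][1L],
             count_retweet = count_retweet[ngram == target][1L])
      } else {
        list(rank = NA_real_, count_total = NA_integer_,
             count_organic = NA_integer_, count_retweet = NA_integer_)
      }
    }, by = date]
    return(list(
      anchor_day = anchor_day,
      totals = ledger_totals(led, n = ord),
      summary = led[n == 1L, .(unique_1grams = .N,
                               total_1grams = sum(count_total),
                               total_1grams_no_retweets = sum(count_organic)),
                    by = date]))
  }
  ids <- match(flat, vocab)
  day <- as.IDate(dates)[midx]
  rt <- as.logical(is_retweet)[midx]
  m <- length(ids)

  d1 <- data.table(date = day, gid = ids, rt = rt)
  a1 <- d1[, .(ct = .N, crt = sum(rt)), by = .(date, gid)]
  summary <- a1[, .(unique_1grams = .N, total_1grams = sum(ct),
                    total_1grams_no_retweets = sum(ct - crt)), by = date]
  setorder(summary, date)

  if (ord == 1L) {
    ao <- a1
    tgid <- {
      j <- match(atoks[1L], vocab)
      if (is.na(j)) -1 else as.double(j)
    }
  } else {
    pos <- seq_len(m - ord + 1L)
    keep <- midx[pos] == midx[pos + (ord - 1L)]
    gid <- as.double(ids[pos])
    for (j in 2:ord) gid <- gid * K + as.double(ids[pos + (j - 1L)] - 1L)
    dd <- data.table(date = day[pos][keep], gid = gid[keep], rt = rt[pos][keep])
    ao <- dd[, .(ct = .N, crt = sum(rt)), by = .(date, gid)]
    aid <- match(atoks, vocab)
    tgid <- if (anyNA(aid)) -1 else {
      g <- as.double(aid[1L])
      for (j in 2:ord) g <- g * K + as.double(aid[j] - 1L)
      g
    }
  }
  totals <- ao[, .(count_total = sum(ct), count_organic = sum(ct - crt),
                   count_retweet = sum(crt)), by = date]
  setorder(totals, date)
  anchor_day <- ao[, {
    i <- which(gid == tgid)
    if (length(i)) {
      ci <- ct[i[1L]]
      list(rank = sum(ct > ci) + (sum(ct == ci) + 1) / 2,
           count_total = ci, count_organic = ci - crt[i[1L]],
           count_retweet = crt[i[1L]])
    } else {
      list(rank = NA_real_, count_total = NA_integer_,
           count_organic = NA_integer_, count_retweet = NA_integer_)
    }
  }, by = date]
  setorder(anchor_day, date)
  list(anchor_day = anchor_day, totals = totals, summary = summary)
}

split_by_chunk <- function(stream, chunk_days) {
  d0 <- min(stream$date)
  grp <- as.integer(stream$date - d0) %/% chunk_days
  split(stream, grp)
}

# stable hash of the analytic configuration (md5 of its canonical JSON
# form); the output location and plot toggle do not affect results and
# are excluded
config_hash <- function(cfg) {
  x <- cfg
  x$out_dir <- NULL
  x$plots <- NULL
  x$lexicon <- as.data.frame(x$lexicon)
  if (inherits(x$source, "stream_config")) {
    x$source <- lapply(unclass(x$source), function(v) {
      if (inherits(v, "IDate")) as.character(v)
      else if (is.data.frame(v)) {
        v <- as.data.frame(v)
        if ("date" %in% names(v)) v$date <- as.character(v$date)
        v
      } else v
    })
  }
  if (!is.null(x$events)) {
    x$events <- as.data.frame(x$events)
    x$events$date <- as.character(x$events$date)
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
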