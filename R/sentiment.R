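#' Read a happiness lexicon
#'
#' Reads a tab-separated lexicon of word happiness scores on the 1-9 scale
#' (labMT-style: 1 = saddest, 9 = happiest, ~5 neutral). The package ships a
#' small synthetic lexicon fixture (see [lexicon_fixture_path()]).
#'
#' @param path TSV file with columns `word` and `score` (header required).
#' @return `data.table` with columns `word`, `score`; scores validated to
#'   lie in \[1, 9\].
#' @export
read_lexicon <- function(path) {
  lex <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = "word", numeric = "score"), encoding = "UTF-8")
  if (!all(c("word", "score") %in% names(lex))) {
    stop("lexicon must have columns `word` and `score`", call. = FALSE)
  }
  if (any(!is.finite(lex$score)) || any(lex$score < 1 | lex$score > 9)) {
    stop("lexicon scores must lie in [1, 9]", call. = FALSE)
  }
  if (anyDuplicated(lex$word)) {
    stop("lexicon has duplicated words", call. = FALSE)
  }
  lex[]
}

#' Path to the bundled synthetic lexicon
#'
#' A ~220-word happiness lexicon with hand-assigned synthetic scores
#' spanning \[1, 9\], sufficient for testing and simulation; it is not a
#' crowdsourced instrument.
#' @return file path to the TSV fixture.
#' @export
lexicon_fixture_path <- function() {
  system.file("extdata", "lexicon_synthetic.tsv", package = "discourselens",
              mustWork = TRUE)
}

# Filter lexicon by the optional neutral-exclusion lens (lo, hi):
# words with lo < h(w) < hi are ignored when scoring.
apply_lens <- function(lex, lens = NULL) {
  if (is.null(lens)) return(lex)
  stopifnot(length(lens) == 2, lens[1] >= 1, lens[2] <= 9, lens[1] < lens[2])
  lex[!(score > lens[1] & score < lens[2])]
}

# Collapse ledger rows / named counts to a two-column table word|count.
word_counts <- function(x, which = "total") {
  if (is.numeric(x) && !is.null(names(x))) {
    return(data.table(word = names(x), count = as.numeric(x)))
  }
  d <- as.data.table(x)
  if ("n" %in% names(d)) d <- d[n == 1L]
  col <- if (paste0("count_", which) %in% names(d)) paste0("count_", which)
         else "count"
  nm <- if ("ngram" %in% names(d)) "ngram" else "word"
  d[, .(count = sum(.SD[[1]])), by = setNames(list(get(nm)), "word"),
    .SDcols = col][count > 0]
}

#' Ambient happiness of a word-count distribution
#'
#' Count-weighted mean happiness of all words present in the lexicon (and
#' outside the optional lens): `h_avg = sum h(w) c(w) / sum c(w)`. This is
#' the "ambient" score of a topical corpus: the average tone of words
#' co-occurring with the anchor phrase.
#'
#' @param counts 1-gram ledger rows for one period, or a named numeric
#'   vector of word counts.
#' @param lexicon lexicon table from [read_lexicon()].
#' @param lens optional numeric `c(lo, hi)`: words with `lo < h(w) < hi`
#'   are excluded from scoring (off by default).
#' @param exclude optional character vector of words to drop before scoring
#'   (e.g. the anchor's own constituent words).
#' @param which count column when `counts` is a ledger.
#' @return list with `h_avg` (NA when no token matches) and
#'   `matched_tokens`, the number of scored token occurrences.
#' @export
ambient_happiness <- function(counts, lexicon, lens = NULL, exclude = NULL,
                              which = "total") {
  wc <- word_counts(counts, which = which)
  lex <- apply_lens(as.data.table(lexicon), lens)
  if (!is.null(exclude)) lex <- lex[!word %in% exclude]
  m <- merge(wc, lex, by = "word")
  tot <- sum(m$count)
  if (tot == 0) return(list(h_avg = NA_real_, matched_tokens = 0L))
  list(h_avg = sum(m$score * m$count) / tot, matched_tokens = as.integer(tot))
}

#' Daily ambient-happiness series
#'
#' Applies [ambient_happiness()] to each day of a 1-gram ledger, then adds a
#' trailing rolling mean (see [rolling_smooth()]).
#'
#' @param ledger 1-gram ledger of the corpus to score (typically the
#'   anchored sub-corpus).
#' @param lexicon,lens,exclude,which as in [ambient_happiness()].
#' @param window smoothing window in days (default 7, a weekly rolling
#'   average).
#' @return `data.table` with one row per calendar day from the first to the
#'   last ledger day: `date`, `h_avg`, `matched_tokens`, `h_smoothed`.
#' @export
ambient_series <- function(ledger, lexicon, lens = NULL, exclude = NULL,
                           which = "total", window = 7L) {
  x <- as.data.table(ledger)[n == 1L]
  if (nrow(x) == 0L) stop("ledger has no 1-gram rows", call. = FALSE)
  lex <- apply_lens(as.data.table(lexicon), lens)
  if (!is.null(exclude)) lex <- lex[!word %in% exclude]
  col <- paste0("count_", which)
  d <- merge(x, lex, by.x = "ngram", by.y = "word")
  d <- d[, .(h_sum = sum(score * .SD[[1]]), c_sum = sum(.SD[[1]])),
         by = date, .SDcols = col]
  days <- data.table(date = seq(min(x$date), max(x$date), by = 1L))
  out <- d[days, on = "date"]
  out[is.na(c_sum), c_sum := 0]
  out[, h_avg := fifelse(c_sum > 0, h_sum / c_sum, NA_real_)]
  out[, matched_tokens := as.integer(c_sum)]
  out[, c("h_sum", "c_sum") := NULL]
  out[, h_smoothed := rolling_smooth(h_avg, window = window)]
  setorder(out, date)
  out[]
}

#' Trailing rolling mean that tolerates missing days
#'
#' Mean over the trailing `window` positions (the current day and the
#' `window - 1` before it), skipping missing values. If fewer than
#' `window / 2` values are available in the window, the smoothed value is
#' itself missing. With `window = 1` the series is returned unchanged.
#'
#' @param x numeric vector on a regular (daily) grid, `NA` allowed.
#' @param window positive integer window length.
#' @return numeric vector of the same length.
#' @export
rolling_smooth <- function(x, window = 7L) {
  if (!(length(window) == 1L && window >= 1)) {
    stop("`window` must be a positive integer", call. = FALSE)
  }
  window <- as.integer(window)
  if (window == 1L) return(as.numeric(x))
  n <- length(x)
  good <- !is.na(x)
  cs <- cumsum(fifelse(good, as.numeric(x), 0))
  cn <- cumsum(as.numeric(good))
  lo <- pmax(seq_len(n) - window, 0L)
  s <- cs - c(0, cs)[lo + 1L]
  k <- cn - c(0, cn)[lo + 1L]
  out <- ifelse(k >= window / 2, s / k, NA_real_)
  out[k == 0] <- NA_real_
  out
}

#' Pooled reference ledger before an event
#'
#' Builds the reference word-count distribution used by [word_shift()]:
#' either the 7 days strictly before the event pooled together (default) or
#' the single same weekday one week earlier.
#'
#' @param ledger daily 1-gram ledger.
#' @param event_date the event day.
#' @param mode `"pooled_week"` or `"same_day_prior_week"`.
#' @return ledger-shaped `data.table` (without dates) of summed counts.
#' @export
build_reference <- function(ledger, event_date,
                            mode = c("pooled_week", "same_day_prior_week")) {
  mode <- match.arg(mode)
  x <- as.data.table(ledger)[n == 1L]
  ev <- as.IDate(event_date)
  days <- if (mode == "pooled_week") seq(ev - 7L, ev - 1L, by = 1L) else ev - 7L
  ref <- x[date %in% days]
  if (nrow(ref) == 0L) {
    stop("no reference days available before ", format(ev), call. = FALSE)
  }
  ref[, .(count_total = sum(count_total), count_organic = sum(count_organic),
          count_retweet = sum(count_retweet)), by = .(n, ngram)]
}

#' Word-shift decomposition of an ambient-happiness difference
#'
#' Decomposes the difference in ambient happiness between a comparison
#' corpus and a reference corpus into per-word contributions
#' `delta_h(w) = (h(w) - h_ref) * (p_comp(w) - p_ref(w))`, where `p` are
#' word frequencies over lexicon-matched (lens-passing) tokens within each
#' corpus. The contributions sum exactly to `h_comp - h_ref`. Each word is
#' classified by its valence relative to the reference mean and by the
#' direction of its usage change: `pos_up`, `pos_down`, `neg_up`,
#' `neg_down` (zero-contribution words get `none`).
#'
#' @param ref,comp 1-gram ledgers (or named count vectors) for the
#'   reference and comparison corpora.
#' @param lexicon,lens,which as in [ambient_happiness()].
#' @param top_k number of largest-magnitude contributions flagged for
#'   display (ties at the boundary broken alphabetically).
#' @param ref_label,comp_label labels carried into the result.
#' @return an object of class `shift_table`: list with `h_ref`, `h_comp`,
#'   `delta` (= `h_comp - h_ref`), labels, and `table`, a `data.table`
#'   sorted by `|contribution|` descending with columns `word`, `h`,
#'   `p_ref`, `p_comp`, `contribution`, `class`, `h_rank_comp` (happiness
#'   rank among words present in the comparison corpus), `usage_rank_comp`,
#'   `in_top_k`.
#' @export
word_shift <- function(ref, comp, lexicon, lens = NULL, top_k = 20L,
                       which = "total", ref_label = "reference",
                       comp_label = "comparison") {
  lex <- apply_lens(as.data.table(lexicon), lens)
  r <- merge(word_counts(ref, which), lex, by = "word")
  c_ <- merge(word_counts(comp, which), lex, by = "word")
  if (nrow(r) == 0L) stop("reference corpus matches no lexicon words", call. = FALSE)
  if (nrow(c_) == 0L) stop("comparison corpus matches no lexicon words", call. = FALSE)
  tab <- merge(r[, .(word, score, c_ref = count)],
               c_[, .(word, c_comp = count)], by = "word", all = TRUE)
  tab[is.na(c_ref), c_ref := 0]
  tab[is.na(c_comp), c_comp := 0]
  tab[is.na(score), score := lex$score[match(word, lex$word)]]
  tab[, p_ref := c_ref / sum(c_ref)]
  tab[, p_comp := c_comp / sum(c_comp)]
  h_ref <- sum(tab$score * tab$p_ref)
  h_comp <- sum(tab$score * tab$p_comp)
  tab[, contribution := (score - h_ref) * (p_comp - p_ref)]
  tab[, class := fifelse(contribution == 0, "none",
        paste0(fifelse(score >= h_ref, "pos", "neg"),
               fifelse(p_comp >= p_ref, "_up", "_down")))]
  tab[, h_rank_comp := fifelse(c_comp > 0,
        frank(fifelse(c_comp > 0, -score, Inf), ties.method = "average"),
        NA_real_)]
  tab[, usage_rank_comp := fifelse(c_comp > 0,
        frank(fifelse(c_comp > 0, -p_comp, Inf), ties.method = "average"),
        NA_real_)]
  tab <- tab[order(-abs(contribution), word)]
  tab[, in_top_k := seq_len(.N) <= top_k]
  out <- list(h_ref = h_ref, h_comp = h_comp, delta = h_comp - h_ref,
              ref_label = ref_label, comp_label = comp_label,
              table = tab[, .(word, h = score, p_ref, p_comp, contribution,
                              class, h_rank_comp, usage_rank_comp, in_top_k)])
  class(out) <- "shift_table"
  out
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("Word shift: %s (h = %.4f) vs %s (h = %.4f), delta = %+.4f\n",
              x$comp_label, x$h_comp, x$ref_label, x$h_ref, x$delta))
  print(utils::head(x$table[x$table$in_top_k], 20))
  invisible(x)
}
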