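# Independent brute-force oracles and toy fixtures, implemented with plain
# base R (loops, table(), sort()) so they share no code path with the
# package internals they check.

toy_lexicon <- function() {
  data.table::data.table(
    word = c("good", "bad", "ok", "love", "death", "care", "fear",
             "happy", "sad", "calm"),
    score = c(7, 3, 5, 8.4, 1.6, 6.6, 2.7, 8.3, 2.4, 6.9))
}

# random toy stream over a small vocabulary of clean lowercase tokens;
# a fraction of messages contains the anchor phrase as adjacent tokens
random_toy_stream <- function(n_msgs, n_days = 5L, vocab_size = 30L,
                              anchor = c("mental", "health"),
                              anchor_frac = 0.2,
                              start = as.Date("2019-06-01")) {
  vocab <- c(paste0("v", seq_len(vocab_size)), toy_lexicon()$word)
  dates <- start + sample.int(n_days, n_msgs, replace = TRUE) - 1L
  texts <- character(n_msgs)
  for (i in seq_len(n_msgs)) {
    len <- sample(3:9, 1)
    toks <- sample(vocab, len, replace = TRUE)
    if (runif(1) < anchor_frac) {
      p <- sample.int(len + 1L, 1)
      toks <- append(toks, anchor, after = p - 1L)
    }
    texts[i] <- paste(toks, collapse = " ")
  }
  data.table::data.table(
    id = sprintf("m%05d", seq_len(n_msgs)),
    date = data.table::as.IDate(dates),
    text = texts, lang = "en",
    is_retweet = runif(n_msgs) < 0.4)
}

# naive nested-loop recount: per message, per order, enumerate windows,
# then count with table() on composite keys "date\tn\tgram"
oracle_count_keys <- function(stream, orders = 1:3) {
  acc <- vector("list", nrow(stream))
  for (i in seq_len(nrow(stream))) {
    toks <- strsplit(stream$text[i], " ", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    rows <- character(0)
    for (n in orders) {
      if (length(toks) < n) next
      for (j in seq_len(length(toks) - n + 1L)) {
        g <- paste(toks[j:(j + n - 1L)], collapse = " ")
        rows[[length(rows) + 1L]] <-
          paste(as.character(stream$date[i]), n, g, sep = "\t")
      }
    }
    acc[[i]] <- list(keys = rows, rt = stream$is_retweet[i])
  }
  keys <- unlist(lapply(acc, `[[`, "keys"))
  rt <- rep(vapply(acc, `[[`, logical(1), "rt"),
            vapply(acc, function(a) length(a$keys), integer(1)))
  list(total = table(keys), retweet = table(keys[rt]))
}

ledger_to_keyed <- function(ledger) {
  k <- paste(as.character(ledger$date), ledger$n, ledger$ngram, sep = "\t")
  list(total = stats::setNames(ledger$count_total, k),
       retweet = stats::setNames(ledger$count_retweet, k))
}

expect_ledger_matches_oracle <- function(ledger, stream, orders = 1:3) {
  orc <- oracle_count_keys(stream, orders)
  led <- ledger_to_keyed(ledger)
  expect_setequal(names(led$total), names(orc$total))
  ord <- names(orc$total)
  expect_equal(unname(led$total[ord]), unname(as.integer(orc$total[ord])))
  rk <- names(orc$retweet)
  expect_equal(unname(led$retweet[rk]), unname(as.integer(orc$retweet[rk])))
  zero_rt <- setdiff(ord, rk)
  expect_true(all(led$retweet[zero_rt] == 0L))
}

# sort-based fractional ranks: average the 1-based sorted positions of ties
oracle_rank <- function(counts) {
  ord <- order(-counts)
  pos <- integer(length(counts))
  pos[ord] <- seq_along(counts)
  r <- numeric(length(counts))
  for (u in unique(counts)) {
    sel <- counts == u
    r[sel] <- mean(pos[sel])
  }
  r
}

# direct term-by-term rank-turbulence divergence on two named count vectors
oracle_rtd <- function(c1, c2, alpha = 1 / 3) {
  r1 <- stats::setNames(oracle_rank(unname(c1)), names(c1))
  r2 <- stats::setNames(oracle_rank(unname(c2)), names(c2))
  types <- union(names(c1), names(c2))
  n1 <- length(c1); n2 <- length(c2)
  nx1 <- sum(!types %in% names(c2) & types %in% names(c1))
  nx2 <- sum(!types %in% names(c1) & types %in% names(c2))
  term <- function(a, b) (alpha + 1) / alpha * abs(a^(-alpha) - b^(-alpha))^(1 / (alpha + 1))
  s <- 0
  for (t in types) {
    a <- if (t %in% names(r1)) r1[[t]] else n1 + (nx2 + 1) / 2
    b <- if (t %in% names(r2)) r2[[t]] else n2 + (nx1 + 1) / 2
    s <- s + term(a, b)
  }
  norm <- 0
  for (t in names(r1)) norm <- norm + term(r1[[t]], n2 + (n1 + 1) / 2)
  for (t in names(r2)) norm <- norm + term(n1 + (n2 + 1) / 2, r2[[t]])
  s / norm
}

counts_to_ranked <- function(counts) {
  data.table::data.table(ngram = names(counts), count = as.numeric(counts),
                         rank = oracle_rank(unname(counts)))
}

# trailing windowed mean with the availability rule, by explicit loop
oracle_roll <- function(x, window) {
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    w <- x[max(1L, i - window + 1L):i]
    w <- w[!is.na(w)]
    if (length(w) >= window / 2) out[i] <- mean(w)
  }
  out
}

# naive contiguous-subsequence scan for the anchor phrase
oracle_anchor_hits <- function(stream, anchor_tokens) {
  hits <- logical(nrow(stream))
  k <- length(anchor_tokens)
  for (i in seq_len(nrow(stream))) {
    toks <- strsplit(stream$text[i], " ", fixed = TRUE)[[1]]
    if (length(toks) < k) next
    for (j in seq_len(length(toks) - k + 1L)) {
      if (all(toks[j:(j + k - 1L)] == anchor_tokens)) {
        hits[i] <- TRUE
        break
      }
    }
  }
  hits
}

month_index <- function(m) {
  p <- as.integer(strsplit(m, "-", fixed = TRUE)[[1]])
  p[1] * 12L + p[2]
}

# random ranked systems (count vectors) for divergence property tests
random_system <- function(n_types, label = "t") {
  stats::setNames(sample(1:50, n_types, replace = TRUE),
                  paste0(label, sample.int(n_types * 3L, n_types)))
}
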