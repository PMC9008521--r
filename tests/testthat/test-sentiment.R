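test_that("ambient happiness is the count-weighted lexicon mean", {
  lex <- data.table::data.table(word = c("good", "bad", "ok"),
                                score = c(7, 3, 5))
  h <- ambient_happiness(c(good = 3, bad = 1), lex)
  expect_equal(h$h_avg, 6.0)
  expect_equal(h$matched_tokens, 4L)
  # out-of-lexicon words contribute nothing; all-unmatched is missing
  h2 <- ambient_happiness(c(zzz = 5, qqq = 2), lex)
  expect_true(is.na(h2$h_avg))
  expect_equal(h2$matched_tokens, 0L)
  # the neutral-exclusion lens removes mid-scale words
  h3 <- ambient_happiness(c(good = 3, ok = 10, bad = 1), lex, lens = c(4, 6))
  expect_equal(h3$h_avg, 6.0)
  # explicit exclusions (e.g. anchor constituents) are honored
  h4 <- ambient_happiness(c(good = 3, bad = 1), lex, exclude = "bad")
  expect_equal(h4$h_avg, 7.0)
})

test_that("rolling smoothing is a trailing mean with an availability rule", {
  expect_equal(rolling_smooth(rep(4, 10), 7)[7:10], rep(4, 4))
  expect_equal(rolling_smooth(1:10, 1), as.numeric(1:10))
  expect_equal(rolling_smooth(1:10, 7)[10], 7)
  # missing values are skipped; sparse windows become missing
  x <- c(1, NA, 3, NA, NA, NA, NA)
  expect_equal(rolling_smooth(x, 4)[3], 2)     # 2 of 4 available
  expect_true(is.na(rolling_smooth(x, 4)[7]))  # 0 of 4 available
  set.seed(3)
  y <- rnorm(60)
  y[sample(60, 12)] <- NA
  expect_equal(rolling_smooth(y, 7), oracle_roll(y, 7))
  expect_error(rolling_smooth(1:5, 0), "window")
})

test_that("word shift reproduces the two-word hand computation", {
  lex <- data.table::data.table(word = c("good", "bad"), score = c(7, 3))
  sh <- word_shift(c(good = 2, bad = 2), c(good = 1, bad = 3), lex)
  expect_equal(sh$h_ref, 5.0)
  expect_equal(sh$h_comp, 4.0)
  tab <- sh$table
  expect_equal(tab[word == "good"]$contribution, (7 - 5) * (0.25 - 0.5))
  expect_equal(tab[word == "bad"]$contribution, (3 - 5) * (0.75 - 0.5))
  expect_equal(sum(tab$contribution), sh$delta)
  expect_equal(tab[word == "good"]$class, "pos_down")
  expect_equal(tab[word == "bad"]$class, "neg_up")
})

test_that("identical corpora produce an all-zero shift", {
  lex <- toy_lexicon()
  cnt <- c(good = 4, bad = 2, love = 1)
  sh <- word_shift(cnt, cnt, lex)
  expect_true(all(sh$table$contribution == 0))
  expect_equal(sh$delta, 0)
  expect_true(all(sh$table$class == "none"))
})

test_that("shift contributions conserve the happiness difference", {
  lex <- toy_lexicon()
  set.seed(41)
  for (rep in 1:30) {
    w1 <- sample(lex$word, sample(4:10, 1))
    w2 <- sample(lex$word, sample(4:10, 1))
    c1 <- stats::setNames(sample(1:20, length(w1), TRUE), w1)
    c2 <- stats::setNames(sample(1:20, length(w2), TRUE), w2)
    sh <- word_shift(c1, c2, lex)
    expect_equal(sum(sh$table$contribution), sh$h_comp - sh$h_ref,
                 tolerance = 1e-9)
    # independent means over lexicon-matched tokens
    h1 <- sum(lex$score[match(w1, lex$word)] * c1) / sum(c1)
    h2 <- sum(lex$score[match(w2, lex$word)] * c2) / sum(c2)
    expect_equal(sh$h_ref, h1, tolerance = 1e-12)
    expect_equal(sh$h_comp, h2, tolerance = 1e-12)
    # classes partition the non-zero contributions
    nz <- sh$table[contribution != 0]
    expect_true(all(nz$class %in% c("pos_up", "pos_down", "neg_up", "neg_down")))
    up <- nz[h > sh$h_ref & p_comp > p_ref]
    expect_true(all(up$class == "pos_up"))
  }
})

test_that("word shift needs lexicon-matched tokens on both sides", {
  lex <- toy_lexicon()
  expect_error(word_shift(c(zzz = 3), c(good = 1), lex), "reference corpus")
  expect_error(word_shift(c(good = 1), c(zzz = 3), lex), "comparison corpus")
})

test_that("reference pooling sums the prior week's ledgers", {
  days <- data.table::as.IDate("2019-06-01") + 0:7
  led <- data.table::data.table(date = rep(days, each = 2), n = 1L,
                                ngram = c("good", "bad"),
                                count_total = c(3L, 1L),
                                count_organic = c(2L, 1L),
                                count_retweet = c(1L, 0L))
  ref <- build_reference(led, "2019-06-08", mode = "pooled_week")
  expect_equal(ref[ngram == "good"]$count_total, 21L)
  expect_equal(ref[ngram == "bad"]$count_total, 7L)
  one <- build_reference(led, "2019-06-08", mode = "same_day_prior_week")
  expect_equal(one[ngram == "good"]$count_total, 3L)
  expect_error(build_reference(led, "2019-05-01"), "no reference days")
  # pooled equals a brute-force sum on random ledgers
  set.seed(17)
  s <- random_toy_stream(200, n_days = 8L)
  led2 <- count_stream(s, orders = 1)
  ref2 <- build_reference(led2, max(s$date) + 1L)
  brute <- led2[n == 1L & date >= max(s$date) - 6L,
                .(ct = sum(count_total)), by = ngram]
  m <- merge(ref2, brute, by = "ngram", all = TRUE)
  expect_equal(m$count_total, m$ct)
})

test_that("ambient series covers every day and smooths over a week", {
  s <- random_toy_stream(300, n_days = 20L, anchor_frac = 1)
  led <- count_stream(s, orders = 1)
  amb <- ambient_series(led, toy_lexicon())
  expect_equal(nrow(amb), as.integer(max(s$date) - min(s$date)) + 1L)
  expect_true(all(amb$h_avg >= 1 & amb$h_avg <= 9, na.rm = TRUE))
  full <- which(!is.na(amb$h_avg))
  expect_equal(amb$h_smoothed[full[length(full)]],
               oracle_roll(amb$h_avg, 7)[full[length(full)]])
})
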