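stream_of <- function(texts, rt = FALSE, date = "2019-06-01") {
  data.table::data.table(id = sprintf("m%03d", seq_along(texts)),
                         date = data.table::as.IDate(date),
                         text = texts, lang = "en",
                         is_retweet = rep_len(rt, length(texts)))
}

test_that("count_stream splits counts into organic and retweeted parts", {
  led <- count_stream(stream_of(c("a b", "a b")), orders = 1)
  expect_equal(led[ngram == "a", .(count_total, count_organic, count_retweet)],
               data.table::data.table(count_total = 2L, count_organic = 2L,
                                      count_retweet = 0L))
  led2 <- count_stream(stream_of(c("a", "a"), rt = c(FALSE, TRUE)), orders = 1)
  expect_equal(led2$count_total, 2L)
  expect_equal(led2$count_organic, 1L)
  expect_equal(led2$count_retweet, 1L)
  # identity count_total = count_organic + count_retweet holds everywhere
  s <- random_toy_stream(200)
  led3 <- count_stream(s)
  expect_true(all(led3$count_total == led3$count_organic + led3$count_retweet))
})

test_that("messages without a date are skipped with a warning", {
  s <- stream_of(c("a b", "c d"))
  s$date[2] <- NA
  expect_warning(led <- count_stream(s, orders = 1), "missing a valid date")
  expect_false("c" %in% led$ngram)
})

test_that("ledgers equal a naive nested-loop recount on random streams", {
  set.seed(101)
  for (rep in 1:8) {
    s <- random_toy_stream(sample(50:250, 1))
    expect_ledger_matches_oracle(count_stream(s), s)
  }
})

test_that("token conservation: ledger totals equal emitted window counts", {
  set.seed(7)
  s <- random_toy_stream(300)
  led <- count_stream(s)
  toks <- tokenize(s$text)
  for (ord in 1:3) {
    emitted <- sum(pmax(lengths(toks) - ord + 1L, 0L))
    expect_equal(sum(led[n == ord]$count_total), emitted)
  }
})

test_that("rank_distribution uses fractional ranks for ties", {
  led <- data.table::data.table(ngram = c("a", "b", "c", "d"),
                                count_total = c(5L, 3L, 3L, 1L))
  rd <- rank_distribution(led)
  expect_equal(rd[match(c("a", "b", "c", "d"), ngram)]$rank, c(1, 2.5, 2.5, 4))
  expect_equal(sum(rd$frequency), 1, tolerance = 1e-12)
  one <- rank_distribution(data.table::data.table(ngram = "x", count_total = 9L))
  expect_equal(one$rank, 1)
  expect_equal(one$frequency, 1)
  expect_error(rank_distribution(led[0]), "empty|nothing")
})

test_that("ranks agree with a sort-based oracle and sum to N(N+1)/2", {
  set.seed(11)
  for (rep in 1:5) {
    cnt <- sample(1:40, 200, replace = TRUE)
    rd <- rank_distribution(data.table::data.table(
      ngram = sprintf("g%03d", 1:200), count_total = cnt))
    expect_equal(rd[match(sprintf("g%03d", 1:200), ngram)]$rank,
                 oracle_rank(cnt))
    n <- nrow(rd)
    expect_equal(sum(rd$rank), n * (n + 1) / 2, tolerance = 1e-9)
    expect_true(all(diff(rd$count) <= 0))  # count descending => rank ascending
  }
})

test_that("anchor_subset keeps exactly contiguous-match messages", {
  s <- stream_of(c("my mental health matters",
                   "mental illness and health",
                   "Mental Health! awareness",
                   "healthy mental attitude"))
  sub <- anchor_subset(s, "mental health")
  expect_equal(sub$id, c("m001", "m003"))
  expect_error(anchor_subset(s, "..."), "empty anchor")
})

test_that("anchored subset and complement partition the stream and ledger", {
  set.seed(21)
  s <- random_toy_stream(150)
  hits <- anchor_matches(s, "mental health")
  expect_equal(hits, oracle_anchor_hits(s, c("mental", "health")))
  led_all <- count_stream(s)
  led_in <- count_stream(s[hits])
  led_out <- count_stream(s[!hits])
  both <- merge(led_in, led_out, by = c("date", "n", "ngram"), all = TRUE)
  for (col in c("count_total.x", "count_total.y")) {
    both[[col]][is.na(both[[col]])] <- 0L
  }
  both$sum <- both$count_total.x + both$count_total.y
  m <- merge(both, led_all, by = c("date", "n", "ngram"), all = TRUE)
  expect_equal(m$sum, m$count_total)
})

test_that("rank_timeseries records absences as missing and reports a median", {
  s <- rbind(stream_of(c("a b c", "a b d"), date = "2019-06-01"),
             stream_of(c("x y", "a b z"), date = "2019-06-02"),
             stream_of(c("x y", "q r"), date = "2019-06-03"))
  led <- count_stream(s, orders = 2)
  ts <- rank_timeseries(led, "a b")
  expect_equal(nrow(ts$series), 3)
  expect_true(is.na(ts$series$rank[3]))
  expect_equal(ts$series$rank[1], 1)
  expect_equal(ts$median, median(ts$series$rank, na.rm = TRUE))
  ts2 <- rank_timeseries(led, "zz qq")
  expect_true(all(is.na(ts2$series$rank)))
  expect_true(is.na(ts2$median))
})

test_that("yearly aggregation pools daily counts per calendar year", {
  s <- rbind(stream_of("a", date = "2018-03-01"),
             stream_of(c("a", "a"), date = "2018-11-07"),
             stream_of("a", date = "2019-01-02"))
  ya <- yearly_aggregate(count_stream(s, orders = 1))
  expect_equal(ya[year == 2018 & ngram == "a"]$count, 3L)
  expect_equal(ya[year == 2019 & ngram == "a"]$count, 1L)
  # pooled recount equals brute force over a month of toy data
  set.seed(31)
  s2 <- random_toy_stream(120, n_days = 30L)
  ya2 <- yearly_aggregate(count_stream(s2, orders = 1))
  toks <- unlist(lapply(s2$text, function(t) strsplit(t, " ", fixed = TRUE)[[1]]))
  brute <- table(toks)
  expect_equal(ya2[match(names(brute), ngram)]$count,
               unname(as.integer(brute)))
})

test_that("corpus summaries count unique and total 1-grams", {
  led <- data.table::data.table(
    date = data.table::as.IDate("2019-06-01"), n = 1L, ngram = c("a", "b"),
    count_total = c(2L, 1L), count_organic = c(1L, 1L),
    count_retweet = c(1L, 0L))
  sm <- summarize_corpus(led, "2019-06-01", "toy")
  expect_equal(sm$unique_1grams, 2L)
  expect_equal(sm$total_1grams, 3L)
  expect_equal(sm$total_1grams_no_retweets, 2L)
  empty <- summarize_corpus(led, "2019-06-02")
  expect_equal(unlist(empty[, .(unique_1grams, total_1grams,
                                total_1grams_no_retweets)]),
               c(unique_1grams = 0L, total_1grams = 0L,
                 total_1grams_no_retweets = 0L))
})
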