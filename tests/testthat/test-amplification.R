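ledger_days <- function(dates, ngram, ot, rt, n = 1L) {
  data.table::data.table(date = data.table::as.IDate(dates), n = n,
                         ngram = ngram, count_total = ot + rt,
                         count_organic = ot, count_retweet = rt)
}

test_that("monthly balance sums counts and flags strict amplification", {
  led <- ledger_days("2020-01-15", "x", 10L, 30L)
  mb <- monthly_balance(led, "x")
  expect_equal(mb$f_rt, 0.75)
  expect_true(mb$amplified)
  mb2 <- monthly_balance(ledger_days("2020-01-15", "x", 20L, 20L), "x")
  expect_equal(mb2$f_rt, 0.5)
  expect_false(mb2$amplified)  # strict inequality at the boundary
  # fractions always sum to one on populated months
  set.seed(91)
  s <- random_toy_stream(400, n_days = 70L)
  led3 <- count_stream(s, orders = 1)
  mb3 <- monthly_balance(led3, "v1")
  pop <- mb3[!is.na(f_rt)]
  expect_true(all(abs(pop$f_ot + pop$f_rt - 1) < 1e-12))
  # brute-force recount of one month
  jun <- s[format(as.Date(date), "%Y-%m") == "2020-06"]
  if (nrow(jun) == 0) jun <- s[1:0]
  brute_rt <- 0L; brute_ot <- 0L
  for (i in seq_len(nrow(s))) {
    toks <- strsplit(s$text[i], " ", fixed = TRUE)[[1]]
    k <- sum(toks == "v1")
    mo <- format(as.Date(s$date[i]), "%Y-%m")
    if (mo == mb3$month[1]) {
      if (s$is_retweet[i]) brute_rt <- brute_rt + k else brute_ot <- brute_ot + k
    }
  }
  expect_equal(mb3$c_ot[1], brute_ot)
  expect_equal(mb3$c_rt[1], brute_rt)
})

test_that("amplification heatmap compares target odds with background odds", {
  dates <- data.table::as.IDate("2020-03-02") + 0:27
  led <- ledger_days(dates, "x", 10L, 30L)
  bg <- data.table::data.table(date = dates, count_total = 200L,
                               count_organic = 100L, count_retweet = 100L)
  hm <- amplification_heatmap(led, "x", bg)
  expect_true(all(hm$defined))
  expect_true(all(abs(hm$R - 3) < 1e-12))
  # a target that is the whole background has R = 1 in every defined cell
  full <- ledger_days(dates, "x", 100L, 100L)
  hm2 <- amplification_heatmap(full, "x", bg)
  expect_true(all(abs(hm2$R - 1) < 1e-12))
  # zero organic target counts are undefined, never infinite
  led0 <- ledger_days(dates, "x", 0L, 5L)
  hm3 <- amplification_heatmap(led0, "x", bg)
  expect_true(all(!hm3$defined))
  expect_true(all(is.na(hm3$R)))
  # misaligned coverage errors with the missing dates
  expect_error(amplification_heatmap(led, "x", bg[1:10]), "does not cover")
})

test_that("planted retweet boost is recovered by the heatmap", {
  cfg <- stream_config(start_date = "2019-01-01", end_date = "2019-12-31",
                       messages_per_day = 200L, vocab_size = 2000L,
                       pi_start = 0.05, pi_end = 0.05,
                       rho_lo = 0.3, rho_hi = 0.3,
                       anchor_retweet_odds_boost = 2,
                       event_list = data.frame(date = character(0),
                                               kind = character(0),
                                               boost = numeric(0),
                                               half_life = numeric(0)),
                       rng_seed = 23L)
  res <- generate_stream(cfg)
  led <- count_stream(res$stream, orders = 2)
  bg <- ledger_totals(led, n = 2)
  hm <- amplification_heatmap(led, "mental health", bg)
  expect_gt(mean(hm$defined), 0.9)
  expect_equal(median(hm$R, na.rm = TRUE), 2, tolerance = 0.1)
})

test_that("rank panel smooths on the log scale with weekly bands", {
  dates <- data.table::as.IDate("2020-01-06") + 0:27
  sp <- smoothed_rank_panel(data.table::data.table(date = dates, rank = 100),
                            window = 7)
  expect_equal(sp$smoothed[7:28], rep(100, 22))
  expect_true(all(sp$week_min == 100 & sp$week_max == 100))
  alt <- smoothed_rank_panel(
    data.table::data.table(date = dates, rank = rep(c(10, 1000), 14)),
    window = 7)
  expect_true(all(alt$week_min == 10 & alt$week_max == 1000))
  set.seed(27)
  rk <- 10^runif(40, 1, 4)
  sp2 <- smoothed_rank_panel(
    data.table::data.table(date = data.table::as.IDate("2020-01-01") + 0:39,
                           rank = rk), window = 9)
  expect_equal(sp2$smoothed, 10^oracle_roll(log10(rk), 9))
  expect_error(smoothed_rank_panel(
    data.table::data.table(date = dates, rank = 1), window = 0), "window")
})

test_that("sustained balance crossings are detected at the right month", {
  mk <- function(frts) {
    data.table::data.table(month = sprintf("2018-%02d", seq_along(frts)),
                           c_ot = 10L, c_rt = 10L, f_ot = 1 - frts,
                           f_rt = frts, amplified = frts > 0.5)
  }
  expect_true(is.na(detect_crossing(mk(rep(0.4, 12)))))
  b <- mk(c(rep(0.4, 9), rep(0.6, 3)))
  expect_equal(detect_crossing(b), "2018-10")
  # a single noisy month does not trigger
  b2 <- mk(c(0.4, 0.6, 0.4, 0.4, 0.6, 0.6, 0.6))
  expect_equal(detect_crossing(b2), "2018-05")
  expect_true(is.na(detect_crossing(mk(c(0.4, 0.6, 0.4)))))
})

test_that("the planted retweet crossing is recovered within a month", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- stream_config(start_date = "2018-01-01", end_date = "2019-06-30",
                         messages_per_day = 150L, vocab_size = 1000L,
                         pi_start = 0.05, pi_end = 0.05,
                         rho_cross_date = "2018-09-15", rho_scale_days = 30,
                         event_list = data.frame(date = character(0),
                                                 kind = character(0),
                                                 boost = numeric(0),
                                                 half_life = numeric(0)),
                         rng_seed = seed)
    res <- generate_stream(cfg)
    sub <- anchor_subset(res$stream, "mental health")
    led <- count_stream(sub, orders = 2)
    det <- detect_crossing(monthly_balance(led, "mental health"))
    truth <- res$truth$anchor_crossing_month
    if (!is.na(det) && !is.na(truth)) {
      dm <- abs(month_index(det) - month_index(truth))
      if (dm <= 1) hits <- hits + 1L
    }
  }
  expect_gte(hits, 18L)
})
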