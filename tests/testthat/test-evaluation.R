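test_that("metric formulas follow their confusion-matrix definitions", {
  # counts from the clinical validation: TP 65, FP 7, FN 0, TN 142
  m <- metrics(confusion_counts(tp = 65, fp = 7, fn = 0, tn = 142))
  expect_equal(metric_pct(m, "sensitivity"), 100.0)
  expect_equal(metric_pct(m, "ppv"), 90.3)          # 65/72
  expect_equal(metric_pct(m, "npv"), 100.0)         # 142/142
  expect_equal(metric_pct(m, "specificity"), 95.3)  # 142/149

  m2 <- metrics(confusion_counts(1, 1, 1, 1))
  expect_true(all(vapply(c("sensitivity", "specificity", "ppv", "npv"),
                         function(k) metric_pct(m2, k) == 50.0, logical(1))))
})

test_that("zero denominators flag single metrics undefined without erroring", {
  m <- metrics(confusion_counts(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_equal(m$sensitivity, 0)
  expect_true(is.na(m$ppv))
  expect_equal(metric_pct(m, "specificity"), 100.0)
  expect_equal(metric_pct(m, "npv"), 50.0)
})

test_that("sensitivity depends only on (tp, fn) and specificity on (tn, fp)", {
  for (extra in c(0, 3, 11)) {
    a <- metrics(confusion_counts(10, 2 + extra, 5, 20))
    b <- metrics(confusion_counts(10, 2, 5, 20 + extra))
    expect_equal(a$sensitivity, b$sensitivity)
    expect_equal(metrics(confusion_counts(10, 2, 5, 20))$specificity,
                 metrics(confusion_counts(10 + extra, 2, 5 + extra, 20))$specificity)
  }
})

test_that("confusion tallies match the verdict table", {
  cc <- tally_confusion(truth = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                        prediction = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 2))
})

test_that("the JT test is exact on the enumerable two-group fixture", {
  r <- jonckheere_terpstra(list(c(1, 2), c(3, 4)), "increasing")
  expect_equal(r$statistic, 4)
  expect_equal(r$p_value, 1 / 6)
  expect_equal(r$method, "exact")
})

test_that("all-tied data give p = 1 by convention", {
  r <- jonckheere_terpstra(list(rep(1, 5), rep(1, 4), rep(1, 4)))
  expect_equal(r$p_value, 1)
})

test_that("reversing the group order swaps increasing and decreasing p-values", {
  g <- list(c(1.2, 0.4, 2.2), c(2.5, 1.9), c(3.3, 2.8, 4.0))
  up <- jonckheere_terpstra(g, "increasing")
  dn <- jonckheere_terpstra(rev(g), "decreasing")
  expect_equal(up$p_value, dn$p_value)
})

test_that("exact and normal-approximation p agree closely at n = 12", {
  set.seed(9)
  g <- list(rnorm(4), rnorm(4, 0.5), rnorm(4, 1))
  ex <- jonckheere_terpstra(g, "increasing", exact_max = 12)
  ap <- jonckheere_terpstra(g, "increasing", exact_max = 0)
  expect_equal(ex$method, "exact")
  expect_equal(ap$method, "normal approximation")
  expect_lt(abs(ex$p_value - ap$p_value), 0.02)
})

test_that("tied small samples use complete enumeration", {
  r <- jonckheere_terpstra(list(c(1, 1, 2), c(2, 3, 3)), "increasing")
  expect_equal(r$method, "exact")
  expect_equal(r$statistic, 8.5)   # ties counted one half
  expect_equal(r$p_value, 0.1)     # 2 of C(6,3)=20 assignments reach 8.5
})

test_that("degenerate inputs are rejected", {
  expect_error(jonckheere_terpstra(list(1:3)), "input error")
  expect_error(jonckheere_terpstra(list(1:3, numeric(0))), "input error")
})

test_that("histogram summaries report totals and half-up rounded rates", {
  counts <- c(304, 206, 107, 88, 52, 20, 11, 7, 5, 6, 4, 3)
  s <- track_count_summary(counts)
  expect_equal(s$total, 813)
  expect_equal(s$table$rate_pct[1], 37.4)
  expect_equal(s$table$cum_rate_pct[2], 62.7)
  expect_equal(sum(s$table$rate_pct), 100, tolerance = 0.5)
})

test_that("corpus track summaries group overlapping wheeze tracks into sounds", {
  rows <- data.frame(start_s = c(1, 1.1, 4), end_s = c(2, 2.1, 5),
                     duration_ms = 1000, n_points = 10,
                     mean_freq_hz = c(400, 800, 500), freq_sd_hz = 1,
                     mean_level_db = -30, mean_margin_db = 10,
                     n_gap_frames = 0)
  lab <- function(l) list(label = l, rule_path = "x")
  pf <- list(list(tracks = fake_tracks(rows),
                  labels = list(lab("wheeze"), lab("wheeze"), lab("wheeze"))))
  s <- summarize_tracks(pf)
  expect_equal(s$n_sounds, 2)               # one polyphonic pair + one lone
  expect_equal(s$histogram, c(1L, 1L))
  expect_equal(s$n_monophonic, 1)
  expect_equal(s$n_polyphonic, 1)
  expect_equal(sum(s$histogram * seq_along(s$histogram)), 3)

  # single monophonic wheeze file
  one <- summarize_tracks(list(list(tracks = fake_tracks(rows[3, ]),
                                    labels = list(lab("wheeze")))))
  expect_equal(one$histogram, 1L)
  expect_equal(one$n_sounds, 1)
})
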