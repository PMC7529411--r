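two_nucleus_table <- function(values, x = 50, group = "reference") {
  do.call(rbind, lapply(seq_along(values), function(k) {
    data.frame(image_id = sprintf("im%d", k), nucleus = 1L, group = group,
               x = x, value = values[k], stringsAsFactors = FALSE)
  }))
}

test_that("group summaries use sample statistics and keep missing bins missing", {
  tbl <- two_nucleus_table(c(0.4, 0.6))
  s <- summarize_group(tbl)
  expect_equal(s$mean[s$x == 50], 0.5)
  expect_equal(s$sd[s$x == 50], sqrt(0.02), tolerance = 1e-12)  # ~0.1414
  expect_equal(s$se[s$x == 50], 0.1, tolerance = 1e-12)
  expect_equal(s$n[s$x == 50], 2L)

  # identical nuclei: zero spread
  s2 <- summarize_group(two_nucleus_table(c(0.5, 0.5, 0.5)))
  expect_equal(s2$sd, 0)
  expect_equal(s2$se, 0)

  # an interval missing in every nucleus: n = 0 and undefined mean, never 0
  tbl3 <- rbind(two_nucleus_table(c(0.4, 0.6), x = 50),
                two_nucleus_table(c(NA, NA), x = 75))
  s3 <- summarize_group(tbl3)
  expect_equal(s3$n[s3$x == 75], 0L)
  expect_true(is.na(s3$mean[s3$x == 75]))

  expect_error(summarize_group(two_nucleus_table(0.4)), "at least 2 nuclei")
})

test_that("Mann-Whitney U handles separation, ties and symmetry", {
  # full separation: U = 0, exact two-sided p = 2/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.1)

  # complete ties: no evidence, U = n1 n2 / 2 and p = 1
  rt <- mann_whitney_u(c(5, 5, 5, 5), c(5, 5, 5, 5))
  expect_equal(rt$U, 8)
  expect_equal(rt$p.value, 1)

  # swapping samples maps U to n1 n2 - U and leaves p unchanged
  set.seed(12)
  for (k in 1:20) {
    a <- runif(sample(2:8, 1)); b <- runif(sample(2:8, 1))
    f <- mann_whitney_u(a, b); g <- mann_whitney_u(b, a)
    expect_equal(f$U + g$U, length(a) * length(b))
    expect_equal(f$p.value, g$p.value, tolerance = 1e-12)
  }

  expect_error(mann_whitney_u(numeric(), 1:3), "nonempty")
})

test_that("Mann-Whitney matches the exhaustive enumeration oracle", {
  set.seed(77)
  for (n1 in 2:4) {
    for (n2 in 2:4) {
      for (rep in 1:8) {
        v <- sample(1:100, n1 + n2)  # tie-free
        a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
        got <- mann_whitney_u(a, b)
        orc <- oracle_mann_whitney(a, b)
        expect_equal(got$U, orc$U)
        expect_equal(got$p.value, orc$p.value, tolerance = 1e-12)
      }
    }
  }
})

test_that("per-interval comparison flags, skips and directions are correct", {
  set.seed(21)
  tbl <- random_profile_table(10)
  # identical cohorts duplicated: every interval completely tied, p = 1
  cmp <- compare_bins(tbl, tbl)
  expect_true(all(!cmp$significant))
  expect_true(all(cmp$p.value[cmp$tested] == 1))

  # significance flag is exactly p < alpha when correction = none
  ref <- random_profile_table(15, prefix = "r")
  test <- random_profile_table(15, prefix = "t")
  cmp2 <- compare_bins(ref, test, alpha = 0.05, correction = "none")
  expect_equal(cmp2$significant[cmp2$tested],
               cmp2$p.value[cmp2$tested] < 0.05)
  expect_equal(cmp2$p.adjusted[cmp2$tested], cmp2$p.value[cmp2$tested])

  # an interval with < 2 values on one side is skipped and flagged
  ref3 <- two_nucleus_table(c(0.4, 0.6), x = 50)
  test3 <- rbind(two_nucleus_table(c(0.3, 0.7), x = 50, group = "test"),
                 data.frame(image_id = "t9", nucleus = 1L, group = "test",
                            x = 55, value = 0.5))
  cmp3 <- compare_bins(ref3, test3)
  expect_false(cmp3$tested[cmp3$x == 55])
  expect_true(is.na(cmp3$p.value[cmp3$x == 55]))
  expect_true(cmp3$tested[cmp3$x == 50])

  # direction reflects the test group relative to the reference
  lo <- two_nucleus_table(c(0.1, 0.2))
  hi <- two_nucleus_table(c(0.8, 0.9), group = "test")
  expect_equal(compare_bins(lo, hi)$direction, "higher")
  expect_equal(compare_bins(hi, lo)$direction, "lower")
})

test_that("the interval-change statistic follows its defining identities", {
  mk <- function(means, group) {
    structure(data.frame(group = group, x = seq(5, 100, 5), n = 10,
                         mean = means, sd = 0.1, se = 0.03),
              class = c("group_summary", "data.frame"))
  }
  L <- seq(70, 100, 5)
  # identical groups: delta = 0
  s <- mk(rep(0.5, 20), "a")
  expect_equal(delta_statistic(s, s, L)$delta_percent, 0)

  # reference at half the test level: delta = 50
  expect_equal(delta_statistic(mk(rep(0.5, 20), "a"), mk(rep(1, 20), "b"),
                               L)$delta_percent, 50)

  # reverse: delta = -100
  expect_equal(delta_statistic(mk(rep(1, 20), "a"), mk(rep(0.5, 20), "b"),
                               L)$delta_percent, -100)

  # invariance to rescaling both groups by a common factor
  set.seed(3)
  m1 <- runif(20, 0.2, 1); m2 <- runif(20, 0.2, 1)
  d1 <- delta_statistic(mk(m1, "a"), mk(m2, "b"), L)$delta_percent
  d2 <- delta_statistic(mk(m1 / 3, "a"), mk(m2 / 3, "b"), L)$delta_percent
  expect_equal(d1, d2, tolerance = 1e-12)

  # sign follows the comparison of interval sums; delta < 100 always
  expect_gt(delta_statistic(mk(rep(0.4, 20), "a"), mk(rep(0.6, 20), "b"),
                            L)$delta_percent, 0)
  expect_lt(d1, 100)

  # errors: zero denominator, undefined bins listed
  s0 <- mk(rep(0, 20), "b"); s0$n <- 10
  expect_error(delta_statistic(mk(rep(0.5, 20), "a"), s0, L), "zero")
  sna <- mk(rep(0.5, 20), "b"); sna$mean[sna$x == 75] <- NA; sna$n[sna$x == 75] <- 0
  expect_error(delta_statistic(mk(rep(0.5, 20), "a"), sna, L), "75")
})

test_that("the default radial thirds partition the twenty intervals by midpoint", {
  thirds <- default_delta_intervals()
  all_bins <- sort(unlist(thirds, use.names = FALSE))
  expect_equal(all_bins, seq(5, 100, 5))
  expect_equal(sum(lengths(thirds)), 20L)
  # midpoint rule at the boundaries: 35 (midpoint 32.5) is inner,
  # 70 (midpoint 67.5) is outer
  expect_true(35 %in% thirds$inner)
  expect_false(40 %in% thirds$inner)
  expect_true(70 %in% thirds$outer)
  expect_true(65 %in% thirds$middle)
})

test_that("a simulated periphery-to-center shift is detected with correct signs", {
  # moderate shift, 50 nuclei per group, count-normalized profiles
  cmp <- simulate_and_compare(
    cohort_spec(n_per_group = 50, shift_fraction = 0.3, seed = 2024),
    config = run_config(ring_statistic = "mean"))
  b <- cmp$bins
  central <- b$x >= 10 & b$x <= 60
  peripheral <- b$x >= 75
  expect_true(any(b$significant[central] & b$direction[central] == "higher"))
  expect_true(any(b$significant[peripheral] & b$direction[peripheral] == "lower"))
  d <- setNames(cmp$deltas$delta_percent, cmp$deltas$interval)
  expect_gt(d[["inner"]], 0)
  expect_lt(d[["outer"]], 0)
})
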