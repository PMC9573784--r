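test_that("IQR filter removes exactly the hand-computed outlier", {
  # [1,2,3,4,100]: Q1 = 2, Q3 = 4 (type-7 quartiles), fences [-1, 7]
  fl <- iqr_filter(c(1, 2, 3, 4, 100))
  expect_equal(fl$removed, 100)
  expect_equal(fl$kept, c(1, 2, 3, 4))
  expect_equal(fl$bounds$lower, -1)
  expect_equal(fl$bounds$upper, 7)

  expect_length(iqr_filter(c(5, 5, 5, 5))$removed, 0)  # IQR = 0, all equal
  expect_equal(iqr_filter(c(1, 2, 1000))$kept, c(1, 2, 1000))  # n < 4 passes

  # grouped: each group filtered with its own fences
  v <- c(1, 2, 3, 4, 100, 10, 11, 12, 13, 14)
  g <- rep(c("a", "b"), each = 5)
  fl2 <- iqr_filter(v, g)
  expect_equal(fl2$removed, 100)
})

test_that("IQR filtering is idempotent away from the fences", {
  set.seed(8)
  for (i in 1:5) {
    # clean bulk with no mass near its own fences, plus far contaminants
    v <- c(runif(40, 10, 20), rep(100, 3))
    first <- iqr_filter(v)
    expect_equal(first$removed, rep(100, 3))
    second <- iqr_filter(first$kept)
    expect_length(second$removed, 0)
  }
})

test_that("Loess with local quadratics reproduces polynomials exactly", {
  t <- seq(0, 18, by = 0.75)
  lin <- loess_smooth(t, 2 * t + 1, span = 0.9)
  interior <- lin$grid > 1 & lin$grid < 17
  expect_lt(max(abs(lin$mean - (2 * lin$grid + 1))[interior]), 1e-6)

  quad <- loess_smooth(t, 0.3 * t^2 - t + 2, span = 0.9)
  expect_lt(max(abs(quad$mean -
                      (0.3 * quad$grid^2 - quad$grid + 2))[interior]), 1e-6)
  expect_true(all(quad$ci_low <= quad$mean + 1e-12))
  expect_true(all(quad$ci_high >= quad$mean - 1e-12))

  expect_error(loess_smooth(c(0, 1, 2, 3), 1:4), "5 distinct")
  expect_error(loess_smooth(t, 2 * t, span = 1.5), "span")
})

test_that("smoothing recovers the stigma peak from noisy draws", {
  p <- trajectory_params(noise_cv = 0.1, outlier_rate = 0,
                         carpels_per_timepoint = 5,
                         timepoints = c(0, 3, 5, 7, 9, 11, 13, 15, 18))
  hits <- 0
  for (r in 1:20) {
    ts <- generate_trajectory_set(p, seed = 100 + r)
    rec <- ts$records
    sc <- loess_smooth(rec$timepoint_days, rec$stigma_area_mm2, span = 0.9)
    t_hat <- sc$grid[which.max(sc$mean)]
    if (abs(t_hat - p$t_peak) <= 3) hits <- hits + 1   # one sampling interval
  }
  expect_gte(hits, 18)
})

test_that("degree days sum clamped daily means inclusively and additively", {
  s <- structure(data.frame(date = as.Date("2021-06-01") + 0:2,
                            daily_mean = c(10, 12, 8)),
                 class = c("temperature_series", "data.frame"))
  expect_equal(cumulative_degree_days(s, 1, 3), 30)

  s2 <- structure(data.frame(date = as.Date("2021-06-01") + 0:1,
                             daily_mean = c(-2, 5)),
                  class = c("temperature_series", "data.frame"))
  expect_equal(cumulative_degree_days(s2, 1, 2), 5)

  tser <- generate_temperature_series(30, seed = 2)
  for (k in c(5, 12, 20)) {
    expect_equal(cumulative_degree_days(tser, 1, k) +
                   cumulative_degree_days(tser, k + 1, 30),
                 cumulative_degree_days(tser, 1, 30))
  }
  expect_gte(cumulative_degree_days(tser, 3, 3), 0)
  expect_error(cumulative_degree_days(tser, 0, 5), "invalid window")
  expect_error(cumulative_degree_days(tser, 10, 5), "invalid window")
  expect_error(cumulative_degree_days(tser, 1, 31), "invalid window")
})

test_that("a triangular curve yields the exact textbook phase boundaries", {
  crv <- triangle_curve(t_peak = 10, t_end = 14)
  rep <- classify_phases(crv, last_sampling = 14, cultivar = "tri")
  expect_equal(rep$growth_end, 8.5)
  expect_equal(rep$peak_onset, 10)
  expect_equal(rep$peak_end, 11.5)
  expect_equal(rep$deterioration_marker_40pct, 14)
  expect_length(rep$censored, 0)
  expect_equal(unname(rep$durations_days),
               c(8.5, 3, 2.5))
})

test_that("curves that never decline are censored; constant curves degenerate cleanly", {
  g <- seq(0, 12, by = 0.1)
  up <- structure(list(grid = g, mean = g^1.5, ci_low = g^1.5,
                       ci_high = g^1.5, span = NA), class = "smoothed_curve")
  rep <- classify_phases(up, last_sampling = 12)
  expect_setequal(rep$censored, c("peak_end", "deterioration_marker_40pct"))
  expect_true(is.na(rep$peak_end))
  expect_true(is.na(rep$durations_days["peak"]))

  flat <- structure(list(grid = g, mean = rep(3, length(g)), ci_low = rep(3, length(g)),
                         ci_high = rep(3, length(g)), span = NA),
                    class = "smoothed_curve")
  repf <- classify_phases(flat, last_sampling = 12)
  expect_equal(repf$growth_end, 0)
  expect_equal(repf$peak_onset, 0)
  expect_setequal(repf$censored, c("peak_end", "deterioration_marker_40pct"))
})

test_that("classifier boundaries match analytic crossings of generator curves", {
  for (decl in c(0.08, 0.15)) {
    p <- trajectory_params(t_peak = 7, decline_rate = decl,
                           timepoints = c(0, 3, 7, 13, 18, 24))
    tr <- generate_trajectory_set(p, seed = 1)$truth
    crv <- structure(list(grid = tr$grid, mean = tr$stigma,
                          ci_low = tr$stigma, ci_high = tr$stigma, span = NA),
                     class = "smoothed_curve")
    rep <- classify_phases(crv, last_sampling = 24)
    # independent oracle: root-find on the closed-form mean
    seg <- asNamespace("carpelseg")
    f <- seg$stigma_mean_fn(p)
    S_max <- max(tr$stigma)
    ge <- uniroot(function(t) f(t) - 0.85 * S_max, c(0, 7))$root
    pe <- uniroot(function(t) f(t) - 0.85 * S_max, c(7, 24))$root
    dm <- uniroot(function(t) f(t) - 0.60 * S_max, c(7, 24))$root
    expect_equal(rep$growth_end, ge, tolerance = 0.1)
    expect_equal(rep$peak_end, pe, tolerance = 0.1)
    expect_equal(rep$deterioration_marker_40pct, dm, tolerance = 0.1)
    # ordering invariant
    expect_true(rep$growth_end <= rep$peak_onset &&
                  rep$peak_onset <= rep$peak_end &&
                  rep$peak_end <= rep$deterioration_marker_40pct &&
                  rep$deterioration_marker_40pct <= rep$last_sampling)
  }
})

test_that("degree-day durations accompany day durations and stay non-negative", {
  crv <- triangle_curve()
  tser <- generate_temperature_series(20, seed = 6)
  rep <- classify_phases(crv, temperature = tser, last_sampling = 14)
  expect_equal(names(rep$durations_degree_days),
               c("growth", "peak", "deterioration"))
  expect_true(all(rep$durations_degree_days >= 0))
  # thermal-time additivity across the three phases
  clock <- asNamespace("carpelseg")$degree_day_clock(tser)
  expect_equal(sum(rep$durations_degree_days), clock(14))
})

test_that("cultivars rank from slow to fast with censoring treated as slowest", {
  mk <- function(cv, pe, dm) structure(
    list(cultivar = cv, growth_end = 2, peak_onset = 5, peak_end = pe,
         deterioration_marker_40pct = dm, last_sampling = 20,
         durations_days = c(growth = 2, peak = pe - 2, deterioration = 20 - pe),
         durations_degree_days = NULL,
         censored = character(0)[c()]),
    class = "phase_report")
  r <- rank_cultivars(list(mk("A", 14, 16), mk("B", 10, 12), mk("C", 8, 9)))
  expect_equal(r$cultivar, c("A", "B", "C"))
  expect_equal(r$speed_class, c("slow", "moderate", "fast"))

  cens <- mk("B", NA, NA); cens$censored <- c("peak_end")
  r2 <- rank_cultivars(list(mk("A", 14, 16), cens))
  expect_equal(r2$cultivar, c("B", "A"))
  expect_error(rank_cultivars(list(mk("A", 14, 16))), "at least 2")
})
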