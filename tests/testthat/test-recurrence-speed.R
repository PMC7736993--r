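test_that("recurrence matrix equals the double-loop correlation oracle", {
  st <- random_stream(n_regions = 4, n_frames = 6, seed = 3)
  d <- compute_dfc_matrix(st)
  expect_equal(unclass(d), oracle_dfc_matrix(st$frames),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(d), rep(1, 6), ignore_attr = TRUE)
  expect_lt(max(abs(d - t(d))), 1e-14)
  expect_true(all(d >= -1 - 1e-12 & d <= 1 + 1e-12))
})

test_that("recurrence extremes: identical frames give 1, anti-linear frames give -1", {
  st <- random_stream(n_regions = 3, n_frames = 2, seed = 1)
  st$frames <- cbind(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1))
  d <- compute_dfc_matrix(st)
  expect_equal(d[1, 2], 1.0)
  expect_equal(d[1, 3], -1.0)

  st$frames[, 2] <- 0.5  # constant frame
  expect_error(compute_dfc_matrix(st), "frame 2 is constant")
})

test_that("speeds are 1 - offset-diagonal entries of the recurrence matrix", {
  st <- random_stream(n_regions = 4, n_frames = 6, seed = 9)
  d <- compute_dfc_matrix(st)
  sp1 <- compute_speeds(d, frame_offset = 1)
  expect_length(sp1$speeds, 5)
  expect_equal(sp1$speeds, 1 - d[cbind(1:5, 2:6)])
  sp2 <- compute_speeds(d, frame_offset = 2)
  expect_length(sp2$speeds, 4)
  expect_equal(sp2$speeds, 1 - c(d[1, 3], d[2, 4], d[3, 5], d[4, 6]))
  expect_error(compute_speeds(d, frame_offset = 6), "frame_offset")
  expect_error(compute_speeds(d, frame_offset = 0), "frame_offset")
  # speeds bounded by the correlation range
  expect_true(all(sp1$speeds >= 0 & sp1$speeds <= 2))
})

test_that("speeds hit their extremes for identical and anti-linear consecutive frames", {
  st <- random_stream(n_regions = 3, n_frames = 2)
  st$frames <- cbind(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1))
  sp <- compute_speeds(compute_dfc_matrix(st))
  expect_equal(sp$speeds, c(0, 2))
})

test_that("speeds stay in [0, 2] across random streams and offsets", {
  for (seed in 1:10) {
    st <- random_stream(n_regions = 3 + seed %% 3, n_frames = 8, seed = seed)
    d <- compute_dfc_matrix(st)
    for (df in c(1, 3, 7)) {
      sp <- compute_speeds(d, frame_offset = df)
      expect_true(all(sp$speeds >= 0 & sp$speeds <= 2))
    }
  }
})

test_that("oversampled speed estimates are flagged non-independent", {
  ts <- gen_stationary_gaussian(80, diag(4), seed = 4)
  smooth <- compute_dfc_stream(ts, window = 10, step = 1)
  sp <- compute_speeds(compute_dfc_matrix(smooth), frame_offset = 10)
  expect_true(sp$oversampled)
  nonov <- compute_dfc_stream(ts, window = 10, step = 10)
  expect_false(compute_speeds(compute_dfc_matrix(nonov))$oversampled)
})

test_that("typical speed: median default, histogram mode within a bin of the peak", {
  sp <- dfcstream:::new_speed_sample(c(0.2, 0.4, 0.6), 10L, 1L)
  expect_equal(typical_speed(sp), 0.4)
  degenerate <- dfcstream:::new_speed_sample(rep(0.7, 25), 10L, 1L)
  expect_equal(typical_speed(degenerate), 0.7)
  expect_lt(abs(typical_speed(degenerate, "histogram_mode") - 0.7), 0.1 / 2 + 1e-12)

  # unimodal sample: mode estimate within one bin width of the true mode
  draws <- withr::with_seed(5, pmin(pmax(rnorm(1000, 0.8, 0.15), 0), 2))
  big <- dfcstream:::new_speed_sample(draws, 10L, 1L)
  expect_lt(abs(typical_speed(big, "histogram_mode") - 0.8), 0.1 + 1e-12)
  expect_error(typical_speed(dfcstream:::new_speed_sample(numeric(0), 10L, 1L)),
               "empty")
})

test_that("pooling concatenates speed lists and records provenance", {
  a <- dfcstream:::new_speed_sample(c(0.1, 0.2, 0.3), 10L, 1L)
  b <- dfcstream:::new_speed_sample(c(0.5, 0.6, 0.7, 0.8, 0.9), 14L, 1L)
  expect_equal(pool_speeds(list(a))$speeds, a$speeds)
  p <- pool_speeds(a, b)
  expect_length(p$speeds, 8)
  expect_equal(sort(p$speeds), sort(c(a$speeds, b$speeds)))
  expect_equal(p$pooled_from, c(10L, 14L))
  # pooled typical speed is the median of the independently sorted union
  merged <- sort(c(a$speeds, b$speeds))
  expect_equal(typical_speed(p), (merged[4] + merged[5]) / 2)
  expect_error(pool_speeds(list()), "at least one")
})

test_that("histogram probabilities and Agresti-Coull intervals match the closed form", {
  sp <- dfcstream:::new_speed_sample(c(rep(0.05, 50), rep(1.95, 50)), 10L, 1L)
  h <- build_speed_histogram(sp, bins = 20)
  expect_equal(sum(h$bin_probabilities), 1, tolerance = 1e-12)
  expect_equal(h$counts[c(1, 20)], c(50L, 50L))

  # x = n/2 centers at exactly 1/2; half-width matches the direct evaluation
  ac <- oracle_agresti_coull(50, 100)
  expect_equal((h$ci_low[1] + h$ci_high[1]) / 2, 0.5, tolerance = 1e-12)
  expect_equal(h$ci_low[1], ac["low"], ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(h$ci_high[1], ac["high"], ignore_attr = TRUE, tolerance = 1e-12)
  # empty bins: lower bound clipped at 0, upper bound positive
  expect_equal(h$ci_low[5], 0)
  expect_gt(h$ci_high[5], 0)
  expect_true(all(h$ci_low <= h$bin_probabilities + 1e-12))
  expect_true(all(h$ci_high >= h$bin_probabilities - 1e-12))

  outlier <- dfcstream:::new_speed_sample(c(0.5, 2.5), 10L, 1L)
  expect_warning(h2 <- build_speed_histogram(outlier), "overflow")
  expect_equal(h2$overflow[["high"]], 1L)
})
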