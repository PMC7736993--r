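test_that("static FC matches the textbook Pearson formula and its limits", {
  x <- sin(seq_len(40))
  ts <- cbind(x, x, -x + 3)
  fc <- compute_static_fc(ts)
  expect_equal(fc[1, 2], 1.0)
  expect_equal(fc[1, 3], -1.0)
  expect_equal(diag(fc), rep(1, 3), ignore_attr = TRUE)

  # 3-region, 6-sample integer matrix against the closed-form oracle
  toy <- matrix(c(1, 3, 2, 5, 4, 6,
                  2, 2, 4, 3, 6, 5,
                  6, 4, 5, 2, 3, 1), ncol = 3)
  expect_equal(compute_static_fc(toy), oracle_cor_matrix(toy),
               tolerance = 1e-12, ignore_attr = TRUE)

  # vector format is the canonical lower-triangle enumeration
  v <- compute_static_fc(toy, format = "vector")
  expect_equal(v, c(fc12 = oracle_pearson(toy[, 1], toy[, 2]),
                    fc13 = oracle_pearson(toy[, 1], toy[, 3]),
                    fc23 = oracle_pearson(toy[, 2], toy[, 3])),
               ignore_attr = TRUE)
})

test_that("zero-variance regions are rejected with the offending index", {
  ts <- cbind(rnorm(20), rep(2, 20), rnorm(20))
  expect_error(compute_static_fc(ts), "region\\(s\\) 2")
  expect_error(as_timeseries(matrix(c(1, 2, NA, 4), 2)), "non-finite")
  expect_error(as_timeseries(matrix(1:3, 3, 1)), "at least 2")
})

test_that("frame count follows floor((T - W)/step) + 1 over a grid", {
  ts <- gen_stationary_gaussian(100, diag(3), seed = 1)
  expect_identical(n_frames(compute_dfc_stream(ts[1:10, ], window = 5, step = 5)), 2L)
  expect_identical(n_frames(compute_dfc_stream(ts, window = 5, step = 1)), 96L)
  for (w in c(2, 5, 17, 50)) {
    for (st in c(1, 3, 7, w)) {
      f <- n_frames(compute_dfc_stream(ts, window = w, step = st))
      expect_identical(f, as.integer((100 - w) %/% st + 1))
    }
  }
})

test_that("each stream frame equals static FC on that window's slice", {
  ts <- gen_stationary_gaussian(60, diag(4), seed = 7)
  st <- compute_dfc_stream(ts, window = 12, step = 5)
  for (k in seq_len(n_frames(st))) {
    sl <- ts[st$frame_starts[k]:(st$frame_starts[k] + st$window - 1), ]
    expect_equal(st$frames[, k], compute_static_fc(sl, format = "vector"),
                 tolerance = 1e-12)
  }
  # frames are valid correlation vectors
  expect_true(all(st$frames >= -1 & st$frames <= 1))
  # static FC is the single-frame stream with W = T
  whole <- compute_dfc_stream(ts, window = 60, step = 60)
  expect_identical(n_frames(whole), 1L)
  expect_equal(whole$frames[, 1], compute_static_fc(ts, format = "vector"))
})

test_that("stream construction rejects invalid windows and constant windows", {
  ts <- gen_stationary_gaussian(30, diag(3), seed = 2)
  expect_error(compute_dfc_stream(ts, window = 31), "exceeds")
  expect_error(compute_dfc_stream(ts, window = 1), ">= 2")
  ts2 <- ts
  ts2[11:20, 2] <- 5
  expect_error(compute_dfc_stream(ts2, window = 10, step = 10),
               "region 2 is constant within frame 2")
})

test_that("vector/matrix conversions are lossless round trips", {
  m3 <- vector_to_matrix(c(0.1, -0.2, 0.3))
  expect_equal(m3[1, 2], 0.1)
  expect_equal(m3[1, 3], -0.2)
  expect_equal(m3[2, 3], 0.3)
  expect_equal(matrix_to_vector(m3), c(0.1, -0.2, 0.3))
  expect_identical(length(matrix_to_vector(diag(100))), 4950L)

  set.seed(31)
  for (rep in 1:5) {
    a <- matrix(runif(25, -1, 1), 5)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_identical(vector_to_matrix(matrix_to_vector(a)), a)
  }

  # stream tensor round trip
  st <- random_stream(n_regions = 4, n_frames = 3)
  tens <- vector_to_matrix(st$frames)
  expect_identical(dim(tens), c(4L, 4L, 3L))
  expect_identical(matrix_to_vector(tens), st$frames)

  asym <- matrix(c(1, 0.5, 0.2, 1), 2)
  expect_error(matrix_to_vector(asym), "asymmetric")
  expect_error(vector_to_matrix(numeric(4)), "not of the form")
})

test_that("time-series round-trip through delimited text preserves data and labels", {
  ts <- gen_stationary_gaussian(25, diag(3), seed = 5)
  colnames(ts) <- c("ROI1", "ROI2", "ROI3")
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(ts, f)
  back <- read_timeseries(f)
  expect_equal(back, ts, tolerance = 1e-12)
  expect_identical(colnames(back), colnames(ts))

  # stream round trip with sidecar
  st <- compute_dfc_stream(ts, window = 10, step = 5)
  g <- withr::local_tempfile(fileext = ".csv")
  write_stream(st, g)
  st2 <- read_stream(g)
  expect_equal(st2$frames, st$frames, tolerance = 1e-12)
  expect_identical(st2$window, st$window)
  expect_identical(st2$frame_starts, st$frame_starts)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "4,x,6"), bad)
  expect_error(read_timeseries(bad), "malformed")
})
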