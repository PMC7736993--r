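#' dFC recurrence matrix
#'
#' Similarity between FC frames observed at different times: entry (a, b) is
#' the Pearson correlation between the vectorized triangular parts of frames
#' a and b of the stream. Square red-ish blocks of high similarity between
#' consecutive frames are "dFC knots" (transient FC stabilization); stripes
#' of low similarity are "dFC leaps" (fast reconfiguration). The result
#' depends on the window and step used to build the stream.
#'
#' @param stream a `dfc_stream`, see [compute_dfc_stream()].
#' @return F x F symmetric numeric matrix with unit diagonal; the stream's
#'   `window` and `step` are attached as attributes.
#' @export
compute_dfc_matrix <- function(stream) {
  stopifnot(inherits(stream, "dfc_stream"))
  frames <- stream$frames
  if (ncol(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  const <- which(apply(frames, 2L, function(x) max(x) == min(x)))
  if (length(const)) {
    stop(sprintf("frame %d is constant across links; inter-frame correlation undefined",
                 const[1L]), call. = FALSE)
  }
  d <- stats::cor(frames)
  diag(d) <- 1
  attr(d, "window") <- stream$window
  attr(d, "step") <- stream$step
  d
}

#' Instantaneous dFC speeds from a recurrence matrix
#'
#' The speed of FC reconfiguration between frame a and frame a + Delta-f:
#' `speed[a] = 1 - dfc[a, a + frame_offset]`. With a non-overlapping stream
#' (`step = window`) and `frame_offset = 1` this is the single-window global
#' dFC speed. With a smooth stream (`step = 1`) and `frame_offset = window`
#' each frame is compared to the first non-overlapping frame, yielding the
#' window-oversampled estimate; oversampled speeds are not statistically
#' independent samples and are flagged as such.
#'
#' @param dfc recurrence matrix from [compute_dfc_matrix()].
#' @param frame_offset integer Delta-f, `1 <= frame_offset < F`.
#' @return an object of class `speed_sample`: list with `speeds` (numeric,
#'   each in \[0, 2\]), `window_size`, `frame_offset`, `pooled_from` and
#'   `oversampled` flag.
#' @export
compute_speeds <- function(dfc, frame_offset = 1L) {
  stopifnot(is.matrix(dfc), nrow(dfc) == ncol(dfc))
  nf <- nrow(dfc)
  frame_offset <- as.integer(frame_offset)
  if (length(frame_offset) != 1L || is.na(frame_offset) ||
      frame_offset < 1L || frame_offset >= nf) {
    stop(sprintf("'frame_offset' must lie in 1..%d (F - 1)", nf - 1L), call. = FALSE)
  }
  a <- seq_len(nf - frame_offset)
  speeds <- 1 - dfc[cbind(a, a + frame_offset)]
  w <- attr(dfc, "window")
  step <- attr(dfc, "step")
  new_speed_sample(speeds,
                   window_size = if (is.null(w)) NA_integer_ else w,
                   frame_offset = frame_offset,
                   oversampled = !is.null(step) && !is.null(w) && step < w)
}

new_speed_sample <- function(speeds, window_size, frame_offset,
                             pooled_from = window_size, oversampled = FALSE) {
  structure(list(speeds = as.numeric(speeds), window_size = window_size,
                 frame_offset = frame_offset, pooled_from = pooled_from,
                 oversampled = oversampled),
            class = "speed_sample")
}

#' @export
print.speed_sample <- function(x, ...) {
  cat(sprintf("dFC speed sample: %d speed(s), W = %s, frame offset = %d%s\n",
              length(x$speeds), paste(x$pooled_from, collapse = "+"),
              x$frame_offset, if (isTRUE(x$oversampled)) " [oversampled]" else ""))
  invisible(x)
}

#' Typical dFC speed of a speed sample
#'
#' Summary location of the speed distribution: either the median of the
#' speeds (default; binning-free, the convention used for pooled samples) or
#' the center of the highest-probability bin of a speed histogram
#' (`"histogram_mode"`, the distribution's mode up to bin width).
#'
#' @param sample a `speed_sample` (see [compute_speeds()], [pool_speeds()]).
#' @param method `"median"` or `"histogram_mode"`.
#' @param bins,range histogram settings for the mode method, as in
#'   [build_speed_histogram()].
#' @return a single numeric value.
#' @export
typical_speed <- function(sample, method = c("median", "histogram_mode"),
                          bins = 20L, range = c(0, 2)) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "speed_sample"))
  if (length(sample$speeds) == 0L) stop("empty speed sample", call. = FALSE)
  if (method == "median") return(stats::median(sample$speeds))
  h <- build_speed_histogram(sample, bins = bins, range = range)
  centers <- (h$bin_edges[-1L] + h$bin_edges[-length(h$bin_edges)]) / 2
  centers[which.max(h$bin_probabilities)]
}

#' Pool speed samples across window sizes
#'
#' Window pooling: concatenates speed observations evaluated at several
#' window sizes into one unified sample (no reweighting), recording the
#' contributing window sizes. The median of the pooled sample is the pooled
#' typical speed. Pooling is a pragmatic smoothing device and should be
#' cross-checked against single-window analyses.
#'
#' @param samples a list of `speed_sample` objects (or several passed as
#'   `...`).
#' @param ... additional `speed_sample` objects.
#' @return a pooled `speed_sample`.
#' @export
pool_speeds <- function(samples, ...) {
  if (inherits(samples, "speed_sample")) samples <- list(samples)
  samples <- c(samples, list(...))
  if (length(samples) == 0L) stop("need at least one speed sample", call. = FALSE)
  ok <- vapply(samples, inherits, logical(1L), what = "speed_sample")
  if (!all(ok)) stop("all inputs must be 'speed_sample' objects", call. = FALSE)
  new_speed_sample(unlist(lapply(samples, `[[`, "speeds")),
                   window_size = NA_integer_,
                   frame_offset = samples[[1L]]$frame_offset,
                   pooled_from = unlist(lapply(samples, `[[`, "pooled_from")),
                   oversampled = any(vapply(samples, `[[`, logical(1L), "oversampled")))
}

#' Speed histogram with Agresti-Coull binomial confidence intervals
#'
#' Histogram of a dFC speed distribution over equal-width bins, with
#' bin-by-bin confidence intervals from the Agresti-Coull approximation to
#' the binomial proportion: with `z` the standard-normal quantile at
#' `(1 + level)/2`, `n~ = n + z^2`, `p~ = (x + z^2/2)/n~`, half-width
#' `z * sqrt(p~ (1 - p~) / n~)`, clipped to \[0, 1\]. The reported bin
#' probability is the raw proportion `x/n`. Speeds outside `range` are
#' counted in flagged overflow bins with a warning.
#'
#' @inheritParams typical_speed
#' @param bins number of equal-width bins.
#' @param range numeric length-2, histogram support; dFC speeds always lie
#'   in \[0, 2\].
#' @param confidence_level confidence level of the bin intervals.
#' @return an object of class `speed_histogram`: list with `bin_edges`,
#'   `counts`, `bin_probabilities`, `ci_low`, `ci_high`, `confidence_level`,
#'   `n_observations` and `overflow` (counts below/above the range).
#' @export
build_speed_histogram <- function(sample, bins = 20L, range = c(0, 2),
                                  confidence_level = 0.95) {
  stopifnot(inherits(sample, "speed_sample"))
  speeds <- sample$speeds
  n <- length(speeds)
  if (n < 1L) stop("empty speed sample", call. = FALSE)
  bins <- as.integer(bins)
  stopifnot(bins >= 1L, length(range) == 2L, range[2L] > range[1L],
            confidence_level > 0, confidence_level < 1)
  edges <- seq(range[1L], range[2L], length.out = bins + 1L)
  below <- sum(speeds < range[1L])
  above <- sum(speeds > range[2L])
  if (below + above > 0L) {
    warning(sprintf("%d speed(s) outside [%g, %g] counted in overflow bins",
                    below + above, range[1L], range[2L]))
  }
  inside <- speeds >= range[1L] & speeds <= range[2L]
  bi <- pmin.int(findInterval(speeds[inside], edges), bins)
  counts <- tabulate(bi, nbins = bins)
  z <- stats::qnorm((1 + confidence_level) / 2)
  nt <- n + z^2
  pt <- (counts + z^2 / 2) / nt
  hw <- z * sqrt(pt * (1 - pt) / nt)
  structure(list(bin_edges = edges,
                 counts = counts,
                 bin_probabilities = counts / n,
                 ci_low = pmax(pt - hw, 0),
                 ci_high = pmin(pt + hw, 1),
                 confidence_level = confidence_level,
                 n_observations = n,
                 overflow = c(low = below, high = above)),
            class = "speed_histogram")
}

#' @export
print.speed_histogram <- function(x, ...) {
  cat(sprintf("dFC speed histogram: %d bins over [%g, %g], n = %d (%.0f%% CIs)\n",
              length(x$counts), x$bin_edges[1L], x$bin_edges[length(x$bin_edges)],
              x$n_observations, 100 * x$confidence_level))
  invisible(x)
}
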