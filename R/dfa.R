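#' Instantaneous dFC increments of a smooth stream
#'
#' The increment series feeding detrended fluctuation analysis:
#' `v[a] = 1 - Corr(frame_a, frame_{a+1})`, i.e. the offset-1 speeds of a
#' maximally smooth stream whose slide step equals the minimum time-shift
#' `delta_t` (one sample by default). Increments are only defined on such a
#' smooth stream; any other step raises an error. The increments inherit the
#' stream's window size W: the scaling analysis remains W-specific because
#' coarse-graining acts on the temporal network, not on raw time.
#'
#' @param stream a `dfc_stream` built with `step = delta_t`.
#' @param delta_t minimum slide step in samples (default 1).
#' @return an object of class `increment_series`: list with `values`
#'   (length F - 1, each in \[0, 2\]), `window_size` and `delta_t`.
#' @export
dfc_increments <- function(stream, delta_t = 1L) {
  stopifnot(inherits(stream, "dfc_stream"))
  delta_t <- as.integer(delta_t)
  if (stream$step != delta_t) {
    stop(sprintf("increments require a smooth stream with step = delta_t (= %d); this stream has step = %d",
                 delta_t, stream$step), call. = FALSE)
  }
  frames <- stream$frames
  nf <- ncol(frames)
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  const <- which(apply(frames, 2L, function(x) max(x) == min(x)))
  if (length(const)) {
    stop(sprintf("frame %d is constant across links; inter-frame correlation undefined",
                 const[1L]), call. = FALSE)
  }
  z <- scale(frames)  # center + sample-sd scale each frame column
  v <- 1 - colSums(z[, -nf, drop = FALSE] * z[, -1L, drop = FALSE]) / (nrow(frames) - 1L)
  new_increment_series(v, window_size = stream$window, delta_t = delta_t)
}

new_increment_series <- function(values, window_size = NA_integer_, delta_t = 1L) {
  structure(list(values = as.numeric(values), window_size = window_size,
                 delta_t = as.integer(delta_t)),
            class = "increment_series")
}

#' @export
print.increment_series <- function(x, ...) {
  cat(sprintf("dFC increment series: %d increment(s), W = %s, delta_t = %d\n",
              length(x$values), format(x$window_size), x$delta_t))
  invisible(x)
}

increment_values <- function(x) {
  if (inherits(x, "increment_series")) x$values else as.numeric(x)
}

#' Integrated (profile) series of dFC increments
#'
#' Converts the bounded increment series into an unbounded random-walk
#' profile by cumulative summation after removing the increments' mean.
#' Centering is the standard DFA convention: without it the positive mean of
#' dFC speeds injects a deterministic ramp that distorts the scaling
#' exponent.
#'
#' @param inc an `increment_series` or a plain numeric vector of increments.
#' @return numeric vector `D(t_i) = sum_{l<=i} (v_l - mean(v))`.
#' @export
integrate_profile <- function(inc) {
  v <- increment_values(inc)
  if (length(v) == 0L) stop("empty increment series", call. = FALSE)
  cumsum(v - mean(v))
}

#' Detrended fluctuation strength at one scale
#'
#' Splits the profile into `M = floor(K / k)` non-overlapping segments of
#' length `k` (trailing remainder samples dropped), removes the per-segment
#' least-squares linear trend, and returns
#' `F(k) = sqrt(mean over segments of the mean squared residual)`.
#'
#' @param profile integrated profile from [integrate_profile()].
#' @param k segment length (scale), `4 <= k` and `floor(K/k) >= 4`.
#' @return the scalar fluctuation strength F(k).
#' @export
dfa_fluctuation <- function(profile, k) {
  profile <- as.numeric(profile)
  K <- length(profile)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 4L || K %/% k < 4L) {
    stop(sprintf("scale k = %s out of admissible range (4 <= k <= K/4, K = %d)",
                 format(k), K), call. = FALSE)
  }
  m <- K %/% k
  y <- matrix(profile[seq_len(m * k)], nrow = k)  # one column per segment
  x <- cbind(1, seq_len(k))
  res <- qr.resid(qr(x), y)
  sqrt(mean(colMeans(res^2)))
}

default_dfa_scales <- function(K, n_scales = 12L, k_min = 8L) {
  k_max <- K %/% 4L
  if (k_max < k_min) stop("series too short for DFA (need K >= 32)", call. = FALSE)
  ks <- unique(as.integer(round(exp(seq(log(k_min), log(k_max), length.out = n_scales)))))
  ks[ks >= 4L & (K %/% ks) >= 4L]
}

#' DFA self-similarity exponent of a dFC increment series
#'
#' Ordinary least squares of `log F(k)` on `log k` over a grid of scales
#' (default: 12 logarithmically spaced integer scales from 8 to K/4,
#' deduplicated), where F(k) is the linearly detrended fluctuation strength
#' of the integrated increment profile. The slope `alpha` is the primary
#' outcome: `alpha < 0.5` anti-persistent, `= 0.5` memoryless (uncorrelated
#' Gaussian fluctuations), `> 0.5` persistent, `>= 1` non-stationary
#' (strictly, DFA is undefined there). The value is only interpretable as a
#' scaling exponent when the log-log relation is genuinely linear; results
#' with fit R-squared below `r2_threshold` are flagged `is_scaling = FALSE`
#' and must not be read as exponents.
#'
#' @param inc an `increment_series` (see [dfc_increments()]) or plain
#'   numeric vector of increments.
#' @param scales integer vector of segment lengths; `NULL` for the default
#'   log-spaced grid. Scales with zero fluctuation are excluded with a
#'   warning; fewer than 3 usable scales is an error.
#' @param r2_threshold minimum R-squared for the linear-scaling flag.
#' @return an object of class `dfa_result`: list with `scales`,
#'   `fluctuations`, `alpha`, `intercept`, `fit_r2`, `is_scaling` and a
#'   descriptive `label`.
#' @examples
#' inc <- gen_fgn_increments(0.5, 2048, seed = 1)
#' dfa_exponent(inc)$alpha
#' @export
dfa_exponent <- function(inc, scales = NULL, r2_threshold = 0.95) {
  v <- increment_values(inc)
  K <- length(v)
  if (is.null(scales)) scales <- default_dfa_scales(K)
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 3L) stop("need at least 3 scales", call. = FALSE)
  profile <- integrate_profile(v)
  fl <- vapply(scales, function(k) dfa_fluctuation(profile, k), numeric(1L))
  zero <- fl == 0
  if (any(zero)) {
    warning(sprintf("excluding %d scale(s) with zero fluctuation", sum(zero)))
    scales <- scales[!zero]
    fl <- fl[!zero]
  }
  if (length(scales) < 3L) {
    stop("fewer than 3 usable scales after excluding zero fluctuations", call. = FALSE)
  }
  fit <- stats::lm(log(fl) ~ log(scales))
  alpha <- unname(stats::coef(fit)[2L])
  label <- if (alpha >= 1) "non-stationary"
           else if (alpha > 0.5) "persistent"
           else if (alpha < 0.5) "anti-persistent"
           else "memoryless"
  r2 <- summary(fit)$r.squared
  structure(list(scales = scales, fluctuations = fl, alpha = alpha,
                 intercept = unname(stats::coef(fit)[1L]), fit_r2 = r2,
                 is_scaling = r2 >= r2_threshold, label = label),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA: alpha = %.3f (%s), intercept = %.3f, R^2 = %.4f%s, %d scales %d..%d\n",
              x$alpha, x$label, x$intercept, x$fit_r2,
              if (x$is_scaling) "" else " [no linear scaling - do not interpret]",
              length(x$scales), min(x$scales), max(x$scales)))
  invisible(x)
}
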