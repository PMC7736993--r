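#' Validate a multivariate activity time-series matrix
#'
#' The universal input of the package: a numeric matrix with rows = time
#' samples and columns = regions/nodes (fMRI BOLD, LFP, EEG channels, or any
#' real-valued signals). Requires at least 2 samples and 2 regions and all
#' entries finite. Data frames are coerced; column names, when present, are
#' kept as region labels.
#'
#' @param ts matrix-like, T samples x N regions.
#' @return the validated numeric matrix.
#' @export
as_timeseries <- function(ts) {
  if (is.data.frame(ts)) ts <- as.matrix(ts)
  if (!is.matrix(ts) || !is.numeric(ts)) {
    stop("time-series input must be a numeric matrix (rows = time, columns = regions)",
         call. = FALSE)
  }
  if (nrow(ts) < 2L || ncol(ts) < 2L) {
    stop("time-series must have at least 2 samples (rows) and 2 regions (columns)",
         call. = FALSE)
  }
  if (!all(is.finite(ts))) {
    stop("time-series contains non-finite entries", call. = FALSE)
  }
  ts
}

# regions whose values do not vary over the given rows (exact check)
constant_regions <- function(ts) {
  which(apply(ts, 2L, function(x) max(x) == min(x)))
}

#' Static (time-averaged) functional connectivity
#'
#' Pairwise Pearson correlation between all region time-series over the full
#' session. All entries are retained: no thresholding or significance
#' masking, since FC entries are treated as features. Output either as a
#' symmetric N x N matrix with unit diagonal, or in compact vector format of
#' length L = N(N-1)/2 under the canonical link order (see [n_links()]).
#'
#' @param ts time-series matrix, see [as_timeseries()].
#' @param format `"matrix"` (default) or `"vector"`.
#' @return symmetric N x N correlation matrix, or a length-L numeric vector.
#' @examples
#' ts <- cbind(a = sin(1:50), b = cos(1:50), c = sin(1:50 + 1))
#' compute_static_fc(ts)
#' compute_static_fc(ts, format = "vector")
#' @export
compute_static_fc <- function(ts, format = c("matrix", "vector")) {
  format <- match.arg(format)
  ts <- as_timeseries(ts)
  const <- constant_regions(ts)
  if (length(const)) {
    stop(sprintf("region(s) %s have zero variance; correlation is undefined for constant signals",
                 paste(const, collapse = ", ")), call. = FALSE)
  }
  fc <- stats::cor(ts)
  diag(fc) <- 1
  if (format == "vector") matrix_to_vector(fc) else fc
}

#' Sliding-window dFC stream
#'
#' Computes the temporal network of windowed FC frames: frame k is the
#' Pearson correlation matrix of the sample slice `[t_k, t_k + W)` with
#' `t_k = (k-1) * step + 1` (1-based, half-open in sample units). Trailing
#' windows that would be trimmed by the end of the series are dropped, so
#' the stream holds exactly `F = floor((T - W) / step) + 1` frames. Frames
#' are stored in compact vector format as an L x F matrix (row m = the FC
#' time-course of link m).
#'
#' @inheritParams compute_static_fc
#' @param window window size W in samples, `2 <= W <= T`.
#' @param step slide step (Delta-tau) in samples, default `window`
#'   (non-overlapping frames). Use `step = 1` for maximally smooth streams
#'   as needed by DFA and meta-connectivity analyses.
#' @return an object of class `dfc_stream`: list with elements `frames`
#'   (L x F matrix), `n_regions`, `window`, `step`, `frame_starts` (first
#'   sample of each window, 1-based), `links` (original link ordinals of the
#'   rows) and `region_labels`.
#' @examples
#' ts <- gen_stationary_gaussian(100, diag(4), seed = 1)
#' st <- compute_dfc_stream(ts, window = 10, step = 10)
#' st
#' @export
compute_dfc_stream <- function(ts, window, step = window) {
  ts <- as_timeseries(ts)
  n_t <- nrow(ts)
  n <- ncol(ts)
  window <- as.integer(window)
  step <- as.integer(step)
  if (length(window) != 1L || is.na(window) || window < 2L) {
    stop("'window' must be a single integer >= 2", call. = FALSE)
  }
  if (window > n_t) {
    stop(sprintf("'window' (%d) exceeds the number of samples (%d)", window, n_t),
         call. = FALSE)
  }
  if (length(step) != 1L || is.na(step) || step < 1L) {
    stop("'step' must be a single integer >= 1", call. = FALSE)
  }
  n_frames <- (n_t - window) %/% step + 1L
  L <- n_links(n)
  frames <- matrix(NA_real_, L, n_frames)
  starts <- (seq_len(n_frames) - 1L) * step + 1L
  for (k in seq_len(n_frames)) {
    sl <- ts[starts[k]:(starts[k] + window - 1L), , drop = FALSE]
    const <- constant_regions(sl)
    if (length(const)) {
      stop(sprintf("region %d is constant within frame %d (samples %d..%d); windowed correlation undefined",
                   const[1L], k, starts[k], starts[k] + window - 1L), call. = FALSE)
    }
    fc <- stats::cor(sl)
    frames[, k] <- fc[lower.tri(fc)]
  }
  new_dfc_stream(frames, n_regions = n, window = window, step = step,
                 frame_starts = starts, links = seq_len(L),
                 region_labels = colnames(ts))
}

new_dfc_stream <- function(frames, n_regions, window, step, frame_starts,
                           links, region_labels = NULL) {
  structure(list(frames = frames, n_regions = n_regions, window = window,
                 step = step, frame_starts = frame_starts, links = links,
                 region_labels = region_labels),
            class = "dfc_stream")
}

#' @export
print.dfc_stream <- function(x, ...) {
  cat(sprintf("dFC stream: %d frame(s) of %d link(s) (%d regions), W = %d, step = %d%s\n",
              ncol(x$frames), nrow(x$frames), x$n_regions, x$window, x$step,
              if (length(x$links) < n_links(x$n_regions)) " [restricted]" else ""))
  invisible(x)
}

#' Number of frames of a dFC stream
#' @param stream a `dfc_stream`.
#' @return integer number of frames F.
#' @export
n_frames <- function(stream) {
  stopifnot(inherits(stream, "dfc_stream"))
  ncol(stream$frames)
}

#' Convert FC matrices / dFC streams between matrix and vector formats
#'
#' `matrix_to_vector()` maps a symmetric N x N FC matrix to the length-L
#' vector of its L = N(N-1)/2 independent entries under the canonical link
#' order, and an N x N x F tensor to an L x F matrix (one column per frame).
#' `vector_to_matrix()` inverts both, restoring the unit diagonal. The round
#' trip is lossless.
#'
#' @param x symmetric numeric matrix (unit diagonal not required for the
#'   conversion itself) or an N x N x F array of such matrices.
#' @param tol maximum tolerated asymmetry `max(abs(x - t(x)))`.
#' @return `matrix_to_vector()`: numeric vector of length L, or L x F matrix.
#' @export
matrix_to_vector <- function(x, tol = 1e-10) {
  if (is.array(x) && length(dim(x)) == 3L) {
    nf <- dim(x)[3L]
    return(vapply(seq_len(nf), function(k) matrix_to_vector(x[, , k], tol = tol),
                  numeric(n_links(dim(x)[1L]))))
  }
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop("input must be a square matrix or an N x N x F array", call. = FALSE)
  }
  asym <- max(abs(x - t(x)))
  if (asym > tol) {
    stop(sprintf("matrix is asymmetric (max |x - t(x)| = %.3g > %.3g)", asym, tol),
         call. = FALSE)
  }
  x[lower.tri(x)]
}

#' @rdname matrix_to_vector
#' @param v numeric vector of length L = N(N-1)/2, or an L x F matrix.
#' @param diag_value value placed on the diagonal of the reconstructed
#'   matrices (1 for correlation-type matrices).
#' @return `vector_to_matrix()`: symmetric N x N matrix, or N x N x F array.
#' @export
vector_to_matrix <- function(v, diag_value = 1) {
  if (is.matrix(v)) {
    n <- infer_n_regions(nrow(v))
    out <- array(NA_real_, c(n, n, ncol(v)))
    for (k in seq_len(ncol(v))) out[, , k] <- vector_to_matrix(v[, k], diag_value)
    return(out)
  }
  n <- infer_n_regions(length(v))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

infer_n_regions <- function(L) {
  n <- (1 + sqrt(1 + 8 * L)) / 2
  if (L < 1 || n != round(n)) {
    stop(sprintf("length %d is not of the form N(N-1)/2 for an integer N", L),
         call. = FALSE)
  }
  as.integer(n)
}
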