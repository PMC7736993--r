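#' Phase-randomized surrogate time-series (FC stationarity null)
#'
#' Fourier-based surrogate preserving both each region's power spectrum and
#' the full static covariance matrix, while destroying any systematic
#' non-stationarity. Each region's series is de-meaned and transformed; one
#' random phase is drawn per positive frequency bin, uniform on
#' \[0, 2pi), and the *same* rotation is applied to all regions at that
#' bin (an independent rotation per region would destroy the cross-spectra
#' and with them the covariance). Conjugate symmetry is enforced so the
#' inverse transform is real; the DC bin is left unrotated and, for even
#' length, the Nyquist bin is multiplied by a common random sign. Means are
#' re-added afterwards.
#'
#' @inheritParams compute_static_fc
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param .angles,.nyquist_sign test hooks overriding the random draws
#'   (angles are recycled over the positive-frequency bins; forcing all
#'   angles to 0 and the sign to 1 returns the input unchanged).
#' @return surrogate time-series matrix of the same dimension; attribute
#'   `max_imag` records the largest imaginary residue discarded after the
#'   inverse transform.
#' @export
phase_randomize <- function(ts, seed = NULL, .angles = NULL, .nyquist_sign = NULL) {
  ts <- as_timeseries(ts)
  n_t <- nrow(ts)
  nf <- (n_t - 1L) %/% 2L          # positive frequencies below Nyquist
  even <- n_t %% 2L == 0L
  draw <- function() list(ang = stats::runif(nf, 0, 2 * pi),
                          s = if (even) sample(c(-1, 1), 1L) else 1)
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (!is.null(.angles)) d$ang <- rep_len(as.numeric(.angles), nf)
  if (!is.null(.nyquist_sign)) d$s <- .nyquist_sign
  mu <- colMeans(ts)
  X <- stats::mvfft(sweep(ts, 2L, mu))
  if (nf > 0L) {
    rot <- exp(1i * d$ang)
    X[2L:(nf + 1L), ] <- X[2L:(nf + 1L), , drop = FALSE] * rot
    X[seq(n_t, n_t - nf + 1L), ] <- X[seq(n_t, n_t - nf + 1L), , drop = FALSE] * Conj(rot)
  }
  if (even) X[n_t / 2L + 1L, ] <- X[n_t / 2L + 1L, ] * d$s
  y <- stats::mvfft(X, inverse = TRUE) / n_t
  out <- sweep(Re(y), 2L, mu, `+`)
  dimnames(out) <- dimnames(ts)
  attr(out, "max_imag") <- max(abs(Im(y)))
  out
}

#' Time-shuffled surrogate dFC stream (no-sequential-correlation null)
#'
#' Randomly permutes the order of the FC frames while keeping each frame
#' individually unchanged. The per-link mean and variance across frames are
#' preserved exactly (the frame multiset is unchanged); all sequential
#' correlations in the stream are destroyed.
#'
#' @param stream a `dfc_stream` with at least 2 frames.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param .permutation test hook: an explicit permutation of `1..F` used
#'   instead of a random draw (the identity returns the stream unchanged).
#' @return a `dfc_stream` with permuted frames; the applied permutation is
#'   stored in the `permutation` element.
#' @export
time_shuffle_stream <- function(stream, seed = NULL, .permutation = NULL) {
  stopifnot(inherits(stream, "dfc_stream"))
  nf <- ncol(stream$frames)
  if (nf < 2L) stop("need at least 2 frames to shuffle", call. = FALSE)
  perm <- if (!is.null(.permutation)) {
    p <- as.integer(.permutation)
    if (!identical(sort(p), seq_len(nf))) stop("'.permutation' is not a permutation of 1..F",
                                               call. = FALSE)
    p
  } else if (is.null(seed)) {
    sample.int(nf)
  } else {
    withr::with_seed(seed, sample.int(nf))
  }
  out <- new_dfc_stream(stream$frames[, perm, drop = FALSE],
                        n_regions = stream$n_regions, window = stream$window,
                        step = stream$step, frame_starts = stream$frame_starts,
                        links = stream$links, region_labels = stream$region_labels)
  out$permutation <- perm
  out
}

#' Surrogate chance band for a dFC feature
#'
#' Generates an ensemble of surrogates under the requested null, evaluates
#' a feature on each, and returns per-component percentile bounds (default
#' 5th and 95th) as the chance band against which the empirical feature
#' value is compared. For `kind = "phase_randomized"` the source is a
#' time-series matrix and the feature function receives a surrogate
#' time-series (typically re-running the stream/speed pipeline inside); for
#' `kind = "time_shuffled"` the source is a `dfc_stream` and the feature
#' function receives a shuffled stream. Instances on which the feature
#' function fails are skipped with a warning; 10% or more failures abort.
#'
#' @param feature_fn function mapping a surrogate (time-series or stream)
#'   to a numeric scalar or vector of fixed length.
#' @param source the empirical time-series matrix or `dfc_stream`.
#' @param kind `"phase_randomized"` or `"time_shuffled"`.
#' @param n_instances ensemble size (1000 recommended for final inference;
#'   reduce for quick exploration).
#' @param seed integer seed; the ensemble is fully reproducible given it.
#' @param percentiles two percentiles in (0, 100).
#' @return list with `lower` and `upper` (numeric, one per feature
#'   component), `percentiles`, `kind`, `n_effective` (instances that
#'   succeeded) and `values` (the n_effective x p matrix of feature values).
#' @export
surrogate_chance_band <- function(feature_fn, source,
                                  kind = c("phase_randomized", "time_shuffled"),
                                  n_instances = 1000L, seed = 1L,
                                  percentiles = c(5, 95)) {
  kind <- match.arg(kind)
  stopifnot(is.function(feature_fn), n_instances >= 1L,
            length(percentiles) == 2L, all(percentiles > 0), all(percentiles < 100))
  if (kind == "time_shuffled" && !inherits(source, "dfc_stream")) {
    stop("'time_shuffled' surrogates require a 'dfc_stream' source", call. = FALSE)
  }
  if (kind == "phase_randomized") source <- as_timeseries(source)
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_instances))
  vals <- vector("list", n_instances)
  failed <- 0L
  for (b in seq_len(n_instances)) {
    surr <- if (kind == "phase_randomized") {
      phase_randomize(source, seed = sub_seeds[b])
    } else {
      time_shuffle_stream(source, seed = sub_seeds[b])
    }
    v <- tryCatch(as.numeric(feature_fn(surr)), error = function(e) e)
    if (inherits(v, "error")) {
      warning(sprintf("feature failed on surrogate %d: %s", b, conditionMessage(v)))
      failed <- failed + 1L
    } else {
      vals[[b]] <- v
    }
  }
  if (failed >= 0.1 * n_instances) {
    stop(sprintf("feature failed on %d of %d surrogates (>= 10%%)", failed, n_instances),
         call. = FALSE)
  }
  mat <- do.call(rbind, vals[!vapply(vals, is.null, logical(1L))])
  qs <- apply(mat, 2L, stats::quantile, probs = sort(percentiles) / 100, names = FALSE)
  qs <- matrix(qs, nrow = 2L)
  list(lower = qs[1L, ], upper = qs[2L, ], percentiles = sort(percentiles),
       kind = kind, n_effective = nrow(mat), values = mat)
}
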