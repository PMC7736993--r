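#' @name fixtures
#' @title Seedable synthetic generators
#' @description Generators producing multivariate series with the
#'   statistical structure the analysis modules assume, so every downstream
#'   test is a parameter-recovery test against known ground truth: a
#'   stationary Gaussian null, covariance-switching series (dFC
#'   "knots"/"leaps"), planted covarying link groups (dFC modules), and
#'   fractional Gaussian noise for DFA calibration. All generators are
#'   deterministic under a fixed seed.
NULL

# symmetric PSD square root; eigenvalues in [-tol, 0) are floored to 0,
# anything lower is an error
psd_factor <- function(sigma, tol = 1e-8) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma) ||
      max(abs(sigma - t(sigma))) > 1e-10) {
    stop("covariance must be a symmetric square matrix", call. = FALSE)
  }
  e <- eigen(sigma, symmetric = TRUE)
  lo <- min(e$values)
  if (lo < -tol * max(abs(e$values), 1)) {
    stop(sprintf("covariance is not positive semi-definite (min eigenvalue %.3g)", lo),
         call. = FALSE)
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(sigma))
}

maybe_seeded <- function(seed, expr) {
  f <- function() expr
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

#' Stationary multivariate Gaussian series
#'
#' i.i.d.-in-time draws from a zero-mean multivariate Gaussian with the
#' given covariance: the null model of FC stationarity (no dFC structure
#' beyond sampling fluctuations of the windowed estimator).
#'
#' @param n_samples number of time samples T.
#' @param covariance symmetric positive semi-definite N x N matrix.
#' @param seed optional integer seed.
#' @return T x N numeric matrix.
#' @export
gen_stationary_gaussian <- function(n_samples, covariance, seed = NULL) {
  stopifnot(n_samples >= 2)
  fac <- psd_factor(covariance)
  n <- nrow(covariance)
  maybe_seeded(seed, {
    matrix(stats::rnorm(n_samples * n), n_samples, n) %*% t(fac)
  })
}

#' Covariance-switching Gaussian series with ground-truth regimes
#'
#' Piecewise-stationary Gaussian series alternating cyclically between two
#' or more covariance regimes with fixed dwell times. Windows falling
#' inside one regime produce mutually similar FC frames ("dFC knots");
#' regime changes produce sharp dissimilarity transients ("dFC leaps"), so
#' the recurrence matrix shows a block contrast recoverable against the
#' returned labels.
#'
#' @param n_samples number of time samples T.
#' @param covariances list of >= 1 symmetric PSD N x N matrices (a single
#'   regime reduces to [gen_stationary_gaussian()]).
#' @param dwell samples spent in a regime before switching (>= 2); scalar
#'   or one value per regime, recycled cyclically.
#' @param seed optional integer seed.
#' @return list with `ts` (T x N matrix) and `regimes` (integer label per
#'   sample).
#' @export
gen_switching_covariance <- function(n_samples, covariances, dwell, seed = NULL) {
  stopifnot(n_samples >= 2, is.list(covariances), length(covariances) >= 1L)
  n_reg <- length(covariances)
  dwell <- as.integer(rep_len(dwell, n_reg))
  if (any(dwell < 2L)) stop("'dwell' must be >= 2 samples", call. = FALSE)
  facs <- lapply(covariances, psd_factor)
  n <- nrow(covariances[[1L]])
  if (!all(vapply(covariances, nrow, 1L) == n)) {
    stop("all regime covariances must have the same dimension", call. = FALSE)
  }
  labels <- integer(0)
  r <- 1L
  while (length(labels) < n_samples) {
    labels <- c(labels, rep.int(r, dwell[r]))
    r <- r %% n_reg + 1L
  }
  labels <- labels[seq_len(n_samples)]
  ts <- maybe_seeded(seed, {
    z <- matrix(stats::rnorm(n_samples * n), n_samples, n)
    out <- matrix(NA_real_, n_samples, n)
    for (g in seq_len(n_reg)) {
      rows <- labels == g
      out[rows, ] <- z[rows, , drop = FALSE] %*% t(facs[[g]])
    }
    out
  })
  list(ts = ts, regimes = labels)
}

# moving-average smoother with reflecting ends (span = window length)
smooth_ma <- function(x, span) {
  span <- max(1L, as.integer(span))
  if (span == 1L) return(x)
  pad <- c(rev(x[seq_len(span)]), x, rev(x[seq(length(x) - span + 1L, length(x))]))
  f <- stats::filter(pad, rep(1 / span, span), sides = 2L)
  as.numeric(f[span + seq_along(x)])
}

#' Gaussian series with planted covarying link groups (dFC modules)
#'
#' Generates a time-varying covariance
#' `Sigma(t) = Sigma0 + sum_m a_m(t) B_m`, where each template `B_m` places
#' unit off-diagonal weight on all links internal to one disjoint region
#' set and `a_m(t)` are slow, independent modulation signals
#' (moving-average-smoothed white noise, rescaled to `amplitude` and
#' clipped to `clip`). Links inside a region set therefore co-fluctuate in
#' time — a planted dFC module — while links across sets carry no planted
#' structure. Defaults keep every `Sigma(t)` positive semi-definite without
#' repair (for region sets of size `s`, PSD holds whenever
#' `|a_m(t)| <= 1/(s-1)`); if repair is ever needed and it changes any
#' covariance entry by more than 10% of its magnitude, the fixture is
#' declared invalid with an error. The default amplitude drives the
#' modulation to that PSD ceiling for the default 4-region modules, the
#' calibration at which the planted structure is reliably recoverable
#' (within- vs between-group MC contrast, module detection, and
#' reproducibility of MC across generator seeds).
#'
#' @param n_samples number of time samples T.
#' @param module_regions list of disjoint integer vectors of region
#'   indices, one per planted module.
#' @param n_regions total number of regions N (>= max region index).
#' @param amplitude standard deviation of the modulation signals.
#' @param clip hard bound on |a_m(t)|; default just inside the PSD limit of
#'   the largest module.
#' @param smooth_span moving-average span (samples) of the modulation.
#' @param base_covariance Sigma0, default identity.
#' @param seed optional integer seed.
#' @return list with `ts` (T x N matrix), `link_modules` (length-L integer
#'   vector: module id of each canonical link, `NA` for background links),
#'   `module_regions` and `modulation` (T x n_modules matrix of a_m(t)).
#' @export
gen_planted_mc_modules <- function(n_samples = 4000L,
                                   module_regions = list(1:4, 5:8),
                                   n_regions = max(unlist(module_regions)),
                                   amplitude = 0.32,
                                   clip = NULL,
                                   smooth_span = 100L,
                                   base_covariance = diag(n_regions),
                                   seed = NULL) {
  stopifnot(n_samples >= 2, length(module_regions) >= 1L)
  all_regions <- unlist(module_regions)
  if (anyDuplicated(all_regions)) stop("module region sets must be disjoint", call. = FALSE)
  n <- check_n_regions(n_regions)
  if (max(all_regions) > n || min(all_regions) < 1L) {
    stop("module regions out of range", call. = FALSE)
  }
  sizes <- lengths(module_regions)
  if (any(sizes < 2L)) stop("each module needs at least 2 regions", call. = FALSE)
  if (is.null(clip)) clip <- 1 / (max(sizes) - 1) - 0.01
  n_mod <- length(module_regions)
  templates <- lapply(module_regions, function(rs) {
    b <- matrix(0, n, n)
    b[rs, rs] <- 1
    diag(b) <- 0
    b
  })
  res <- maybe_seeded(seed, {
    a <- vapply(seq_len(n_mod), function(m) {
      s <- smooth_ma(stats::rnorm(n_samples), smooth_span)
      s <- s / stats::sd(s) * amplitude
      pmin(pmax(s, -clip), clip)
    }, numeric(n_samples))
    z <- matrix(stats::rnorm(n_samples * n), n_samples, n)
    ts <- matrix(NA_real_, n_samples, n)
    for (t in seq_len(n_samples)) {
      sigma <- base_covariance
      for (m in seq_len(n_mod)) sigma <- sigma + a[t, m] * templates[[m]]
      u <- tryCatch(chol(sigma), error = function(e) NULL)
      if (is.null(u)) {
        e <- eigen(sigma, symmetric = TRUE)
        repaired <- e$vectors %*% diag(pmax(e$values, 0), n) %*% t(e$vectors)
        rel <- abs(repaired - sigma) / pmax(abs(sigma), 1e-12)
        if (max(rel[abs(sigma) > 1e-12]) > 0.1) {
          stop(sprintf("PSD repair at sample %d changes a covariance entry by > 10%%; fixture invalid",
                       t), call. = FALSE)
        }
        u <- chol(repaired + 1e-10 * diag(n))
      }
      ts[t, ] <- z[t, ] %*% u
    }
    list(ts = ts, a = a)
  })
  pairs <- link_pairs(n)
  link_modules <- rep(NA_integer_, nrow(pairs))
  for (m in seq_len(n_mod)) {
    inside <- pairs[, "i"] %in% module_regions[[m]] & pairs[, "j"] %in% module_regions[[m]]
    link_modules[inside] <- m
  }
  list(ts = res$ts, link_modules = link_modules,
       module_regions = module_regions, modulation = res$a)
}

#' Fractional Gaussian noise by circulant (Davies-Harte) embedding
#'
#' Exact spectral synthesis of stationary fractional Gaussian noise with
#' Hurst exponent H: the target autocovariance
#' `g(h) = (|h+1|^(2H) - 2|h|^(2H) + |h-1|^(2H)) / 2` is embedded in a
#' circulant of size 2K whose eigenvalues must be nonnegative (an error
#' suggests a larger K otherwise), and the series is drawn in the Fourier
#' domain. Serves as the calibration input for the DFA module: the scaling
#' exponent of fGn increments equals H (H = 0.5 is white noise).
#'
#' @param hurst Hurst exponent H in (0, 1).
#' @param n_samples series length K.
#' @param seed optional integer seed.
#' @return an `increment_series`-compatible numeric vector of length K with
#'   unit marginal variance.
#' @export
gen_fgn_increments <- function(hurst, n_samples, seed = NULL) {
  stopifnot(length(hurst) == 1L, hurst > 0, hurst < 1, n_samples >= 2)
  K <- as.integer(n_samples)
  h <- 0:K
  g <- (abs(h + 1)^(2 * hurst) - 2 * abs(h)^(2 * hurst) + abs(h - 1)^(2 * hurst)) / 2
  row <- c(g, g[K:2])                       # circulant first row, length 2K
  lam <- Re(stats::fft(row))
  if (min(lam) < -1e-8 * max(lam)) {
    stop("circulant embedding has negative eigenvalues; try a larger n_samples",
         call. = FALSE)
  }
  lam <- pmax(lam, 0)
  m <- 2L * K
  x <- maybe_seeded(seed, {
    z1 <- stats::rnorm(K + 1L)
    z2 <- stats::rnorm(K - 1L)
    w <- complex(length.out = m)
    w[1L] <- sqrt(lam[1L]) * z1[1L]
    w[K + 1L] <- sqrt(lam[K + 1L]) * z1[K + 1L]
    j <- 2:K
    w[j] <- sqrt(lam[j] / 2) * (z1[j] + 1i * z2[j - 1L])
    w[m - j + 2L] <- Conj(w[j])
    Re(stats::fft(w))[seq_len(K)] / sqrt(m)
  })
  x
}
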