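# Independent brute-force oracles, written from the defining formulas and
# kept free of the package's internal code paths.

# textbook Pearson correlation of two vectors
oracle_pearson <- function(x, y) {
  n <- length(x)
  xc <- x - sum(x) / n
  yc <- y - sum(y) / n
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# full correlation matrix via the scalar oracle
oracle_cor_matrix <- function(m) {
  p <- ncol(m)
  out <- diag(1, p)
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      out[a, b] <- out[b, a] <- oracle_pearson(m[, a], m[, b])
    }
  }
  out
}

# recurrence matrix by double loop over frame pairs
oracle_dfc_matrix <- function(frames) {
  nf <- ncol(frames)
  out <- diag(1, nf)
  for (a in seq_len(nf - 1)) {
    for (b in (a + 1):nf) {
      out[a, b] <- out[b, a] <- oracle_pearson(frames[, a], frames[, b])
    }
  }
  out
}

# compact meta-connectivity by double loop over link-row pairs
oracle_mc <- function(frames) {
  L <- nrow(frames)
  out <- diag(1, L)
  for (a in seq_len(L - 1)) {
    for (b in (a + 1):L) {
      out[a, b] <- out[b, a] <- oracle_pearson(frames[a, ], frames[b, ])
    }
  }
  out
}

# trimer meta-strengths by exhaustive triple loop over (i, k, l), k < l
oracle_trimer <- function(compact, n) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    for (a in seq_len(length(others) - 1)) {
      for (b in (a + 1):length(others)) {
        m1 <- index_of_link(i, others[a], n)
        m2 <- index_of_link(i, others[b], n)
        out[i] <- out[i] + compact[m1, m2]
      }
    }
  }
  out
}

# per-segment polyfit-and-residual DFA fluctuation
oracle_dfa_fluctuation <- function(profile, k) {
  m <- length(profile) %/% k
  f2 <- numeric(m)
  for (q in seq_len(m)) {
    seg <- profile[((q - 1) * k + 1):(q * k)]
    t <- seq_len(k)
    fit <- lm(seg ~ t)
    f2[q] <- mean(residuals(fit)^2)
  }
  sqrt(mean(f2))
}

# Agresti-Coull interval evaluated directly from its closed form
oracle_agresti_coull <- function(x, n, level = 0.95) {
  z <- qnorm((1 + level) / 2)
  nt <- n + z^2
  pt <- (x + z^2 / 2) / nt
  hw <- z * sqrt(pt * (1 - pt) / nt)
  c(low = max(0, pt - hw), high = min(1, pt + hw))
}

# small random stream fixture built directly from Gaussian data
random_stream <- function(n_regions = 4, n_frames = 6, window = 8, seed = 1) {
  ts <- gen_stationary_gaussian(window * n_frames, diag(n_regions), seed = seed)
  compute_dfc_stream(ts, window = window, step = window)
}
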