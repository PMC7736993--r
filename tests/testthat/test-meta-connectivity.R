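test_that("compact MC equals the brute-force row-correlation oracle", {
  st <- random_stream(n_regions = 4, n_frames = 30, window = 5, seed = 13)
  mc <- compute_mc(st)
  expect_equal(mc$compact, oracle_mc(st$frames), tolerance = 1e-12)
  expect_lt(max(abs(mc$compact - t(mc$compact))), 1e-14)
  expect_equal(diag(mc$compact), rep(1, n_links(4)))
  expect_true(all(abs(mc$compact) <= 1 + 1e-12))
  # definitional identity: MC is the correlation matrix of stream rows
  expect_equal(mc$compact, cor(t(st$frames)), tolerance = 1e-12)
})

test_that("identical link rows give an all-ones MC; constant links zero out with a warning", {
  st <- random_stream(n_regions = 3, n_frames = 5)
  st$frames <- matrix(rep(c(0.1, 0.4, -0.3, 0.2, 0.5), each = 3), nrow = 3)
  mc <- compute_mc(st)
  expect_equal(mc$compact, matrix(1, 3, 3))

  st$frames[2, ] <- 0.7
  expect_warning(mc2 <- compute_mc(st), "link\\(s\\) 2")
  expect_equal(mc2$compact[2, c(1, 3)], c(0, 0))
  expect_equal(mc2$compact[2, 2], 1)
})

test_that("MC is equivariant under region relabeling", {
  ts <- gen_stationary_gaussian(200, diag(5) + 0.2, seed = 17)
  st <- compute_dfc_stream(ts, window = 10, step = 5)
  mc <- compute_mc(st)
  perm <- c(3, 5, 1, 4, 2)
  stp <- compute_dfc_stream(ts[, perm], window = 10, step = 5)
  mcp <- compute_mc(stp)
  # induced permutation of link ordinals
  pairs <- link_pairs(5)
  inv <- order(perm)  # region r of permuted data was original perm[r]
  lp <- index_of_link(inv[pairs[, "i"]], inv[pairs[, "j"]], 5)
  expect_equal(mcp$compact, mc$compact[lp, lp], tolerance = 1e-12)
})

test_that("expansion places every unique value in its eight degenerate positions", {
  n <- 5
  st <- random_stream(n_regions = n, n_frames = 12, window = 6, seed = 19)
  mc <- compute_mc(st)
  expanded <- expand_mc(mc)
  M <- n_links_directed(n)
  expect_identical(dim(expanded), c(M, M))

  set.seed(23)
  for (rep in 1:20) {
    p <- sample(n, 4)  # i,j,k,l distinct
    i <- p[1]; j <- p[2]; k <- p[3]; l <- p[4]
    val <- mc$compact[index_of_link(i, j, n), index_of_link(k, l, n)]
    rows <- c(directed_index_of_link(i, j, n), directed_index_of_link(j, i, n))
    cols <- c(directed_index_of_link(k, l, n), directed_index_of_link(l, k, n))
    eight <- c(expanded[as.matrix(expand.grid(rows, cols))],
               expanded[as.matrix(expand.grid(cols, rows))])
    expect_equal(eight, rep(val, 8), tolerance = 1e-15)
  }
  # symmetric as a matrix
  expect_lt(max(abs(expanded - t(expanded))), 1e-14)
})

test_that("expansion is memory-guarded", {
  st <- random_stream(n_regions = 3, n_frames = 6)
  mc <- compute_mc(st)
  expect_identical(dim(expand_mc(mc)), c(6L, 6L))
  expect_error(expand_mc(mc, max_bytes = 100), "compact-mode")
})

test_that("trimer strengths match the exhaustive triple-loop oracle", {
  n <- 4
  st <- random_stream(n_regions = n, n_frames = 20, window = 5, seed = 29)
  mc <- compute_mc(st)
  expect_equal(trimer_strengths(mc), oracle_trimer(mc$compact, n), tolerance = 1e-12)

  # all-ones MC, N = 5: C(4,2) = 6 trimers per region
  mc5 <- mc
  mc5$compact <- matrix(1, n_links(5), n_links(5))
  mc5$n_regions <- 5L
  mc5$links <- seq_len(n_links(5))
  expect_equal(trimer_strengths(mc5), rep(6, 5))

  # compact and expanded representations agree: recompute strengths from the
  # expanded matrix by summing over directed trimer positions / 8-fold copies
  expanded <- expand_mc(mc)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    acc <- 0
    for (a in seq_along(others)) for (b in seq_along(others)) {
      if (a < b) {
        acc <- acc + expanded[directed_index_of_link(i, others[a], n),
                              directed_index_of_link(i, others[b], n)]
      }
    }
    expect_equal(acc, trimer_strengths(mc)[i], tolerance = 1e-12)
  }
})

test_that("restricted trimer strengths drop out-of-set links", {
  n <- 5
  st <- random_stream(n_regions = n, n_frames = 20, window = 5, seed = 31)
  mc <- compute_mc(st)
  # restriction to region 1's star with all off-star MC zeroed equals the
  # unrestricted strength of region 1 on that zeroed matrix
  star <- index_of_link(rep(1, n - 1), 2:n, n)
  zeroed <- mc
  off <- setdiff(seq_len(n_links(n)), star)
  zeroed$compact[off, ] <- 0
  zeroed$compact[, off] <- 0
  diag(zeroed$compact) <- 1
  expect_equal(trimer_strengths(zeroed)[1],
               trimer_strengths(mc, restrict_links = star)[1], tolerance = 1e-12)
  expect_warning(z <- trimer_strengths(mc, restrict_links = integer(0)), "empty")
  expect_equal(z, numeric(n), ignore_attr = TRUE)
  expect_error(trimer_strengths(mc, restrict_links = 99), "1..10")
})

test_that("signed Louvain recovers a planted two-block MC exactly", {
  L <- 10
  block <- rep(1:2, each = 5)
  A <- matrix(-0.3, L, L)
  A[block == 1, block == 1] <- 0.8
  A[block == 2, block == 2] <- 0.8
  diag(A) <- 1
  mc <- structure(list(compact = A, n_regions = 5L, window = 5L, step = 1L,
                       links = seq_len(L)), class = "mc_matrix")
  part <- detect_mc_modules(mc, seed = 7)
  expect_identical(part$n_modules, 2L)
  expect_true(all(table(part$labels, block) %in% c(0L, 5L)))
  expect_gt(part$quality, 0)
  expect_false(part$uninformative)
  # deterministic given the seed
  part2 <- detect_mc_modules(mc, seed = 7)
  expect_identical(part$labels, part2$labels)

  # recovered partition has the maximal signed modularity among alternatives
  worse <- signed_modularity(A, rep(1:2, times = 5))
  expect_gt(part$quality, worse)
})

test_that("structureless MC yields an uninformative singleton partition", {
  L <- n_links(4)
  mc <- structure(list(compact = diag(L), n_regions = 4L, window = 5L, step = 1L,
                       links = seq_len(L)), class = "mc_matrix")
  expect_warning(part <- detect_mc_modules(mc), "no off-diagonal structure")
  expect_true(part$uninformative)
  expect_equal(part$quality, 0)
  expect_identical(part$n_modules, as.integer(L))
})

test_that("subgraph streams restrict rows and keep provenance", {
  st <- random_stream(n_regions = 4, n_frames = 6, seed = 37)
  full <- pick_subgraph_stream(st, seq_len(n_links(4)))
  expect_equal(full$frames, st$frames)
  sub <- pick_subgraph_stream(st, c(2, 5))
  expect_identical(sub$links, c(2L, 5L))
  expect_equal(sub$frames, st$frames[c(2, 5), ])
  # downstream ops accept the restriction unchanged
  expect_silent(d <- compute_dfc_matrix(sub))
  expect_true(all(compute_speeds(d)$speeds >= 0))
  # single-link stream: degeneracy surfaces as a constant-frame error
  single <- pick_subgraph_stream(st, 3)
  expect_error(compute_dfc_matrix(single), "constant")
  expect_error(pick_subgraph_stream(st, 99), "1..6")
  expect_error(pick_subgraph_stream(st, integer(0)), "non-empty")
})

test_that("eFC matches its defining product-series construction", {
  ts <- gen_stationary_gaussian(150, diag(4) + 0.3, seed = 41)
  e <- compute_efc(ts)
  L <- n_links(4)
  expect_identical(dim(e), c(L, L))
  expect_equal(diag(e), rep(1, L))
  expect_lt(max(abs(e - t(e))), 1e-12)

  # duplicated regions: P_12 = P_13 = z1^2 when regions 2,3 copy region 1
  dup <- cbind(ts[, 1], ts[, 1], ts[, 1], ts[, 4])
  edup <- compute_efc(dup)
  expect_equal(edup[index_of_link(1, 2, 4), index_of_link(1, 3, 4)], 1, tolerance = 1e-12)
  expect_error(compute_efc(cbind(ts[, 1], rep(1, 150))), "zero variance")
})

test_that("eFC and MC entries are positively rank-correlated", {
  pm <- gen_planted_mc_modules(n_samples = 1500, module_regions = list(1:2, 3:4),
                               n_regions = 4, seed = 43)
  st <- compute_dfc_stream(pm$ts, window = 20, step = 1)
  mc <- compute_mc(st)
  e <- compute_efc(pm$ts)
  ut <- upper.tri(e)
  expect_gt(cor(e[ut], mc$compact[ut], method = "spearman"), 0)
})

test_that("MC from independent realizations of the same generator agree", {
  mcs <- lapply(c(47, 53), function(s) {
    pm <- gen_planted_mc_modules(n_samples = 4000, seed = s)
    compute_mc(compute_dfc_stream(pm$ts, window = 20, step = 1))$compact
  })
  ut <- upper.tri(mcs[[1]])
  expect_gt(cor(mcs[[1]][ut], mcs[[2]][ut]), 0.8)
})
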