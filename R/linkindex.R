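#' Number of undirected links between N regions
#'
#' For `n_regions = N` there are `L = N(N-1)/2` unordered region pairs
#' ("links"). The package enumerates them in a single canonical order used
#' everywhere (FC vectors, dFC stream rows, meta-connectivity rows):
#' row-major over pairs `(i, j)` with `i < j`, i.e.
#' `(1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N)` (1-based). This coincides
#' with the order in which R extracts `m[lower.tri(m)]` from a symmetric
#' matrix.
#'
#' @param n_regions integer, number of regions N (>= 2).
#' @return integer L = N(N-1)/2.
#' @seealso [link_of_index()], [index_of_link()], [link_pairs()]
#' @export
n_links <- function(n_regions) {
  n_regions <- check_n_regions(n_regions)
  as.integer(n_regions * (n_regions - 1L) / 2L)
}

#' Number of directed links between N regions
#'
#' The redundant (directed) enumeration lists all `M = N(N-1)` ordered pairs
#' `(i, j)` with `i != j`, row-major with the diagonal skipped. It is the row
#' ordering of the expanded, redundant meta-connectivity representation.
#'
#' @inheritParams n_links
#' @return integer M = N(N-1).
#' @export
n_links_directed <- function(n_regions) {
  n_regions <- check_n_regions(n_regions)
  as.integer(n_regions * (n_regions - 1L))
}

check_n_regions <- function(n_regions) {
  if (length(n_regions) != 1L || !is.finite(n_regions) ||
      n_regions != round(n_regions) || n_regions < 2) {
    stop("'n_regions' must be a single integer >= 2", call. = FALSE)
  }
  as.integer(n_regions)
}

#' Table of all undirected region pairs in canonical order
#'
#' @inheritParams n_links
#' @return integer matrix with L rows and columns `i`, `j` (`i < j`); row `m`
#'   is the pair of link ordinal `m`.
#' @export
link_pairs <- function(n_regions) {
  n <- check_n_regions(n_regions)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Map a link ordinal to its region pair
#'
#' Inverse bijections of the canonical link enumerations (see [n_links()]).
#' `link_of_index()` maps undirected ordinals `m` in `1..L` to pairs
#' `(i, j)`, `i < j`; `directed_link_of_index()` maps directed ordinals in
#' `1..M` to ordered pairs `(i, j)`, `i != j`. Both are vectorized.
#'
#' @param m integer vector of link ordinals.
#' @inheritParams n_links
#' @return integer matrix with columns `i`, `j`, one row per ordinal.
#' @export
link_of_index <- function(m, n_regions) {
  n <- check_n_regions(n_regions)
  L <- n * (n - 1L) / 2L
  m <- as.integer(m)
  if (any(!is.finite(m)) || any(m < 1L) || any(m > L)) {
    stop(sprintf("link ordinal out of range 1..%d", L), call. = FALSE)
  }
  starts <- cumsum(c(1L, (n - 1L):2L))[seq_len(n - 1L)]
  i <- findInterval(m, starts)
  j <- m - starts[i] + i + 1L
  cbind(i = i, j = j)
}

#' Map a region pair to its link ordinal
#'
#' `index_of_link()` returns the undirected ordinal of the unordered pair
#' `{i, j}` (the order of the two arguments does not matter);
#' `directed_index_of_link()` returns the directed ordinal of the ordered
#' pair `(i, j)`. Self-loops `i == j` are excluded.
#'
#' @param i,j integer vectors of region indices in `1..n_regions`, `i != j`.
#' @inheritParams n_links
#' @return integer vector of link ordinals.
#' @export
index_of_link <- function(i, j, n_regions) {
  n <- check_n_regions(n_regions)
  ij <- check_pair(i, j, n)
  lo <- pmin(ij$i, ij$j)
  hi <- pmax(ij$i, ij$j)
  as.integer((lo - 1L) * (2L * n - lo) / 2L + (hi - lo))
}

#' @rdname link_of_index
#' @export
directed_link_of_index <- function(m, n_regions) {
  n <- check_n_regions(n_regions)
  M <- n * (n - 1L)
  m <- as.integer(m)
  if (any(!is.finite(m)) || any(m < 1L) || any(m > M)) {
    stop(sprintf("directed link ordinal out of range 1..%d", M), call. = FALSE)
  }
  i <- (m - 1L) %/% (n - 1L) + 1L
  r <- (m - 1L) %% (n - 1L) + 1L
  j <- r + (r >= i)
  cbind(i = i, j = as.integer(j))
}

#' @rdname index_of_link
#' @export
directed_index_of_link <- function(i, j, n_regions) {
  n <- check_n_regions(n_regions)
  ij <- check_pair(i, j, n)
  as.integer((ij$i - 1L) * (n - 1L) + ij$j - (ij$j > ij$i))
}

check_pair <- function(i, j, n) {
  i <- as.integer(i)
  j <- as.integer(j)
  if (length(i) != length(j)) stop("'i' and 'j' must have equal length", call. = FALSE)
  if (any(i < 1L | i > n) || any(j < 1L | j > n)) {
    stop(sprintf("region indices must lie in 1..%d", n), call. = FALSE)
  }
  if (any(i == j)) {
    stop("self-loops (i == j) are excluded from the link enumeration", call. = FALSE)
  }
  list(i = i, j = j)
}

# ordinal map: directed ordinal d -> undirected ordinal of the same pair
directed_to_undirected <- function(n_regions) {
  n <- check_n_regions(n_regions)
  dp <- directed_link_of_index(seq_len(n * (n - 1L)), n)
  index_of_link(dp[, "i"], dp[, "j"], n)
}
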