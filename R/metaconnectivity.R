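#' Meta-connectivity (inter-link covariance) of a dFC stream
#'
#' Each row of a vector-format dFC stream is the time-course FC_ij(t) of one
#' link. Meta-connectivity correlates those time-courses pairwise:
#' `MC[m, m'] = Corr(FC_m(t), FC_m'(t))` over frames — "links between
#' links". The canonical storage is the compact L x L matrix over unordered
#' links; the redundant M x M representation over directed pairs
#' (M = N(N-1)) is materialized on demand by [expand_mc()]. All entries are
#' retained unthresholded. Estimation benefits from a smooth stream (small
#' step, e.g. 1 sample) and a relatively short window: poorer per-frame
#' precision is compensated by many more frames.
#'
#' A link whose time-course is constant across frames is uninformative, not
#' a failure: its row/column is set to 0 (diagonal 1) with a warning.
#'
#' @param stream a `dfc_stream` with at least 3 frames.
#' @return an object of class `mc_matrix`: list with `compact` (L x L
#'   symmetric, unit diagonal), `n_regions`, `window`, `step` and `links`
#'   (original link ordinals of the rows).
#' @export
compute_mc <- function(stream) {
  stopifnot(inherits(stream, "dfc_stream"))
  frames <- stream$frames
  if (ncol(frames) < 3L) stop("need at least 3 frames to correlate link time-courses",
                              call. = FALSE)
  L <- nrow(frames)
  const <- apply(frames, 1L, function(x) max(x) == min(x))
  compact <- matrix(0, L, L)
  if (any(!const)) {
    compact[!const, !const] <- stats::cor(t(frames[!const, , drop = FALSE]))
  }
  diag(compact) <- 1
  if (any(const)) {
    warning(sprintf("link(s) %s have constant FC time-courses; their MC rows are set to 0",
                    paste(stream$links[const], collapse = ", ")))
  }
  structure(list(compact = compact, n_regions = stream$n_regions,
                 window = stream$window, step = stream$step,
                 links = stream$links),
            class = "mc_matrix")
}

#' @export
print.mc_matrix <- function(x, ...) {
  cat(sprintf("Meta-connectivity: compact %d x %d (N = %d regions, W = %s, step = %s)\n",
              nrow(x$compact), ncol(x$compact), x$n_regions,
              format(x$window), format(x$step)))
  invisible(x)
}

complete_link_set <- function(mc) {
  identical(as.integer(mc$links), seq_len(n_links(mc$n_regions)))
}

#' Expand compact meta-connectivity to the redundant M x M representation
#'
#' The presentation form of MC indexes rows by all M = N(N-1) directed
#' region pairs (diagonal excluded), so that each unique inter-link value
#' occupies its eight degenerate positions
#' `MC_ij,kl = MC_ji,kl = MC_ij,lk = ... = MC_lk,ji`
#' (four on the diagonal blocks where both entries refer to the same
#' unordered link). The expansion is a view over the compact matrix and
#' grows with the fourth power of N; a memory guard refuses to materialize
#' it beyond `max_bytes`, directing the user to compact-mode operations.
#'
#' @param mc an `mc_matrix` over the complete link set.
#' @param max_bytes memory cap for the expanded matrix (8 bytes/entry);
#'   default 4 GB.
#' @return M x M numeric matrix in directed-ordinal order (see
#'   [directed_index_of_link()]).
#' @export
expand_mc <- function(mc, max_bytes = 4e9) {
  stopifnot(inherits(mc, "mc_matrix"))
  if (!complete_link_set(mc)) {
    stop("expansion requires an MC over the complete link set of the region set",
         call. = FALSE)
  }
  n <- mc$n_regions
  M <- n_links_directed(n)
  need <- 8 * as.numeric(M)^2
  if (need > max_bytes) {
    stop(sprintf(paste0("expanded MC would need %d x %d doubles (%.2f GB) > cap of %.2f GB; ",
                        "raise 'max_bytes' or stay with compact-mode operations"),
                 M, M, need / 1e9, max_bytes / 1e9), call. = FALSE)
  }
  map <- directed_to_undirected(n)
  mc$compact[map, map]
}

#' Trimer meta-strengths of regions
#'
#' The meta-strength of region i sums the meta-connectivity weights between
#' all pairs of links incident on i (trimers rooted at i): unordered pairs
#' of distinct links `{(i,k), (i,l)}`, `k != l`, each pair counted once,
#' diagonal self meta-links excluded. Under this convention an all-ones
#' compact MC yields `MC(i) = (N-1)(N-2)/2` for every region. Regions with
#' large trimer meta-strength are "meta-hubs": localized controllers of a
#' distributed set of covarying links. The sum can be restricted to the
#' links of one dFC module (or any link list), giving module-restricted
#' meta-strengths.
#'
#' @param mc an `mc_matrix` over the complete link set.
#' @param restrict_links optional integer vector of link ordinals; only
#'   trimers whose two links both belong to it are summed. An empty
#'   restriction yields all-zero strengths with a warning.
#' @return numeric vector of length N (named by region labels when known),
#'   with attribute `restricted_to` when restricted.
#' @export
trimer_strengths <- function(mc, restrict_links = NULL) {
  stopifnot(inherits(mc, "mc_matrix"))
  if (!complete_link_set(mc)) {
    stop("trimer strengths require an MC over the complete link set", call. = FALSE)
  }
  n <- mc$n_regions
  L <- n_links(n)
  if (!is.null(restrict_links)) {
    restrict_links <- as.integer(restrict_links)
    if (length(restrict_links) == 0L) {
      warning("empty link restriction: all meta-strengths are zero")
      out <- numeric(n)
      attr(out, "restricted_to") <- integer(0)
      return(out)
    }
    if (any(restrict_links < 1L | restrict_links > L)) {
      stop(sprintf("link ordinals must lie in 1..%d", L), call. = FALSE)
    }
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    idx <- index_of_link(rep.int(i, n - 1L), others, n)
    if (!is.null(restrict_links)) idx <- intersect(idx, restrict_links)
    if (length(idx) >= 2L) {
      s <- mc$compact[idx, idx, drop = FALSE]
      out[i] <- (sum(s) - sum(diag(s))) / 2
    }
  }
  if (!is.null(restrict_links)) attr(out, "restricted_to") <- restrict_links
  out
}

#' dFC modules: signed community detection on the MC matrix
#'
#' Treats the compact MC as a weighted signed graph over links and extracts
#' communities of covarying links ("dFC modules") by Louvain optimization
#' of signed modularity, in which positive and negative weights contribute
#' with opposite sign through separate configuration-model null terms (the
#' uniform signed formulation; see [signed_modularity()]). The diagonal is
#' ignored. The partition is deterministic given the seed (which fixes the
#' node sweep orders).
#'
#' @param mc an `mc_matrix`.
#' @param resolution resolution parameter gamma of the signed modularity
#'   (1 = standard).
#' @param seed integer seed controlling the Louvain sweep order.
#' @return an object of class `module_partition`: list with `labels`
#'   (length-L module assignment of each link row of `mc`), `quality`
#'   (signed modularity of the partition), `n_modules`, `resolution`,
#'   `seed` and `uninformative` flag (set when there is no off-diagonal
#'   structure to cluster).
#' @export
detect_mc_modules <- function(mc, resolution = 1, seed = 1L) {
  stopifnot(inherits(mc, "mc_matrix"))
  A <- mc$compact
  diag(A) <- 0
  L <- nrow(A)
  if (all(A == 0)) {
    warning("MC has no off-diagonal structure; returning the singleton partition")
    return(new_module_partition(seq_len(L), quality = 0, resolution = resolution,
                                seed = seed, uninformative = TRUE))
  }
  res <- louvain_signed(A, resolution = resolution, seed = seed)
  new_module_partition(res$labels, quality = res$quality, resolution = resolution,
                       seed = seed, uninformative = res$quality <= 1e-12)
}

new_module_partition <- function(labels, quality, resolution, seed,
                                 uninformative = FALSE) {
  structure(list(labels = as.integer(labels), quality = quality,
                 n_modules = length(unique(labels)),
                 resolution = resolution, seed = as.integer(seed),
                 uninformative = uninformative),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("dFC module partition: %d module(s) over %d link(s), Q = %.4f%s\n",
              x$n_modules, length(x$labels), x$quality,
              if (isTRUE(x$uninformative)) " [uninformative]" else ""))
  invisible(x)
}

#' Restrict a dFC stream to a subset of links
#'
#' Row-subset of the stream frames. The restriction list can be a dFC
#' module, the links internal to an anatomical subdivision, or any list of
#' links of interest; all downstream operations (recurrence matrix, speeds
#' — then called "modular dFC speeds" —, DFA, MC) accept the restricted
#' stream unchanged. Degenerate restrictions (e.g. a single link, whose
#' frames are constant scalars) surface as the usual constant-frame errors
#' downstream rather than being silently patched.
#'
#' @param stream a `dfc_stream`.
#' @param links integer vector of row positions in the current stream
#'   (1..number of rows), non-empty.
#' @return a restricted `dfc_stream`; its `links` field keeps the original
#'   link ordinals.
#' @export
pick_subgraph_stream <- function(stream, links) {
  stopifnot(inherits(stream, "dfc_stream"))
  links <- as.integer(links)
  if (length(links) == 0L) stop("'links' must be non-empty", call. = FALSE)
  if (any(is.na(links)) || any(links < 1L | links > nrow(stream$frames))) {
    stop(sprintf("link positions must lie in 1..%d", nrow(stream$frames)), call. = FALSE)
  }
  new_dfc_stream(stream$frames[links, , drop = FALSE],
                 n_regions = stream$n_regions, window = stream$window,
                 step = stream$step, frame_starts = stream$frame_starts,
                 links = stream$links[links],
                 region_labels = stream$region_labels)
}

#' Edge-centric functional connectivity (eFC)
#'
#' The windowless analogue of meta-connectivity: each region series is
#' z-scored over the full session (sample sd, n-1), instantaneous pairwise
#' products `P_ij(t) = z_i(t) * z_j(t)` are formed for every link i < j in
#' canonical order, and eFC is the L x L Pearson correlation matrix of
#' those product series. Unlike MC there is no sliding-window smoothing, so
#' eFC is more sensitive to fast noise in link fluctuations; the two are
#' strongly correlated but not identical.
#'
#' @inheritParams compute_static_fc
#' @return L x L symmetric numeric matrix with unit diagonal.
#' @export
compute_efc <- function(ts) {
  ts <- as_timeseries(ts)
  const <- constant_regions(ts)
  if (length(const)) {
    stop(sprintf("region(s) %s have zero variance; z-scoring undefined",
                 paste(const, collapse = ", ")), call. = FALSE)
  }
  z <- scale(ts)
  pairs <- link_pairs(ncol(ts))
  P <- z[, pairs[, "i"], drop = FALSE] * z[, pairs[, "j"], drop = FALSE]
  e <- stats::cor(P)
  diag(e) <- 1
  e
}
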