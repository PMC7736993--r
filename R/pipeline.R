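#' Run one analysis pipeline from a configuration list
#'
#' Backend of the `dfcstream` command-line script: validates a
#' configuration, executes the requested subcommand, writes the outputs
#' plus a JSON sidecar with the fully resolved configuration (package
#' version, seed, parameters) next to the main output for provenance, and
#' returns the paths of everything written. Errors are raised as ordinary
#' R conditions; the CLI wrapper converts them to a one-line diagnosis and
#' a nonzero exit status.
#'
#' Subcommands and their main outputs:
#' \describe{
#'   \item{`fc`}{static FC matrix -> delimited text.}
#'   \item{`stream`}{dFC stream -> delimited text + sidecar
#'     ([write_stream()]).}
#'   \item{`dfcmat`}{recurrence (dFC) matrix -> delimited text.}
#'   \item{`speed`}{typical speed, speed list and histogram -> JSON.}
#'   \item{`dfa`}{scales, fluctuations, alpha, R^2, scaling flag -> JSON.}
#'   \item{`mc`}{compact MC -> delimited text (optional expanded matrix,
#'     memory-capped).}
#'   \item{`modules`}{signed-Louvain partition of an MC -> JSON.}
#'   \item{`strengths`}{trimer meta-strengths -> two-column delimited
#'     text.}
#'   \item{`surrogate`}{percentile chance band of a feature -> JSON.}
#'   \item{`simulate`}{synthetic series -> delimited text (+ ground-truth
#'     JSON).}
#' }
#'
#' @param cfg named list: `command`, `input` (path, where applicable),
#'   `out` (output path) and the per-command parameters `window`, `step`,
#'   `frame_offset`, `scales`, `bins`, `resolution`, `n_surrogates`,
#'   `kind`, `feature`, `preset`, `module`, `mc`, `truth`,
#'   `export_expanded`, `max_bytes`, `seed`.
#' @return invisibly, a named list of paths written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$command))
  command <- match.arg(cfg$command,
                       c("fc", "stream", "dfcmat", "speed", "dfa", "mc",
                         "modules", "strengths", "surrogate", "simulate"))
  if (is.null(cfg$out)) stop("'out' output path is required", call. = FALSE)
  out <- cfg$out
  num <- function(x, default = NULL) if (is.null(x)) default else as.numeric(x)
  int <- function(x, default = NULL) if (is.null(x)) default else as.integer(x)
  need_input <- !command %in% c("simulate", "modules", "strengths")
  ts <- NULL
  if (need_input) {
    if (is.null(cfg$input)) stop("'input' time-series path is required", call. = FALSE)
    ts <- read_timeseries(cfg$input)
  }
  make_stream <- function(step_default = NULL) {
    w <- int(cfg$window)
    if (is.null(w)) stop("'window' is required", call. = FALSE)
    st <- int(cfg$step, if (is.null(step_default)) w else step_default)
    compute_dfc_stream(ts, window = w, step = st)
  }
  read_mc <- function() {
    if (is.null(cfg$mc)) stop("'mc' compact-matrix path is required", call. = FALSE)
    meta <- jsonlite::read_json(paste0(cfg$mc, ".json"), simplifyVector = TRUE)
    compact <- as.matrix(utils::read.table(cfg$mc, sep = ",", colClasses = "numeric"))
    dimnames(compact) <- NULL
    structure(list(compact = compact, n_regions = as.integer(meta$n_regions),
                   window = int(meta$window), step = int(meta$step),
                   links = as.integer(meta$links)),
              class = "mc_matrix")
  }
  paths <- list(main = out)

  if (command == "fc") {
    fc <- compute_static_fc(ts)
    utils::write.table(fc, out, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else if (command == "stream") {
    write_stream(make_stream(), out)
    paths$sidecar <- stream_sidecar_path(out)
  } else if (command == "dfcmat") {
    d <- compute_dfc_matrix(make_stream())
    utils::write.table(d, out, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else if (command == "speed") {
    stream <- make_stream()
    dfc <- compute_dfc_matrix(stream)
    df_default <- if (stream$step < stream$window) stream$window else 1L
    sp <- compute_speeds(dfc, frame_offset = int(cfg$frame_offset, df_default))
    hist <- build_speed_histogram(sp, bins = int(cfg$bins, 20L))
    write_result_json(list(
      typical_speed = typical_speed(sp),
      window = stream$window, step = stream$step,
      frame_offset = sp$frame_offset, oversampled = sp$oversampled,
      speeds = sp$speeds,
      histogram = list(bin_edges = hist$bin_edges,
                       bin_probabilities = hist$bin_probabilities,
                       ci_low = hist$ci_low, ci_high = hist$ci_high,
                       confidence_level = hist$confidence_level,
                       n_observations = hist$n_observations)), out)
  } else if (command == "dfa") {
    stream <- make_stream(step_default = 1L)
    inc <- dfc_increments(stream, delta_t = stream$step)
    r <- dfa_exponent(inc, scales = int(cfg$scales))
    write_result_json(list(alpha = r$alpha, intercept = r$intercept,
                           fit_r2 = r$fit_r2, is_scaling = r$is_scaling,
                           label = r$label, scales = r$scales,
                           fluctuations = r$fluctuations,
                           window = stream$window), out)
  } else if (command == "mc") {
    stream <- make_stream(step_default = 1L)
    mc <- compute_mc(stream)
    utils::write.table(mc$compact, out, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    write_result_json(list(n_regions = mc$n_regions, window = mc$window,
                           step = mc$step, links = mc$links),
                      paste0(out, ".json"))
    paths$sidecar <- paste0(out, ".json")
    if (isTRUE(cfg$export_expanded) || identical(cfg$export_expanded, "true")) {
      exp_path <- paste0(out, ".expanded")
      expanded <- expand_mc(mc, max_bytes = num(cfg$max_bytes, 4e9))
      utils::write.table(expanded, exp_path, sep = ",", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
      paths$expanded <- exp_path
    }
  } else if (command == "modules") {
    mc <- read_mc()
    part <- detect_mc_modules(mc, resolution = num(cfg$resolution, 1),
                              seed = int(cfg$seed, 1L))
    write_result_json(list(labels = part$labels, quality = part$quality,
                           n_modules = part$n_modules,
                           resolution = part$resolution, seed = part$seed,
                           uninformative = part$uninformative), out)
  } else if (command == "strengths") {
    mc <- read_mc()
    restrict <- if (!is.null(cfg$links)) as.integer(cfg$links) else NULL
    s <- trimer_strengths(mc, restrict_links = restrict)
    utils::write.table(data.frame(region = seq_along(s), strength = as.numeric(s)),
                       out, sep = ",", row.names = FALSE, quote = FALSE)
  } else if (command == "surrogate") {
    kind <- match.arg(cfg$kind %||% "phase_randomized",
                      c("phase_randomized", "time_shuffled", "phase", "shuffle"))
    kind <- c(phase = "phase_randomized", shuffle = "time_shuffled")[kind] %|NA|% kind
    w <- int(cfg$window)
    if (is.null(w)) stop("'window' is required", call. = FALSE)
    feature <- function(x) {
      st <- if (inherits(x, "dfc_stream")) x else compute_dfc_stream(x, window = w)
      typical_speed(compute_speeds(compute_dfc_matrix(st)))
    }
    source <- if (kind == "time_shuffled") make_stream() else ts
    band <- surrogate_chance_band(feature, source, kind = kind,
                                  n_instances = int(cfg$n_surrogates, 1000L),
                                  seed = int(cfg$seed, 1L))
    empirical <- feature(if (kind == "time_shuffled") source else ts)
    write_result_json(list(kind = band$kind, lower = band$lower,
                           upper = band$upper, percentiles = band$percentiles,
                           n_effective = band$n_effective,
                           empirical = empirical,
                           inside = empirical >= band$lower & empirical <= band$upper),
                      out)
  } else if (command == "simulate") {
    preset <- match.arg(cfg$preset %||% "stationary",
                        c("stationary", "switching", "planted-modules", "fgn"))
    seed <- int(cfg$seed, 1L)
    truth <- NULL
    if (preset == "stationary") {
      n <- int(cfg$n_regions, 8L)
      sim <- gen_stationary_gaussian(int(cfg$n_samples, 1000L), diag(n), seed = seed)
      write_timeseries(sim, out)
    } else if (preset == "switching") {
      n <- int(cfg$n_regions, 8L)
      covs <- default_switching_covariances(n)
      sw <- gen_switching_covariance(int(cfg$n_samples, 1200L), covs,
                                     dwell = int(cfg$dwell, 200L), seed = seed)
      write_timeseries(sw$ts, out)
      truth <- list(regimes = sw$regimes)
    } else if (preset == "planted-modules") {
      pm <- gen_planted_mc_modules(n_samples = int(cfg$n_samples, 4000L), seed = seed)
      write_timeseries(pm$ts, out)
      truth <- list(link_modules = pm$link_modules,
                    module_regions = pm$module_regions)
    } else {
      x <- gen_fgn_increments(num(cfg$hurst, 0.5), int(cfg$n_samples, 4096L),
                              seed = seed)
      utils::write.table(x, out, sep = ",", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    }
    if (!is.null(truth)) {
      truth_path <- cfg$truth %||% paste0(out, ".truth.json")
      write_result_json(truth, truth_path)
      paths$truth <- truth_path
    }
  }

  cfg_path <- paste0(out, ".config.json")
  resolved <- cfg
  resolved$package_version <- as.character(utils::packageVersion("dfcstream"))
  write_result_json(resolved, cfg_path)
  paths$config <- cfg_path
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%|NA|%` <- function(a, b) if (length(a) == 1L && is.na(a)) b else a

# two mildly contrasting correlation regimes used by the switching preset
default_switching_covariances <- function(n) {
  half <- seq_len(n %/% 2L)
  s1 <- diag(n); s1[half, half] <- 0.8; diag(s1) <- 1
  s2 <- diag(n); other <- setdiff(seq_len(n), half)
  s2[other, other] <- 0.8; diag(s2) <- 1
  list(s1, s2)
}
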