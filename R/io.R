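#' Read a time-series matrix from delimited text
#'
#' Rows are time samples, columns are regions. The separator is sniffed
#' from the first line (tab, comma, or whitespace) unless given; a header
#' row of region labels is detected automatically (first row entirely
#' non-numeric) unless stated. Ragged or non-numeric rows are reported with
#' their line number.
#'
#' @param path file path.
#' @param sep field separator, or `NULL` to sniff.
#' @param header logical, or `NULL` to detect.
#' @return numeric matrix (T x N) with region labels as column names when
#'   a header is present.
#' @export
read_timeseries <- function(path, sep = NULL, header = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  }
  split_first <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1L]]
  if (is.null(header)) {
    header <- all(is.na(suppressWarnings(as.numeric(split_first))))
  }
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = header, fill = FALSE,
                      colClasses = "numeric", check.names = FALSE),
    error = function(e) stop(sprintf("malformed input table '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  as_timeseries(as.matrix(df))
}

#' Write a time-series matrix as delimited text
#'
#' @param ts numeric matrix, rows = time.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, sep = ",") {
  utils::write.table(ts, path, sep = sep, row.names = FALSE,
                     col.names = !is.null(colnames(ts)), quote = FALSE)
  invisible(path)
}

stream_sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a dFC stream as delimited text plus a JSON sidecar
#'
#' The L x F frame matrix is written as delimited text (rows = links,
#' columns = frames) and the stream metadata (number of regions, window,
#' step, frame starts, link ordinals, the link-ordering version tag and the
#' package version) goes to `<path>.json`. `read_stream()` restores the
#' `dfc_stream` object.
#'
#' @param stream a `dfc_stream`.
#' @param path output path of the frame table.
#' @param sep field separator.
#' @return `write_stream()`: `path`, invisibly. `read_stream()`: a
#'   `dfc_stream`.
#' @export
write_stream <- function(stream, path, sep = ",") {
  stopifnot(inherits(stream, "dfc_stream"))
  utils::write.table(stream$frames, path, sep = sep,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(n_regions = stream$n_regions, window = stream$window,
               step = stream$step, frame_starts = stream$frame_starts,
               links = stream$links,
               link_order = "row-major-i<j-1based-v1",
               package_version = as.character(utils::packageVersion("dfcstream")))
  jsonlite::write_json(meta, stream_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path, sep = ",") {
  meta_path <- stream_sidecar_path(path)
  if (!file.exists(meta_path)) {
    stop(sprintf("stream sidecar not found: %s", meta_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frames <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                        colClasses = "numeric"))
  dimnames(frames) <- NULL
  new_dfc_stream(frames, n_regions = as.integer(meta$n_regions),
                 window = as.integer(meta$window), step = as.integer(meta$step),
                 frame_starts = as.integer(meta$frame_starts),
                 links = as.integer(meta$links))
}

# compact JSON writer used by the pipeline outputs
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
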