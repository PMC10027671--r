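#' Read and write current traces
#'
#' Traces are stored as CSV with header `time_s,current_pA` on a uniform time
#' grid. On reading, the grid is validated; the first non-uniform row is
#' named in the error. (`format = "hdf5"` is reserved; only CSV is currently
#' implemented.)
#'
#' @param path file path.
#' @param format `"csv"`.
#' @return [read_trace()] returns a `porekin_trace`; [write_trace()] returns
#'   `path` invisibly.
#' @name trace_io
NULL

#' @rdname trace_io
#' @param trace a `porekin_trace`.
#' @export
write_trace <- function(trace, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 trace output is not implemented; use format = 'csv'",
         call. = FALSE)
  }
  stopifnot(inherits(trace, "porekin_trace"))
  readr::write_csv(as_tibble.porekin_trace(trace), path)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 trace input is not implemented; use format = 'csv'",
         call. = FALSE)
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), current_pA = readr::col_double()))
  if (!all(c("time_s", "current_pA") %in% names(df))) {
    stop("malformed trace file: expected header time_s,current_pA",
         call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (length(dt) == 0) stop("trace file has fewer than 2 samples", call. = FALSE)
  bad <- which(abs(dt - dt[1]) > 1e-6 * dt[1])
  if (length(bad) > 0) {
    stop("non-uniform time grid at row ", bad[1] + 2,
         " (data row ", bad[1] + 1, ")", call. = FALSE)
  }
  structure(list(current_pA = df$current_pA, dt = dt[1], config = NULL),
            class = "porekin_trace")
}

#' Read and write idealized event tables
#'
#' Event tables are TSV files with columns `start_s`, `duration_s`, `class`,
#' `mean_current_pA`, `blockade_fraction`, `mode` (and `censored` when
#' present).
#'
#' @param events an `event_table`.
#' @param path file path.
#' @return [read_events()] returns an `event_table` tibble; [write_events()]
#'   returns `path` invisibly.
#' @name event_io
NULL

#' @rdname event_io
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events))
  readr::write_tsv(tibble::as_tibble(events), path)
  invisible(path)
}

#' @rdname event_io
#' @param deadtime deadtime (s) to attach to the read table.
#' @export
read_events <- function(path, deadtime = 0) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    start_s = readr::col_double(), duration_s = readr::col_double(),
    class = readr::col_character(), mean_current_pA = readr::col_double(),
    blockade_fraction = readr::col_double(), mode = readr::col_integer(),
    .default = readr::col_guess()))
  needed <- c("start_s", "duration_s", "class")
  if (!all(needed %in% names(df))) {
    stop("malformed event file: missing column(s) ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  if (is.null(df$censored)) df$censored <- FALSE
  attr(df, "deadtime") <- deadtime
  class(df) <- c("event_table", class(df))
  df
}

#' Write an analysis report as JSON
#'
#' @param report a named list (e.g. a `run_report`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file path.
#' @return an `experiment_config` (see [experiment_config()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experiment_config, cfg)
}
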