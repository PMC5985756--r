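#' Unit conversions
#'
#' All pressures inside the solvers are kept in kPa; clinical tables print
#' mmHg. The conversion factor lives here and nowhere else.
#'
#' @param p numeric vector of pressures.
#' @return converted numeric vector.
#' @export
mmHg_to_kPa <- function(p) p * 0.133322

#' @rdname mmHg_to_kPa
#' @export
kPa_to_mmHg <- function(p) p / 0.133322

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_emf <- function(..., class = "cardioemf_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

emf_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}

#' Write a named time-series table as CSV
#'
#' First column is always \code{time_ms}; remaining columns are named signals.
#'
#' @param trace data.frame with a \code{time_ms} column.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(is.data.frame(trace), "time_ms" %in% names(trace))
  trace <- trace[, c("time_ms", setdiff(names(trace), "time_ms")), drop = FALSE]
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path, check.names = FALSE)
  if (!"time_ms" %in% names(tr))
    stop_emf("trace file '", path, "' has no time_ms column")
  tr
}
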