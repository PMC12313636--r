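#' Uniformly sampled time-series trace
#'
#' A thin data.frame wrapper used for all simulator outputs: the first
#' column is time in ms (\code{t_ms}), remaining columns are the recorded
#' channels; the sampling step and a units tag travel as attributes.
#'
#' @param data data.frame of channel columns (without the time column).
#' @param dt sampling interval (ms).
#' @param units named character vector tagging channel units.
#' @param t0 time of the first sample (ms).
#' @return An object of classes \code{"ts_trace"} and \code{"data.frame"}.
#' @export
ts_trace <- function(data, dt, units = character(), t0 = 0) {
  stopifnot(is.data.frame(data) || is.list(data), dt > 0)
  data <- as.data.frame(data)
  n <- nrow(data)
  out <- cbind(data.frame(t_ms = t0 + dt * (seq_len(n) - 1)), data)
  structure(out, dt = dt, units = units,
            class = c("ts_trace", "data.frame"))
}

#' @export
print.ts_trace <- function(x, ...) {
  cat(sprintf("Time-series trace: %d samples, dt = %g ms, %.6g ms total\n",
              nrow(x), attr(x, "dt"), nrow(x) * attr(x, "dt")))
  cat("  channels:", paste(setdiff(names(x), "t_ms"), collapse = ", "), "\n")
  u <- attr(x, "units")
  if (length(u))
    cat("  units:", paste(names(u), u, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ts_trace <- function(x, channel = setdiff(names(x), "t_ms")[1], ...) {
  graphics::plot(x$t_ms, x[[channel]], type = "l",
                 xlab = "time (ms)", ylab = channel, ...)
  invisible(x)
}

#' Read/write traces as CSV
#'
#' Traces are exchanged as plain CSV with a header row; the sampling step is
#' recovered from the \code{t_ms} column on read.
#'
#' @param x a \code{ts_trace}.
#' @param path file path.
#' @return \code{write_trace} returns \code{path} invisibly;
#'   \code{read_trace} returns a \code{ts_trace}.
#' @export
write_trace <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!"t_ms" %in% names(df)) stop("trace CSV must have a t_ms column")
  dt <- stats::median(diff(df$t_ms))
  ts_trace(df[setdiff(names(df), "t_ms")], dt = dt, t0 = df$t_ms[1])
}
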