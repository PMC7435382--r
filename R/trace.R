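# Timestamped physical signal containers and their plain-text serialisation.

new_trace <- function(times, values, unit, sample_rate = NULL, label = "") {
  assert_finite(times, "times")
  assert_finite(values, "values")
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (is.null(sample_rate) && length(times) > 1L) {
    sample_rate <- 1 / median(diff(times))
  }
  cls <- switch(unit,
    "Pa" = "pressure_trace",
    "L/s" = "flow_trace",
    "L" = "volume_trace",
    stop(sprintf("unsupported unit '%s'", unit), call. = FALSE)
  )
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         unit = unit, sample_rate = sample_rate, label = label),
    class = c(cls, "spiro_trace")
  )
}

#' Pressure trace
#'
#' A uniformly or non-uniformly sampled barometric pressure signal (Pa)
#' with strictly increasing timestamps.
#'
#' @param times Timestamps in seconds, strictly increasing.
#' @param values Pressure samples in Pa.
#' @param sample_rate Nominal sampling rate in Hz (inferred from timestamps
#'   when omitted).
#' @param label Free-text label (sensor id, inside/outside).
#' @return A `pressure_trace` object.
#' @export
pressure_trace <- function(times, values, sample_rate = NULL, label = "") {
  new_trace(times, values, "Pa", sample_rate, label)
}

#' Flow trace
#'
#' A sampled airflow signal in L/s; positive values are expiration.
#'
#' @inheritParams pressure_trace
#' @param values Flow samples in L/s (signed, positive = expiration).
#' @return A `flow_trace` object.
#' @export
flow_trace <- function(times, values, sample_rate = NULL, label = "") {
  new_trace(times, values, "L/s", sample_rate, label)
}

#' @export
print.spiro_trace <- function(x, ...) {
  cat(sprintf("<%s> %d samples, %.3f..%.3f s, unit %s, ~%.4g Hz%s\n",
              class(x)[1], length(x$times),
              min(x$times), max(x$times), x$unit,
              if (is.null(x$sample_rate)) NA_real_ else x$sample_rate,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.spiro_trace <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

#' @export
length.spiro_trace <- function(x) length(x$times)

trace_start <- function(trace) trace$times[1L]
trace_end <- function(trace) trace$times[length(trace$times)]
trace_duration <- function(trace) trace_end(trace) - trace_start(trace)

# Linear interpolation of a trace onto new timestamps (rule = 1: NA outside
# the covered span, which callers must have excluded already).
trace_interp <- function(trace, at) {
  approx(trace$times, trace$values, xout = at, method = "linear", rule = 1)$y
}

#' Write a trace to a two-column CSV file
#'
#' The file carries one comment line with the unit, nominal sample rate and
#' label, then a `time_s,value` header and the samples printed with 17
#' significant digits so that [read_trace()] round-trips values exactly.
#'
#' @param trace A [pressure_trace()] or [flow_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "spiro_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit=%s sample_rate=%.10g label=%s",
                     trace$unit,
                     if (is.null(trace$sample_rate)) NA_real_ else trace$sample_rate,
                     trace$label), con)
  writeLines("time_s,value", con)
  writeLines(sprintf("%.17g,%.17g", trace$times, trace$values), con)
  invisible(path)
}

#' Read a trace from a two-column CSV file
#'
#' Parses files written by [write_trace()]. The unit in the header decides
#' whether a pressure or flow trace is returned. Non-monotone timestamps,
#' missing headers and NA rows are rejected with row-numbered diagnostics.
#'
#' @param path File path.
#' @return A [pressure_trace()] or [flow_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) {
    stop(sprintf("'%s': expected a comment line, a header and at least one sample", path),
         call. = FALSE)
  }
  meta <- lines[1L]
  if (!grepl("^#\\s*unit=", meta)) {
    stop(sprintf("'%s': missing '# unit=...' metadata line", path), call. = FALSE)
  }
  unit <- sub("^#\\s*unit=(\\S+).*$", "\\1", meta)
  rate <- suppressWarnings(as.numeric(sub("^.*sample_rate=(\\S+).*$", "\\1", meta)))
  label <- sub("^.*label=(.*)$", "\\1", meta)
  if (!identical(lines[2L], "time_s,value")) {
    stop(sprintf("'%s': line 2 must be the header 'time_s,value'", path), call. = FALSE)
  }
  body <- lines[-(1:2)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad_shape <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad_shape)) {
    stop(sprintf("'%s': malformed row(s) at line(s) %s", path,
                 paste(bad_shape + 2L, collapse = ", ")), call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  values <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(!is.finite(times) | !is.finite(values))
  if (length(bad)) {
    stop(sprintf("'%s': non-finite/NA sample(s) at line(s) %s", path,
                 paste(head(bad, 5L) + 2L, collapse = ", ")), call. = FALSE)
  }
  nonmono <- which(diff(times) <= 0)
  if (length(nonmono)) {
    stop(sprintf("'%s': timestamps not strictly increasing at line(s) %s", path,
                 paste(head(nonmono, 5L) + 3L, collapse = ", ")), call. = FALSE)
  }
  new_trace(times, values, unit,
            sample_rate = if (is.finite(rate)) rate else NULL,
            label = label)
}
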