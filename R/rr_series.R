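#' RR-interval series
#'
#' Container for a beat-to-beat (RR) interval series. Intervals are stored
#' canonically in seconds; inputs in milliseconds are converted at construction.
#' With `unit = "auto"` the unit is detected from the median interval (a median
#' above 10 is taken to mean milliseconds, since no physiological RR interval
#' lasts 10 s). Ectopic beats must not be removed before analysis: the
#' short-long compensated pairs they produce are precisely the structure the
#' arrhythmic-line detectors target.
#'
#' @param intervals numeric vector of positive beat-to-beat intervals.
#' @param unit `"auto"`, `"seconds"` or `"milliseconds"`. A declared unit
#'   overrides detection.
#' @param source_id optional label describing the record's origin.
#' @return An object of class `rr_series` with elements `intervals` (seconds),
#'   `M` (beat count), `source_id` and `unit_declared`.
#' @examples
#' rr <- rr_series(c(0.8, 0.82, 0.79, 0.81))
#' rr$M
#' @export
rr_series <- function(intervals, unit = c("auto", "seconds", "milliseconds"),
                      source_id = "") {
  unit <- match.arg(unit)
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L)
    stop("an RR series needs at least 2 intervals, got ", length(intervals))
  bad <- which(!is.finite(intervals) | intervals <= 0)
  if (length(bad))
    stop("non-positive or non-finite RR interval at index ", bad[1L],
         " (value ", intervals[bad[1L]], ")")
  if (unit == "auto")
    unit <- if (stats::median(intervals) > 10) "milliseconds" else "seconds"
  if (unit == "milliseconds") intervals <- intervals / 1000
  structure(
    list(intervals = intervals, M = length(intervals),
         source_id = source_id, unit_declared = unit),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat("RR series: ", x$M, " beats, mean ",
      format(mean(x$intervals), digits = 4), " s",
      if (nzchar(x$source_id)) paste0(" [", x$source_id, "]"), "\n", sep = "")
  invisible(x)
}

as_rr_series <- function(x) {
  if (inherits(x, "rr_series")) return(x)
  if (is.numeric(x)) return(rr_series(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an RR series")
}
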