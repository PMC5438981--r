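#' Create a genomic interval
#'
#' Intervals are 0-based, half-open \code{[start, end)} on the record's
#' deposited linearization. An interval crossing the circular origin is
#' expressed with \code{wraps = TRUE} and \code{end <= start}; its length is
#' \code{(end - start) mod genome_length}.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param wraps Does the interval cross the circular origin?
#' @return An object of class \code{interval}.
#' @export
interval <- function(start, end, wraps = FALSE) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L, start >= 0, end >= 0)
  if (!wraps && end <= start)
    stop("non-wrapping interval must have end > start")
  structure(list(start = as.integer(start), end = as.integer(end),
                 wraps = isTRUE(wraps)),
            class = "interval")
}

#' Interval length under circular arithmetic
#'
#' @param iv An \code{interval}.
#' @param genome_length Total circle length (required when \code{iv$wraps}).
#' @return Integer length in bp.
#' @export
interval_length <- function(iv, genome_length = NULL) {
  if (iv$wraps) {
    if (is.null(genome_length))
      stop("genome_length required for a wrapping interval")
    as.integer((iv$end - iv$start) %% genome_length)
  } else {
    iv$end - iv$start
  }
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("[%d, %d)%s\n", x$start, x$end, if (x$wraps) " (wraps)" else ""))
  invisible(x)
}

# does interval (non-wrapping or wrapping) contain 0-based position p?
.iv_contains <- function(iv, p, n) {
  if (iv$wraps) (p >= iv$start && p < n) || (p >= 0 && p < iv$end)
  else p >= iv$start && p < iv$end
}
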