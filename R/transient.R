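#' OJIP fluorescence transient
#'
#' Container for one fast chlorophyll-fluorescence induction curve: a strictly
#' increasing time grid (microseconds) and the fluorescence signal recorded on
#' it (arbitrary instrument units), plus optional acquisition metadata.
#'
#' The canonical internal time unit is the microsecond; integral areas derived
#' from a transient are therefore in a.u.*us.
#'
#' @param times Numeric vector of acquisition times in microseconds; strictly
#'   increasing, length >= 2.
#' @param fluorescence Numeric vector of fluorescence values (a.u.), same
#'   length as `times`, all finite and non-negative.
#' @param metadata Optional named list of acquisition metadata (e.g.
#'   `sample_id`, `excitation_nm`, `pulse_umol`, `actinic_umol`,
#'   `dark_adaptation_min`, `sample_volume_mL`).
#' @return An object of class `ojip_transient`.
#' @examples
#' tr <- ojip_transient(c(0, 1e3, 1e6), c(100, 500, 30000))
#' tr
#' @export
ojip_transient <- function(times, fluorescence, metadata = list()) {
  times <- as.numeric(times)
  fluorescence <- as.numeric(fluorescence)
  if (length(times) != length(fluorescence)) {
    stop("`times` and `fluorescence` must have the same length (",
         length(times), " vs ", length(fluorescence), ")", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a transient needs at least 2 points, got ", length(times),
         call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("`times` must be finite and non-missing", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing (no duplicate or out-of-order ",
         "timestamps); refusing to reorder silently", call. = FALSE)
  }
  if (anyNA(fluorescence) || any(!is.finite(fluorescence))) {
    stop("`fluorescence` must be finite and non-missing", call. = FALSE)
  }
  if (any(fluorescence < 0)) {
    stop("`fluorescence` must be non-negative", call. = FALSE)
  }
  if (!is.list(metadata)) stop("`metadata` must be a list", call. = FALSE)
  structure(
    list(times = times, fluorescence = fluorescence, metadata = metadata),
    class = "ojip_transient"
  )
}

#' @export
print.ojip_transient <- function(x, ...) {
  n <- length(x$times)
  cat("<ojip_transient> ", n, " points, t = [",
      format(x$times[1]), ", ", format(x$times[n]), "] us, F in [",
      format(min(x$fluorescence)), ", ", format(max(x$fluorescence)),
      "] a.u.\n", sep = "")
  if (length(x$metadata)) {
    cat("  metadata:",
        paste(names(x$metadata), unlist(x$metadata, use.names = FALSE),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.ojip_transient <- function(x) length(x$times)

is_transient <- function(x) inherits(x, "ojip_transient")

assert_transient <- function(x, arg = "transient") {
  if (!is_transient(x)) {
    stop("`", arg, "` must be an `ojip_transient` (see `ojip_transient()`)",
         call. = FALSE)
  }
  invisible(x)
}
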