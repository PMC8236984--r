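#' Integral area of an OJIP transient
#'
#' The summary statistic on which all calibrations in this package are built:
#' the area under the fluorescence-versus-time curve over the recorded span,
#' computed by the trapezoidal rule on linear time. No extrapolation is done
#' to t = 0 or beyond the last sample.
#'
#' @param transient An [ojip_transient].
#' @return Numeric scalar, area in a.u.*us (non-negative for non-negative
#'   fluorescence). Divide by 1e10 (see [area_to_display()]) for the display
#'   scale conventionally used when reporting.
#' @examples
#' tr <- ojip_transient(c(0, 1e6), c(1, 1))
#' integral_area(tr) # 1e6
#' @export
integral_area <- function(transient) {
  assert_transient(transient)
  t <- transient$times
  f <- transient$fluorescence
  n <- length(t)
  sum(diff(t) * (f[-1] + f[-n]) / 2)
}

#' Convert an integral area between base and display units
#'
#' Calibration equations are conventionally reported with the integral area on
#' a 1e10 a.u.*us display scale; internally areas are stored in base a.u.*us.
#'
#' @param area Area in a.u.*us.
#' @param display_area Area on the 1e10 display scale.
#' @return The converted value.
#' @export
area_to_display <- function(area) area / 1e10

#' @rdname area_to_display
#' @export
display_to_area <- function(display_area) display_area * 1e10

#' Extract JIP-test descriptors from a transient
#'
#' Computes the integral area plus the basic fast-induction descriptors:
#' Fo (minimal fluorescence), Fm (maximal fluorescence), Fv/Fm (maximum PSII
#' quantum yield), and the fluorescence at the J (nominal 2 ms) and I
#' (nominal 30 ms) steps by linear interpolation.
#'
#' Fo is taken as the mean of the first `f_o_points` recorded samples (default
#' 1: the instrument's first reliable point), not an extrapolation to t = 0.
#'
#' @param transient An [ojip_transient].
#' @param j_time,i_time Step times in microseconds (defaults 2000 and 30000,
#'   the conventional J and I positions).
#' @param f_o_points Number of leading samples averaged for Fo (default 1).
#' @return A `transient_features` list with elements `integral_area`, `f_o`,
#'   `f_m`, `fv_fm`, `f_j`, `f_i`.
#' @export
extract_features <- function(transient, j_time = 2000, i_time = 30000,
                             f_o_points = 1L) {
  assert_transient(transient)
  t <- transient$times
  f <- transient$fluorescence
  f_o_points <- as.integer(f_o_points)
  if (f_o_points < 1L || f_o_points > length(t)) {
    stop("`f_o_points` must be between 1 and the number of samples",
         call. = FALSE)
  }
  step_at <- function(time, label) {
    if (time < t[1] || time > t[length(t)]) {
      stop(label, " step time ", time, " us is outside the recorded span [",
           t[1], ", ", t[length(t)], "] us", call. = FALSE)
    }
    stats::approx(t, f, xout = time)$y
  }
  f_o <- mean(f[seq_len(f_o_points)])
  f_m <- max(f)
  structure(list(
    integral_area = integral_area(transient),
    f_o = f_o,
    f_m = f_m,
    fv_fm = if (f_m > 0) (f_m - f_o) / f_m else 0,
    f_j = step_at(j_time, "J"),
    f_i = step_at(i_time, "I")
  ), class = "transient_features")
}

#' @export
print.transient_features <- function(x, ...) {
  cat("<transient_features>\n")
  cat(sprintf("  integral area: %.6g a.u.*us (%.4f x 1e10)\n",
              x$integral_area, area_to_display(x$integral_area)))
  cat(sprintf("  Fo %.6g  Fm %.6g  Fv/Fm %.4f  FJ %.6g  FI %.6g\n",
              x$f_o, x$f_m, x$fv_fm, x$f_j, x$f_i))
  invisible(x)
}

#' @export
as.data.frame.transient_features <- function(x, ...) {
  data.frame(integral_area = x$integral_area,
             integral_area_1e10 = area_to_display(x$integral_area),
             f_o = x$f_o, f_m = x$f_m, fv_fm = x$fv_fm,
             f_j = x$f_j, f_i = x$f_i)
}
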