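#' Labelled quantity
#'
#' A quantity label carried by calibrations so that slopes keep their units
#' straight: a name, a unit string, and a display scale (1 for base units;
#' e.g. 1e10 for integral areas reported on the conventional display scale).
#'
#' @param name Quantity name, e.g. `"integral area"`.
#' @param unit Unit string, e.g. `"1e10 a.u.*us"` or `"mg L-1"`.
#' @param scale Display scale factor (default 1).
#' @return A `quantity` list.
#' @export
quantity <- function(name, unit, scale = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(unit), length(unit) == 1L,
            is.numeric(scale), length(scale) == 1L, scale > 0)
  structure(list(name = name, unit = unit, scale = scale),
            class = "quantity")
}

quantity_label <- function(q) paste0(q$name, " (", q$unit, ")")

#' Linear calibration line
#'
#' A fitted or literature-supplied straight line y = slope * x + intercept
#' relating the OJIP integral area (or any x quantity) to a measured quantity,
#' together with its fit statistics where available. Use [fit_linear()] to
#' estimate one from data; use this constructor directly to load published
#' coefficients.
#'
#' @param slope,intercept Line coefficients (y-units per x-unit; y-units).
#' @param r Pearson correlation of the fit (`NA` if not applicable).
#' @param r_squared Coefficient of determination (`NA` if not applicable).
#' @param n Number of calibration points (`NA` if not applicable).
#' @param p_value Two-sided p-value of the correlation (`NA` if not
#'   applicable).
#' @param x_quantity,y_quantity [quantity()] labels for the axes.
#' @return A `linear_calibration` object.
#' @examples
#' # published integral-area -> Chl a line for a natural pond community
#' cal <- linear_calibration(0.594, -0.9021,
#'   x_quantity = quantity("integral area", "1e10 a.u.*us", 1e10),
#'   y_quantity = quantity("Chl a", "mg L-1"))
#' predict(cal, 12.40)
#' @export
linear_calibration <- function(slope, intercept,
                               r = NA_real_, r_squared = NA_real_,
                               n = NA_integer_, p_value = NA_real_,
                               x_quantity = quantity("x", "a.u."),
                               y_quantity = quantity("y", "a.u.")) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  if (!is.na(r) && abs(r) > 1 + 1e-12) stop("`r` must be in [-1, 1]",
                                            call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1 + 1e-12)) {
    stop("`r_squared` must be in [0, 1]", call. = FALSE)
  }
  if (!inherits(x_quantity, "quantity") || !inherits(y_quantity, "quantity")) {
    stop("`x_quantity` and `y_quantity` must be `quantity()` objects",
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, r = r,
                 r_squared = r_squared, n = n, p_value = p_value,
                 x_quantity = x_quantity, y_quantity = y_quantity),
            class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat("<linear_calibration> ", equation_string(x), "\n", sep = "")
  cat("  x: ", quantity_label(x$x_quantity),
      "   y: ", quantity_label(x$y_quantity), "\n", sep = "")
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 = %.4f, r = %.4f, n = %s, p = %s\n",
                x$r_squared, x$r, format(x$n), format.pval(x$p_value)))
  } else {
    cat("  fit statistics: not applicable (literature or composite line)\n")
  }
  invisible(x)
}

#' Format a calibration as a "y = ax + b" equation string
#' @param cal A `linear_calibration`.
#' @param digits Significant digits (default 6).
#' @return A character scalar.
#' @export
equation_string <- function(cal, digits = 6) {
  sign <- if (cal$intercept < 0) " - " else " + "
  paste0("y = ", signif(cal$slope, digits), "x", sign,
         signif(abs(cal$intercept), digits))
}

#' Fit a linear calibration by ordinary least squares
#'
#' Regresses the measured quantity (y) on the integral area (x), the direction
#' used for all calibrations here. The two-sided p-value comes from the exact
#' t-distribution with n - 2 degrees of freedom via the Pearson correlation
#' t-statistic — small-n field calibrations are the intended use case.
#'
#' @param x,y Equal-length numeric vectors, n >= 3; x must not be constant.
#' @param x_quantity,y_quantity [quantity()] labels for the axes.
#' @return A `linear_calibration` with slope, intercept, r, R squared, n and
#'   p-value filled in.
#' @export
fit_linear <- function(x, y,
                       x_quantity = quantity("x", "a.u."),
                       y_quantity = quantity("y", "a.u.")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in calibration data",
                                 call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 calibration points, got ", n,
                   call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate calibration: x has zero variance",
                               call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  if (stats::var(y) == 0) {
    # flat response: a valid (horizontal) line, but correlation is undefined
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  linear_calibration(unname(co[2]), unname(co[1]),
                     r = r, r_squared = r^2, n = n, p_value = p,
                     x_quantity = x_quantity, y_quantity = y_quantity)
}

#' Predict from a linear calibration
#'
#' @param object A `linear_calibration`.
#' @param x Numeric x value(s) (on the calibration's x display scale).
#' @param ... Ignored.
#' @return `slope * x + intercept`, in the calibration's y units.
#' @export
predict.linear_calibration <- function(object, x, ...) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("`x` must be finite",
                                           call. = FALSE)
  object$slope * x + object$intercept
}

#' Invert a linear calibration
#'
#' Answers "what integral area corresponds to this measured value":
#' `(y - intercept) / slope`.
#'
#' @param cal A `linear_calibration` with non-zero slope.
#' @param y Numeric y value(s).
#' @return x value(s) such that `predict(cal, x) == y`.
#' @export
invert <- function(cal, y) {
  stopifnot(inherits(cal, "linear_calibration"))
  if (cal$slope == 0) stop("cannot invert a calibration with zero slope",
                           call. = FALSE)
  (as.numeric(y) - cal$intercept) / cal$slope
}

#' Pearson correlation test with field-style significance labels
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return A list with `r`, `p_value`, and `label` in
#'   `"ns"`, `"significant (p<0.05)"`, `"extremely significant (p<0.01)"`.
#' @export
correlation_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined: zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- ct$p.value
  label <- if (p < 0.01) "extremely significant (p<0.01)"
           else if (p < 0.05) "significant (p<0.05)"
           else "ns"
  list(r = unname(ct$estimate), p_value = p, label = label)
}

#' Relative deviation between an estimate and a reference, in percent
#'
#' `100 * |estimate - reference| / denominator`. Published validation tables
#' in this area use both conventions (dividing by the reference measurement or
#' by the estimate), so the denominator choice is a required argument — there
#' is no default hiding it.
#'
#' @param estimate,reference Numeric values (vectorised).
#' @param denominator `"reference"` or `"estimate"`.
#' @return Percent deviation(s), always non-negative.
#' @export
relative_deviation <- function(estimate, reference,
                               denominator = c("reference", "estimate")) {
  if (missing(denominator)) {
    stop("`denominator` must be given explicitly: \"reference\" or ",
         "\"estimate\"", call. = FALSE)
  }
  denominator <- match.arg(denominator)
  den <- if (denominator == "reference") reference else estimate
  if (any(den == 0)) stop("chosen denominator is zero", call. = FALSE)
  100 * abs(estimate - reference) / abs(den)
}

#' Save / load a calibration as JSON
#'
#' Round-trips all fields and quantity labels exactly. Schema:
#' `{slope, intercept, r, r_squared, n, p_value,
#'   x_quantity: {name, unit, scale}, y_quantity: {name, unit, scale}}`.
#'
#' @param cal A `linear_calibration`.
#' @param path JSON file path.
#' @return `save_calibration()`: invisibly, `path`. `load_calibration()`: the
#'   restored `linear_calibration`.
#' @export
save_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "linear_calibration"))
  obj <- unclass(cal)
  obj$x_quantity <- unclass(obj$x_quantity)
  obj$y_quantity <- unclass(obj$y_quantity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path,
                               call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse calibration JSON ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  need <- c("slope", "intercept", "x_quantity", "y_quantity")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop("calibration JSON ", path, " is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  qfrom <- function(q, which) {
    if (!all(c("name", "unit") %in% names(q))) {
      stop("calibration JSON ", path, ": ", which,
           " must have name and unit", call. = FALSE)
    }
    quantity(q$name, q$unit, if (is.null(q$scale)) 1 else q$scale)
  }
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  linear_calibration(
    slope = as.numeric(obj$slope), intercept = as.numeric(obj$intercept),
    r = num_or_na(obj$r), r_squared = num_or_na(obj$r_squared),
    n = if (is.null(obj$n) || is.na(num_or_na(obj$n))) NA_integer_
        else as.integer(obj$n),
    p_value = num_or_na(obj$p_value),
    x_quantity = qfrom(obj$x_quantity, "x_quantity"),
    y_quantity = qfrom(obj$y_quantity, "y_quantity")
  )
}
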