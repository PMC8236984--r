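#' Empirical productivity-formula parameters
#'
#' Parameters of the empirical formula P = K * r * c(Chl a) * DH relating
#' chlorophyll a concentration to daily volumetric primary productivity.
#' K (experience constant) and r (assimilation coefficient,
#' mg biomass h-1 mg-1 Chl a) are site- and community-specific and carry no
#' defaults; DH is the daily sunshine time in hours; PQ (photosynthetic
#' quotient, mol O2 per mol CO2) defaults to 1.25, the customary value for
#' natural phytoplankton communities.
#'
#' @param K Dimensionless experience constant (> 0).
#' @param r_assim Assimilation coefficient, mg biomass h-1 mg-1 Chl a (> 0).
#' @param DH Sunshine hours per day (> 0).
#' @param PQ Photosynthetic quotient (> 0, default 1.25).
#' @return A `productivity_params` list.
#' @export
productivity_params <- function(K, r_assim, DH, PQ = 1.25) {
  if (missing(K) || missing(r_assim) || missing(DH)) {
    stop("K, r_assim and DH have no defaults: supply them from local ",
         "knowledge, or calibrate productivity directly against the OJIP ",
         "integral area with fit_linear()/cross_calibrate()", call. = FALSE)
  }
  vals <- c(K = K, r_assim = r_assim, DH = DH, PQ = PQ)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all productivity parameters must be finite and > 0", call. = FALSE)
  }
  structure(as.list(vals), class = "productivity_params")
}

#' Chlorophyll a concentration from methanol-extract absorbances
#'
#' The standard two-wavelength methanol-extract formula:
#' `16.72 * OD665.2 - 9.16 * OD652.4`, in ug/mL of extract. Slightly negative
#' results (possible with noisy blanks near the detection limit) are clamped
#' to zero with a warning rather than treated as errors.
#'
#' @param od_665_2 Absorbance at 665.2 nm (>= 0).
#' @param od_652_4 Absorbance at 652.4 nm (>= 0).
#' @return Chlorophyll a in ug/mL (vectorised).
#' @examples
#' chl_a_from_absorbance(0.5, 0.2) # 6.528
#' @export
chl_a_from_absorbance <- function(od_665_2, od_652_4) {
  if (any(od_665_2 < 0) || any(od_652_4 < 0)) {
    stop("absorbances must be non-negative", call. = FALSE)
  }
  chla <- 16.72 * od_665_2 - 9.16 * od_652_4
  below <- chla < 0
  if (any(below)) {
    warning("chlorophyll a below detection (negative extract estimate) ",
            "clamped to 0 for ", sum(below), " value(s)")
    chla[below] <- 0
  }
  chla
}

#' Convert chlorophyll a between mg/L and mg/m3
#'
#' Calibration tables report Chl a in mg/L while the empirical productivity
#' formula takes mg/m3; 1 mg/L = 1000 mg/m3.
#'
#' @param chl_a_mg_L Chlorophyll a in mg/L.
#' @return Chlorophyll a in mg/m3.
#' @export
chla_mgL_to_mgm3 <- function(chl_a_mg_L) 1000 * chl_a_mg_L

#' Primary productivity from chlorophyll a
#'
#' Evaluates the empirical formula P = K * r * c(Chl a) * DH.
#'
#' @param chl_a Chlorophyll a concentration in mg/m3 (>= 0; see
#'   [chla_mgL_to_mgm3()] for the mg/L tables convention).
#' @param params A [productivity_params()] object.
#' @return Primary productivity in mg C m-3 d-1 (vectorised, linear in
#'   `chl_a`).
#' @export
productivity_from_chla <- function(chl_a, params) {
  if (missing(params) || !inherits(params, "productivity_params")) {
    stop("`params` must be a productivity_params() object; K, r_assim and ",
         "DH must be configured explicitly (there are no defaults), or use ",
         "the calibration route instead", call. = FALSE)
  }
  if (any(chl_a < 0)) stop("`chl_a` must be non-negative", call. = FALSE)
  params$K * params$r_assim * chl_a * params$DH
}

#' Oxygen-method productivity converted to carbon units
#'
#' Light/dark-bottle incubations yield net oxygen production; carbon fixation
#' follows from 1 mg O2 = 0.375 mg C / PQ, where PQ is the photosynthetic
#' quotient. Negative net production (net heterotrophy) is flagged with a
#' warning but converted, not rejected.
#'
#' @param net_o2 Net oxygen production, mg O2 m-3 d-1 (vectorised).
#' @param pq Photosynthetic quotient (> 0; 1.25 is customary for natural
#'   communities).
#' @return Productivity in mg C m-3 d-1.
#' @examples
#' oxygen_to_carbon(1, pq = 1.25) # 0.3
#' @export
oxygen_to_carbon <- function(net_o2, pq = 1.25) {
  if (!is.numeric(pq) || length(pq) != 1L || !is.finite(pq) || pq <= 0) {
    stop("`pq` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(net_o2))) stop("`net_o2` must be finite", call. = FALSE)
  if (any(net_o2 < 0)) {
    warning("negative net O2 production (net heterotrophy) for ",
            sum(net_o2 < 0), " value(s)")
  }
  net_o2 * 0.375 / pq
}

#' Compose two linear calibrations
#'
#' Chains `inner` (x -> y1) with `outer` (y1 -> y2) into the single line
#' x -> y2: slope `outer$slope * inner$slope`, intercept
#' `outer$slope * inner$intercept + outer$intercept`. Quantity labels
#' propagate (x from `inner`, y from `outer`). Fit statistics do not compose,
#' so r, R squared and p of the result are `NA` unless refit on data.
#'
#' @param inner,outer `linear_calibration` objects; `inner`'s y quantity must
#'   name the same quantity as `outer`'s x quantity.
#' @return The composite `linear_calibration`.
#' @export
compose_linear <- function(inner, outer) {
  stopifnot(inherits(inner, "linear_calibration"),
            inherits(outer, "linear_calibration"))
  qy <- inner$y_quantity; qx <- outer$x_quantity
  if (qy$unit != qx$unit || qy$scale != qx$scale) {
    stop("cannot compose: inner y quantity ", quantity_label(qy),
         " does not match outer x quantity ", quantity_label(qx),
         call. = FALSE)
  }
  linear_calibration(
    slope = outer$slope * inner$slope,
    intercept = outer$slope * inner$intercept + outer$intercept,
    x_quantity = inner$x_quantity,
    y_quantity = outer$y_quantity
  )
}

#' Cross-calibrate OJIP productivity estimates against the oxygen method
#'
#' Fits the correction line (oxygen-method productivity regressed on the
#' OJIP-based estimate) and composes it with the base integral-area ->
#' productivity calibration, yielding the "modified" integral-area ->
#' productivity calibration benchmarked to light/dark-bottle incubations.
#'
#' @param ojip_estimates OJIP-based productivity estimates (mg C m-3 d-1 or a
#'   consistent display scale), n >= 3.
#' @param oxygen_measurements Paired oxygen-method productivity values, same
#'   units/scale.
#' @param base The integral-area -> OJIP-productivity `linear_calibration`.
#' @return The modified `linear_calibration` (integral area -> oxygen-anchored
#'   productivity), with the fitted correction line attached as attribute
#'   `"correction"`.
#' @export
cross_calibrate <- function(ojip_estimates, oxygen_measurements, base) {
  stopifnot(inherits(base, "linear_calibration"))
  correction <- fit_linear(
    ojip_estimates, oxygen_measurements,
    x_quantity = base$y_quantity,
    y_quantity = quantity(paste0(base$y_quantity$name, " (oxygen method)"),
                          base$y_quantity$unit, base$y_quantity$scale)
  )
  modified <- compose_linear(base, correction)
  attr(modified, "correction") <- correction
  modified
}

#' Check that two calibrations are scalar multiples of each other
#'
#' When a productivity calibration is derived from a Chl a calibration through
#' a constant conversion factor, its slope and intercept are the Chl a line's
#' scaled by one common constant. This utility verifies that consistency.
#'
#' @param cal_a,cal_b `linear_calibration` objects.
#' @param tol Relative tolerance on the agreement of the two coefficient
#'   ratios (default 0.01).
#' @return A list: `proportional` (logical), `ratio` (the common factor,
#'   slope-based), `slope_ratio`, `intercept_ratio`.
#' @export
check_proportional <- function(cal_a, cal_b, tol = 0.01) {
  stopifnot(inherits(cal_a, "linear_calibration"),
            inherits(cal_b, "linear_calibration"))
  if (cal_a$slope == 0 || cal_a$intercept == 0) {
    stop("cal_a has a zero coefficient; proportionality check undefined",
         call. = FALSE)
  }
  sr <- cal_b$slope / cal_a$slope
  ir <- cal_b$intercept / cal_a$intercept
  list(proportional = abs(sr - ir) <= tol * max(abs(sr), abs(ir)),
       ratio = sr, slope_ratio = sr, intercept_ratio = ir)
}
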