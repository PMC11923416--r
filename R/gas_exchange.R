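#' Total leaf conductance to water vapor from transpiration
#'
#' Inverts the transpiration equation for total (stomatal + boundary-layer)
#' conductance:
#' \deqn{g_t = E\,(p - \dot e)/(e_i - e_a),\qquad \dot e = (e_i + e_a)/2}
#' with air pressure `p` and intercellular/ambient vapor pressures `e_i`,
#' `e_a` (all kPa). For well-coupled conifer shoots `g_t` is a close proxy
#' for stomatal conductance because boundary-layer conductance is an order
#' of magnitude larger.
#'
#' Records where `e_a > e_i` with positive `E` would yield a negative
#' conductance; these are returned as `NA` and flagged in the `"invalid"`
#' attribute rather than silently propagated.
#'
#' @param E Transpiration, mol m-2 s-1.
#' @param p Air pressure, kPa.
#' @param e_i Leaf intercellular vapor pressure, kPa (saturated at leaf
#'   temperature, see [leaf_intercellular_vapor()]).
#' @param e_a Ambient vapor pressure, kPa.
#' @return Total conductance `g_t`, mol m-2 s-1.
#' @examples
#' total_conductance(0.002, 100, 2, 1)  # 0.197
#' @export
total_conductance <- function(E, p, e_i, e_a) {
  if (any(abs(e_i - e_a) < .Machine$double.eps * 100, na.rm = TRUE)) {
    stop("e_i = e_a: conductance undefined (zero vapor-pressure gradient)")
  }
  edot <- (e_i + e_a) / 2
  if (any(p <= edot, na.rm = TRUE)) {
    stop("air pressure must exceed the mean vapor pressure")
  }
  gt <- E * (p - edot) / (e_i - e_a)
  bad <- which(gt < 0)
  if (length(bad)) {
    gt[bad] <- NA_real_
    attr(gt, "invalid") <- bad
  }
  gt
}

#' Filter assimilation records by a minimum-flux threshold
#'
#' Removes records whose net CO2 influx is at or below a detection
#' threshold, guarding against instrument noise near zero. The threshold is
#' applied in the units of the supplied column (default 0.1): published unit
#' conventions for this cutoff are inconsistent, so the value is exposed
#' rather than converted.
#'
#' @param records Data frame with the flux column.
#' @param threshold Minimum retained flux (strictly greater than); default
#'   0.1 in column units.
#' @param column Name of the flux column, default `"A_n"`.
#' @return The filtered data frame (rows with `NA` flux are retained).
#' @export
filter_assimilation <- function(records, threshold = 0.1, column = "A_n") {
  stopifnot(is.data.frame(records), column %in% names(records))
  flux <- records[[column]]
  keep <- is.na(flux) | flux > threshold
  records[keep, , drop = FALSE]
}

#' Gap-fill missing flux records with a pluggable empirical model
#'
#' Fits a registered empirical model to the non-missing records of one flux
#' column and predicts the missing ones. Observed values are never altered;
#' filled rows are marked in a logical `gapfilled` column (created or OR-ed
#' with an existing one). Fit diagnostics (R2 and RMSE of self-prediction on
#' the observed records) are attached as attribute `"diagnostics"`.
#'
#' Registered models:
#' \describe{
#'   \item{`"linear"`}{`flux ~ T_air + VPD + daylight`, where
#'     `VPD = e_sat(T_air) - e_a` and `daylight` is a clipped solar
#'     elevation proxy `pmax(0, sin(pi * (hour - 4) / 14))` covering
#'     a boreal summer photoperiod.}
#'   \item{`"constant"`}{intercept-only (mean of observed records).}
#' }
#'
#' @param records Forcing-style data frame with `timestamp`, `T_air`, `e_a`
#'   and the flux column.
#' @param column Flux column to fill (`"A_n"` or `"E"`).
#' @param model One of `"linear"`, `"constant"`.
#' @return `records` with gaps filled and `gapfilled` flag set.
#' @export
gapfill_fluxes <- function(records, column = "A_n", model = "linear") {
  stopifnot(is.data.frame(records), column %in% names(records))
  model <- match.arg(model, c("linear", "constant"))
  flux <- records[[column]]
  obs <- !is.na(flux)
  if (sum(obs) < 3) {
    stop("insufficient non-missing records to fit the gap-filler")
  }
  if (!"gapfilled" %in% names(records)) records$gapfilled <- FALSE
  hour <- as.numeric(format(records$timestamp, "%H")) +
    as.numeric(format(records$timestamp, "%M")) / 60
  df <- data.frame(
    flux = flux,
    T_air = records$T_air,
    VPD = e_sat(records$T_air) - records$e_a,
    daylight = pmax(0, sin(pi * (hour - 4) / 14))
  )
  fit <- if (model == "linear") {
    stats::lm(flux ~ T_air + VPD + daylight, data = df[obs, ])
  } else {
    stats::lm(flux ~ 1, data = df[obs, ])
  }
  pred_obs <- stats::predict(fit, newdata = df[obs, ])
  resid <- flux[obs] - pred_obs
  ss_tot <- sum((flux[obs] - mean(flux[obs]))^2)
  diagnostics <- list(
    r2 = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1,
    rmse = sqrt(mean(resid^2)),
    n_filled = sum(!obs)
  )
  if (any(!obs)) {
    records[[column]][!obs] <- stats::predict(fit, newdata = df[!obs, ])
    records$gapfilled <- records$gapfilled | !obs
  }
  attr(records, "diagnostics") <- diagnostics
  records
}

#' Add total conductance to a forcing table
#'
#' Convenience wrapper computing `e_i` from air temperature and `g_t` from
#' transpiration for every record; nighttime records with `E = 0` get
#' `g_t = 0`.
#'
#' @param forcings Forcing data frame (see [simulate_forcings()]).
#' @return The data frame with a `g_t` column appended.
#' @export
derive_conductance <- function(forcings) {
  e_i <- leaf_intercellular_vapor(forcings$T_air)
  gt <- numeric(nrow(forcings))
  pos <- forcings$E > 0 & (e_i - forcings$e_a) > 1e-9
  gt[pos] <- forcings$E[pos] *
    (forcings$p_air[pos] - (e_i[pos] + forcings$e_a[pos]) / 2) /
    (e_i[pos] - forcings$e_a[pos])
  gt[gt < 0] <- 0
  forcings$g_t <- gt
  forcings
}
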