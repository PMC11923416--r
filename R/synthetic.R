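#' Default parameters for the synthetic boreal forcing generator
#'
#' All values are package defaults chosen to emulate a southern-boreal Scots
#' pine growing season at half-hourly resolution; none are site
#' measurements. Temperature follows an annual cosine (minimum mid-January,
#' maximum mid-July, so the minimum of a April-October simulation falls at
#' the start in early April) plus a diurnal sine peaking at 15:00, a
#' day-scale synoptic AR(1) (weather systems) and a 30-min AR(1) noise term.
#' Precipitation delta-2H spans -130 per mil (winter) to -55 per mil
#' (summer); vapor is in isotopic equilibrium with precipitation at air
#' temperature.
#'
#' @param T_mean Annual mean air temperature, degrees C.
#' @param T_seasonal_amp Annual temperature amplitude, degrees C.
#' @param T_diurnal_amp Diurnal temperature amplitude, degrees C.
#' @param ar1_coef 30-min AR(1) coefficient for temperature noise.
#' @param ar1_sd Stationary SD of the 30-min noise, degrees C.
#' @param synoptic_coef Day-scale AR(1) coefficient (weather persistence).
#' @param synoptic_sd Stationary SD of the day-scale temperature anomaly,
#'   degrees C.
#' @param RH_base Mean daytime-neutral relative humidity, percent.
#' @param RH_diurnal_amp Diurnal RH amplitude (anti-phase with temperature),
#'   percent.
#' @param RH_synoptic_gain RH response to the synoptic anomaly, percent per
#'   degree C (negative: warm spells are dry).
#' @param p_air Air pressure, kPa (constant; the site is flat lowland).
#' @param gs_max Maximum stomatal conductance, mol m-2 s-1.
#' @param An_max Maximum net assimilation, micromol m-2 s-1.
#' @param precip_rate Poisson rate of precipitation event starts per 30-min
#'   step.
#' @param precip_mean_depth Mean event depth, mm.
#' @param d2H_precip_winter,d2H_precip_summer Seasonal extremes of
#'   precipitation delta-2H, per mil VSMOW (package defaults, not site
#'   values).
#' @param d2H_precip_event_sd Event-to-event delta-2H scatter, per mil.
#' @param An_noise_sd Multiplicative 30-min noise SD on assimilation
#'   (fraction).
#' @param cloud_persistence Day-scale AR(1) coefficient of the latent
#'   cloudiness process.
#' @param cloud_sd Stationary SD of the latent cloudiness process (0
#'   disables cloud variability).
#' @param RH_cloud_gain RH increase on fully overcast days, percent.
#' @param An_day_sd SD of the day-scale log-normal assimilation-capacity
#'   anomaly (photosynthetic capacity varies independently of stomata).
#' @param An_day_coef Day-scale AR(1) coefficient of that anomaly.
#' @return Named list of generator parameters.
#' @export
forcing_params <- function(T_mean = 5, T_seasonal_amp = 12, T_diurnal_amp = 4,
                           ar1_coef = 0.8, ar1_sd = 1.2,
                           synoptic_coef = 0.7, synoptic_sd = 2.5,
                           RH_base = 72, RH_diurnal_amp = 18,
                           RH_synoptic_gain = -3,
                           p_air = 100,
                           gs_max = 0.15, An_max = 8,
                           precip_rate = 0.01, precip_mean_depth = 2,
                           d2H_precip_winter = -130,
                           d2H_precip_summer = -55,
                           d2H_precip_event_sd = 4, An_noise_sd = 0.05,
                           cloud_persistence = 0.5, cloud_sd = 1,
                           RH_cloud_gain = 25,
                           An_day_sd = 0.15, An_day_coef = 0.3) {
  as.list(environment())
}

# Fixed-offset timezone used for all synthetic timestamps (UTC+2).
ISO_TZ <- "Etc/GMT-2"

#' Simulate half-hourly boreal forcings
#'
#' Generates a complete 30-min forcing series between two dates:
#' air temperature, relative humidity, ambient vapor pressure, transpiration
#' and net assimilation (daytime light-response shapes, zero at night),
#' precipitation (Poisson event starts) and the isotopic composition of
#' precipitation and vapor. Identical `seed` and parameters give a
#' bit-identical series.
#'
#' @param start_date,end_date Calendar dates (coerced by [as.Date()]),
#'   inclusive.
#' @param params Parameter list from [forcing_params()].
#' @param seed Integer RNG seed.
#' @return Data frame of class `forcing_series`: `timestamp` (POSIXct,
#'   UTC+2), `RH` (percent), `T_air` (degrees C), `p_air` (kPa), `e_a`
#'   (kPa), `E` (mol m-2 s-1), `A_n` (micromol m-2 s-1), `precip` (mm per
#'   step), `d2H_precip`, `d2H_vapor` (per mil VSMOW).
#' @export
simulate_forcings <- function(start_date, end_date, params = forcing_params(),
                              seed = 1) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (start_date > end_date) stop("start_date must not exceed end_date")
  bad <- vapply(params[c("T_seasonal_amp", "T_diurnal_amp", "ar1_sd",
                         "synoptic_sd", "RH_diurnal_amp", "precip_rate",
                         "precip_mean_depth", "d2H_precip_event_sd",
                         "gs_max", "An_max", "An_noise_sd")],
                function(x) x < 0, logical(1))
  if (any(bad)) stop("amplitude/rate parameters must be non-negative: ",
                     paste(names(bad)[bad], collapse = ", "))
  set.seed(seed)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = ISO_TZ)
  t1 <- as.POSIXct(paste(end_date, "23:30:00"), tz = ISO_TZ)
  ts <- seq(t0, t1, by = 1800)
  n <- length(ts)
  if (n <= 0) stop("non-positive step count")
  doy <- as.integer(format(as.Date(ts, tz = ISO_TZ), "%j"))
  hour <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  day_index <- as.integer(as.Date(ts, tz = ISO_TZ) - start_date) + 1L
  n_days <- max(day_index)

  seasonal_shape <- -cos(2 * pi * (doy - 15) / 365)  # min mid-Jan, max mid-Jul
  diurnal_shape <- sin(2 * pi * (hour - 9) / 24)     # max 15:00, min 03:00

  # day-scale synoptic anomaly (AR(1) across days, stationary SD synoptic_sd)
  syn_day <- numeric(n_days)
  innov_sd <- params$synoptic_sd * sqrt(1 - params$synoptic_coef^2)
  if (n_days > 0) {
    syn_day[1] <- stats::rnorm(1, 0, params$synoptic_sd)
    if (n_days > 1) {
      for (d in 2:n_days) {
        syn_day[d] <- params$synoptic_coef * syn_day[d - 1] +
          stats::rnorm(1, 0, innov_sd)
      }
    }
  }
  syn <- syn_day[day_index]

  # 30-min AR(1) noise, stationary SD ar1_sd
  eps <- numeric(n)
  e_innov <- params$ar1_sd * sqrt(1 - params$ar1_coef^2)
  eps[1] <- stats::rnorm(1, 0, params$ar1_sd)
  if (n > 1) {
    z <- stats::rnorm(n - 1, 0, e_innov)
    for (i in 2:n) eps[i] <- params$ar1_coef * eps[i - 1] + z[i - 1]
  }

  T_air <- params$T_mean + params$T_seasonal_amp * seasonal_shape +
    params$T_diurnal_amp * diurnal_shape + syn + eps

  # day-scale cloudiness: latent AR(1), squashed to [0.35, 1]
  # (1 = clear sky); persistence ~half a day-pair, so adjacent days differ
  ar1_days <- function(n_days, coef, sd) {
    w <- numeric(n_days)
    if (n_days == 0 || sd == 0) return(w)
    w[1] <- stats::rnorm(1, 0, sd)
    if (n_days > 1) {
      zi <- stats::rnorm(n_days - 1, 0, sd * sqrt(1 - coef^2))
      for (d in 2:n_days) w[d] <- coef * w[d - 1] + zi[d - 1]
    }
    w
  }
  cloud_latent <- ar1_days(n_days, params$cloud_persistence, params$cloud_sd)
  cloud_day <- 0.35 + 0.65 * stats::plogis(1.2 * cloud_latent)
  cloud <- cloud_day[day_index]

  RH <- params$RH_base - params$RH_diurnal_amp * diurnal_shape +
    params$RH_synoptic_gain * syn + params$RH_cloud_gain * (1 - cloud) +
    0.5 * eps
  RH <- pmin(100, pmax(20, RH))

  e_a <- RH / 100 * e_sat(T_air)

  # daytime light response: fixed 04:00-18:00 solar window (simplification)
  light <- pmax(0, sin(pi * (hour - 4) / 14))
  season_capacity <- pmax(0, seasonal_shape)  # growing-season envelope

  # stomata close with vapor-pressure deficit; assimilation capacity has its
  # own day-scale anomaly so A_n and g_t are correlated but not rank-tied
  e_i <- e_sat(T_air)
  vpd <- pmax(0, e_i - e_a)
  gs <- params$gs_max * season_capacity * light * cloud / (1 + vpd)
  E <- gs * vpd / (params$p_air - (e_i + e_a) / 2)
  an_anom <- exp(ar1_days(n_days, params$An_day_coef, params$An_day_sd))
  A_n <- params$An_max * season_capacity * light * cloud *
    an_anom[day_index] *
    pmax(0, 1 + params$An_noise_sd * stats::rnorm(n))

  precip_event <- stats::rpois(n, params$precip_rate) > 0
  precip <- ifelse(precip_event,
                   stats::rexp(n, 1 / params$precip_mean_depth), 0)

  mid <- (params$d2H_precip_winter + params$d2H_precip_summer) / 2
  amp <- (params$d2H_precip_summer - params$d2H_precip_winter) / 2
  d2H_precip <- mid + amp * seasonal_shape +
    ifelse(precip_event, stats::rnorm(n, 0, params$d2H_precip_event_sd), 0)

  # vapor in isotopic equilibrium with precipitation at air temperature
  alpha_p <- 1 + equilibrium_fractionation(pmax(-10, pmin(50, T_air))) / 1000
  d2H_vapor <- (1000 + d2H_precip) / alpha_p - 1000

  out <- data.frame(timestamp = ts, RH = RH, T_air = T_air,
                    p_air = params$p_air, e_a = e_a, E = E, A_n = A_n,
                    precip = precip, d2H_precip = d2H_precip,
                    d2H_vapor = d2H_vapor)
  class(out) <- c("forcing_series", "data.frame")
  out
}

#' Planted ground-truth signal specification
#'
#' Describes the linear response planted into synthetic sampling events:
#' the organic delta-2H of each event is
#' `beta0 + beta1 * T:driver + b_tree + eps`, where `T:driver` is the true
#' daytime-filtered windowed mean of `driver_name` ending on the sampling
#' date, `b_tree ~ N(0, sigma_tree^2)` is drawn once per tree and
#' `eps ~ N(0, sigma_eps^2)` per event.
#'
#' Defaults mirror a strong assimilation signal in current-year needle
#' sugars: slope 17 per mil per micromol m-2 s-1 on a 3-day window, with
#' tree-level SD 3 per mil and residual SD 8 per mil (intraclass
#' correlation about 0.12).
#'
#' @param driver_name Driver column or derived driver (e.g. `"A_n"`,
#'   `"RH"`, `"E"`, `"g_t"`).
#' @param window Integration length in `unit` units (>= 1 day; week 0 means
#'   the sampling day only).
#' @param unit `"days"` or `"weeks"`.
#' @param beta0 Intercept, per mil.
#' @param beta1 Slope, per mil per driver unit.
#' @param sigma_tree SD of the tree random intercept, per mil (>= 0).
#' @param sigma_eps Residual SD, per mil (>= 0).
#' @return List of class `planted_signal`.
#' @export
planted_signal <- function(driver_name = "A_n", window = 3, unit = "days",
                           beta0 = -247, beta1 = 17,
                           sigma_tree = 3, sigma_eps = 8) {
  stopifnot(sigma_tree >= 0, sigma_eps >= 0,
            window >= if (identical(unit, "weeks")) 0 else 1)
  unit <- match.arg(unit, c("days", "weeks"))
  structure(list(driver_name = driver_name, window = window, unit = unit,
                 beta0 = beta0, beta1 = beta1,
                 sigma_tree = sigma_tree, sigma_eps = sigma_eps),
            class = "planted_signal")
}

#' Biweekly sampling schedule for two needle-age cohorts
#'
#' Five trees sampled approximately once every two weeks; one-year-old
#' needles (1N) between 30 April and 8 August, current-year needles (0N)
#' between 12 June and 11 October (the cohort date windows of the study
#' design this generator emulates).
#'
#' @param trees Tree identifiers (default `"T1"`..`"T5"`).
#' @param year Season year (default 2019).
#' @param cohorts Which cohorts to schedule, subset of `c("1N", "0N")`.
#' @param interval_days Sampling interval, days (default 14).
#' @return Data frame `tree_id`, `date`, `needle_age`.
#' @export
sampling_schedule <- function(trees = paste0("T", 1:5), year = 2019,
                              cohorts = c("1N", "0N"), interval_days = 14) {
  ranges <- list(
    "1N" = as.Date(c(sprintf("%d-04-30", year), sprintf("%d-08-08", year))),
    "0N" = as.Date(c(sprintf("%d-06-12", year), sprintf("%d-10-11", year)))
  )
  out <- do.call(rbind, lapply(intersect(cohorts, names(ranges)), function(a) {
    dates <- seq(ranges[[a]][1], ranges[[a]][2], by = interval_days)
    expand.grid(tree_id = trees, date = dates, needle_age = a,
                stringsAsFactors = FALSE)
  }))
  out <- out[order(out$needle_age, out$date, out$tree_id), ]
  rownames(out) <- NULL
  out
}

#' Simulate per-tree sampling events with a planted signal
#'
#' For every scheduled (tree, date, cohort) event, generates an organic
#' delta-2H value as a linear response to the true daytime-windowed driver
#' mean ending on the sampling date, plus a tree random intercept and
#' Gaussian noise (see [planted_signal()]). The true driver values used are
#' returned in column `true_driver` so recovery can be asserted exactly.
#'
#' @param forcings Forcing series; a `g_t` column is added via
#'   [derive_conductance()] if the planted driver requires it.
#' @param planted A [planted_signal()].
#' @param schedule Sampling schedule (default [sampling_schedule()]).
#' @param response Name of the response column to create (default
#'   `"d2H_WSC"`).
#' @param extra_drivers Optional named list of daily driver series (data
#'   frames with `date` and `value`) usable as planted drivers.
#' @param seed Integer RNG seed.
#' @return Data frame of sampling events: `tree_id`, `date`, `needle_age`,
#'   the response column, `true_driver`.
#' @export
simulate_sampling <- function(forcings, planted = planted_signal(),
                              schedule = sampling_schedule(),
                              response = "d2H_WSC",
                              extra_drivers = NULL, seed = 1) {
  f_dates <- as.Date(forcings$timestamp, tz = ISO_TZ)
  if (any(schedule$date < min(f_dates)) || any(schedule$date > max(f_dates))) {
    stop("sampling schedule extends outside the forcing period")
  }
  drv <- planted$driver_name
  daily <- NULL
  if (!is.null(extra_drivers) && drv %in% names(extra_drivers)) {
    daily <- extra_drivers[[drv]]
  } else {
    if (identical(drv, "g_t") && !"g_t" %in% names(forcings)) {
      forcings <- derive_conductance(forcings)
    }
    if (!drv %in% names(forcings)) {
      stop("planted driver '", drv, "' not derivable from the forcings")
    }
  }
  set.seed(seed)
  trees <- unique(schedule$tree_id)
  b_tree <- stats::setNames(stats::rnorm(length(trees), 0, planted$sigma_tree),
                            trees)
  stats <- if (is.null(daily)) {
    daytime_daily_stats(forcings, drv)
  } else {
    daytime_daily_stats(daily)
  }
  truth <- vapply(seq_len(nrow(schedule)), function(i) {
    dates <- window_dates(schedule$date[i], planted$window, planted$unit)
    window_value(stats, dates)[["value"]]
  }, numeric(1))
  eps <- stats::rnorm(nrow(schedule), 0, planted$sigma_eps)
  out <- schedule
  out[[response]] <- planted$beta0 + planted$beta1 * truth +
    b_tree[schedule$tree_id] + eps
  out$true_driver <- truth
  rownames(out) <- NULL
  out
}
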