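#' Initialise the rooting-zone water reservoir
#'
#' A single well-mixed reservoir: storage in mm of water with one bulk
#' delta-2H. Uptake and drainage are non-fractionating; incoming
#' precipitation mixes by isotope mass balance; overflow above capacity
#' leaves at the post-mixing composition. Soil layering and evaporative
#' fractionation of the soil surface are deliberately omitted (the model's
#' job is gap-filling a slowly varying source-water signal, not soil
#' physics).
#'
#' @param storage Initial storage, mm (default: full capacity, a winter
#'   snowmelt-recharged profile).
#' @param d2H Initial composition, per mil VSMOW (default -90, a plausible
#'   boreal winter recharge value; package default, not a measurement).
#' @param capacity Maximum storage, mm.
#' @param min_storage Floor applied when demand exceeds available water, mm.
#' @return List of class `source_reservoir`.
#' @export
source_reservoir <- function(storage = 150, d2H = -90, capacity = 150,
                             min_storage = 5) {
  stopifnot(storage >= 0, storage <= capacity, is.finite(d2H),
            min_storage >= 0)
  structure(list(storage = storage, d2H = d2H, capacity = capacity,
                 min_storage = min_storage),
            class = "source_reservoir")
}

#' Advance the reservoir by one step
#'
#' Order of operations: (1) precipitation mixes in by exact isotope mass
#' balance, `d2H' = (S*d2H + P*d2H_P)/(S + P)`; (2) storage above capacity
#' overflows at the post-mixing composition; (3) uptake + drainage demand
#' (non-fractionating) reduces storage without changing `d2H`. Demand
#' exceeding available water floors storage at `min_storage` and the event
#' is flagged in attribute `"floored"`.
#'
#' @param state A [source_reservoir()].
#' @param precip_in Precipitation input, mm (>= 0).
#' @param d2H_precip Composition of the input, per mil.
#' @param outflow_demand Uptake + drainage demand, mm (>= 0).
#' @return Updated `source_reservoir`.
#' @examples
#' st <- source_reservoir(100, -90, capacity = 1000)
#' step_reservoir(st, 50, -60, 0)$d2H  # -80
#' @export
step_reservoir <- function(state, precip_in, d2H_precip, outflow_demand) {
  stopifnot(inherits(state, "source_reservoir"),
            precip_in >= 0, outflow_demand >= 0)
  s <- state$storage
  d <- state$d2H
  if (s + precip_in > 0 && precip_in > 0) {
    d <- (s * d + precip_in * d2H_precip) / (s + precip_in)
  }
  s <- s + precip_in
  if (s > state$capacity) s <- state$capacity  # overflow, post-mixing d2H
  floored <- FALSE
  if (s - outflow_demand < state$min_storage) {
    floored <- outflow_demand > 0 && (s - outflow_demand) < state$min_storage
    s <- max(state$min_storage, s - outflow_demand)
  } else {
    s <- s - outflow_demand
  }
  out <- state
  out$storage <- s
  out$d2H <- d
  if (floored) attr(out, "floored") <- TRUE
  out
}

#' Run the rooting-zone model over a forcing series
#'
#' Aggregates half-hourly forcings to daily precipitation (depth-weighted
#' delta-2H) and daily transpiration demand (mol m-2 s-1 integrated to mm
#' via the molar volume of water and a canopy scaling factor), then steps
#' the reservoir once per day. The output series starts exactly at
#' `start_date`; nothing is emitted before it, though forcings before the
#' start still drive the spin-up if present.
#'
#' @param forcings Forcing series (see [simulate_forcings()]).
#' @param init Initial [source_reservoir()].
#' @param start_date First date of the emitted series (default
#'   `"2019-04-01"`, the earliest date the downstream integration windows
#'   are allowed to touch).
#' @param uptake_scale Multiplier from leaf-area transpiration to
#'   rooting-zone extraction depth (dimensionless; default 1).
#' @return Data frame `date`, `d2H_source`, `storage_mm`, `provenance`
#'   (all `"modeled"`).
#' @export
run_source_model <- function(forcings, init = source_reservoir(),
                             start_date = "2019-04-01", uptake_scale = 1) {
  start_date <- as.Date(start_date)
  dates <- as.Date(forcings$timestamp, tz = ISO_TZ)
  udates <- sort(unique(dates))
  if (max(udates) < start_date) stop("forcings end before start_date")
  if (any(diff(udates) > 1)) stop("forcings contain a gap longer than 1 day")
  state <- init
  keep <- udates >= start_date
  res <- data.frame(date = udates[keep],
                    d2H_source = NA_real_, storage_mm = NA_real_,
                    provenance = "modeled")
  j <- 0L
  for (i in seq_along(udates)) {
    sel <- dates == udates[i]
    p <- sum(forcings$precip[sel])
    dp <- if (p > 0) {
      sum(forcings$precip[sel] * forcings$d2H_precip[sel]) / p
    } else {
      0
    }
    # mol m-2 s-1 * 1800 s * 18 g/mol / 1000 g/mm = mm per half hour
    demand <- sum(forcings$E[sel]) * 1800 * 18 / 1000 * uptake_scale
    state <- step_reservoir(state, p, dp, demand)
    if (keep[i]) {
      j <- j + 1L
      res$d2H_source[j] <- state$d2H
      res$storage_mm[j] <- state$storage
    }
  }
  res
}

#' Gap-fill the modeled source-water series with measurements
#'
#' Measured twig-water delta-2H takes precedence on its dates; modeled
#' values fill everywhere else. Each day carries a provenance flag. The mean
#' model-minus-measurement bias on measured days is attached as attribute
#' `"bias"` (reported, never corrected for).
#'
#' @param modeled Daily data frame from [run_source_model()].
#' @param measured Data frame with `date` and `d2H_source` columns (may be
#'   empty or `NULL`).
#' @return Daily data frame `date`, `d2H_source`, `provenance`.
#' @export
blend_with_measurements <- function(modeled, measured = NULL) {
  out <- modeled[, c("date", "d2H_source")]
  out$provenance <- "modeled"
  if (!is.null(measured) && nrow(measured)) {
    if (any(!measured$date %in% modeled$date)) {
      warning("measurements outside the modeled period are ignored")
      measured <- measured[measured$date %in% modeled$date, ]
    }
    idx <- match(measured$date, out$date)
    bias <- mean(out$d2H_source[idx] - measured$d2H_source)
    out$d2H_source[idx] <- measured$d2H_source
    out$provenance[idx] <- "measured"
    attr(out, "bias") <- bias
  }
  out
}
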