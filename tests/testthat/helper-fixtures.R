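# shared fixtures, built in code at test time

# constant-weather half-hourly forcing table over n_days
constant_forcings <- function(n_days = 10, T_air = 15, RH = 60, p_air = 100,
                              E = 0.001, g_t = 0.1, d2H_vapor = -160,
                              start = "2019-06-01") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "Etc/GMT-2")
  ts <- seq(t0, by = 1800, length.out = n_days * 48)
  data.frame(timestamp = ts, RH = RH, T_air = T_air, p_air = p_air,
             e_a = RH / 100 * isoneedle::e_sat(T_air), E = E, A_n = 5,
             precip = 0, d2H_precip = -90, d2H_vapor = d2H_vapor, g_t = g_t)
}

default_season <- function(seed = 1, params = forcing_params()) {
  derive_conductance(
    simulate_forcings("2019-04-01", "2019-10-15", params = params,
                      seed = seed))
}

# suppress lme4 singular-fit messages and stray optimizer-convergence
# warnings in many-seed loops (the loops assert aggregate behaviour)
quiet_lmm <- function(...) {
  suppressWarnings(suppressMessages(fit_confirmation_lmm(...)))
}
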