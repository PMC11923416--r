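#' Biosynthetic 2H fractionation defaults for n-alkanes
#'
#' Mean, minimum and maximum apparent fractionation between needle water and
#' n-alkane delta-2H used for inferring leaf water from alkanes: mean -156,
#' minimum -133, maximum -192 per mil (literature values for conifer leaf
#' wax; overridable). On the per-mil scale the ordering min >= mean >= max
#' is enforced.
#'
#' @param mean,min,max Fractionation values, per mil.
#' @return Named list with `mean`, `min`, `max`.
#' @export
epsilon_bio <- function(mean = -156, min = -133, max = -192) {
  if (!(min >= mean && mean >= max)) {
    stop("epsilon_bio ordering violated: require min >= mean >= max (per mil)")
  }
  list(mean = mean, min = min, max = max)
}

#' Solve nonexchangeable delta-2H from a two-water equilibration pair
#'
#' A sample measured after equilibration with two isotopically distinct
#' waters obeys the mixing model
#' `m = f * x(water) + (1 - f) * d2H_ne`, where `f` is the exchangeable-H
#' fraction and `x(water) = eps_exchange + d2H_water * (1 + eps_exchange/1000)`
#' is the composition of exchangeable H in equilibrium with that water.
#' Two equations in two unknowns give the closed form
#' `f = (mA - mB)/(xA - xB)` and `d2H_ne = (mA - f*xA)/(1 - f)`.
#'
#' For sugars roughly a third of H is exchangeable, so `f` outside
#' \[0, 1) is physically implausible and is flagged (`ok = FALSE`), not
#' silently returned.
#'
#' @param d2H_measured_A,d2H_measured_B Measured sample delta-2H after
#'   equilibration with waters A and B, per mil.
#' @param d2H_water_A,d2H_water_B Compositions of the equilibration waters,
#'   per mil (must differ).
#' @param eps_exchange Equilibrium enrichment of exchangeable H over water,
#'   per mil; default 80 (typical carbohydrate hydroxyl value; package
#'   default).
#' @return List `f_exch`, `d2H_ne`, `ok`.
#' @examples
#' solve_nonexchangeable(-99.2, -138.08, 0, -100)  # f = 0.36, d2H_ne = -200
#' @export
solve_nonexchangeable <- function(d2H_measured_A, d2H_measured_B,
                                  d2H_water_A, d2H_water_B,
                                  eps_exchange = 80) {
  if (isTRUE(all.equal(d2H_water_A, d2H_water_B))) {
    stop("equilibration waters must be isotopically distinct")
  }
  xA <- eps_exchange + d2H_water_A * (1 + eps_exchange / 1000)
  xB <- eps_exchange + d2H_water_B * (1 + eps_exchange / 1000)
  f <- (d2H_measured_A - d2H_measured_B) / (xA - xB)
  if (any(abs(1 - f) < 1e-12)) {
    return(list(f_exch = f, d2H_ne = NA_real_, ok = FALSE))
  }
  ne <- (d2H_measured_A - f * xA) / (1 - f)
  list(f_exch = f, d2H_ne = ne, ok = all(f >= 0 & f < 1))
}

#' Forward two-water equilibration model
#'
#' Inverse companion of [solve_nonexchangeable()]: predicts the measured
#' composition of a sample with exchangeable fraction `f_exch` and
#' nonexchangeable composition `d2H_ne` equilibrated with a given water.
#'
#' @inheritParams solve_nonexchangeable
#' @param f_exch Exchangeable-H fraction.
#' @param d2H_ne Nonexchangeable delta-2H, per mil.
#' @param d2H_water Equilibration water delta-2H, per mil.
#' @return Predicted measured delta-2H, per mil.
#' @export
equilibrated_measurement <- function(f_exch, d2H_ne, d2H_water,
                                     eps_exchange = 80) {
  x <- eps_exchange + d2H_water * (1 + eps_exchange / 1000)
  f_exch * x + (1 - f_exch) * d2H_ne
}

#' Remove the alpha-amylase contribution from starch measurements
#'
#' Enzymatic starch hydrolysis leaves a known mass fraction of alpha-amylase
#' in the analyte; its delta-2H is unmixed by exact mass balance
#' `d2H_starch = (d2H_mix - w * d2H_amylase) / (1 - w)`. Concentrations are
#' corrected by the same fraction.
#'
#' @param d2H_mix Measured delta-2H of the starch + amylase mixture, per
#'   mil.
#' @param w_amylase Amylase mass fraction in \[0, 1).
#' @param d2H_amylase Measured amylase delta-2H, per mil.
#' @param conc_mix Optional measured concentration of the mixture; if given,
#'   the amylase-free concentration `conc_mix * (1 - w_amylase)` is returned
#'   alongside.
#' @return Corrected starch delta-2H (per mil), or a list with `d2H_starch`
#'   and `conc_starch` when `conc_mix` is supplied.
#' @examples
#' amylase_unmix(-150, 0.2, -100)  # -162.5
#' @export
amylase_unmix <- function(d2H_mix, w_amylase, d2H_amylase, conc_mix = NULL) {
  if (any(w_amylase < 0 | w_amylase >= 1)) {
    stop("amylase mass fraction must lie in [0, 1)")
  }
  d2H_starch <- (d2H_mix - w_amylase * d2H_amylase) / (1 - w_amylase)
  if (is.null(conc_mix)) {
    d2H_starch
  } else {
    list(d2H_starch = d2H_starch, conc_starch = conc_mix * (1 - w_amylase))
  }
}

#' Abundance-weighted mean alkane delta-2H
#'
#' Concentration-weighted mean delta-2H over the dominant odd-chain
#' homologues (n-C25, n-C27, n-C29). Chains with `NA` composition are
#' excluded together with their weights.
#'
#' @param conc Per-chain concentrations, micrograms per gram (>= 0).
#' @param d2H Per-chain delta-2H, per mil.
#' @return Weighted mean delta-2H, per mil.
#' @examples
#' weighted_alkane_mean(c(10, 5, 5), c(-190, -200, -180))  # -190
#' @export
weighted_alkane_mean <- function(conc, d2H) {
  stopifnot(length(conc) == length(d2H))
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  ok <- !is.na(conc) & !is.na(d2H)
  if (!any(ok) || sum(conc[ok]) <= 0) {
    stop("no chain with positive concentration")
  }
  sum(conc[ok] * d2H[ok]) / sum(conc[ok])
}

#' Infer needle-water delta-2H from alkane delta-2H via epsilon_bio
#'
#' Exact ratio algebra: with apparent fractionation `eps_bio` between
#' needle water and alkanes,
#' `d2H_n_water = (d2H_alkane - eps_bio) / (1 + eps_bio/1000)`.
#' [apply_epsilon_bio()] is the forward map; the round trip is exact.
#'
#' @param d2H_alkane Alkane delta-2H, per mil.
#' @param eps_bio Apparent biosynthetic fractionation, per mil (> -1000);
#'   see [epsilon_bio()] for defaults.
#' @return Inferred needle-water delta-2H, per mil.
#' @examples
#' invert_epsilon_bio(-192.5, -156)  # -43.25
#' @export
invert_epsilon_bio <- function(d2H_alkane, eps_bio = epsilon_bio()$mean) {
  if (any(eps_bio <= -1000)) stop("eps_bio must exceed -1000 per mil")
  (d2H_alkane - eps_bio) / (1 + eps_bio / 1000)
}

#' @rdname invert_epsilon_bio
#' @param d2H_n_water Needle-water delta-2H, per mil.
#' @export
apply_epsilon_bio <- function(d2H_n_water, eps_bio = epsilon_bio()$mean) {
  eps_bio + d2H_n_water * (1 + eps_bio / 1000)
}

#' Flag replicate precision failures
#'
#' Analytical acceptance rule: replicate delta-2H SDs above 2 per mil are
#' flagged for inspection (never auto-dropped).
#'
#' @param sd_replicates Replicate standard deviations, per mil.
#' @param limit Acceptance limit, per mil (default 2).
#' @return Logical vector, `TRUE` where precision is acceptable.
#' @export
precision_ok <- function(sd_replicates, limit = 2) {
  is.na(sd_replicates) | sd_replicates <= limit
}
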