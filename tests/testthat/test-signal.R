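test_that("spearman matches hand ranks and the rank-Pearson oracle", {
  sp <- spearman(1:4, c(2, 1, 4, 3))
  expect_equal(sp$rho, 0.6)  # 1 - 6*4/(4*15)
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  # brute-force oracle: Pearson correlation of midranks, with ties
  set.seed(41)
  for (i in 1:30) {
    x <- sample(1:6, 12, replace = TRUE) + rnorm(12, 0, 0.01)
    y <- sample(1:4, 12, replace = TRUE)
    if (sd(y) == 0) next
    oracle <- cor(rank(x), rank(y), method = "pearson")
    expect_equal(spearman(x, y)$rho, oracle, tolerance = 1e-12)
  }
})

test_that("small-sample p-values agree with the exact null distribution", {
  # tie-free case: compare with the exact distribution in cor.test
  x <- c(3, 1, 4, 5, 2, 6)
  y <- c(2, 1, 5, 6, 4, 3)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  sp <- spearman(x, y)
  expect_equal(sp$rho, unname(ref$estimate))
  expect_equal(sp$p, ref$p.value, tolerance = 1e-12)
  # large-sample branch against the t reference
  set.seed(3)
  x2 <- rnorm(30); y2 <- x2 + rnorm(30)
  ref2 <- cor.test(x2, y2, method = "spearman", exact = FALSE,
                   continuity = FALSE)
  sp2 <- spearman(x2, y2)
  expect_equal(sp2$rho, unname(ref2$estimate), tolerance = 1e-12)
  expect_equal(sp2$p, ref2$p.value, tolerance = 1e-6)
})

test_that("degenerate correlation inputs are flagged or rejected", {
  expect_error(spearman(1:2, 2:3), "at least 3")
  s <- spearman(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(s$rho))
  expect_equal(s$flag, "constant")
})

test_that("Holm adjustment matches the brute-force step-down closure", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  # brute-force step-down definition, applied to every input ordering
  brute_holm <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- cummax((m - seq_len(m) + 1) * p[o])
    adj <- pmin(1, adj)
    out <- numeric(m)
    out[o] <- adj
    out
  }
  p6 <- c(0.001, 0.008, 0.02, 0.04, 0.2, 0.7)
  perms <- isoneedle:::permutations_of(6)
  base <- holm_adjust(p6)
  for (i in seq_len(nrow(perms))) {
    pp <- p6[perms[i, ]]
    got <- holm_adjust(pp)
    expect_equal(got, brute_holm(pp))
    # order invariance: the same p gets the same adjusted value
    expect_equal(got[order(perms[i, ])], base)
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("grid cardinality is the full compound x age x driver x window cross", {
  fc <- default_season(seed = 3)
  ev <- simulate_sampling(fc, seed = 4)
  drivers <- list(RH = fc[, c("timestamp", "RH")],
                  A_n = fc[, c("timestamp", "A_n")])
  tab <- build_integration_table(ev, drivers, 1:5)
  g <- correlation_grid(tab, ev, "d2H_WSC")
  expect_equal(nrow(g), 2 * 2 * 5)  # 2 ages x 2 drivers x 5 windows
  expect_true(all(g$p_adj >= g$p_raw - 1e-15))
  expect_true(all(g$p_adj <= 1 & g$p_adj >= 0))
  expect_true(all(abs(g$rho) <= 1))
})

test_that("a planted signal is the strongest cell with the right sign", {
  fc <- default_season(seed = 17)
  ps <- planted_signal(driver_name = "RH", window = 3, beta0 = -150,
                       beta1 = 2, sigma_tree = 0.5, sigma_eps = 0.5)
  ev <- simulate_sampling(fc, planted = ps, seed = 18)
  drivers <- list(RH = fc[, c("timestamp", "RH")],
                  E = fc[, c("timestamp", "E")],
                  A_n = fc[, c("timestamp", "A_n")])
  tab <- build_integration_table(ev, drivers, 1:5)
  g <- correlation_grid(tab, ev, "d2H_WSC")
  top <- g[which.max(abs(g$rho)), ]
  expect_equal(top$driver, "RH")
  expect_equal(top$window, 3)
  expect_gt(top$rho, 0)
  # negative slope flips the sign
  psn <- planted_signal(driver_name = "RH", window = 3, beta0 = -150,
                        beta1 = -2, sigma_tree = 0.5, sigma_eps = 0.5)
  evn <- simulate_sampling(fc, planted = psn, seed = 18)
  gn <- correlation_grid(tab, evn, "d2H_WSC")
  expect_lt(gn[which.max(abs(gn$rho)), "rho"], 0)
})

test_that("familywise error stays controlled under the null", {
  fc <- default_season(seed = 99)
  drivers <- list(RH = fc[, c("timestamp", "RH")],
                  A_n = fc[, c("timestamp", "A_n")])
  sched <- sampling_schedule()
  tab <- build_integration_table(sched, drivers, 1:5)
  fam_hits <- 0; fam_total <- 0
  for (s in 1:100) {
    set.seed(s)
    ev <- sched
    ev$d2H_WSC <- rnorm(nrow(sched), -170, 10)
    g <- correlation_grid(tab, ev, "d2H_WSC")
    fam <- interaction(g$needle_age, g$driver, drop = TRUE)
    for (f in levels(fam)) {
      fam_total <- fam_total + 1
      if (any(g$p_adj[fam == f] < 0.05, na.rm = TRUE)) fam_hits <- fam_hits + 1
    }
  }
  expect_lte(fam_hits / fam_total, 0.07)
})

test_that("prevailing-signal selection ranks and reports co-leaders", {
  g <- data.frame(response = "d2H_alkane", needle_age = "1N",
                  driver = c("RH", "d2H_source", "A_n"),
                  window = c(10, 5, 2), unit = "weeks",
                  rho = c(-0.80, -0.78, -0.50),
                  p_raw = c(1e-4, 2e-4, 0.2), p_adj = c(1e-3, 2e-3, 0.4),
                  n = 40)
  class(g) <- c("correlation_grid", "data.frame")
  sel <- select_prevailing(g, tie_band = 0.04)
  expect_equal(nrow(sel), 2)           # A_n not significant
  expect_true(all(sel$co_leader))      # 0.78 within 0.04 of 0.80
  expect_equal(sel$driver[1], "RH")    # ranked by |rho|
  # single significant cell is the sole selection
  g2 <- g; g2$p_adj <- c(0.01, 0.3, 0.4)
  sel2 <- select_prevailing(g2)
  expect_equal(nrow(sel2), 1)
  # nothing significant -> explicit empty selection
  g3 <- g; g3$p_adj <- rep(0.5, 3)
  expect_equal(nrow(select_prevailing(g3)), 0)
})

test_that("grid and selection print methods summarise without error", {
  g <- data.frame(response = "d2H_WSC", needle_age = "0N", driver = "A_n",
                  window = 1:3, unit = "days", rho = c(0.9, 0.95, 0.85),
                  p_raw = c(1e-5, 1e-6, 1e-4), p_adj = c(2e-5, 3e-6, 1e-4),
                  n = 40)
  class(g) <- c("correlation_grid", "data.frame")
  expect_output(print(g), "cells")
  expect_output(summary(g), "strongest")
  expect_output(print(select_prevailing(g)), "Prevailing")
})
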