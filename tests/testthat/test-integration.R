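test_that("window dates end on the sampling date, inclusive", {
  expect_equal(window_dates(as.Date("2019-06-12"), 2, "days"),
               as.Date(c("2019-06-11", "2019-06-12")), ignore_attr = TRUE)
  expect_equal(window_dates(as.Date("2019-06-12"), 1, "days"),
               as.Date("2019-06-12"), ignore_attr = TRUE)
  # week 0 means the sampling day alone
  expect_equal(window_dates(as.Date("2019-06-12"), 0, "weeks"),
               as.Date("2019-06-12"), ignore_attr = TRUE)
  w2 <- window_dates(as.Date("2019-06-12"), 2, "weeks")
  expect_length(w2, 14)
  expect_equal(max(w2), as.Date("2019-06-12"))
})

test_that("windows are clipped at the floor date and flagged", {
  d <- window_dates(as.Date("2019-04-30"), 10, "weeks",
                    floor_date = "2019-04-01")
  expect_true(attr(d, "truncated"))
  expect_equal(min(d), as.Date("2019-04-01"))
  expect_length(d, 30)  # ~4.3 weeks remain of the requested 10
  d2 <- window_dates(as.Date("2019-08-06"), 2, "days",
                     floor_date = "2019-04-01")
  expect_false(attr(d2, "truncated"))
  expect_error(window_dates(as.Date("2019-06-12"), 0, "days"), ">= 1 day")
})

test_that("daytime window means pool half-hours exactly", {
  fc <- constant_forcings(3)
  # day 1 daytime mean 10, day 2 daytime mean 20 -> pooled 15
  d <- as.Date(fc$timestamp, tz = "Etc/GMT-2")
  hr <- as.integer(format(fc$timestamp, "%H"))
  fc$X <- NA_real_
  fc$X[d == as.Date("2019-06-01") & hr >= 9 & hr < 15] <- 10
  fc$X[d == as.Date("2019-06-02") & hr >= 9 & hr < 15] <- 20
  res <- integrate_driver(fc, "X", as.Date(c("2019-06-01", "2019-06-02")))
  expect_equal(res$value, 15)
  expect_equal(res$n_halfhours, 24)
  # constant series gives the constant for every window
  res2 <- integrate_driver(fc, "RH", as.Date("2019-06-01") + 0:2)
  expect_equal(res2$value, 60)
  # all values outside the daytime interval -> absent
  fc$Y <- ifelse(hr >= 9 & hr < 15, NA, 1)
  res3 <- integrate_driver(fc, "Y", as.Date("2019-06-01"))
  expect_true(is.na(res3$value))
  expect_equal(res3$n_halfhours, 0)
})

test_that("the daytime filter is half-open [09:00, 15:00)", {
  fc <- constant_forcings(1)
  hr <- as.integer(format(fc$timestamp, "%H"))
  mn <- as.integer(format(fc$timestamp, "%M"))
  res <- integrate_driver(fc, "RH", as.Date("2019-06-01"))
  expect_equal(res$n_halfhours, 12)  # 09:00 ... 14:30, not 15:00
})

test_that("daily drivers skip the daytime filter", {
  daily <- data.frame(date = as.Date("2019-06-01") + 0:9, value = 1:10)
  res <- integrate_driver(daily, dates = as.Date("2019-06-03") + 0:1)
  expect_equal(res$value, 3.5)
  expect_equal(res$n_halfhours, 2)
})

test_that("the integration table is a full deterministic cross", {
  fc <- constant_forcings(40, start = "2019-06-01")
  ev <- data.frame(tree_id = "T1", date = as.Date("2019-07-05"),
                   needle_age = "0N")
  tab <- build_integration_table(ev, list(RH = fc[, c("timestamp", "RH")]),
                                 windows = 1:5, floor_date = "2019-06-01")
  expect_equal(nrow(tab), 5)
  tabw <- build_integration_table(ev, list(RH = fc[, c("timestamp", "RH")]),
                                  windows = 0:10, unit = "weeks",
                                  floor_date = "2019-06-01")
  expect_equal(nrow(tabw), 11)  # week 0 included
  # event 2019-07-05 with floor 2019-06-01: a 5-week window starts exactly
  # on the floor; only longer windows are clipped
  expect_true(all(tabw$truncated[tabw$window >= 6]))
  expect_false(any(tabw$truncated[tabw$window <= 5]))
  # identical rebuild
  expect_identical(tab, build_integration_table(
    ev, list(RH = fc[, c("timestamp", "RH")]), windows = 1:5,
    floor_date = "2019-06-01"))
})

test_that("longer windows are convex combinations of shorter ones", {
  fc <- default_season(seed = 9)
  ev <- data.frame(tree_id = "T1", date = as.Date("2019-07-20"),
                   needle_age = "0N")
  tab <- build_integration_table(ev, list(A_n = fc[, c("timestamp", "A_n")]),
                                 windows = 1:5)
  day_means <- vapply(1:5, function(k) {
    integrate_driver(fc, "A_n", ev$date - (k - 1))$value
  }, numeric(1))
  for (k in 2:5) {
    v_k <- tab$value[tab$window == k]
    v_prev <- tab$value[tab$window == k - 1]
    # pooled mean = weighted mean of previous window and the added day
    lam <- (k - 1) / k
    expect_equal(v_k, lam * v_prev + (1 - lam) * day_means[k],
                 tolerance = 1e-12)
    expect_true(v_k >= min(v_prev, day_means[k]) - 1e-12)
    expect_true(v_k <= max(v_prev, day_means[k]) + 1e-12)
  }
})

test_that("low-coverage windows are flagged, not dropped", {
  fc <- constant_forcings(10)
  fc$RH[format(fc$timestamp, "%d") %in% c("04", "05")] <- NA
  ev <- data.frame(tree_id = "T1", date = as.Date("2019-06-05"),
                   needle_age = "0N")
  tab <- build_integration_table(ev, list(RH = fc[, c("timestamp", "RH")]),
                                 windows = 1:3, floor_date = "2019-06-01")
  expect_true(is.na(tab$value[tab$window == 1]))
  expect_true(tab$low_coverage[tab$window == 1])
  expect_true(tab$low_coverage[tab$window == 2])
  expect_false(tab$low_coverage[tab$window == 3])  # 1 of 3 days present
})
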