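#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation using midranks for ties: `rho` is the Pearson
#' correlation of the rank vectors. The p-value (two-sided, against
#' rho = 0) is exact by full permutation enumeration for `n <= 7`
#' (at most 5040 permutations; valid under ties, unlike the classical
#' null tables), and the large-sample t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y Paired numeric vectors; pairs with any `NA` are dropped,
#'   at least 3 complete pairs are required.
#' @return List `rho`, `p`, `n`. Constant `x` or `y` gives `rho = NA` with
#'   `flag = "constant"`.
#' @examples
#' spearman(1:4, c(2, 1, 4, 3))$rho  # 0.6
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = "constant"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cov(rx, ry) / (stats::sd(rx) * stats::sd(ry))
  if (n <= 7) {
    perms <- permutations_of(n)
    obs <- abs(rho)
    count <- 0L
    srx <- (rx - mean(rx)) / stats::sd(rx)
    sry <- (ry - mean(ry)) / stats::sd(ry)
    for (i in seq_len(nrow(perms))) {
      r <- sum(srx * sry[perms[i, ]]) / (n - 1)
      if (abs(r) >= obs - 1e-12) count <- count + 1L
    }
    p <- count / nrow(perms)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(1, p), n = n)
}

# all permutations of 1..n as a matrix (n! rows); n <= 7 in practice
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Holm step-down adjustment of p-values
#'
#' Familywise-error control over a family of tests: sort ascending, take
#' the running maximum of `(m - i + 1) * p_(i)`, cap at 1, return in the
#' original order. Delegates to [stats::p.adjust()].
#'
#' @param p Vector of p-values in \[0, 1\] (`NA` preserved).
#' @return Adjusted p-values, same order as input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Screen every driver x window against each compound response
#'
#' Spearman rank correlation between each response column and every
#' (driver, window) predictor in the integration table, within needle-age
#' cohorts. Holm adjustment is applied within families; the default family
#' is one compound x cohort x driver across its windows (the multiple
#' comparisons arise from trying many integration lengths of the same
#' driver). Setting `family = "global"` pools all drivers of a compound x
#' cohort into one stricter family.
#'
#' @param table An [build_integration_table()] result.
#' @param events Sampling events carrying the response columns.
#' @param responses Character vector of response column names present in
#'   `events`.
#' @param family `"per_driver"` (default) or `"global"`.
#' @return Data frame of class `correlation_grid`: `response`,
#'   `needle_age`, `driver`, `window`, `unit`, `rho`, `p_raw`, `p_adj`,
#'   `n`.
#' @export
correlation_grid <- function(table, events, responses,
                             family = c("per_driver", "global")) {
  family <- match.arg(family)
  stopifnot(all(responses %in% names(events)))
  key_ev <- interaction(events$tree_id, events$date, events$needle_age,
                        drop = FALSE)
  combos <- unique(table[, c("driver", "window", "unit", "needle_age")])
  rows <- list()
  for (resp in responses) {
    for (i in seq_len(nrow(combos))) {
      cb <- combos[i, ]
      sub <- table[table$driver == cb$driver & table$window == cb$window &
                     table$needle_age == cb$needle_age, ]
      key_tb <- interaction(sub$tree_id, sub$date, sub$needle_age,
                            drop = FALSE)
      idx <- match(key_tb, key_ev)
      y <- events[[resp]][idx]
      keep <- !is.na(y) & !is.na(sub$value)
      if (sum(keep) < 3) next
      sp <- spearman(sub$value[keep], y[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, needle_age = cb$needle_age, driver = cb$driver,
        window = cb$window, unit = cb$unit,
        rho = sp$rho, p_raw = sp$p, p_adj = NA_real_, n = sp$n)
    }
  }
  grid <- do.call(rbind, rows)
  fam <- if (family == "per_driver") {
    interaction(grid$response, grid$needle_age, grid$driver, drop = TRUE)
  } else {
    interaction(grid$response, grid$needle_age, drop = TRUE)
  }
  for (f in levels(fam)) {
    sel <- fam == f
    grid$p_adj[sel] <- holm_adjust(grid$p_raw[sel])
  }
  rownames(grid) <- NULL
  class(grid) <- c("correlation_grid", "data.frame")
  grid
}

#' Select prevailing signals from a correlation grid
#'
#' Per response x cohort: cells significant after Holm adjustment
#' (`p_adj < alpha`) ranked by absolute rho; every cell whose absolute rho
#' lies within `tie_band` of the leader is reported as a co-leading signal
#' (rank differences that small are not interpretable).
#'
#' @param grid A [correlation_grid()].
#' @param alpha Significance level (default 0.05).
#' @param tie_band Width of the co-leader band on absolute rho (default
#'   0.04).
#' @return Data frame of class `signal_selection` with the significant
#'   cells, a logical `co_leader` column, and an empty (zero-row) frame
#'   when nothing is significant.
#' @export
select_prevailing <- function(grid, alpha = 0.05, tie_band = 0.04) {
  stopifnot(nrow(grid) > 0)
  groups <- split(seq_len(nrow(grid)),
                  interaction(grid$response, grid$needle_age, drop = TRUE))
  rows <- list()
  for (g in groups) {
    sig <- g[!is.na(grid$p_adj[g]) & grid$p_adj[g] < alpha]
    if (!length(sig)) next
    sub <- grid[sig, ]
    sub <- sub[order(-abs(sub$rho)), ]
    top <- abs(sub$rho[1])
    sub$co_leader <- abs(sub$rho) >= top - tie_band
    rows[[length(rows) + 1L]] <- sub
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    cbind(grid[0, ], co_leader = logical(0))
  }
  rownames(out) <- NULL
  class(out) <- c("signal_selection", "data.frame")
  out
}

#' @export
print.correlation_grid <- function(x, ...) {
  cat("Correlation grid:", nrow(x), "cells;",
      sum(x$p_adj < 0.05, na.rm = TRUE), "significant at p_adj < 0.05\n")
  invisible(x)
}

#' @export
summary.correlation_grid <- function(object, ...) {
  groups <- split(object, interaction(object$response, object$needle_age,
                                      drop = TRUE))
  for (g in groups) {
    best <- g[which.max(abs(g$rho)), ]
    cat(sprintf("%s %s: strongest |rho| = %.2f at %s, %d %s (p_adj = %.3g)\n",
                best$response, best$needle_age, abs(best$rho), best$driver,
                best$window, best$unit, best$p_adj))
  }
  invisible(object)
}

#' @export
print.signal_selection <- function(x, ...) {
  needed <- c("co_leader", "response", "needle_age", "driver", "window",
              "unit", "rho", "p_adj")
  if (!all(needed %in% names(x))) {  # column-subset views print plainly
    print.data.frame(x, ...)
    return(invisible(x))
  }
  if (!nrow(x)) {
    cat("No significant signals.\n")
  } else {
    cat("Prevailing signals (co-leaders marked *):\n")
    for (i in seq_len(nrow(x))) {
      cat(sprintf(" %s %s %s ~ %s @ %d %s  rho = %+.2f  p_adj = %.3g\n",
                  if (x$co_leader[i]) "*" else " ",
                  x$response[i], x$needle_age[i], x$driver[i], x$window[i],
                  x$unit[i], x$rho[i], x$p_adj[i]))
    }
  }
  invisible(x)
}

#' Plot a correlation grid as a rho heat map
#'
#' Driver x window image of Spearman rho for one response and cohort, with
#' cells annotated and significant cells (Holm-adjusted p < alpha) boxed.
#'
#' @param x A [correlation_grid()].
#' @param response,needle_age Which panel to draw (defaults: first present).
#' @param alpha Significance level for boxing.
#' @param ... Unused.
#' @export
plot.correlation_grid <- function(x, response = x$response[1],
                                  needle_age = x$needle_age[1],
                                  alpha = 0.05, ...) {
  sub <- x[x$response == response & x$needle_age == needle_age, ]
  drivers <- unique(sub$driver)
  windows <- sort(unique(sub$window))
  m <- matrix(NA_real_, length(windows), length(drivers),
              dimnames = list(windows, drivers))
  for (i in seq_len(nrow(sub))) {
    m[as.character(sub$window[i]), sub$driver[i]] <- sub$rho[i]
  }
  pal <- grDevices::hcl.colors(21, "Blue-Red 3", rev = TRUE)
  graphics::image(seq_along(windows), seq_along(drivers), m,
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "integration window", ylab = "",
                  main = paste(response, needle_age))
  graphics::axis(1, seq_along(windows), windows)
  graphics::axis(2, seq_along(drivers), drivers, las = 2, cex.axis = 0.8)
  for (i in seq_len(nrow(sub))) {
    xi <- match(sub$window[i], windows)
    yi <- match(sub$driver[i], drivers)
    graphics::text(xi, yi, sprintf("%.2f", sub$rho[i]), cex = 0.6)
    if (!is.na(sub$p_adj[i]) && sub$p_adj[i] < alpha) {
      graphics::rect(xi - 0.5, yi - 0.5, xi + 0.5, yi + 0.5, lwd = 2)
    }
  }
  invisible(x)
}
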