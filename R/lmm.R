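#' Confirm a screened signal with a random-intercept mixed model
#'
#' REML fit of `response ~ predictor` with random intercepts for tree
#' identity and, optionally, sampling date (`random = c("tree", "date")`;
#' alkane responses typically need the more parsimonious tree-only
#' structure). Variance components are turned into the standard
#' pseudo-R-squared summaries:
#' \deqn{R^2_M = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)}
#' \deqn{R^2_C = (\sigma^2_f + \sigma^2_r) / (\sigma^2_f + \sigma^2_r + \sigma^2_e)}
#' \deqn{ICC = \sigma^2_r / (\sigma^2_r + \sigma^2_e)}
#' where `sigma2_f` is the variance of the fixed-effect fitted values,
#' `sigma2_r` the sum of the random-intercept variances and `sigma2_e` the
#' residual variance.
#'
#' @param data Data frame with the response, predictor, `tree_id` and
#'   `date` columns.
#' @param response,predictor Column names.
#' @param random Random-intercept factors, subset of `c("tree", "date")`.
#' @param exclude Optional logical vector or row indices to drop before
#'   fitting (e.g. an out-of-season sampling event).
#' @return Object of class `iso_lmm`: list with `fit` (the lme4 fit),
#'   `coef` (intercept/slope with SEs), `varcomp` (named components),
#'   `R2M`, `R2C`, `ICC`, `singular` flag, `n`.
#' @export
fit_confirmation_lmm <- function(data, response, predictor,
                                 random = c("tree", "date"),
                                 exclude = NULL) {
  random <- match.arg(random, c("tree", "date"), several.ok = TRUE)
  if (!is.null(exclude)) {
    if (is.logical(exclude)) data <- data[!exclude, ] else data <- data[-exclude, ]
  }
  data <- data[stats::complete.cases(data[, c(response, predictor)]), ]
  for (r in random) {
    col <- if (r == "tree") "tree_id" else "date"
    if (length(unique(data[[col]])) < 2) {
      stop("need >= 2 groups for random factor '", r, "' after exclusions")
    }
  }
  terms <- c(if ("tree" %in% random) "(1 | tree_id)",
             if ("date" %in% random) "(1 | date)")
  fml <- stats::as.formula(paste(response, "~", predictor, "+",
                                 paste(terms, collapse = " + ")))
  fit <- lme4::lmer(fml, data = data, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_r <- sum(vc$vcov[vc$grp != "Residual"])
  sigma2_e <- vc$vcov[vc$grp == "Residual"]
  fixed_fitted <- stats::model.matrix(fit) %*% lme4::fixef(fit)
  sigma2_f <- stats::var(as.numeric(fixed_fitted))
  denom <- sigma2_f + sigma2_r + sigma2_e
  co <- summary(fit)$coefficients
  out <- list(
    fit = fit,
    response = response, predictor = predictor, random = random,
    coef = data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], row.names = NULL),
    varcomp = c(fixed = sigma2_f, random = sigma2_r, residual = sigma2_e),
    R2M = sigma2_f / denom,
    R2C = (sigma2_f + sigma2_r) / denom,
    ICC = if (sigma2_r + sigma2_e > 0) sigma2_r / (sigma2_r + sigma2_e) else 0,
    singular = lme4::isSingular(fit),
    n = nrow(data)
  )
  class(out) <- "iso_lmm"
  out
}

#' @export
print.iso_lmm <- function(x, ...) {
  cat(sprintf("Mixed model: %s ~ %s + (1 | %s)\n", x$response, x$predictor,
              paste(x$random, collapse = ") + (1 | ")))
  sl <- x$coef[2, ]
  cat(sprintf("  slope = %.2f +/- %.2f   intercept = %.2f +/- %.2f   n = %d\n",
              sl$estimate, sl$se, x$coef$estimate[1], x$coef$se[1], x$n))
  cat(sprintf("  R2(M) = %.2f   R2(C) = %.2f   ICC = %.2f%s\n",
              x$R2M, x$R2C, x$ICC,
              if (x$singular) "   [singular fit]" else ""))
  invisible(x)
}

#' @export
summary.iso_lmm <- function(object, ...) {
  print(object)
  cat("Variance components:\n")
  print(round(object$varcomp, 4))
  invisible(object)
}

#' @export
coef.iso_lmm <- function(object, ...) {
  stats::setNames(object$coef$estimate, object$coef$term)
}

#' Confidence interval for the fixed slope
#'
#' Wald interval `estimate +/- z * SE` on the predictor's fixed slope.
#'
#' @param object An `iso_lmm`.
#' @param parm Ignored (slope only).
#' @param level Coverage (default 0.95).
#' @param ... Unused.
#' @return Length-2 vector (lower, upper).
#' @export
confint.iso_lmm <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  sl <- object$coef[2, ]
  c(lower = sl$estimate - z * sl$se, upper = sl$estimate + z * sl$se)
}
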