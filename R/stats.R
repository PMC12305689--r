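#' Linear dose-response fit with Wald test
#'
#' Ordinary least-squares regression of mean ROI GFAP+ fraction on
#' prescription dose, with a two-sided Wald test of the slope against zero
#' using the t distribution on n - 2 degrees of freedom (significance
#' level 0.05), as in the study's statistical analysis.
#'
#' @param doses numeric vector of prescription doses (Gy); at least two
#'   distinct values.
#' @param fractions numeric vector of mean ROI fractions, same length
#'   (n >= 3).
#' @param alpha significance level for the reported decision.
#' @return An object of class `dose_response_fit` with fields `slope`
#'   (fraction per Gy), `intercept`, `slope_se`, `intercept_se`,
#'   `p_value`, `r_value` (Pearson correlation), `n`, `df`, `alpha`,
#'   `significant`, and the data (`doses`, `fractions`).
#' @export
fit_dose_response <- function(doses, fractions, alpha = 0.05) {
  doses <- as.numeric(doses); fractions <- as.numeric(fractions)
  if (length(doses) != length(fractions)) stop("inputs must have equal length")
  if (anyNA(doses) || anyNA(fractions)) stop("missing values are not allowed")
  n <- length(doses)
  if (n < 3L) stop("at least 3 points are required")
  if (length(unique(doses)) < 2L)
    stop("all doses identical: slope is undefined")
  fit <- lm(fractions ~ doses)
  # degenerate exact fits warn in summary.lm; they are handled explicitly below
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["doses", "Estimate"]
  se <- cf["doses", "Std. Error"]
  if (se == 0 || !is.finite(cf["doses", "Pr(>|t|)"])) {
    # degenerate exact fits: zero residual variance
    p <- if (slope == 0) 1 else 0
  } else {
    p <- cf["doses", "Pr(>|t|)"]
  }
  sy <- sd(fractions)
  r <- if (sy == 0) 0 else cor(doses, fractions)
  structure(
    list(slope = slope, intercept = cf["(Intercept)", "Estimate"],
         slope_se = se, intercept_se = cf["(Intercept)", "Std. Error"],
         p_value = p, r_value = r, n = n, df = n - 2L, alpha = alpha,
         significant = p < alpha, doses = doses, fractions = fractions),
    class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Linear dose-response fit (GFAP+ fraction vs prescription dose)\n")
  cat(sprintf("  slope     %.6g +/- %.3g per Gy\n", x$slope, x$slope_se))
  cat(sprintf("  intercept %.6g +/- %.3g\n", x$intercept, x$intercept_se))
  cat(sprintf("  Wald test (t, df = %d): p = %.4g -> slope %s from 0 at alpha = %g\n",
              x$df, x$p_value,
              if (x$significant) "significantly different" else "not significantly different",
              x$alpha))
  cat(sprintf("  r = %.4f, n = %d\n", x$r_value, x$n))
  invisible(x)
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.dose_response_fit <- function(object, parm = "slope", level = 0.95, ...) {
  q <- qt(1 - (1 - level) / 2, object$df)
  est <- c(intercept = object$intercept, slope = object$slope)
  se <- c(intercept = object$intercept_se, slope = object$slope_se)
  parm <- match.arg(parm, c("slope", "intercept"), several.ok = TRUE)
  cbind(lower = est[parm] - q * se[parm], upper = est[parm] + q * se[parm])
}

#' @export
predict.dose_response_fit <- function(object, newdoses = NULL, ...) {
  if (is.null(newdoses)) newdoses <- object$doses
  object$intercept + object$slope * newdoses
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  plot(x$doses, x$fractions, xlab = "Prescription dose (Gy)",
       ylab = "Mean ROI GFAP+ fraction", pch = 19, ...)
  abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Per-dose-level hemisphere summary
#'
#' Aggregates per-slice right/left mean ROI fractions by dose level: mean
#' and sample standard deviation (n - 1 denominator) per level and side,
#' plus paired right-minus-left differences per slice. Slices missing one
#' hemisphere value are excluded with a warning.
#'
#' @param per_slice data frame with columns `slice_id`, `dose`, `right`,
#'   `left`.
#' @return An object of class `hemisphere_summary` with fields
#'   `per_level` (data frame: dose, n, right_mean, right_sd, left_mean,
#'   left_sd) and `per_slice` (input plus `diff = right - left`).
#' @export
summarize_hemispheres <- function(per_slice) {
  req <- c("slice_id", "dose", "right", "left")
  if (!all(req %in% names(per_slice)))
    stop("'per_slice' needs columns slice_id, dose, right, left")
  bad <- is.na(per_slice$right) | is.na(per_slice$left)
  if (any(bad)) {
    warning(sprintf("excluding %d slice(s) with a missing hemisphere value", sum(bad)))
    per_slice <- per_slice[!bad, , drop = FALSE]
  }
  if (nrow(per_slice) == 0L) stop("no complete slices to summarise")
  per_slice$diff <- per_slice$right - per_slice$left
  lv <- sort(unique(per_slice$dose))
  per_level <- do.call(rbind, lapply(lv, function(d) {
    s <- per_slice[per_slice$dose == d, ]
    data.frame(dose = d, n = nrow(s),
               right_mean = mean(s$right),
               right_sd = if (nrow(s) > 1) sd(s$right) else 0,
               left_mean = mean(s$left),
               left_sd = if (nrow(s) > 1) sd(s$left) else 0)
  }))
  structure(list(per_level = per_level, per_slice = per_slice),
            class = "hemisphere_summary")
}

#' @export
print.hemisphere_summary <- function(x, ...) {
  cat("Mean ROI GFAP+ fraction by dose level (right / left hemisphere)\n")
  print(x$per_level, row.names = FALSE, digits = 4)
  cat(sprintf("paired right-left difference: mean %.4g over %d slices\n",
              mean(x$per_slice$diff), nrow(x$per_slice)))
  invisible(x)
}
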