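#' Power-model dose-proportionality fit
#'
#' Fits the power model ln(y) = alpha + beta * ln(dose) by ordinary least
#' squares to subject-level (dose, value) pairs and judges dose
#' proportionality by whether the two-sided confidence interval for beta
#' (Student t, n - 2 degrees of freedom) contains 1. Natural logs are used
#' throughout; the base does not affect beta, and rescaling the dose unit
#' shifts only alpha.
#'
#' @param formula a model formula `value ~ dose` naming columns of `data`.
#' @param data data frame of subject-level observations.
#' @param range optional `c(low, high)` dose range (mg); observations
#'   outside it are dropped before fitting.
#' @param level confidence level (default 0.95).
#' @return An object of class `"power_model"` with elements `beta`,
#'   `alpha`, `ci` (length-2), `proportional` (does `ci` contain 1?),
#'   `n_obs`, `range`, `parameter` (response name), `level`, and the
#'   underlying `lm` fit.
#' @examples
#' d <- data.frame(dose = c(2, 2, 20, 20, 60, 60),
#'                 cmax = c(40, 46, 420, 470, 1100, 1280))
#' fit <- power_model(cmax ~ dose, d)
#' coef(fit); confint(fit)
#' @export
power_model <- function(formula, data, range = NULL, level = 0.95) {
  mf <- stats::model.frame(formula, data)
  y <- mf[[1L]]
  dose <- mf[[2L]]
  if (!is.null(range)) {
    stopifnot(length(range) == 2, range[1] < range[2])
    keep <- dose >= range[1] & dose <= range[2]
    y <- y[keep]; dose <- dose[keep]
  }
  if (any(y <= 0) || any(dose <= 0))
    stop("power model requires strictly positive doses and values")
  if (length(unique(dose)) < 2)
    stop("need at least 2 distinct doses in the range")
  if (length(y) < 3)
    stop("need at least 3 observations in the range")
  fit <- stats::lm(log(y) ~ log(dose))
  beta <- unname(stats::coef(fit)[2L])
  # suppressed: summary.lm warns on zero residual variance, the perfect-
  # power-law case handled explicitly below
  ci <- suppressWarnings(stats::confint(fit, level = level)[2L, ])
  # a perfect power law has zero residual variance; confint then returns
  # NaN, but the CI is degenerate at beta
  if (any(!is.finite(ci))) ci <- c(beta, beta)
  structure(list(beta = beta, alpha = unname(stats::coef(fit)[1L]),
                 ci = unname(ci),
                 proportional = ci[1] <= 1 && 1 <= ci[2],
                 n_obs = length(y), range = range %||% range(dose),
                 parameter = deparse(formula[[2L]]), level = level,
                 fit = fit),
            class = "power_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.power_model <- function(x, digits = 4, ...) {
  cat(sprintf("Power model: %s ~ dose^beta, %g-%g mg (n = %d)\n",
              x$parameter, x$range[1], x$range[2], x$n_obs))
  cat(sprintf("  beta = %s, %d%% CI (%s, %s) -> %s\n",
              signif(x$beta, digits), round(100 * x$level),
              signif(x$ci[1], digits), signif(x$ci[2], digits),
              if (x$proportional) "dose-proportional (CI contains 1)"
              else "NOT dose-proportional (CI excludes 1)"))
  invisible(x)
}

#' @export
coef.power_model <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
confint.power_model <- function(object, parm = "beta", level = NULL, ...) {
  if (!is.null(level) && level != object$level)
    return(stats::confint(object$fit, level = level)[2L, ])
  stats::setNames(object$ci, c("lower", "upper"))
}

#' @export
summary.power_model <- function(object, ...) {
  s <- summary(object$fit)
  cat(sprintf("Power-model fit for %s over %g-%g mg\n", object$parameter,
              object$range[1], object$range[2]))
  print(s$coefficients)
  cat(sprintf("beta %d%% CI: (%.4f, %.4f); proportional: %s\n",
              round(100 * object$level), object$ci[1], object$ci[2],
              object$proportional))
  invisible(s)
}

#' @export
predict.power_model <- function(object, newdose, ...) {
  exp(object$alpha + object$beta * log(newdose))
}

#' Dose-proportionality report over several dose ranges
#'
#' Fits the power model for each requested parameter and dose range,
#' producing the usual one-row-per-fit report (beta, CI bounds, verdict).
#'
#' @param results subject-level data frame (e.g. from [nca_table()]) with
#'   a `dose` column.
#' @param params parameter columns to assess (default Cmax and AUC0-inf).
#' @param ranges list of `c(low, high)` dose ranges in mg.
#' @param level confidence level.
#' @return A data frame with columns `parameter`, `range_low`,
#'   `range_high`, `n`, `beta`, `ci_lower`, `ci_upper`, `proportional`.
#' @export
dose_proportionality <- function(results,
                                 params = c("cmax", "auc_0_inf"),
                                 ranges = list(c(2, 20), c(20, 60),
                                               c(2, 60)),
                                 level = 0.95) {
  params <- intersect(params, names(results))
  rows <- list()
  for (p in params) for (r in ranges) {
    f <- stats::as.formula(paste(p, "~ dose"))
    sub <- results[!is.na(results[[p]]), , drop = FALSE]
    fit <- power_model(f, sub, range = r, level = level)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, range_low = r[1], range_high = r[2], n = fit$n_obs,
      beta = fit$beta, ci_lower = fit$ci[1], ci_upper = fit$ci[2],
      proportional = fit$proportional)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportional interpolation between two dose levels
#'
#' Linear interpolation of a parameter between two dose means, used to
#' read off the expected value at an untested intermediate dose once dose
#' proportionality has been established.
#'
#' @param dose_low,dose_high bracketing doses (mg), `dose_low <
#'   dose_high`.
#' @param value_low,value_high parameter values at the bracketing doses
#'   (positive).
#' @param dose_target dose at which to interpolate; must lie strictly
#'   inside the bracket.
#' @return Interpolated value at `dose_target`.
#' @examples
#' proportional_interpolation(40, 858.2, 60, 1187.7, 50)  # 1022.95 ng/mL
#' @export
proportional_interpolation <- function(dose_low, value_low, dose_high,
                                       value_high, dose_target) {
  if (!(dose_low < dose_target && dose_target < dose_high))
    stop("dose_target must lie strictly between dose_low and dose_high")
  if (value_low <= 0 || value_high <= 0) stop("values must be positive")
  stats::approx(c(dose_low, dose_high), c(value_low, value_high),
                xout = dose_target)$y
}

#' Exposure ratio between two routes or formulations
#'
#' Quotient of a reference exposure over a test exposure (e.g. oral over
#' transdermal), optionally rounded to the nearest integer for an
#' "approximately k-fold" presentation.
#'
#' @param reference_value,test_value positive exposures in the same unit.
#' @param rounding `"none"` (default) or `"integer"`.
#' @return The ratio.
#' @export
exposure_ratio <- function(reference_value, test_value,
                           rounding = c("none", "integer")) {
  rounding <- match.arg(rounding)
  if (reference_value <= 0 || test_value <= 0)
    stop("exposures must be positive")
  r <- reference_value / test_value
  if (rounding == "integer") round(r) else r
}
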