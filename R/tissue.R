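#' Impute below-LLOQ observations at the LLOQ
#'
#' Replaces every BLQ observation's value by the assay lower limit of
#' quantification; quantifiable values are untouched. Imputing at the
#' LLOQ (rather than zero) deliberately biases a mostly-censored group
#' upward, which is conservative when testing whether the other group is
#' higher.
#'
#' @param value numeric vector (BLQ entries may be `NA`).
#' @param blq logical vector of BLQ flags.
#' @param lloq positive LLOQ in the observations' unit.
#' @return Numeric vector with BLQ entries set to `lloq`; the number of
#'   imputed entries is attached as attribute `"n_blq"`.
#' @export
impute_blq <- function(value, blq, lloq) {
  if (missing(lloq) || is.null(lloq) || !is.finite(lloq) || lloq <= 0)
    stop("a positive LLOQ is required for imputation")
  stopifnot(length(value) == length(blq))
  blq <- as.logical(blq)
  value[blq] <- lloq
  structure(value, n_blq = sum(blq))
}

#' Group summary with t-based confidence interval
#'
#' Arithmetic mean, sample SD (n - 1 denominator) and the two-sided
#' Student-t confidence interval of the mean on the untransformed scale:
#' mean +/- t(1 - (1-level)/2, n - 1) * sd / sqrt(n). Can be built either
#' from raw observations or from published summary statistics (n, mean,
#' sd), so printed tables can be replayed without raw data.
#'
#' @param x numeric observations; omit when replaying summaries.
#' @param n,mean,sd summary-statistic entry path (used when `x` missing).
#' @param level confidence level (default 0.95).
#' @param n_blq number of LLOQ-imputed observations contributing to `x`
#'   (recorded; when positive the CI is suppressed, mirroring the
#'   convention of not reporting a CI for a mostly-censored group). If `x`
#'   carries an `"n_blq"` attribute from [impute_blq()] it is picked up
#'   automatically.
#' @param unit measurement unit label.
#' @return An object of class `"group_summary"` with `n`, `mean`, `sd`,
#'   `ci` (length-2, `NA` when suppressed or n < 2), `n_blq`, `unit`.
#' @examples
#' group_summary(n = 9, mean = 5.82, sd = 1.64)$ci  # (4.56, 7.08)
#' @export
group_summary <- function(x = NULL, n = NULL, mean = NULL, sd = NULL,
                          level = 0.95, n_blq = NULL, unit = "") {
  if (!is.null(x)) {
    if (is.null(n_blq)) n_blq <- attr(x, "n_blq") %||% 0L
    x <- as.numeric(x)
    if (!length(x)) stop("empty group")
    if (anyNA(x)) stop("NA observations; impute or drop BLQ values first")
    n <- length(x)
    mean <- base::mean(x)
    sd <- if (n > 1) stats::sd(x) else NA_real_
  } else {
    if (is.null(n) || is.null(mean) || is.null(sd))
      stop("supply either raw observations x or all of n, mean, sd")
    if (is.null(n_blq)) n_blq <- 0L
  }
  ci <- c(NA_real_, NA_real_)
  if (n >= 2 && is.finite(sd) && n_blq == 0) {
    hw <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
    ci <- c(mean - hw, mean + hw)
  }
  structure(list(n = as.integer(n), mean = mean, sd = sd, ci = ci,
                 n_blq = as.integer(n_blq), unit = unit, level = level),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  ci_txt <- if (anyNA(x$ci)) "(CI not calculated)"
            else sprintf("(%s, %s)", signif(x$ci[1], 3), signif(x$ci[2], 3))
  cat(sprintf("n = %d%s: %s %s %s\n", x$n,
              if (x$n_blq) sprintf(" (%d imputed at LLOQ)", x$n_blq) else "",
              format_mean_sd(x$mean, x$sd), ci_txt, x$unit))
  invisible(x)
}

#' Welch's two-sample t test
#'
#' Unequal-variance comparison of two group means:
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite
#' degrees of freedom. Works from raw observations or directly from
#' summary statistics -- the latter is what published tables provide.
#'
#' @param x,y numeric observation vectors, or `group_summary` objects, or
#'   lists with `n`, `mean`, `sd`.
#' @param alpha two-sided significance level for the `significant` verdict
#'   (default 0.05).
#' @return An object of class `"welch_test"` with `statistic` (t), `df`
#'   (non-integer real), `p.value` (two-sided), `significant`, `estimate`
#'   (difference of means m1 - m2).
#' @examples
#' welch_test(group_summary(n = 10, mean = 84.5, sd = 56.0),
#'            group_summary(n = 9,  mean = 5.70, sd = 2.10))
#' @export
welch_test <- function(x, y, alpha = 0.05) {
  s1 <- as_welch_summary(x)
  s2 <- as_welch_summary(y)
  if (s1$n < 2 || s2$n < 2) stop("each group needs n >= 2")
  v1 <- s1$sd^2 / s1$n
  v2 <- s2$sd^2 / s2$n
  if (v1 + v2 == 0)
    stop("both groups have zero variance; the test is undefined")
  tstat <- (s1$mean - s2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  structure(list(statistic = tstat, df = df, p.value = p,
                 significant = p < alpha, alpha = alpha,
                 estimate = s1$mean - s2$mean,
                 n = c(s1$n, s2$n)),
            class = "welch_test")
}

as_welch_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x[c("n", "mean", "sd")])
  if (is.list(x)) {
    if (!all(c("n", "mean", "sd") %in% names(x)))
      stop("summary input must have n, mean, sd")
    return(x[c("n", "mean", "sd")])
  }
  x <- as.numeric(x)
  if (anyNA(x)) stop("NA observations; impute or drop BLQ values first")
  list(n = length(x), mean = mean(x), sd = stats::sd(x))
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch's t test: t = %.3f, df = %.2f, p = %s (%ssignificant at %g%%, two-sided)\n",
              x$statistic, x$df, format_p(x$p.value),
              if (x$significant) "" else "not ", 100 * x$alpha))
  invisible(x)
}

#' Format a p-value for reporting
#'
#' Exact value to three decimals, `"<0.001"` below that threshold.
#'
#' @param p p-value in (0, 1].
#' @return Character scalar.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", formatC(round(p, 3), format = "f", digits = 3))
}

#' Fold-ratio of two group means
#'
#' @param summary_test,summary_reference `group_summary` objects (or
#'   anything with a `mean` element); the reference mean must be positive.
#' @param digits decimals for the reported ratio (default 1; use `NULL`
#'   for full precision).
#' @return `mean_test / mean_reference`, rounded to `digits`.
#' @export
fold_ratio <- function(summary_test, summary_reference, digits = 1) {
  mt <- if (is.list(summary_test)) summary_test$mean else summary_test
  mr <- if (is.list(summary_reference)) summary_reference$mean
        else summary_reference
  if (!is.finite(mr) || mr <= 0) stop("reference mean must be positive")
  r <- mt / mr
  if (is.null(digits)) r else round(r, digits)
}

#' Estimate the S-enantiomer concentration from a racemate measurement
#'
#' For a racemic flurbiprofen measurement, the S-enantiomer concentration
#' is estimated as half the total, justified by the near-unity S/R
#' exposure ratio and absence of chiral inversion.
#'
#' @param fp_concentration non-negative racemate concentration(s).
#' @return `fp_concentration / 2`, vectorized.
#' @export
sfp_from_racemate <- function(fp_concentration) {
  if (any(fp_concentration < 0)) stop("concentration must be non-negative")
  fp_concentration / 2
}

#' Two-group tissue comparison with BLQ imputation
#'
#' For each matrix (tissue / fluid / plasma / absorption ratio) in a long
#' observation table: imputes BLQ values at the matrix LLOQ, summarizes
#' each group (mean, SD, t-based CI -- suppressed whenever a group
#' contains imputed values), runs Welch's t test, and reports the
#' test-over-reference fold-ratio of means.
#'
#' @param data data frame with columns `subject`, `group`, `tissue`,
#'   `value`, `blq`.
#' @param lloq named list / vector mapping each tissue to its LLOQ;
#'   matrices that can never be censored (e.g. `absorption_ratio`) may be
#'   omitted only if they contain no BLQ flags.
#' @param test,ref group labels; the fold-ratio is test mean over
#'   reference mean.
#' @param level CI level.
#' @param alpha significance level for the Welch verdicts.
#' @return An object of class `"tissue_comparison"`: a data frame with one
#'   row per tissue (group summaries, Welch t / df / p, fold ratio), with
#'   the per-group `group_summary` objects in attribute `"summaries"`.
#' @export
compare_groups <- function(data, lloq, test, ref, level = 0.95,
                           alpha = 0.05) {
  need <- c("group", "tissue", "value", "blq")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (!all(c(test, ref) %in% data$group))
    stop("groups '", test, "' and '", ref, "' must both be present")
  tissues <- unique(data$tissue)
  miss <- setdiff(tissues[vapply(tissues, function(tt)
    any(data$blq[data$tissue == tt]), logical(1))], names(lloq))
  if (length(miss))
    stop("missing LLOQ for matrix with BLQ observations: ",
         paste(miss, collapse = ", "))
  summaries <- list()
  rows <- lapply(tissues, function(tt) {
    one <- function(g) {
      d <- data[data$tissue == tt & data$group == g, , drop = FALSE]
      v <- if (tt %in% names(lloq))
        impute_blq(d$value, d$blq, lloq[[tt]])
      else d$value
      group_summary(v, level = level)
    }
    st <- one(test); sr <- one(ref)
    summaries[[tt]] <<- stats::setNames(list(st, sr), c(test, ref))
    w <- welch_test(st, sr, alpha = alpha)
    data.frame(tissue = tt,
               n_test = st$n, mean_test = st$mean, sd_test = st$sd,
               ci_lower_test = st$ci[1], ci_upper_test = st$ci[2],
               n_blq_test = st$n_blq,
               n_ref = sr$n, mean_ref = sr$mean, sd_ref = sr$sd,
               ci_lower_ref = sr$ci[1], ci_upper_ref = sr$ci[2],
               n_blq_ref = sr$n_blq,
               t = w$statistic, df = w$df, p = w$p.value,
               significant = w$significant,
               fold_ratio = fold_ratio(st, sr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, summaries = summaries, groups = c(test = test, ref = ref),
            class = c("tissue_comparison", "data.frame"))
}

#' @export
print.tissue_comparison <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("Two-group comparison: %s (test) vs %s (reference)\n",
              g["test"], g["ref"]))
  for (i in seq_len(nrow(x))) {
    ci_t <- if (is.na(x$ci_lower_test[i])) "(-)"
            else sprintf("(%s, %s)", signif(x$ci_lower_test[i], 3),
                         signif(x$ci_upper_test[i], 3))
    ci_r <- if (is.na(x$ci_lower_ref[i])) "(-)"
            else sprintf("(%s, %s)", signif(x$ci_lower_ref[i], 3),
                         signif(x$ci_upper_ref[i], 3))
    cat(sprintf("  %-16s %s %s | %s %s | p = %s | %.1f-fold\n",
                x$tissue[i],
                format_mean_sd(x$mean_test[i], x$sd_test[i]), ci_t,
                format_mean_sd(x$mean_ref[i], x$sd_ref[i]), ci_r,
                format_p(x$p[i]), x$fold_ratio[i]))
  }
  invisible(x)
}
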