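# Closed-form simple linear regression of ln(conc) on time.
# Returns slope, intercept, R^2 and adjusted R^2. Used instead of lm()
# because terminal-phase selection evaluates it many thousands of times
# in simulation studies; equivalence with lm() is asserted in the tests.
loglin_fit <- function(time, conc) {
  y <- log(conc)
  n <- length(y)
  mx <- mean(time); my <- mean(y)
  dx <- time - mx; dy <- y - my
  sxx <- sum(dx^2)
  slope <- sum(dx * dy) / sxx
  ss_res <- sum((dy - slope * dx)^2)
  ss_tot <- sum(dy^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  r2_adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  list(slope = slope, intercept = my - slope * mx, r2 = r2,
       r2_adj = r2_adj, n = n)
}

#' Peak concentration and its time
#'
#' Cmax and tmax are read directly off the quantifiable observations: no
#' interpolation or smoothing. Ties are broken by the earliest time.
#'
#' @param profile a [pk_profile()].
#' @return Named numeric vector `c(cmax = , tmax = )`.
#' @export
cmax_tmax <- function(profile) {
  q <- quantifiable(profile)
  if (!nrow(q)) stop("no quantifiable records")
  i <- which.max(q$conc)   # which.max takes the first maximum: earliest time
  c(cmax = q$conc[i], tmax = q$time[i])
}

#' Select the terminal elimination phase
#'
#' Among contiguous suffixes of the quantifiable observations strictly
#' after tmax (tmax itself excluded, at least `min_points` points), picks
#' the window maximizing the adjusted R^2 of the log-linear regression of
#' concentration on time -- the common automated best-fit rule. Supply
#' `window` (a vector of times) to override the automatic choice.
#'
#' @param profile a [pk_profile()].
#' @param min_points minimum number of points in the window (default 3).
#' @param window optional numeric vector of sampling times to force as the
#'   terminal window (manual override).
#' @return A list with `time`, `conc` (the window), `r2_adj`, and `ok`
#'   (`FALSE` when fewer than `min_points` eligible points exist, in which
#'   case the terminal slope and its dependents are undefined for this
#'   profile).
#' @export
select_terminal_phase <- function(profile, min_points = 3, window = NULL) {
  q <- quantifiable(profile)
  if (!is.null(window)) {
    keep <- q$time %in% window
    if (sum(keep) < min_points)
      stop("manual terminal window has fewer than ", min_points,
           " quantifiable points")
    f <- loglin_fit(q$time[keep], q$conc[keep])
    return(list(time = q$time[keep], conc = q$conc[keep],
                r2_adj = f$r2_adj, ok = TRUE, manual = TRUE))
  }
  tmax <- cmax_tmax(profile)["tmax"]
  post <- q[q$time > tmax & q$conc > 0, , drop = FALSE]
  n <- nrow(post)
  if (n < min_points)
    return(list(time = numeric(0), conc = numeric(0), r2_adj = NA_real_,
                ok = FALSE, manual = FALSE))
  starts <- seq_len(n - min_points + 1)
  fits <- lapply(starts, function(s) loglin_fit(post$time[s:n], post$conc[s:n]))
  best <- which.max(vapply(fits, `[[`, numeric(1), "r2_adj"))
  s <- starts[best]
  list(time = post$time[s:n], conc = post$conc[s:n],
       r2_adj = fits[[best]]$r2_adj, ok = TRUE, manual = FALSE)
}

#' Terminal rate constant by log-linear regression
#'
#' Ordinary least-squares fit of natural-log concentration against time
#' over the terminal window; lambda_z is the negated slope. A non-positive
#' estimate (rising or flat tail) is flagged undefined rather than
#' returned.
#'
#' @param window a terminal window as returned by
#'   [select_terminal_phase()], or a list with numeric `time` and `conc`.
#' @return A list with `lambda_z`, `r2_adj`, and `ok`.
#' @export
fit_lambda_z <- function(window) {
  if (length(window$time) < 3)
    stop("terminal window needs at least 3 points")
  if (any(window$conc <= 0))
    stop("terminal window contains non-positive concentrations")
  f <- loglin_fit(window$time, window$conc)
  lz <- -f$slope
  if (!is.finite(lz) || lz <= 0)
    return(list(lambda_z = NA_real_, r2_adj = f$r2_adj, ok = FALSE))
  list(lambda_z = lz, r2_adj = f$r2_adj, ok = TRUE)
}

#' Terminal half-life
#'
#' @param lambda_z terminal rate constant (1/h), positive.
#' @return `log(2) / lambda_z` in hours.
#' @export
half_life <- function(lambda_z) {
  if (any(!is.finite(lambda_z)) || any(lambda_z <= 0))
    stop("lambda_z must be positive")
  log(2) / lambda_z
}

# Trapezoidal area over paired (time, conc) nodes. method "linear" is the
# plain linear trapezoid; "linlog" uses the log trapezoid on strictly
# decreasing positive segments (linear-up/log-down).
trapezoid_area <- function(time, conc, method = c("linear", "linlog")) {
  method <- match.arg(method)
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linlog") {
    down <- c2 < c1 & c2 > 0 & c1 > 0
    seg[down] <- (c1[down] - c2[down]) * dt[down] /
      log(c1[down] / c2[down])
  }
  sum(seg)
}

#' Area under the curve to the last quantifiable time
#'
#' Trapezoidal AUC over the quantifiable observations, with the BLQ rules:
#' a leading BLQ segment contributes through a zero-valued anchor at time
#' zero, BLQ observations between quantifiable points are dropped from the
#' trapezoid nodes, and trailing BLQ observations truncate the profile at
#' the last quantifiable time (which defines t and Ct).
#'
#' @param profile a [pk_profile()].
#' @param method `"linear"` (default) for the plain linear trapezoid, or
#'   `"linlog"` for linear-up/log-down.
#' @return AUC0-t in concentration x hours.
#' @export
auc_0_t <- function(profile, method = "linear") {
  q <- quantifiable(profile)
  if (!nrow(q)) stop("no quantifiable records")
  leading_blq <- any(profile$data$blq & profile$data$time < q$time[1])
  if (nrow(q) < 2 && !leading_blq)
    stop("need at least 2 quantifiable records for AUC")
  if (q$time[1] > 0) {
    # leading BLQ (or simply no sample) before the first quantifiable
    # point: anchor at (0, 0)
    q <- rbind(data.frame(time = 0, conc = 0), q)
  }
  trapezoid_area(q$time, q$conc, method = method)
}

#' Extrapolate the AUC to infinite time
#'
#' Adds the tail area Ct / lambda_z beyond the last quantifiable
#' concentration Ct.
#'
#' @param auc_0_t area to the last quantifiable time.
#' @param c_t last observed quantifiable concentration (must be > 0).
#' @param lambda_z terminal rate constant.
#' @return A list with `auc_0_inf` and `extrap_frac`, the extrapolated
#'   fraction of the total area.
#' @export
auc_0_inf <- function(auc_0_t, c_t, lambda_z) {
  if (!is.finite(c_t) || c_t <= 0)
    stop("Ct must be a positive quantifiable concentration")
  if (!is.finite(lambda_z) || lambda_z <= 0)
    stop("lambda_z must be positive")
  tail_area <- c_t / lambda_z
  total <- auc_0_t + tail_area
  list(auc_0_inf = total, extrap_frac = tail_area / total)
}

#' Noncompartmental analysis of one concentration-time profile
#'
#' Derives the standard single-dose NCA parameter set: Cmax and tmax read
#' directly from the observations, the terminal rate constant lambda_z by
#' log-linear regression over an automatically selected (or manually
#' supplied) terminal window, t1/2 = ln 2 / lambda_z, the trapezoidal
#' AUC0-t, and AUC0-inf = AUC0-t + Ct / lambda_z. Profiles whose terminal
#' phase cannot be estimated (fewer than 3 eligible post-peak points, or a
#' non-decaying tail) yield `NA` for lambda_z-dependent parameters and are
#' flagged, not failed.
#'
#' @param profile a [pk_profile()].
#' @param min_points minimum terminal-window size (default 3).
#' @param window optional manual terminal window (vector of times).
#' @param auc_method `"linear"` or `"linlog"`, see [auc_0_t()].
#' @param extrap_warn warn when the extrapolated AUC fraction exceeds this
#'   (default 0.2); reporting aid only.
#' @return An object of class `"nca"`: a list with the parameter estimates
#'   (`cmax`, `tmax`, `lambda_z`, `t_half`, `auc_0_t`, `auc_0_inf`, `c_t`,
#'   `t_last`, `extrap_frac`), the terminal-window metadata
#'   (`terminal_window`, `r2_adj`, `lambda_ok`), and the profile's
#'   `subject_id` and `dose`.
#' @examples
#' p <- simulate_profile(dose = 20, residual_cv = 0, seed = 1)
#' fit <- nca(p)
#' coef(fit)
#' @export
nca <- function(profile, min_points = 3, window = NULL,
                auc_method = "linear", extrap_warn = 0.2) {
  stopifnot(inherits(profile, "pk_profile"))
  q <- quantifiable(profile)
  if (nrow(q) < 3)
    stop("full NCA requires at least 3 quantifiable records; subject ",
         profile$subject_id, " has ", nrow(q))
  ct <- cmax_tmax(profile)
  win <- select_terminal_phase(profile, min_points = min_points,
                               window = window)
  lambda_z <- NA_real_; r2_adj <- NA_real_; lambda_ok <- FALSE
  if (win$ok) {
    lf <- fit_lambda_z(win)
    lambda_z <- lf$lambda_z; r2_adj <- lf$r2_adj; lambda_ok <- lf$ok
  }
  a0t <- auc_0_t(profile, method = auc_method)
  c_t <- q$conc[nrow(q)]
  t_last <- q$time[nrow(q)]
  t_half <- if (lambda_ok) half_life(lambda_z) else NA_real_
  if (lambda_ok) {
    ext <- auc_0_inf(a0t, c_t, lambda_z)
    a0inf <- ext$auc_0_inf; efrac <- ext$extrap_frac
    if (efrac > extrap_warn)
      warning(sprintf("subject %s: extrapolated AUC fraction %.1f%% exceeds %g%%",
                      profile$subject_id, 100 * efrac, 100 * extrap_warn))
  } else {
    a0inf <- NA_real_; efrac <- NA_real_
  }
  structure(list(subject_id = profile$subject_id, dose = profile$dose,
                 cmax = unname(ct["cmax"]), tmax = unname(ct["tmax"]),
                 lambda_z = lambda_z, t_half = t_half,
                 auc_0_t = a0t, auc_0_inf = a0inf,
                 c_t = c_t, t_last = t_last, extrap_frac = efrac,
                 terminal_window = win$time, r2_adj = r2_adj,
                 lambda_ok = lambda_ok),
            class = "nca")
}

#' @export
print.nca <- function(x, digits = 4, ...) {
  cat(sprintf("NCA: subject %s, dose %g mg\n", x$subject_id, x$dose))
  print(signif(coef(x), digits))
  if (!x$lambda_ok)
    cat("  [terminal phase undefined: lambda_z and dependents are NA]\n")
  else
    cat(sprintf("  terminal window: %s h (adj. R^2 = %.4f), %.1f%% of AUC extrapolated\n",
                paste(x$terminal_window, collapse = ", "), x$r2_adj,
                100 * x$extrap_frac))
  invisible(x)
}

#' @export
coef.nca <- function(object, ...) {
  with(object, c(cmax = cmax, tmax = tmax, lambda_z = lambda_z,
                 t_half = t_half, auc_0_t = auc_0_t,
                 auc_0_inf = auc_0_inf, c_t = c_t))
}

#' Run NCA over a study and tabulate per-subject results
#'
#' @param study a `pk_study`.
#' @param ... passed to [nca()].
#' @return A data frame with one row per subject: identifiers, the NCA
#'   parameters, and the flags `lambda_ok` / `extrap_frac`.
#' @export
nca_table <- function(study, ...) {
  stopifnot(inherits(study, "pk_study"))
  rows <- lapply(study, function(p) {
    r <- nca(p, ...)
    data.frame(subject = r$subject_id, dose = r$dose, cmax = r$cmax,
               tmax = r$tmax, lambda_z = r$lambda_z, t_half = r$t_half,
               auc_0_t = r$auc_0_t, auc_0_inf = r$auc_0_inf,
               c_t = r$c_t, r2_adj = r$r2_adj, lambda_ok = r$lambda_ok,
               extrap_frac = r$extrap_frac)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-dose summary of NCA parameters
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of each requested
#' parameter by dose group -- the layout of a single-application PK
#' summary table. Groups keep their own n; a single-subject group reports
#' `NA` for the SD.
#'
#' @param results data frame from [nca_table()], optionally with an
#'   `absorption_ratio` column merged in.
#' @param params character vector of columns to summarize.
#' @return A data frame with columns `dose`, `parameter`, `n`, `mean`,
#'   `sd`.
#' @export
summarize_by_dose <- function(results,
                              params = c("cmax", "tmax", "t_half",
                                         "auc_0_inf")) {
  params <- intersect(params, names(results))
  if (!length(params)) stop("no requested parameter columns present")
  doses <- sort(unique(results$dose))
  rows <- list()
  for (d in doses) {
    sub <- results[results$dose == d, , drop = FALSE]
    for (p in params) {
      v <- sub[[p]][!is.na(sub[[p]])]
      if (!length(v))
        stop("dose group ", d, " mg has no evaluable values for ", p)
      rows[[length(rows) + 1L]] <- data.frame(
        dose = d, parameter = p, n = length(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percutaneous absorption ratio from patch mass balance
#'
#' The fraction of labeled drug content absorbed through the skin,
#' estimated from the residual content of the used patch:
#' ratio (%) = (A - B) / A x 100, where A is the labeled content and B the
#' residual content (both mg).
#'
#' @param patch a [patch_record()], or the labeled content A when `B` is
#'   given.
#' @param B residual content (mg) when `patch` is given as A.
#' @return A list of class `"absorption_ratio"` with `ratio_percent`,
#'   `content_labeled`, `content_residual`.
#' @examples
#' absorption_ratio(patch_record("S01", 20, 10))$ratio_percent  # 50
#' @export
absorption_ratio <- function(patch, B = NULL) {
  if (!inherits(patch, "patch_record")) {
    if (is.null(B)) stop("supply a patch_record or both A and B")
    patch <- patch_record("<anon>", patch, B)
  }
  A <- patch$content_labeled
  B <- patch$content_residual
  structure(list(ratio_percent = (A - B) / A * 100,
                 content_labeled = A, content_residual = B,
                 subject_id = patch$subject_id),
            class = "absorption_ratio")
}

#' @export
print.absorption_ratio <- function(x, ...) {
  cat(sprintf("absorption ratio: %.1f%% (A = %g mg, B = %g mg)\n",
              x$ratio_percent, x$content_labeled, x$content_residual))
  invisible(x)
}
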