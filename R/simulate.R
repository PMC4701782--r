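#' Default per-dose absorbed fractions for the transdermal model
#'
#' Fractions of the labeled dose absorbed over a 24-h wear, by dose (mg),
#' calibrated to typical single-application mass-balance results for a
#' tape-type plaster (absorption falls off at the highest doses, where the
#' applied area rather than the content is increased).
#'
#' @return Named numeric vector (names are doses in mg).
#' @export
default_f_abs <- function() {
  c("2" = 0.612, "5" = 0.680, "10" = 0.722, "20" = 0.641,
    "40" = 0.575, "60" = 0.514)
}

#' Transdermal one-compartment model parameters
#'
#' Population parameters of the synthetic trial generator: zero-order
#' drug input k0 = f_abs * dose / wear_duration into a one-compartment
#' disposition model with elimination rate `ke` and apparent volume `v_f`,
#' lognormal between-subject variability on (ke, v_f, f_abs), and
#' proportional lognormal residual error on each sample.
#'
#' Defaults: ke = ln 2 / 8 per hour (8-h terminal half-life), v_f = 12.15
#' L (calibrated so the noiseless 20-mg 24-h plateau is ~444 ng/mL at the
#' default absorbed fraction), between-subject CV 25 % per parameter,
#' residual CV 10 %, LLOQ 2 ng/mL, and the 13-point sampling schedule
#' 2, 4, 6, 8, 10, 12, 14, 24, 28, 32, 36, 47, 71 h under 24-h wear.
#'
#' @param wear_duration patch wear in hours.
#' @param f_abs absorbed fraction over wear: a single value (exactly
#'   dose-proportional construction) or a named per-dose vector such as
#'   [default_f_abs()].
#' @param ke elimination rate constant (1/h).
#' @param v_f apparent volume of distribution (L).
#' @param bsv named list of between-subject lognormal CVs for `ke`, `v_f`,
#'   `f_abs`.
#' @param residual_cv proportional residual-error CV.
#' @param lloq assay LLOQ (ng/mL).
#' @param sampling_times strictly increasing sampling times (h).
#' @return A list of class `"transdermal_params"`.
#' @export
transdermal_params <- function(wear_duration = 24, f_abs = default_f_abs(),
                               ke = log(2) / 8, v_f = 12.15,
                               bsv = list(ke = 0.25, v_f = 0.25,
                                          f_abs = 0.25),
                               residual_cv = 0.10, lloq = 2,
                               sampling_times = c(2, 4, 6, 8, 10, 12, 14,
                                                  24, 28, 32, 36, 47, 71)) {
  stopifnot(wear_duration > 0, ke > 0, v_f > 0, lloq > 0,
            all(f_abs > 0), all(f_abs <= 1), residual_cv >= 0,
            all(unlist(bsv) >= 0))
  if (is.unsorted(sampling_times, strictly = TRUE))
    stop("sampling_times must be strictly increasing")
  structure(list(wear_duration = wear_duration, f_abs = f_abs, ke = ke,
                 v_f = v_f, bsv = bsv, residual_cv = residual_cv,
                 lloq = lloq, sampling_times = sampling_times),
            class = "transdermal_params")
}

# absorbed fraction applicable to a dose, from a scalar or per-dose vector
f_abs_for_dose <- function(f_abs, dose) {
  if (length(f_abs) == 1L && is.null(names(f_abs))) return(unname(f_abs))
  key <- as.character(dose)
  if (!key %in% names(f_abs))
    stop("no absorbed fraction configured for dose ", dose, " mg")
  unname(f_abs[[key]])
}

#' Noiseless transdermal concentration-time function
#'
#' Closed-form plasma concentration under zero-order input during wear
#' and first-order elimination: for t <= T,
#' C(t) = k0 / (ke V) * (1 - exp(-ke t)); afterwards
#' C(t) = C(T) * exp(-ke (t - T)), with k0 = f_abs * dose / T. Doses are
#' mg, volumes L; the result is in ng/mL.
#'
#' @param time hours since application (vectorized, >= 0).
#' @param dose mg applied.
#' @param ke elimination rate (1/h).
#' @param v_f apparent volume (L).
#' @param f_abs absorbed fraction over wear.
#' @param wear_duration wear time T (h).
#' @return Concentrations in ng/mL.
#' @export
transdermal_conc <- function(time, dose, ke, v_f, f_abs,
                             wear_duration = 24) {
  k0 <- f_abs * dose / wear_duration              # mg/h
  css <- 1000 * k0 / (ke * v_f)                   # mg/L -> ng/mL
  rising <- css * (1 - exp(-ke * pmin(time, wear_duration)))
  rising * exp(-ke * pmax(time - wear_duration, 0))
}

# lognormal sigma for a given coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate one subject's concentration-time profile
#'
#' Evaluates the noiseless transdermal model at the sampling schedule,
#' applies proportional lognormal residual error, and flags values below
#' the LLOQ as BLQ.
#'
#' @param dose mg applied.
#' @param params a [transdermal_params()]; subject-level `ke`, `v_f`,
#'   `f_abs` may be overridden individually.
#' @param ke,v_f,f_abs optional subject-specific values (default: the
#'   population typicals in `params`).
#' @param residual_cv optional override of the residual CV.
#' @param subject_id identifier.
#' @param seed optional RNG seed for this profile.
#' @return A [pk_profile()].
#' @export
simulate_profile <- function(dose, params = transdermal_params(),
                             ke = NULL, v_f = NULL, f_abs = NULL,
                             residual_cv = NULL, subject_id = "S1",
                             seed = NULL) {
  stopifnot(inherits(params, "transdermal_params"))
  if (!is.null(seed)) set.seed(seed)
  ke <- ke %||% params$ke
  v_f <- v_f %||% params$v_f
  f_abs <- f_abs %||% f_abs_for_dose(params$f_abs, dose)
  rcv <- residual_cv %||% params$residual_cv
  tt <- params$sampling_times
  c_true <- transdermal_conc(tt, dose, ke, v_f, f_abs,
                             params$wear_duration)
  obs <- if (rcv > 0) {
    sdl <- cv_to_sdlog(rcv)
    c_true * exp(stats::rnorm(length(tt), -sdl^2 / 2, sdl))
  } else c_true
  blq <- obs < params$lloq
  pk_profile(subject_id, dose = dose, time = tt, conc = obs, blq = blq,
             lloq = params$lloq, wear_duration = params$wear_duration)
}

#' Simulate a multi-dose single-application transdermal trial
#'
#' Generates a full dose-escalation dataset (default: 6 dose groups of
#' 2-60 mg with group sizes 7, 7, 7, 6, 7, 7) with lognormal
#' between-subject variability on ke, V and the absorbed fraction, plus
#' matching patch mass-balance records whose residual content is
#' consistent with each subject's realized absorbed fraction (with a
#' small 2 % assay error). Per-subject ground truth is returned alongside
#' the data.
#'
#' @param n_per_dose named integer vector: subjects per dose (names are
#'   doses in mg).
#' @param params a [transdermal_params()].
#' @param seed RNG seed (same seed, same dataset).
#' @return A list with `study` (a `pk_study`), `patches` (a data frame
#'   with columns `subject`, `dose`, `content_labeled`,
#'   `content_residual`, `absorption_ratio`), and `truth` (per-subject
#'   true `ke`, `t_half`, `v_f`, `f_abs`).
#' @export
simulate_study1 <- function(n_per_dose = c("2" = 7, "5" = 7, "10" = 7,
                                           "20" = 6, "40" = 7, "60" = 7),
                            params = transdermal_params(), seed = NULL) {
  stopifnot(inherits(params, "transdermal_params"), all(n_per_dose >= 1))
  if (!is.null(seed)) set.seed(seed)
  doses <- as.numeric(names(n_per_dose))
  if (anyNA(doses)) stop("n_per_dose must be named by dose in mg")
  profiles <- list(); truth <- list(); patches <- list()
  for (k in seq_along(doses)) {
    d <- doses[k]
    f_typ <- f_abs_for_dose(params$f_abs, d)
    for (i in seq_len(n_per_dose[k])) {
      id <- sprintf("D%03d-%02d", round(d), i)
      ke_i <- params$ke * stats::rlnorm(1, -cv_to_sdlog(params$bsv$ke)^2 / 2,
                                        cv_to_sdlog(params$bsv$ke))
      v_i <- params$v_f * stats::rlnorm(1, -cv_to_sdlog(params$bsv$v_f)^2 / 2,
                                        cv_to_sdlog(params$bsv$v_f))
      f_i <- min(f_typ * stats::rlnorm(1, -cv_to_sdlog(params$bsv$f_abs)^2 / 2,
                                       cv_to_sdlog(params$bsv$f_abs)),
                 0.995)
      profiles[[id]] <- simulate_profile(d, params, ke = ke_i, v_f = v_i,
                                         f_abs = f_i, subject_id = id)
      resid_mg <- min(d * (1 - f_i) * exp(stats::rnorm(1, 0, 0.02)), d)
      patches[[id]] <- data.frame(subject = id, dose = d,
                                  content_labeled = d,
                                  content_residual = resid_mg,
                                  absorption_ratio = (d - resid_mg) / d * 100)
      truth[[id]] <- data.frame(subject = id, dose = d, ke = ke_i,
                                t_half = log(2) / ke_i, v_f = v_i,
                                f_abs = f_i)
    }
  }
  list(study = pk_study(profiles),
       patches = do.call(rbind, c(patches, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Lognormal parameters matching a target mean and SD
#'
#' Moment matching on the natural scale: for target mean m > 0 and sd
#' s >= 0, sdlog = sqrt(log(1 + (s/m)^2)) and meanlog = log(m) -
#' sdlog^2 / 2. Every positive (m, s) pair is attainable.
#'
#' @param mean target arithmetic mean (> 0).
#' @param sd target arithmetic SD (>= 0).
#' @return List with `meanlog`, `sdlog`.
#' @export
lognormal_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0)
    stop("target mean must be positive for a lognormal")
  if (!is.finite(sd) || sd < 0) stop("target sd must be non-negative")
  sdlog <- cv_to_sdlog(sd / mean)
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Default targets for the two-group tissue simulation
#'
#' Per-group, per-matrix target means and SDs (lognormal on the natural
#' scale), group sizes of 10 (test plaster, "SFPP") versus 9 (reference
#' gel patch, "FP"), and the matrix LLOQs (5.0 ng/g synovial tissue,
#' 0.500 ng/mL synovial fluid and plasma). The reference-group synovial
#' tissue target (mean 3.0, SD 2.5 ng/g) sits below the LLOQ so that most
#' of its draws are censored, as observed with a poorly penetrating
#' formulation; all other targets equal the observed group summaries.
#'
#' @return A list with `targets` (data frame: `group`, `tissue`, `mean`,
#'   `sd`), `n` (named group sizes), and `lloq` (named per-matrix LLOQs;
#'   the absorption ratio has none).
#' @export
study2_targets <- function() {
  targets <- rbind(
    data.frame(group = "SFPP",
               tissue = c("synovial_tissue", "synovial_fluid", "plasma",
                          "absorption_ratio"),
               mean = c(84.5, 149, 362, 44.46),
               sd = c(56.0, 44.9, 84.8, 10.63)),
    data.frame(group = "FP",
               tissue = c("synovial_tissue", "synovial_fluid", "plasma",
                          "absorption_ratio"),
               mean = c(3.0, 4.55, 10.5, 5.82),
               sd = c(2.5, 3.66, 10.1, 1.64)))
  list(targets = targets, n = c(SFPP = 10L, FP = 9L),
       lloq = c(synovial_tissue = 5.0, synovial_fluid = 0.500,
                plasma = 0.500))
}

#' Simulate a two-group tissue-concentration dataset
#'
#' Draws per-subject lognormal tissue, fluid and plasma concentrations
#' (and percutaneous absorption ratios) with moments matched to the
#' per-group targets, and flags values below the matrix LLOQ as BLQ.
#'
#' @param targets a [study2_targets()]-shaped list (`targets`, `n`,
#'   `lloq`).
#' @param seed RNG seed.
#' @return A data frame with columns `subject`, `group`, `tissue`,
#'   `value`, `blq` (BLQ values are `NA` until imputed); the target list
#'   is attached as attribute `"targets"`.
#' @export
simulate_study2 <- function(targets = study2_targets(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tg <- targets$targets
  stopifnot(all(c("group", "tissue", "mean", "sd") %in% names(tg)))
  rows <- list()
  for (g in names(targets$n)) {
    n <- targets$n[[g]]
    if (n < 2) stop("group sizes must be at least 2")
    ids <- sprintf("%s-%02d", g, seq_len(n))
    sub <- tg[tg$group == g, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      lp <- lognormal_moments(sub$mean[j], sub$sd[j])
      v <- if (lp$sdlog > 0) stats::rlnorm(n, lp$meanlog, lp$sdlog)
           else rep(sub$mean[j], n)
      tt <- sub$tissue[j]
      lloq <- if (tt %in% names(targets$lloq)) targets$lloq[[tt]] else NA
      blq <- if (is.na(lloq)) rep(FALSE, n) else v < lloq
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ids, group = g, tissue = tt,
        value = ifelse(blq, NA_real_, v), blq = blq)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "targets") <- targets
  out
}
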