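#' Concentration-time profile for one subject
#'
#' Constructs a validated single-subject concentration-time profile for a
#' transdermal application. Concentrations are ng/mL (plasma / fluids) or
#' ng/g (tissue); times are hours since patch application. Observations
#' below the assay lower limit of quantification (LLOQ) carry `blq = TRUE`
#' and an undefined concentration until an imputation policy is applied
#' downstream -- never at this layer.
#'
#' @param subject_id identifier (coerced to character).
#' @param dose applied dose in mg; must be positive.
#' @param time numeric vector of sampling times in hours, strictly
#'   increasing, non-negative.
#' @param conc numeric vector of concentrations; entries where `blq` is
#'   `TRUE` are ignored and stored as `NA`.
#' @param blq logical vector of below-LLOQ flags (default all `FALSE`).
#' @param lloq assay lower limit of quantification, same unit as `conc`;
#'   must be positive.
#' @param wear_duration hours the patch remained applied; must be positive.
#'
#' @return An object of class `"pk_profile"`: a list with elements
#'   `subject_id`, `dose`, `wear_duration`, `lloq` and `data` (a data frame
#'   with columns `time`, `conc`, `blq`).
#'
#' @details A quantifiable (non-BLQ) concentration must be at least the
#'   LLOQ, with one exception: an exact zero is accepted at any time and is
#'   treated as a true zero (e.g. a pre-dose baseline anchor).
#'
#' @examples
#' pk_profile("S01", dose = 20, time = c(2, 4, 8, 24, 36),
#'            conc = c(120, 250, 400, 444, 160), lloq = 2)
#' @export
pk_profile <- function(subject_id, dose, time, conc, blq = NULL, lloq = 2,
                       wear_duration = 24) {
  if (is.null(blq)) blq <- rep(FALSE, length(time))
  stopifnot(length(time) == length(conc), length(time) == length(blq))
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0)
    stop("'dose' must be a single positive number (mg)")
  if (!is.numeric(wear_duration) || wear_duration <= 0)
    stop("'wear_duration' must be positive (hours)")
  if (!is.numeric(lloq) || lloq <= 0)
    stop("'lloq' must be positive")
  if (any(!is.finite(time)) || any(time < 0))
    stop("sampling times must be finite and non-negative")
  if (is.unsorted(time, strictly = TRUE))
    stop("sampling times must be strictly increasing (no duplicates)")
  blq <- as.logical(blq)
  conc <- as.numeric(conc)
  conc[blq] <- NA_real_
  bad <- !blq & (!is.finite(conc) | conc < 0)
  if (any(bad))
    stop("quantifiable concentrations must be finite and non-negative")
  sub_lloq <- !blq & conc > 0 & conc < lloq
  if (any(sub_lloq))
    stop("non-BLQ concentration below LLOQ at time ",
         paste(time[sub_lloq], collapse = ", "),
         " h; flag it BLQ or correct the LLOQ")
  structure(
    list(subject_id = as.character(subject_id)[1L],
         dose = as.numeric(dose),
         wear_duration = as.numeric(wear_duration),
         lloq = as.numeric(lloq),
         data = data.frame(time = time, conc = conc, blq = blq)),
    class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  nq <- sum(!x$data$blq)
  cat(sprintf("pk_profile: subject %s, dose %g mg, wear %g h, LLOQ %g\n",
              x$subject_id, x$dose, x$wear_duration, x$lloq))
  cat(sprintf("  %d samples (%d quantifiable, %d BLQ) over %g-%g h\n",
              nrow(x$data), nq, sum(x$data$blq),
              min(x$data$time), max(x$data$time)))
  invisible(x)
}

# quantifiable records of a profile (drops BLQ rows)
quantifiable <- function(profile) {
  profile$data[!profile$data$blq, c("time", "conc"), drop = FALSE]
}

#' Patch mass-balance record
#'
#' Labeled and residual drug content of a single patch, the inputs of the
#' percutaneous absorption ratio (A - B)/A x 100.
#'
#' @param subject_id identifier.
#' @param content_labeled drug amount A in the unused patch (mg), positive.
#' @param content_residual drug amount B recovered from the used patch
#'   (mg); must satisfy 0 <= B <= A. A violation is an input error and is
#'   never clamped silently.
#' @return An object of class `"patch_record"`.
#' @seealso [absorption_ratio()]
#' @export
patch_record <- function(subject_id, content_labeled, content_residual) {
  if (!is.numeric(content_labeled) || content_labeled <= 0)
    stop("labeled content A must be positive (mg)")
  if (!is.numeric(content_residual) || content_residual < 0 ||
      content_residual > content_labeled)
    stop("residual content B must satisfy 0 <= B <= A; got B = ",
         content_residual, ", A = ", content_labeled)
  structure(list(subject_id = as.character(subject_id)[1L],
                 content_labeled = as.numeric(content_labeled),
                 content_residual = as.numeric(content_residual)),
            class = "patch_record")
}

#' @export
print.patch_record <- function(x, ...) {
  cat(sprintf("patch_record: subject %s, A = %g mg, B = %g mg\n",
              x$subject_id, x$content_labeled, x$content_residual))
  invisible(x)
}

#' Bundle of concentration-time profiles
#'
#' A study is a list of [pk_profile()] objects, typically one per subject.
#'
#' @param profiles list of `pk_profile` objects.
#' @return An object of class `"pk_study"`.
#' @export
pk_study <- function(profiles) {
  ok <- vapply(profiles, inherits, logical(1), what = "pk_profile")
  if (!length(profiles) || !all(ok))
    stop("'profiles' must be a non-empty list of pk_profile objects")
  structure(profiles, class = "pk_study")
}

#' @export
print.pk_study <- function(x, ...) {
  doses <- vapply(x, `[[`, numeric(1), "dose")
  cat(sprintf("pk_study: %d profiles, doses %s mg\n", length(x),
              paste(sort(unique(doses)), collapse = "/")))
  invisible(x)
}

#' @export
`[.pk_study` <- function(x, i) pk_study(unclass(x)[i])

#' Plot mean concentration-time profiles by dose group
#'
#' Arithmetic mean (+ SD bars) of quantifiable concentrations at each
#' nominal sampling time, one curve per dose group, concentration on a log
#' scale.
#'
#' @param x a `pk_study`.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the matrix of group means (time x dose).
#' @export
plot.pk_study <- function(x, ...) {
  doses <- vapply(x, `[[`, numeric(1), "dose")
  times <- sort(unique(unlist(lapply(x, function(p) p$data$time))))
  ud <- sort(unique(doses))
  m <- sapply(ud, function(d) {
    vals <- sapply(times, function(tt) {
      v <- unlist(lapply(x[doses == d], function(p) {
        p$data$conc[!p$data$blq & p$data$time == tt]
      }))
      if (length(v)) mean(v) else NA_real_
    })
    vals
  })
  m <- matrix(m, nrow = length(times),
              dimnames = list(NULL, paste0(ud, " mg")))
  graphics::matplot(times, m, type = "b", log = "y", pch = 19, lty = 1,
                    xlab = "Time after application (h)",
                    ylab = "Concentration (ng/mL)", ...)
  graphics::legend("topright", legend = colnames(m), col = seq_along(ud),
                   pch = 19, lty = 1, bty = "n")
  invisible(m)
}
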