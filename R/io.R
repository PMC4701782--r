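#' I/O dialect configuration for delimited concentration tables
#'
#' Column names, separator, BLQ text encodings and per-matrix LLOQs used by
#' the delimited-table readers and writers. The defaults match the CSV
#' dialect written by [write_concentration_table()] and
#' [simulate_study1()].
#'
#' @param sep field separator (default `","`).
#' @param columns named list mapping the roles `subject`, `dose`, `time`,
#'   `conc`, `blq` to header names. The `blq` column is optional in input
#'   files: BLQ may instead be encoded in the concentration cell.
#' @param blq_tokens character vector of concentration-cell encodings that
#'   mean below-LLOQ (matched case-insensitively after trimming); an empty
#'   cell always counts as BLQ.
#' @param lloq default LLOQ applied to every profile (assay units).
#' @param wear_duration hours of patch wear recorded on every profile.
#' @return A list of class `"pk_io_config"`.
#' @export
pk_io_config <- function(sep = ",",
                         columns = list(subject = "subject", dose = "dose",
                                        time = "time", conc = "conc",
                                        blq = "blq"),
                         blq_tokens = c("BLQ", "<LLOQ"),
                         lloq = 2, wear_duration = 24) {
  need <- c("subject", "dose", "time", "conc")
  if (!all(need %in% names(columns)))
    stop("'columns' must name at least: ", paste(need, collapse = ", "))
  structure(list(sep = sep, columns = columns,
                 blq_tokens = toupper(trimws(blq_tokens)),
                 lloq = lloq, wear_duration = wear_duration),
            class = "pk_io_config")
}

#' Read a delimited concentration-time table into a study
#'
#' Parses a plain-text delimited file (one row per observation: subject,
#' dose, time, concentration, optional BLQ flag) into a [pk_study()].
#' Rows are grouped by subject and sorted by time. BLQ observations --
#' encoded either by a truthy value in the BLQ column or by a BLQ token
#' ("BLQ", "<LLOQ", or an empty cell) in the concentration column -- become
#' records with `blq = TRUE` and an undefined concentration. No imputation
#' happens here.
#'
#' @param path file to read.
#' @param config a [pk_io_config()].
#' @return A `pk_study`.
#' @export
read_concentration_table <- function(path, config = pk_io_config()) {
  stopifnot(inherits(config, "pk_io_config"))
  raw <- utils::read.table(path, header = TRUE, sep = config$sep,
                           colClasses = "character", strip.white = TRUE,
                           check.names = FALSE)
  cols <- config$columns
  need <- unlist(cols[c("subject", "dose", "time", "conc")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  conc_chr <- trimws(raw[[cols$conc]])
  blq <- conc_chr == "" | toupper(conc_chr) %in% config$blq_tokens
  if (!is.null(cols$blq) && cols$blq %in% names(raw)) {
    flag <- toupper(trimws(raw[[cols$blq]]))
    blq <- blq | flag %in% c("TRUE", "T", "1", "YES", "Y", "BLQ")
  }
  conc <- suppressWarnings(as.numeric(conc_chr))
  conc[blq] <- NA_real_
  if (any(!blq & is.na(conc)))
    stop("unparseable concentration value(s): ",
         paste(unique(conc_chr[!blq & is.na(conc)]), collapse = ", "))
  time <- suppressWarnings(as.numeric(raw[[cols$time]]))
  dose <- suppressWarnings(as.numeric(raw[[cols$dose]]))
  if (any(is.na(time)) || any(is.na(dose)))
    stop("unparseable time or dose value(s)")
  if (any(time < 0)) stop("negative sampling time in input")
  if (any(!blq & conc < 0)) stop("negative concentration in input")
  subj <- as.character(raw[[cols$subject]])
  profiles <- lapply(split(seq_len(nrow(raw)), subj), function(idx) {
    o <- idx[order(time[idx])]
    tt <- time[o]
    if (anyDuplicated(tt))
      stop("duplicate sampling times for subject ", subj[idx[1]])
    d <- unique(dose[idx])
    if (length(d) != 1L)
      stop("subject ", subj[idx[1]], " has more than one dose")
    pk_profile(subj[idx[1]], dose = d, time = tt, conc = conc[o],
               blq = blq[o], lloq = config$lloq,
               wear_duration = config$wear_duration)
  })
  pk_study(profiles[order(names(profiles))])
}

#' Write a study back to the delimited dialect
#'
#' Inverse of [read_concentration_table()]: one row per observation, BLQ
#' records written with the first configured BLQ token in the
#' concentration cell and `TRUE` in the BLQ column. Numeric content
#' round-trips at full double precision.
#'
#' @param study a `pk_study`.
#' @param path output file.
#' @param config a [pk_io_config()].
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(study, path, config = pk_io_config()) {
  stopifnot(inherits(study, "pk_study"))
  cols <- config$columns
  token <- if (length(config$blq_tokens)) config$blq_tokens[1] else "BLQ"
  rows <- lapply(study, function(p) {
    conc <- ifelse(p$data$blq, token,
                   formatC(p$data$conc, digits = 17, format = "g"))
    stats::setNames(
      data.frame(p$subject_id, p$dose,
                 formatC(p$data$time, digits = 17, format = "g"),
                 conc, p$data$blq, stringsAsFactors = FALSE),
      c(cols$subject, cols$dose, cols$time, cols$conc,
        if (is.null(cols$blq)) "blq" else cols$blq))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = config$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a patch mass-balance table
#'
#' Expects columns `subject`, `content_labeled`, `content_residual`
#' (mg).
#'
#' @param path file to read.
#' @param sep field separator.
#' @return A list of [patch_record()] objects.
#' @export
read_patch_table <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("subject", "content_labeled", "content_residual")
  if (!all(need %in% names(raw)))
    stop("patch table must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(raw)), function(i)
    patch_record(raw$subject[i], raw$content_labeled[i],
                 raw$content_residual[i]))
}

#' Format a value as "mean +/- SD" with a rounding policy
#'
#' @param mean,sd numeric scalars.
#' @param policy `"signif3"` (3 significant figures, the report default) or
#'   `"dp1"` (1 decimal place).
#' @return A character scalar such as `"84.5 ± 56.0"`.
#' @export
format_mean_sd <- function(mean, sd, policy = c("signif3", "dp1")) {
  policy <- match.arg(policy)
  f <- switch(policy,
              signif3 = function(v) formatC(signif(v, 3), format = "fg",
                                            flag = "#", digits = 3),
              dp1 = function(v) formatC(round(v, 1), format = "f",
                                        digits = 1))
  sprintf("%s ± %s", sub("\\.$", "", f(mean)),
          if (is.na(sd)) "NA" else sub("\\.$", "", f(sd)))
}

#' Write a group-summary report table
#'
#' Writes a delimited report with one row per group (dose group or tissue),
#' columns for n, mean, SD, a formatted "mean +/- SD" string and, when
#' present, the 95 % CI bounds. Internal computations are always full
#' precision; the rounding policy affects only the formatted column.
#'
#' @param results data frame with at least columns `group`, `n`, `mean`,
#'   `sd`; optional `ci_lower`, `ci_upper`.
#' @param path output file.
#' @param policy rounding policy for the formatted column, see
#'   [format_mean_sd()].
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(results, path, policy = "signif3",
                                sep = ",") {
  if (!is.data.frame(results) || !nrow(results)) stop("empty results")
  need <- c("group", "n", "mean", "sd")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  results$mean_sd <- mapply(format_mean_sd, results$mean, results$sd,
                            MoreArgs = list(policy = policy))
  utils::write.table(results, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
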