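# Shared fixtures: published-style group summaries and profile builders.
# All fixtures are built in code; nothing is read from disk.

# Printed two-group tissue summaries (test plaster vs reference gel patch),
# as they would appear in a report: n, mean, SD per matrix. The reference
# synovial tissue row is the LLOQ-imputed summary (8 of 9 censored).
table5_summaries <- function() {
  list(
    synovial_tissue = list(
      test = list(n = 10L, mean = 84.5, sd = 56.0),
      ref  = list(n = 9L,  mean = 5.70, sd = 2.10)),
    synovial_fluid = list(
      test = list(n = 9L,  mean = 149,  sd = 44.9),
      ref  = list(n = 9L,  mean = 4.55, sd = 3.66)),
    plasma = list(
      test = list(n = 10L, mean = 362,  sd = 84.8),
      ref  = list(n = 9L,  mean = 10.5, sd = 10.1)),
    absorption_ratio = list(
      test = list(n = 10L, mean = 44.46, sd = 10.63),
      ref  = list(n = 9L,  mean = 5.82,  sd = 1.64)))
}

# Published per-dose mean PK parameters of the dose-escalation study
table2_means <- function() {
  data.frame(dose = c(2, 5, 10, 20, 40, 60),
             cmax = c(43.3, 114.5, 248.0, 444.1, 858.2, 1187.7),
             auc_0_inf = c(1051.0, 2801.4, 6055.8, 11705.3, 23129.8,
                           30236.9))
}

# exact mono-exponential decay profile C0 * exp(-ke t)
mono_profile <- function(C0 = 100, ke = 0.1, times = c(1, 2, 4, 8, 16, 24),
                         lloq = 1e-6, subject = "mono") {
  pk_profile(subject, dose = 20, time = times, conc = C0 * exp(-ke * times),
             lloq = lloq, wear_duration = 24)
}

# write a small concentration CSV and return its path
write_conc_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
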