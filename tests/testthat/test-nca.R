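test_that("cmax/tmax are read directly, ties broken by earliest time", {
  p <- pk_profile("S", 20, c(2, 12, 24), c(10, 50, 40), lloq = 1)
  expect_equal(cmax_tmax(p), c(cmax = 50, tmax = 12))
  tie <- pk_profile("S", 20, c(12, 14), c(50, 50), lloq = 1)
  expect_equal(cmax_tmax(tie), c(cmax = 50, tmax = 12))
  # a BLQ maximum cannot be Cmax
  masked <- pk_profile("S", 20, c(2, 12), c(10, NA), blq = c(FALSE, TRUE),
                       lloq = 1)
  expect_equal(unname(cmax_tmax(masked)["cmax"]), 10)
  allblq <- pk_profile("S", 20, c(2, 4), c(NA, NA), blq = c(TRUE, TRUE),
                       lloq = 1)
  expect_error(cmax_tmax(allblq), "no quantifiable")
})

test_that("noiseless zero-order input peaks at the end of wear", {
  p <- simulate_profile(20, transdermal_params(residual_cv = 0))
  ct <- cmax_tmax(p)
  expect_equal(unname(ct["tmax"]), 24)
  expect_equal(unname(ct["cmax"]),
               transdermal_conc(24, 20, log(2) / 8, 12.15, 0.641))
})

test_that("terminal window selection maximizes adjusted R-squared", {
  # exact mono-exponential tail: the full post-peak suffix wins, R^2 = 1
  times <- c(2, 24, 28, 32, 36, 47, 71)
  conc <- c(50, 100 * exp(-0.1 * 24), 100 * exp(-0.1 * c(28, 32, 36, 47, 71)))
  p <- pk_profile("S", 20, times, conc, lloq = 1e-6)
  win <- select_terminal_phase(p)
  expect_equal(win$time, c(24, 28, 32, 36, 47, 71))
  expect_equal(win$r2_adj, 1, tolerance = 1e-12)

  # a plateau point right after the peak spoils the early windows; the
  # best-adjusted-R^2 rule drops it.  Oracle: enumerate every candidate
  # suffix with lm() and pick the best by hand.
  times2 <- c(2, 10, 12, 24, 28, 32, 36, 47)
  conc2 <- c(40, 100, 99.5, 80 * exp(-0.09 * c(24, 28, 32, 36, 47)))
  p2 <- pk_profile("S", 20, times2, conc2, lloq = 1e-6)
  post <- data.frame(time = times2, conc = conc2)[times2 > 10, ]
  cand <- lapply(seq_len(nrow(post) - 2), function(s) post[s:nrow(post), ])
  adj <- vapply(cand, function(d) suppressWarnings(
    summary(lm(log(conc) ~ time, d))$adj.r.squared), numeric(1))
  expected <- cand[[which.max(adj)]]$time
  win2 <- select_terminal_phase(p2)
  expect_equal(win2$time, expected)
  expect_false(12 %in% win2$time)   # the plateau point is excluded

  # fewer than 3 post-peak points: terminal phase undefined, flagged
  p3 <- pk_profile("S", 20, c(2, 12, 24, 28), c(10, 50, 40, 30), lloq = 1)
  expect_false(select_terminal_phase(p3)$ok)
  fit3 <- nca(p3)
  expect_false(fit3$lambda_ok)
  expect_true(is.na(fit3$lambda_z) && is.na(fit3$t_half) &&
                is.na(fit3$auc_0_inf))
})

test_that("manual terminal window override is honoured", {
  p <- mono_profile(times = c(1, 2, 4, 8, 16, 24))
  win <- select_terminal_phase(p, window = c(8, 16, 24))
  expect_equal(win$time, c(8, 16, 24))
  expect_true(win$manual)
  expect_error(select_terminal_phase(p, window = c(16, 24)), "fewer than 3")
})

test_that("log-linear regression recovers exact rates", {
  # points lying exactly on ln C = 5 - 0.1 t
  t <- c(24, 28, 32, 36)
  win <- list(time = t, conc = exp(5 - 0.1 * t))
  f <- fit_lambda_z(win)
  expect_equal(f$lambda_z, 0.1, tolerance = 1e-12)
  expect_equal(f$r2_adj, 1, tolerance = 1e-12)

  # noiseless simulated subject: machine-precision recovery of ke
  ke <- 0.0866
  p <- simulate_profile(20, transdermal_params(ke = ke, residual_cv = 0))
  expect_equal(nca(p)$lambda_z, ke, tolerance = 1e-10)

  # rising tail is flagged, not returned as a negative rate
  bad <- list(time = c(24, 28, 32), conc = c(10, 20, 40))
  expect_false(fit_lambda_z(bad)$ok)
  expect_error(fit_lambda_z(list(time = c(24, 28, 32), conc = c(10, 0, 5))),
               "non-positive")
})

test_that("closed-form log-linear fit agrees with lm()", {
  set.seed(11)
  for (i in 1:20) {
    t <- sort(runif(6, 0, 48))
    conc <- exp(rnorm(6, 3, 1))
    f <- patchpk:::loglin_fit(t, conc)
    m <- lm(log(conc) ~ t)
    expect_equal(f$slope, unname(coef(m)[2]), tolerance = 1e-10)
    expect_equal(f$r2_adj, summary(m)$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("median lambda_z is near truth under proportional noise", {
  ke <- log(2) / 8
  pars <- transdermal_params(residual_cv = 0.10, bsv = list(
    ke = 0, v_f = 0, f_abs = 0))
  set.seed(101)
  est <- replicate(500, {
    p <- simulate_profile(20, pars, f_abs = 0.641,
                          subject_id = "rep")
    nca(p)$lambda_z
  })
  expect_lt(abs(median(est) - ke) / ke, 0.05)
})

test_that("half-life follows ln 2 over lambda_z", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(0.0866), 8.004, tolerance = 5e-4)
  expect_equal(round(half_life(0.0825), 1), 8.4)
  expect_error(half_life(0), "positive")
})

test_that("trapezoidal AUC handles anchors, plateaus and BLQ rules", {
  # leading BLQ contributes through a zero anchor at time 0
  p <- pk_profile("S", 20, c(0, 10), c(NA, 100), blq = c(TRUE, FALSE),
                  lloq = 1)
  expect_equal(auc_0_t(p), 500)
  # a true-zero baseline node gives the same single trapezoid
  p0 <- pk_profile("S", 20, c(0, 10), c(0, 100), lloq = 1)
  expect_equal(auc_0_t(p0), 500)
  # constant profile: a rectangle
  flat <- pk_profile("S", 20, seq(0, 24, by = 4), rep(50, 7), lloq = 1)
  expect_equal(auc_0_t(flat), 1200)
  # interior BLQ points are dropped from the nodes
  mid <- pk_profile("S", 20, c(0, 4, 8, 12), c(50, NA, 50, 50),
                    blq = c(FALSE, TRUE, FALSE, FALSE), lloq = 1)
  expect_equal(auc_0_t(mid), 600)
  # trailing BLQ truncates the profile: t and Ct come from the last
  # quantifiable point
  tail <- pk_profile("S", 20, c(0, 4, 8, 12), c(50, 50, 50, NA),
                     blq = c(FALSE, FALSE, FALSE, TRUE), lloq = 1)
  expect_equal(auc_0_t(tail), 400)
  expect_error(auc_0_t(pk_profile("S", 20, 2, 10, lloq = 1)),
               "at least 2")
})

test_that("dense sampling converges to the analytic integral", {
  t <- seq(0, 71, by = 0.1)
  p <- pk_profile("S", 20, t, 100 * exp(-0.1 * t), lloq = 1e-9)
  analytic <- 1000 * (1 - exp(-7.1))
  expect_lt(abs(auc_0_t(p) - analytic) / analytic, 0.001)
  # cross-check the trapezoid against an independent implementation
  skip_if_not_installed("pracma")
  expect_equal(auc_0_t(p), pracma::trapz(t, 100 * exp(-0.1 * t)),
               tolerance = 1e-12)
  # extrapolated total within 0.1 % of C0/ke
  fit <- nca(p)
  expect_lt(abs(fit$auc_0_inf - 1000) / 1000, 0.001)
})

test_that("extrapolation adds Ct over lambda_z", {
  ext <- auc_0_inf(400, c_t = 10, lambda_z = 0.1)
  expect_equal(ext$auc_0_inf, 500)
  expect_equal(ext$extrap_frac, 0.2)
  expect_error(auc_0_inf(400, c_t = 0, lambda_z = 0.1), "positive")
  expect_error(auc_0_inf(400, c_t = 10, lambda_z = 0), "positive")
})

test_that("NCA invariants hold across simulated subjects", {
  set.seed(3)
  sim <- simulate_study1(seed = 3)
  res <- suppressWarnings(nca_table(sim$study))
  ok <- res[res$lambda_ok, ]
  expect_gt(nrow(ok), 30)
  expect_equal(ok$t_half * ok$lambda_z, rep(log(2), nrow(ok)))
  expect_true(all(ok$auc_0_inf >= ok$auc_0_t))
  expect_true(all(ok$extrap_frac >= 0 & ok$extrap_frac < 1))
})

test_that("doubling concentrations scales areas and leaves rates alone", {
  p <- simulate_profile(20, transdermal_params(), seed = 9)
  d <- p$data
  p2 <- pk_profile("S2", p$dose, d$time[!d$blq], 2 * d$conc[!d$blq],
                   lloq = p$lloq)
  p1 <- pk_profile("S1", p$dose, d$time[!d$blq], d$conc[!d$blq],
                   lloq = p$lloq)
  f1 <- nca(p1); f2 <- nca(p2)
  expect_equal(f2$cmax, 2 * f1$cmax)
  expect_equal(f2$auc_0_t, 2 * f1$auc_0_t)
  expect_equal(f2$auc_0_inf, 2 * f1$auc_0_inf)
  expect_equal(f2$tmax, f1$tmax)
  expect_equal(f2$lambda_z, f1$lambda_z)
  expect_equal(f2$t_half, f1$t_half)
})

test_that("per-dose summaries use each group's own n", {
  # identical profiles give SD 0 for every parameter
  p <- mono_profile(subject = "a")
  study <- pk_study(list(a = p, b = mono_profile(subject = "b")))
  res <- nca_table(study)
  sm <- summarize_by_dose(res, params = c("cmax", "t_half"))
  expect_true(all(sm$sd == 0))
  expect_true(all(sm$n == 2))
  # single-profile group: mean is the value, SD undefined
  one <- summarize_by_dose(res[1, ], params = "cmax")
  expect_equal(one$mean, res$cmax[1])
  expect_true(is.na(one$sd))
  # a study-shaped replica yields the 6-dose x parameter summary layout
  sim <- simulate_study1(seed = 5)
  full <- suppressWarnings(nca_table(sim$study))
  tab <- summarize_by_dose(full)
  expect_setequal(unique(tab$dose), c(2, 5, 10, 20, 40, 60))
  expect_equal(nrow(tab), 6 * 4)
  expect_equal(tab$n[tab$dose == 20 & tab$parameter == "cmax"], 6)
  expect_equal(tab$n[tab$dose == 2 & tab$parameter == "cmax"], 7)
})

test_that("absorption ratio is the mass-balance fraction in percent", {
  expect_equal(absorption_ratio(patch_record("S", 20, 10))$ratio_percent, 50)
  expect_equal(absorption_ratio(patch_record("S", 20, 20))$ratio_percent, 0)
  expect_equal(absorption_ratio(20, 0)$ratio_percent, 100)
  expect_error(patch_record("S", 20, 25), "B <= A")
  expect_error(patch_record("S", 0, 0), "positive")
})

test_that("simulated patch residuals reproduce the configured mean ratio", {
  pars <- transdermal_params(f_abs = c("20" = 0.641))
  sim <- simulate_study1(n_per_dose = c("20" = 200), params = pars,
                         seed = 77)
  ratios <- sim$patches$absorption_ratio
  # truth 64.1 %, between-subject CV 25 % -> SE ~ 1.1 at n = 200
  expect_lt(abs(mean(ratios) - 64.1), 3.5)
  expect_true(all(ratios >= 0 & ratios <= 100))
})
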