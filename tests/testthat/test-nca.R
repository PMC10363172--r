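test_that("observed extrema read off correctly, with first-occurrence Tmax", {
  p <- make_profile(c(1, 8, 24), c(0.5, 2.0, 1.0))
  ext <- observed_extrema(p)
  expect_equal(ext[c("cmax", "tmax", "tlast", "clast")],
               list(cmax = 2.0, tmax = 8, tlast = 24, clast = 1.0))
  plateau <- observed_extrema(make_profile(c(1, 8, 24), c(1.0, 2.0, 2.0)))
  expect_equal(plateau$tmax, 8)  # earliest time attaining the max
  single <- observed_extrema(make_profile(8, 1.2))
  expect_equal(single, list(cmax = 1.2, tmax = 8, tlast = 8, clast = 1.2))
})

test_that("all-BLQ profiles signal no-quantifiable-data", {
  p <- make_profile(c(1, 8), c(NA, NA), blq = c(TRUE, TRUE))
  expect_error(observed_extrema(p), class = "depotnca_no_quantifiable_data")
  expect_error(run_nca(p), class = "depotnca_no_quantifiable_data")
})

test_that("segment areas follow the linear-up/log-down rule exactly", {
  expect_equal(auc_segment(0, 0, 1, 2), 1.0)
  expect_equal(auc_segment(1, 2.0, 2, 1.0), 1 / log(2), tolerance = 1e-12)
  expect_equal(auc_segment(1, 2.0, 2, 1.0), 1.442695, tolerance = 1e-6)
  expect_equal(auc_segment(0, 5, 2, 5), 10.0)     # flat -> linear branch
  expect_equal(auc_segment(0, 5, 2, 0), 5.0)      # down to zero -> linear
  expect_error(auc_segment(2, 1, 1, 2), "t2 > t1")
})

test_that("moment segment areas match their closed forms", {
  expect_equal(aumc_segment(1, 2.0, 2, 1.0), (2 - 2) / log(2) + 1 / log(2)^2,
               tolerance = 1e-12)
  expect_equal(aumc_segment(1, 2.0, 2, 1.0), 2.081368, tolerance = 1e-6)
  expect_equal(aumc_segment(0, 0, 1, 2), 1.0)     # moment trapezoid
  expect_equal(aumc_segment(3, 0, 5, 0), 0)
})

test_that("segment formulas agree with adaptive quadrature of the interpolant", {
  set.seed(2218)
  for (i in 1:250) {
    t1 <- runif(1, 0, 100); t2 <- t1 + runif(1, 0.05, 48)
    c1 <- runif(1, 0, 5)
    c2 <- if (i %% 3 == 0) 0 else runif(1, 0, 5)
    expect_equal(auc_segment(t1, c1, t2, c2),
                 segment_quadrature(t1, c1, t2, c2), tolerance = 1e-9)
    expect_equal(aumc_segment(t1, c1, t2, c2),
                 segment_quadrature(t1, c1, t2, c2, moment = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("auc_last anchors at (0, 0), is linear in scale, never shrinks with data", {
  p <- make_profile(c(1, 2), c(2.0, 1.0))
  a <- auc_last(p)
  expect_equal(a$auc_last, 1.0 + 1 / log(2), tolerance = 1e-12)
  doubled <- auc_last(make_profile(c(1, 2), c(4.0, 2.0)))
  expect_equal(doubled$auc_last, 2 * a$auc_last, tolerance = 1e-12)
  single <- auc_last(make_profile(8, 1.2))
  expect_equal(single$auc_last, 8 * 1.2 / 2)      # anchor segment only
  extended <- auc_last(make_profile(c(1, 2, 4), c(2.0, 1.0, 0.3)))
  expect_gt(extended$auc_last, a$auc_last)
})

test_that("BLQ policy: leading BLQ to zero, embedded and trailing excluded", {
  p <- make_profile(c(0.25, 1, 8, 24, 48, 72),
                    c(NA, 1.0, 2.0, NA, 0.5, NA),
                    blq = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  a <- auc_last(p)
  # segments: (0,0)-(0.25,0)-(1,1)-(8,2)-(48,0.5): embedded 24 h BLQ dropped,
  # trailing 72 h BLQ ignored
  manual <- auc_segment(0.25, 0, 1, 1) + auc_segment(1, 1, 8, 2) +
    auc_segment(8, 2, 48, 0.5)
  expect_equal(a$auc_last, manual, tolerance = 1e-12)
  ext <- observed_extrema(p)
  expect_equal(ext$tlast, 48)
})

test_that("lambda_z fit is exact on a noise-free mono-exponential tail", {
  tt <- c(8, 24, 48, 72)
  p <- make_profile(tt, 1.6 * exp(-0.0231 * tt))
  # make 8 h the Tmax by prepending a smaller leading sample
  p <- make_profile(c(1, tt), c(0.5, 1.6 * exp(-0.0231 * tt)))
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z, 0.0231, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_equal(fit$n_points, 3L)  # points strictly after Tmax (8 h excluded)
  expect_equal(fit$t_lower, 24)
  expect_equal(fit$t_upper, 72)
})

test_that("lambda_z window search skips the fast phase of a biphasic curve", {
  tt <- c(seq(0.5, 12, by = 0.5), seq(14, 96, by = 2))
  conc <- 2 * exp(-0.3 * tt) + 0.8 * exp(-0.025 * tt)
  fit <- fit_lambda_z(make_profile(tt, conc))
  expect_equal(fit$lambda_z, 0.025, tolerance = 0.01)
  expect_gt(fit$t_lower, 12)
})

test_that("profiles without a declining terminal phase are not estimable", {
  rising <- make_profile(c(1, 8, 24, 48, 72), c(0.1, 0.3, 0.7, 1.2, 2.0))
  expect_null(fit_lambda_z(rising))
  res <- run_nca(rising)
  expect_true("lambda_z_not_estimable" %in% res$flags)
  expect_true(is.na(res$t_half) && is.na(res$auc_inf) &&
                is.na(res$clearance_over_F) && is.na(res$mrt_inf))
  expect_false(is.na(res$auc_last))
  short <- make_profile(c(1, 8, 24), c(0.5, 2, 1))  # only 1 point after Tmax
  expect_null(fit_lambda_z(short))
})

test_that("half-life is ln(2) over lambda_z", {
  expect_equal(half_life(0.0231), 30.01, tolerance = 1e-3)
  expect_equal(half_life(0.0289), 23.98, tolerance = 1e-3)
  expect_equal(half_life(0.0462), half_life(0.0231) / 2, tolerance = 1e-12)
})

test_that("AUC extrapolation arithmetic, flagging and the clast limit", {
  fit <- structure(list(lambda_z = 0.02, intercept = 0, n_points = 3L,
                        adj_r2 = 1, t_lower = 24, t_upper = 72),
                   class = "lambda_z_fit")
  out <- auc_inf(55, clast = 0.5, tlast = 72, fit = fit)
  expect_equal(out$auc_inf, 80)
  expect_equal(out$pct_extrapolated, 31.25)
  expect_true(out$extrapolation_flag)
  tiny <- auc_inf(55, clast = 1e-12, tlast = 72, fit = fit)
  expect_equal(tiny$auc_inf, 55, tolerance = 1e-9)
  expect_false(tiny$extrapolation_flag)
})

test_that("clearance is dose over AUC0-inf in consistent units", {
  expect_equal(clearance_over_F(0.15, 75), 2.0)
  expect_equal(clearance_over_F(0.30, 75), 4.0)
})

test_that("MRT matches closed forms for exponential and Bateman profiles", {
  # IV-like mono-exponential from t = 0: MRT_inf = 1/ke
  ke <- 0.05
  tt <- seq(0, 400, by = 0.25)
  prof <- pk_profile(tt, 2 * exp(-ke * tt), dose = NA_real_)
  res <- run_nca(prof, nca_options(threshold = NA))
  expect_equal(res$mrt_inf, 1 / ke, tolerance = 0.01)
  # single-depot Bateman: MRT_inf = 1/ka + 1/ke
  p <- single_depot_params(ka = 0.4)
  sched <- dense_schedule()
  res2 <- run_nca(make_profile(sched, dual_bateman_concentration(sched, 0.15, p)))
  expect_equal(res2$mrt_inf, 1 / 0.4 + 1 / p$ke, tolerance = 0.01)
  expect_gte(res2$mrt_inf, res2$mrt_last)
})

test_that("threshold timing: extrapolation, interpolation, and censoring", {
  fit <- structure(list(lambda_z = 0.0231, intercept = 0, n_points = 3L,
                        adj_r2 = 1, t_lower = 24, t_upper = 72),
                   class = "lambda_z_fit")
  tt <- c(0.25, 0.5, 1, 8, 24, 48, 72)
  cc <- c(0.3, 0.5, 0.9, 1.8, 1.2, 0.7, 0.4)
  ext <- time_above_threshold(tt, cc, 0.1, fit)
  expect_equal(ext$onset, 0.25)
  expect_equal(ext$crossing, 72 + log(4) / 0.0231, tolerance = 1e-10)
  expect_equal(ext$crossing, 132.02, tolerance = 1e-4)
  expect_equal(ext$duration, ext$crossing - 0.25)
  expect_true(ext$extrapolated)
  cens <- time_above_threshold(tt, cc, 0.1, fit = NULL)
  expect_true(cens$censored)
  expect_equal(cens$duration, 72 - 0.25)
  interp <- time_above_threshold(c(24, 48, 72), c(0.5, 0.2, 0.05), 0.1)
  expect_equal(interp$crossing, 48 + 24 * log(0.2 / 0.1) / log(0.2 / 0.05),
               tolerance = 1e-12)
  expect_equal(interp$crossing, 60)
  below <- time_above_threshold(c(1, 8), c(0.01, 0.02), 0.1)
  expect_equal(below$duration, 0)
  expect_true(is.na(below$onset))
  expect_error(time_above_threshold(c(1, 2), c(1, 1), -0.1), "threshold")
})

test_that("run_nca is invariant to input row order and scale-equivariant", {
  p <- typical_params()
  sched <- c(0.25, 0.5, 1, 8, 24, 48, 72)
  conc <- dual_bateman_concentration(sched, 0.15, p)
  base <- run_nca(make_profile(sched, conc))
  perm <- sample(seq_along(sched))
  shuffled <- run_nca(make_profile(sched[perm], conc[perm]))
  expect_identical(unclass(base)[-1], unclass(shuffled)[-1])
  s <- 3.7
  scaled <- run_nca(make_profile(sched, s * conc))
  for (lin in c("cmax", "clast", "auc_last", "auc_inf")) {
    expect_equal(scaled[[lin]], s * base[[lin]], tolerance = 1e-10)
  }
  expect_equal(scaled$clearance_over_F, base$clearance_over_F / s,
               tolerance = 1e-10)
  for (inv in c("tmax", "tlast", "lambda_z", "t_half", "mrt_last", "mrt_inf")) {
    expect_equal(scaled[[inv]], base[[inv]], tolerance = 1e-10)
  }
})

test_that("predicted-clast mode uses the regression value at tlast", {
  tt <- c(1, 8, 24, 48, 72)
  cc <- c(0.5, 2, 1.1, 0.52, 0.26)
  prof <- make_profile(tt, cc)
  obs <- run_nca(prof, nca_options(clast_mode = "observed"))
  pred <- run_nca(prof, nca_options(clast_mode = "predicted"))
  fit <- fit_lambda_z(prof)
  clast_hat <- exp(fit$intercept - fit$lambda_z * 72)
  expect_equal(pred$auc_inf - pred$auc_last, clast_hat / fit$lambda_z,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(obs$auc_inf, pred$auc_inf)))
})
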