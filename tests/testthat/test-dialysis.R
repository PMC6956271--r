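grid_h <- seq(0.5, 5, by = 0.5)

test_that("noiseless exponential decay is inverted exactly", {
  run <- dialysis_run("control", "control", grid_h,
                      100 * exp(-0.44 * grid_h), cd0 = 100)
  fit <- fit_log_linear(run)
  expect_equal(fit$slope_mag, 0.44)
  expect_equal(fit$intercept, log(100), tolerance = 1e-10)
  expect_equal(fit$r2, 1.0)
  expect_identical(fit$status, "ok")
})

test_that("constant donor series yields zero slope", {
  run <- dialysis_run("flat", "formulation", grid_h, rep(80, length(grid_h)),
                      cd0 = 80)
  fit <- fit_log_linear(run)
  expect_equal(fit$slope_mag, 0)
})

test_that("fit recovers a generated slope within 3 standard errors", {
  run <- gen_dialysis_run(km = 0.44, ff = 0.52, cd0 = 100, times = grid_h,
                          noise = 0.02, seed = 42)
  fit <- fit_log_linear(run)
  expect_lt(abs(fit$slope_mag - 0.44 * 0.52), 3 * fit$slope_se)
})

test_that("degenerate and invalid runs are rejected", {
  expect_error(dialysis_run("x", "control", c(1, 2), c(9, 8)),
               class = "ocunano_insufficient_data_error")
  expect_error(dialysis_run("x", "control", c(1, 1, 2), c(9, 8, 7)),
               class = "ocunano_domain_error")
  run <- dialysis_run("x", "control", grid_h, 100 * exp(-0.1 * grid_h),
                      cd0 = 100)
  run$donor_conc[3] <- -1
  expect_error(fit_log_linear(run), class = "ocunano_domain_error")
  # rising donor concentration is flagged, not fatal
  rising <- dialysis_run("up", "formulation", c(1, 2, 3), c(50, 60, 70),
                         cd0 = 100)
  expect_warning(fitr <- fit_log_linear(rising),
                 class = "ocunano_rising_donor_warning")
  expect_identical(fitr$status, "warning")
  expect_gt(fitr$slope_mag, 0)
})

test_that("Km calibration takes the control slope and rejects degenerate ones", {
  ctrl <- fit_log_linear(
    dialysis_run("c", "control", grid_h, 100 * exp(-0.44 * grid_h), cd0 = 100))
  expect_equal(calibrate_km(ctrl), 0.44)
  one <- fit_log_linear(
    dialysis_run("c", "control", grid_h, 100 * exp(-1 * grid_h), cd0 = 100))
  expect_equal(calibrate_km(one), 1.0)
  flat <- fit_log_linear(
    dialysis_run("c", "control", grid_h, rep(100, length(grid_h)), cd0 = 100))
  expect_error(calibrate_km(flat),
               class = "ocunano_degenerate_calibration_error")
  form <- fit_log_linear(
    dialysis_run("f", "formulation", grid_h, 100 * exp(-0.3 * grid_h),
                 cd0 = 100))
  expect_error(calibrate_km(form), class = "ocunano_domain_error")
})

test_that("bound fraction completes the fit and clamps noisy ratios", {
  mkfit <- function(slope) fit_log_linear(
    dialysis_run("f", "formulation", grid_h, 100 * exp(-slope * grid_h),
                 cd0 = 100))
  f <- bound_fraction(mkfit(0.23), km = 0.44)
  expect_equal(round(f$interaction_pct, 1), 47.7)
  expect_equal(f$interaction_pct, 100 * (1 - f$ff))
  f2 <- bound_fraction(mkfit(0.37), km = 0.44)
  expect_equal(round(f2$interaction_pct, 1), 15.9)
  # slope equal to Km: no binding
  f3 <- bound_fraction(mkfit(0.44), km = 0.44)
  expect_equal(f3$interaction_pct, 0, tolerance = 1e-9)
  # ratio > 1 clamps with a warning
  expect_warning(f4 <- bound_fraction(mkfit(0.5), km = 0.44),
                 class = "ocunano_ff_clamp_warning")
  expect_equal(f4$ff, 1)
  expect_error(bound_fraction(mkfit(0.3), km = 0),
               class = "ocunano_domain_error")
})

test_that("interaction decreases strictly as the slope rises towards Km", {
  km <- 0.44
  slopes <- seq(0.05, km, length.out = 12)
  ints <- vapply(slopes, function(s) {
    fit <- fit_log_linear(
      dialysis_run("f", "formulation", grid_h, 100 * exp(-s * grid_h),
                   cd0 = 100))
    bound_fraction(fit, km)$interaction_pct
  }, numeric(1))
  expect_true(all(diff(ints) < 0))
})

test_that("control intercept stays near ln(100) on noiseless data", {
  for (km in c(0.2, 0.44, 0.9)) {
    fit <- fit_log_linear(
      dialysis_run("c", "control", grid_h, 100 * exp(-km * grid_h), cd0 = 100))
    expect_lt(abs(fit$intercept - log(100)), 0.1)
  }
})

test_that("replicated experiment table averages slopes and flags differences", {
  mk_rows <- function(label, role, rate, reps, seed0) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      run <- gen_dialysis_run(rate, 1, 100, grid_h, noise = 0.02,
                              seed = seed0 + r)
      data.frame(label = label, role = role, replicate = r,
                 time_h = run$times, donor_conc = run$donor_conc)
    }))
  }
  dat <- rbind(mk_rows("Control", "control", 0.44, 4, 100),
               mk_rows("QA-Ch", "formulation", 0.23, 4, 200))
  tab <- fit_binding_experiment(dat)
  expect_setequal(tab$label, c("Control", "QA-Ch"))
  qa <- tab[tab$label == "QA-Ch", ]
  expect_equal(qa$slope_mag, 0.23, tolerance = 0.05)
  expect_equal(qa$interaction_pct, 100 * (1 - qa$ff))
  expect_true(qa$significant)          # 0.23 vs 0.44 is a large difference
  expect_true(is.finite(qa$slope_sd))
  # pooled fitting agrees closely with per-replicate averaging here
  pooled <- fit_binding_experiment(dat, pooled = TRUE)
  expect_equal(pooled$slope_mag[pooled$label == "QA-Ch"], qa$slope_mag,
               tolerance = 0.02)
})
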