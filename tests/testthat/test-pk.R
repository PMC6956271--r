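test_that("trapezoidal AUC matches closed-form shapes", {
  # rectangle: constant 0.3 over 0-10 h
  p <- pk_profile("const", c(0, 2, 4, 6, 8, 10), rep(0.3, 6), 0.05, 6)
  expect_equal(trapezoid_auc(p)$auc, 3.0)
  # triangle: 0 at 0 h to 1 at 10 h
  tri <- pk_profile("tri", c(0, 10), c(0, 1), 0, 6)
  expect_equal(trapezoid_auc(tri)$auc, 5.0)
  # missing t = 0 is prepended as zero concentration
  late <- pk_profile("late", c(5, 10), c(1, 1), 0, 6)
  expect_equal(trapezoid_auc(late)$auc, 0.5 * 5 * 1 + 5 * 1)
  expect_error(trapezoid_auc(late, t_end = 12), class = "ocunano_domain_error")
})

test_that("AUC agrees with an independent quadrature oracle to 1e-9", {
  skip_if_not_installed("pracma")
  set.seed(51)
  for (i in 1:10) {
    tt <- sort(c(0, runif(6, 0.1, 9.9), 10))
    cc <- runif(8, 0, 2)
    p <- pk_profile("rand", tt, cc, 0.1, 6)
    auc <- trapezoid_auc(p)$auc
    # oracle: fine-grid trapezoid of the piecewise-linear interpolant,
    # grid containing all breakpoints
    fine <- sort(unique(c(tt, seq(0, 10, length.out = 2001))))
    oracle <- pracma::trapz(fine, approx(tt, cc, xout = fine)$y)
    expect_equal(auc, oracle, tolerance = 1e-9)
  }
})

test_that("AUC is additive over adjacent windows and collinear-point invariant", {
  tt <- c(0, 1, 2, 4, 5, 7, 10)
  cc <- c(0, 0.8, 1.0, 1.1, 1.0, 0.9, 0.4)
  p <- pk_profile("x", tt, cc, 0.1, 6)
  whole <- trapezoid_auc(p, 0, 10)$auc
  expect_equal(trapezoid_auc(p, 0, 5)$auc + trapezoid_auc(p, 5, 10)$auc,
               whole)
  # interpolated interior bound
  expect_equal(trapezoid_auc(p, 0, 3)$auc + trapezoid_auc(p, 3, 10)$auc,
               whole)
  # inserting a collinear midpoint leaves the AUC unchanged
  t_new <- c(0, 1, 2, 3, 4, 5, 7, 10)
  c_new <- c(0, 0.8, 1.0, 1.05, 1.1, 1.0, 0.9, 0.4)
  expect_equal(trapezoid_auc(pk_profile("y", t_new, c_new, 0.1, 6))$auc,
               whole)
})

test_that("the propagated AUC variance tracks the Monte-Carlo spread", {
  k_in <- 1.0; t1 <- 10; k_el <- 3; n <- 6; sdr <- 0.15
  aucs <- vapply(1:400, function(s) {
    trapezoid_auc(gen_pk_profile(k_in, t1, k_el, sdr, n, seed = s))$auc
  }, numeric(1))
  # propagation formula evaluated on the noiseless profile
  tt <- c(0.5, 1, 2, 4, 6, 8, 10)
  mu <- ocunano:::pk_model_conc(tt, k_in, t1, k_el)
  p0 <- pk_profile("mu", tt, mu, sd_conc = mu * sdr, n_per_time = n)
  pred_sd <- trapezoid_auc(p0)$sd_auc
  expect_lt(abs(sd(aucs) / pred_sd - 1), 0.15)
})

test_that("relative AUC reproduces reported ratios at 1 decimal", {
  expect_equal(relative_auc(list(auc = 2.32), list(auc = 0.62)), 3.7)
  expect_equal(relative_auc(list(auc = 3.34), list(auc = 0.62)), 5.4)
  expect_equal(relative_auc(list(auc = 1.7), list(auc = 1.7)), 1.0)
  expect_error(relative_auc(list(auc = 1), list(auc = 0)),
               class = "ocunano_domain_error")
})

test_that("AUC comparison is symmetric-null and errors on degenerate input", {
  p <- pk_profile("a", c(0, 5, 10), c(0, 1, 1), 0.2, 6)
  r <- trapezoid_auc(p)
  same <- compare_auc(r, r)
  expect_equal(same$statistic, 0)
  expect_false(same$significant)
  r0 <- trapezoid_auc(pk_profile("b", c(0, 5, 10), c(0, 1, 1), 0, 6))
  expect_error(compare_auc(r0, r0), class = "ocunano_degenerate_test_error")
  # t reference with per-time contributions gives a finite df
  contrib <- auc_contributions(p)
  tt <- compare_auc(r, r, reference = "t", df_a = contrib, df_b = contrib)
  expect_true(is.finite(tt$df) && tt$df > 0)
})

test_that("profiles built to mimic distinct exposures separate reliably", {
  # control-like (low plateau) versus high-exposure formulation
  rej <- 0
  for (s in 1:50) {
    lo <- trapezoid_auc(gen_pk_profile(0.21, 10, 3, 0.15, 6, seed = 2 * s))
    hi <- trapezoid_auc(gen_pk_profile(1.10, 10, 3, 0.15, 6, seed = 2 * s + 1))
    if (compare_auc(hi, lo)$significant) rej <- rej + 1
  }
  expect_gte(rej / 50, 0.8)
})

test_that("the experiment wrapper reproduces the fixture summary table", {
  # reconstruct flat profiles whose exact AUCs equal the fixture values
  fx <- read.csv(system.file("extdata", "auc_summary.csv",
                             package = "ocunano"))
  tt <- c(1, 2, 4, 6, 8, 10)
  rows <- do.call(rbind, lapply(seq_len(nrow(fx)), function(i) {
    css <- fx$auc_ug_h_ml[i] / 9.5 # AUC of 0-1 h ramp + 1-10 h plateau
    data.frame(label = fx$label[i], time_h = tt, mean_conc_ug_ml = css,
               sd_conc = 0.15 * css, n = 6)
  }))
  res <- fit_pk_experiment(rows, control_label = "Control")
  expect_equal(res$summary$auc_rel[match(c("TSOH", "Ch NP+TSOH",
                                           "QA-Ch NP+TSOH", "SB-Ch NP+TSOH"),
                                         res$summary$label)],
               c(3.7, 3.6, 5.3, 5.4))
})
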