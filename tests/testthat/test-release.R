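min_grid <- seq(30, 300, by = 30)

test_that("noiseless square-root curves are inverted exactly", {
  f <- fit_higuchi(release_curve("Ch NP+TSOH", min_grid,
                                 3.34 * sqrt(min_grid) + 1.6))
  expect_equal(f$slope, 3.34)
  expect_equal(f$intercept, 1.6)
  expect_equal(f$r2, 1.0)
  expect_identical(f$time_unit, "min")
  expect_false(f$intercept_flagged)

  flat <- fit_higuchi(release_curve("flat", min_grid, rep(0, 10)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 0)
})

test_that("generated noisy curves recover the slope within 3 SE", {
  f <- fit_higuchi(gen_release_curve(2.43, 0, min_grid, noise = 1,
                                     seed = 7))
  expect_lt(abs(f$slope - 2.43), 3 * f$slope_se)
})

test_that("fits with too few points or burst intercepts are handled", {
  expect_error(fit_higuchi(release_curve("x", c(30, 60, 90), c(5, 8, 10))),
               class = "ocunano_insufficient_data_error")
  burst <- fit_higuchi(release_curve("x", min_grid,
                                     2 * sqrt(min_grid) + 10))
  expect_true(burst$intercept_flagged)
})

test_that("prediction is the fitted line clamped to [0, 100]", {
  f <- fit_higuchi(release_curve("x", min_grid, 3.34 * sqrt(min_grid) + 1.6))
  expect_equal(predict_release(f, 300), 3.34 * sqrt(300) + 1.6)
  expect_equal(predict_release(f, 0), f$intercept)
  f10 <- structure(list(slope = 10, intercept = 0, time_unit = "min"),
                   class = "higuchi_fit")
  expect_equal(predict_release(f10, 144), 100)
  expect_error(predict_release(f, -1), class = "ocunano_domain_error")
})

test_that("fit and predict round-trip on noiseless grids, also subsampled", {
  set.seed(31)
  for (i in 1:10) {
    slope <- runif(1, 0.5, 4); icpt <- runif(1, -1, 3)
    q <- slope * sqrt(min_grid) + icpt
    f <- fit_higuchi(release_curve("rt", min_grid, q))
    expect_equal(f$slope, slope, tolerance = 1e-9)
    expect_equal(f$intercept, icpt, tolerance = 1e-9)
    # refit on predictions reproduces the coefficients
    f2 <- fit_higuchi(release_curve("rt2", min_grid,
                                    predict_release(f, min_grid)))
    expect_equal(f2$slope, slope, tolerance = 1e-9)
    # subsampling the grid by 2 leaves the slope unchanged
    sub <- min_grid[seq(1, length(min_grid), by = 2)]
    f3 <- fit_higuchi(release_curve("rt3", sub, slope * sqrt(sub) + icpt))
    expect_equal(f3$slope, slope, tolerance = 1e-9)
  }
})

test_that("slope comparison matches a direct t-test and flags differences", {
  a <- c(2.43, 2.22, 2.64); b <- c(3.34, 3.02, 3.66)
  res <- compare_slopes(a, b)
  oracle <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$p, oracle$p.value)
  expect_equal(res$t, unname(oracle$statistic))
  expect_true(res$significant)

  same <- compare_slopes(c(2, 3, 4), c(4, 3, 2))
  expect_false(same$significant)
  expect_equal(same$p, 1.0)
  expect_error(compare_slopes(2.4, c(3.3, 3.0)),
               class = "ocunano_insufficient_data_error")
})

test_that("slope comparison holds its nominal type-I error", {
  nsim <- 1000
  rej <- 0
  for (s in seq_len(nsim)) {
    sa <- vapply(1:3, function(r)
      fit_higuchi(gen_release_curve(3.0, 1, min_grid, noise = 1,
                                    seed = 6 * s + r))$slope, numeric(1))
    sb <- vapply(4:6, function(r)
      fit_higuchi(gen_release_curve(3.0, 1, min_grid, noise = 1,
                                    seed = 6 * s + r))$slope, numeric(1))
    if (compare_slopes(sa, sb)$significant) rej <- rej + 1
  }
  expect_gte(rej / nsim, 0.03)
  expect_lte(rej / nsim, 0.07)
})

test_that("the experiment wrapper summarises replicates and pairwise tests", {
  mk <- function(label, slope, seed0) do.call(rbind, lapply(1:3, function(r) {
    cv <- gen_release_curve(slope, 1, min_grid, noise = 1, seed = seed0 + r,
                            label = label, replicate = r)
    data.frame(label = label, replicate = r, time_min = cv$times,
               released_pct = cv$released_pct)
  }))
  dat <- rbind(mk("QA-Ch NP+TSOH", 3.14, 10), mk("SB-Ch NP+TSOH", 2.43, 20))
  res <- fit_release_experiment(dat)
  expect_equal(res$summary$slope[res$summary$label == "SB-Ch NP+TSOH"], 2.43,
               tolerance = 0.15)
  expect_true(is.finite(res$p_matrix["QA-Ch NP+TSOH", "SB-Ch NP+TSOH"]))
  expect_equal(res$p_matrix[1, 2], res$p_matrix[2, 1])
})
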