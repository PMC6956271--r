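kB <- 1.380649e-23

test_that("the scattering vector follows the standard DLS formula", {
  # sin(90 deg) = 1: q = 4 pi n / lambda
  expect_equal(scattering_vector(633, 1.33, 180),
               4 * pi * 1.33 / 633e-9, tolerance = 1e-12)
  expect_equal(scattering_vector(633, 1.33, 180), 2.641e7,
               tolerance = 1e-3)
  expect_equal(scattering_vector(633, 1.33, 173),
               4 * pi * 1.33 / 633e-9 * sin(173 / 2 * pi / 180),
               tolerance = 1e-12)
  expect_error(scattering_vector(633, 1.33, 0),
               class = "ocunano_domain_error")
})

test_that("MSD inversion recovers free diffusion of a water-like fluid", {
  eta <- 0.89e-3; a <- 250e-9; temp <- 298.15
  D <- kB * temp / (6 * pi * eta * a)
  cg <- gen_dls_g2("newtonian", list(eta_Pa_s = eta),
                   temperature_K = temp, tracer_radius_nm = 250)
  msd <- msd_from_g2(cg)
  expect_gt(nrow(msd), 10)
  fit <- lm(msd_m2 ~ 0 + lag_s, data = msd)
  expect_equal(unname(coef(fit)[1]), 6 * D, tolerance = 0.01)
})

test_that("a frozen tracer gives zero MSD and beta misconfiguration warns", {
  lags <- 10^seq(-5, 1, length.out = 40)
  frozen <- correlogram(lags, rep(1 + 0.9, length(lags)), beta = 0.9)
  msd <- msd_from_g2(frozen)
  expect_lt(max(abs(msd$msd_m2)), 1e-22)
  # beta set below the true coherence: g1^2 apparently exceeds 1
  low_beta <- correlogram(lags, rep(1 + 0.9, length(lags)), beta = 0.5)
  expect_warning(msd2 <- msd_from_g2(low_beta),
                 class = "ocunano_beta_warning")
  expect_true(all(msd2$msd_m2 == 0)) # clamped at g1 = 1
  # pure noise around baseline: no retained lags
  set.seed(3)
  noise_only <- correlogram(lags, 1 + rnorm(40, 0, 1e-8), beta = 0.9,
                            tol = 0.05)
  expect_error(msd_from_g2(noise_only),
               class = "ocunano_insufficient_signal_error")
})

test_that("GSER recovers Newtonian viscosity across half a decade sweep", {
  for (eta in c(0.5e-3, 2e-3, 10e-3, 50e-3)) {
    cg <- gen_dls_g2("newtonian", list(eta_Pa_s = eta),
                     lags = 10^seq(-6, 1, length.out = 70))
    mod <- gser_moduli(msd_from_g2(cg), 250, 298.15)
    lo <- quantile(log10(mod$omega_rad_s), 0.3)
    hi <- quantile(log10(mod$omega_rad_s), 0.7)
    mid <- mod[log10(mod$omega_rad_s) >= lo & log10(mod$omega_rad_s) <= hi, ]
    expect_lt(max(abs(mid$eta_star_Pa_s / eta - 1)), 0.02)
    expect_lt(max(abs(mid$g_prime_Pa)), 0.02 * min(mid$g_dprime_Pa))
    # G'' = eta * omega for a Newtonian fluid
    expect_equal(mid$g_dprime_Pa, eta * mid$omega_rad_s, tolerance = 0.02)
  }
})

test_that("an elastic plateau recovers G' = kB T / (pi a delta^2)", {
  d2 <- 5e-15; a <- 250e-9; temp <- 298.15
  cg <- gen_dls_g2("plateau", list(delta2_m2 = d2),
                   temperature_K = temp, tracer_radius_nm = 250)
  mod <- gser_moduli(msd_from_g2(cg), 250, temp)
  expect_equal(unique(round(mod$alpha, 10)), 0)
  expect_lt(max(abs(mod$g_prime_Pa / (kB * temp / (pi * a * d2)) - 1)), 0.02)
  expect_lt(max(mod$g_dprime_Pa), 1e-10 * max(mod$g_prime_Pa))
})

test_that("a Maxwell fluid crosses G' and G'' near its relaxation rate", {
  lam <- 0.05
  cg <- gen_dls_g2("maxwell", list(G0_Pa = 0.5, lambda_s = lam),
                   lags = 10^seq(-5, 1, length.out = 80))
  mod <- gser_moduli(msd_from_g2(cg), 250, 298.15)
  ratio <- mod$g_prime_Pa / mod$g_dprime_Pa
  # find the frequency where the ratio crosses 1
  cross <- which(diff(sign(ratio - 1)) != 0)
  expect_gt(length(cross), 0)
  w_cross <- mod$omega_rad_s[cross[length(cross)]]
  expect_lt(abs(log10(w_cross * lam)), 0.35) # within grid resolution
})

test_that("moduli spectra satisfy their internal invariants", {
  cg <- gen_dls_g2("maxwell", list(G0_Pa = 1, lambda_s = 0.02),
                   noise = 1e-4, seed = 5)
  mod <- gser_moduli(msd_from_g2(cg), 250, 298.15)
  expect_true(all(mod$g_prime_Pa >= 0))
  expect_true(all(mod$g_dprime_Pa >= 0))
  expect_equal(mod$eta_star_Pa_s,
               sqrt(mod$g_prime_Pa^2 + mod$g_dprime_Pa^2) / mod$omega_rad_s,
               tolerance = 1e-12)
  expect_error(gser_moduli(data.frame(lag_s = 1:3, msd_m2 = c(1, -1, 1) * 1e-14),
                           250, 298.15),
               class = "ocunano_domain_error")
})

test_that("mucoadhesion comparison ranks thickened dispersions correctly", {
  cg_mucin <- gen_dls_g2("newtonian", list(eta_Pa_s = 2e-3))
  mod_mucin <- gser_moduli(msd_from_g2(cg_mucin), 250, 298.15)

  # identical spectra: not mucoadhesive, all ratios 1
  same <- mucoadhesion_compare(mod_mucin, mod_mucin)
  expect_false(same$mucoadhesive)
  expect_equal(unique(round(same$table$eta_ratio, 12)), 1)

  # uniform 2x viscosity: mucoadhesive with ratio 2
  cg_2x <- gen_dls_g2("newtonian", list(eta_Pa_s = 4e-3))
  mod_2x <- gser_moduli(msd_from_g2(cg_2x), 250, 298.15)
  two <- mucoadhesion_compare(mod_mucin, mod_2x)
  expect_true(two$mucoadhesive)
  expect_equal(two$median_eta_ratio, 2, tolerance = 0.02)

  # cationic-like > anionic-like > mucin ordering is preserved
  cg_mid <- gen_dls_g2("newtonian", list(eta_Pa_s = 3e-3))
  mod_mid <- gser_moduli(msd_from_g2(cg_mid), 250, 298.15)
  rank <- mucoadhesion_rank(mod_mucin,
                            list(`QA-Ch NP` = mod_2x, `SB-Ch NP` = mod_mid))
  expect_equal(rank$label, c("QA-Ch NP", "SB-Ch NP"))
  expect_true(all(rank$mucoadhesive))
})
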