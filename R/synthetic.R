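# Synthetic-data generators.
#
# Every input the analysis stages consume can be generated here with
# known ground truth, which makes the full pipeline testable end to end:
# generator truth in, analysis estimate out, tolerance checked. All
# generators are deterministic under a fixed seed (a private RNG stream
# that does not disturb the session RNG).

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Generate a dynamic-dialysis donor-phase decay
#'
#' Exponential donor decay with rate \code{km * ff} and multiplicative
#' Gaussian measurement noise:
#' \code{C_d(t) = cd0 exp(-km ff t) (1 + e_t)}, \code{e_t ~ N(0, noise)}.
#'
#' @param km Membrane constant (h^-1), > 0.
#' @param ff Free (non-interacting) drug fraction in [0, 1].
#' @param cd0 Donor concentration at t = 0, > 0.
#' @param times Sampling grid (h), strictly increasing, > 0.
#' @param noise Relative SD of the multiplicative noise, >= 0.
#' @param seed Integer seed; fixed seed reproduces the run exactly.
#' @param label,role Passed through to [dialysis_run()].
#' @return A [dialysis_run].
#' @examples
#' gen_dialysis_run(0.44, 1, 100, seq(0.5, 5, 0.5), 0, 1)
#' @export
gen_dialysis_run <- function(km, ff, cd0 = 100,
                             times = seq(0.5, 5, by = 0.5),
                             noise = 0.02, seed = NULL,
                             label = sprintf("sim Km=%.3g Ff=%.3g", km, ff),
                             role = if (ff >= 1) "control" else "formulation") {
  check_number(km, "km", lower = 0, strict_lower = TRUE)
  check_number(ff, "ff", lower = 0, upper = 1)
  check_number(noise, "noise", lower = 0)
  conc <- with_seed(seed, {
    cd0 * exp(-km * ff * times) * (1 + stats::rnorm(length(times), 0, noise))
  })
  # keep the run physical under heavy noise draws
  conc <- pmax(conc, cd0 * 1e-9)
  dialysis_run(label, role, times, conc, cd0 = cd0,
               tol = max(0.05, 5 * noise))
}

#' Generate a Higuchi release curve
#'
#' \code{Q(t) = slope sqrt(t) + intercept + e_t}, \code{e_t ~ N(0, noise)}
#' in percentage points, clamped to [0, 100].
#'
#' @param slope Higuchi slope (percent per sqrt time unit), >= 0.
#' @param intercept Ordinate intercept (percent).
#' @param times_min Sampling grid (min), strictly increasing, > 0.
#' @param noise Additive noise SD (percentage points), >= 0.
#' @param seed Integer seed.
#' @param label Curve label.
#' @param replicate Replicate index.
#' @return A [release_curve].
#' @export
gen_release_curve <- function(slope, intercept = 0,
                              times_min = seq(30, 300, by = 30),
                              noise = 1, seed = NULL, label = "sim",
                              replicate = 1L) {
  check_number(slope, "slope", lower = 0)
  check_number(noise, "noise", lower = 0)
  q <- with_seed(seed, {
    slope * sqrt(times_min) + intercept +
      stats::rnorm(length(times_min), 0, noise)
  })
  release_curve(label, times_min, clamp(q, 0, 100), replicate = replicate,
                tol = 1)
}

#' True AUC of the plateau pharmacokinetic model
#'
#' Closed-form integral of the zero-order-input / first-order-elimination
#' concentration curve used by [gen_pk_profile()], over \code{[0, t_end]}.
#'
#' @inheritParams gen_pk_profile
#' @param t_end Upper integration bound (h).
#' @return AUC in ug h/mL.
#' @export
pk_true_auc <- function(k_in, t_plateau_end, k_el, t_end = 10) {
  css <- k_in / k_el
  t1 <- min(t_plateau_end, t_end)
  # rising/plateau phase: integral of css (1 - exp(-k_el t))
  auc <- css * (t1 - (1 - exp(-k_el * t1)) / k_el)
  if (t_end > t_plateau_end) {
    c1 <- css * (1 - exp(-k_el * t_plateau_end))
    auc <- auc + c1 * (1 - exp(-k_el * (t_end - t_plateau_end))) / k_el
  }
  auc
}

# model concentration at time t (vectorized)
pk_model_conc <- function(t, k_in, t_plateau_end, k_el) {
  css <- k_in / k_el
  c1 <- css * (1 - exp(-k_el * t_plateau_end))
  ifelse(t <= t_plateau_end,
         css * (1 - exp(-k_el * t)),
         c1 * exp(-k_el * (t - t_plateau_end)))
}

#' Generate a sparse-sampling aqueous-humor PK profile
#'
#' One-compartment model with zero-order input (gel-erosion-controlled
#' absorption) at rate \code{k_in} until \code{t_plateau_end}, first-order
#' elimination \code{k_el} throughout. With \code{k_el} around 2-4 h^-1
#' the profile rises to its plateau \code{C_ss = k_in / k_el} within about
#' an hour and stays flat through the input window -- the plateau-shaped
#' aqueous profile seen for nanoparticle thermogels. At each sampling time
#' \code{n} destructive replicates are drawn with relative SD
#' \code{sd_rel}, and their mean/SD/n are emitted (each animal gives one
#' sample, so only summaries exist).
#'
#' @param k_in Zero-order input rate (ug/mL/h), > 0.
#' @param t_plateau_end End of the input (gel erosion) window (h), > 0.
#' @param k_el First-order elimination constant (h^-1), > 0.
#' @param sd_rel Relative SD of individual samples, >= 0.
#' @param n Animals per time point, >= 1.
#' @param times Sampling times (h), strictly increasing.
#' @param seed Integer seed.
#' @param label Profile label.
#' @return A [pk_profile].
#' @examples
#' gen_pk_profile(1.0, 10, 3, 0.15, 6, c(0.5, 1, 2, 4, 6, 8, 10), seed = 1)
#' @export
gen_pk_profile <- function(k_in, t_plateau_end, k_el, sd_rel = 0.15, n = 6,
                           times = c(0.5, 1, 2, 4, 6, 8, 10), seed = NULL,
                           label = "sim") {
  check_number(k_in, "k_in", lower = 0, strict_lower = TRUE)
  check_number(t_plateau_end, "t_plateau_end", lower = 0, strict_lower = TRUE)
  check_number(k_el, "k_el", lower = 0, strict_lower = TRUE)
  check_number(sd_rel, "sd_rel", lower = 0)
  mu <- pk_model_conc(times, k_in, t_plateau_end, k_el)
  sim <- with_seed(seed, {
    lapply(mu, function(m) pmax(m * (1 + stats::rnorm(n, 0, sd_rel)), 0))
  })
  pk_profile(label, times,
             vapply(sim, mean, numeric(1)),
             vapply(sim, stats::sd, numeric(1)),
             rep(n, length(times)))
}

#' Generate a DLS correlogram from a rheological model
#'
#' Builds the tracer MSD from a named medium model, maps it to the field
#' correlation \code{g1 = exp(-q^2 MSD / 6)} and to
#' \code{g2 = 1 + beta g1^2 + e}, \code{e ~ N(0, noise)} (additive
#' instrument noise).
#'
#' Models: \code{newtonian} (parameter \code{eta_Pa_s}: MSD = 6 D tau with
#' D from Stokes-Einstein), \code{maxwell} (parameters \code{G0_Pa},
#' \code{lambda_s}: MSD = (kB T / pi a G0)(1 + tau/lambda), a fluid with
#' a single relaxation time and zero-shear viscosity G0 lambda) and
#' \code{plateau} (parameter \code{delta2_m2}: MSD constant, an
#' elastically trapped tracer).
#'
#' @param model \code{"newtonian"}, \code{"maxwell"} or \code{"plateau"}.
#' @param params Named list of model parameters (see above).
#' @param lags Lag grid (s), default 60 log-spaced points over
#'   1e-5..10 s.
#' @param beta Coherence factor in (0, 1], default 0.9.
#' @param noise Additive g2 noise SD, >= 0, default 0.
#' @param seed Integer seed.
#' @param wavelength_nm,ref_index,angle_deg,temperature_K,tracer_radius_nm
#'   Optics and tracer; defaults as in [correlogram()].
#' @return A [correlogram].
#' @examples
#' gen_dls_g2("newtonian", list(eta_Pa_s = 0.89e-3))
#' @export
gen_dls_g2 <- function(model = c("newtonian", "maxwell", "plateau"),
                       params, lags = 10^seq(-5, 1, length.out = 60),
                       beta = 0.9, noise = 0, seed = NULL,
                       wavelength_nm = 633, ref_index = 1.33,
                       angle_deg = 173, temperature_K = 298.15,
                       tracer_radius_nm = 250) {
  model <- match.arg(model)
  check_number(beta, "beta", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(noise, "noise", lower = 0)
  a_m <- tracer_radius_nm * 1e-9
  kT <- .kB * temperature_K
  msd <- switch(model,
    newtonian = {
      eta <- params$eta_Pa_s
      check_number(eta, "eta_Pa_s", lower = 0, strict_lower = TRUE)
      6 * (kT / (6 * pi * eta * a_m)) * lags
    },
    maxwell = {
      G0 <- params$G0_Pa; lam <- params$lambda_s
      check_number(G0, "G0_Pa", lower = 0, strict_lower = TRUE)
      check_number(lam, "lambda_s", lower = 0, strict_lower = TRUE)
      (kT / (pi * a_m * G0)) * (1 + lags / lam)
    },
    plateau = {
      d2 <- params$delta2_m2
      check_number(d2, "delta2_m2", lower = 0, strict_lower = TRUE)
      rep(d2, length(lags))
    })
  q <- scattering_vector(wavelength_nm, ref_index, angle_deg)
  g1 <- exp(-q^2 * msd / 6)
  g2 <- with_seed(seed, {
    1 + beta * g1^2 + stats::rnorm(length(lags), 0, noise)
  })
  correlogram(lags, pmax(g2, 1), beta,
              wavelength_nm = wavelength_nm, ref_index = ref_index,
              angle_deg = angle_deg, temperature_K = temperature_K,
              tracer_radius_nm = tracer_radius_nm)
}

#' Render a synthetic fluorescent bead image
#'
#' Sum of isotropic Gaussian spots on a constant background with additive
#' Gaussian noise at a stated peak SNR. Each spot's apparent width folds
#' the bead size and the point-spread function in quadrature:
#' \code{sigma_eff^2 = (d / 2.3548)^2 + sigma_psf^2}; the ground-truth
#' *apparent* diameter recovered by FWHM fitting is
#' \code{2.3548 sigma_eff} (attribute \code{"true_diameters_um"}).
#'
#' @param diameters_um Bead diameters (micrometers), > 0.
#' @param positions_um Two-column matrix (or length-2 vector for one
#'   bead) of (x, y) centers in micrometers.
#' @param pixel_size_um Pixel size (micrometers), default 0.05.
#' @param img_size_px Image side length in pixels, default 128.
#' @param psf_sigma_um PSF sigma (micrometers), default 0.05.
#' @param snr Peak amplitude / noise SD, > 0, default 20. Use \code{Inf}
#'   for noiseless images.
#' @param background Constant background level, default 0.05 (peak = 1).
#' @param seed Integer seed.
#' @return Numeric matrix (rows = y) with attributes
#'   \code{"pixel_size_um"} and \code{"true_diameters_um"}.
#' @export
gen_bead_image <- function(diameters_um, positions_um,
                           pixel_size_um = 0.05, img_size_px = 128L,
                           psf_sigma_um = 0.05, snr = 20,
                           background = 0.05, seed = NULL) {
  if (any(diameters_um <= 0))
    stop_ocunano("bead diameters must be positive", "ocunano_domain_error")
  if (is.null(dim(positions_um)))
    positions_um <- matrix(positions_um, ncol = 2)
  if (nrow(positions_um) != length(diameters_um))
    stop_ocunano("one (x, y) position per bead is required",
                 "ocunano_domain_error")
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop_ocunano("`snr` must be a positive number (Inf for noiseless)",
                 "ocunano_domain_error")
  px <- (seq_len(img_size_px) - 0.5) * pixel_size_um
  img <- matrix(background, img_size_px, img_size_px)
  sig_eff <- sqrt((diameters_um / FWHM_FACTOR)^2 + psf_sigma_um^2)
  for (i in seq_along(diameters_um)) {
    gx <- exp(-(px - positions_um[i, 1])^2 / (2 * sig_eff[i]^2))
    gy <- exp(-(px - positions_um[i, 2])^2 / (2 * sig_eff[i]^2))
    img <- img + outer(gy, gx) # rows = y, cols = x
  }
  if (is.finite(snr)) {
    img <- with_seed(seed, {
      img + stats::rnorm(length(img), 0, 1 / snr)
    })
    img <- pmax(img, 0)
  }
  attr(img, "pixel_size_um") <- pixel_size_um
  attr(img, "true_diameters_um") <- FWHM_FACTOR * sig_eff
  img
}
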