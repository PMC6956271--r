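# DLS passive microrheology.
#
# Tracer particles embedded in a medium are followed by dynamic light
# scattering. The measured intensity autocorrelation g2(tau) is converted
# to the field correlation g1 through the Siegert relation
# g2 = 1 + beta * g1^2, then to the tracer mean-squared displacement via
# the Gaussian-displacement relation g1 = exp(-q^2 MSD / 6) (3-D
# convention), and finally to viscoelastic spectra with the generalized
# Stokes-Einstein relation evaluated by Mason's local power-law
# approximation:
#
#   |G*(omega)| = kB T / (pi a MSD(1/omega) Gamma(1 + alpha(omega)))
#   G'  = |G*| cos(pi alpha / 2),  G'' = |G*| sin(pi alpha / 2)
#
# with alpha the local logarithmic slope of the MSD. alpha = 1 is a
# Newtonian fluid (G' = 0, G'' = eta omega); alpha = 0 an elastic plateau.

#' DLS scattering vector magnitude
#'
#' \code{q = (4 pi n / lambda) sin(theta / 2)} for light of vacuum
#' wavelength \code{lambda} in a medium of refractive index \code{n}
#' detected at scattering angle \code{theta}.
#'
#' @param wavelength_nm Laser vacuum wavelength (nm), > 0.
#' @param ref_index Medium refractive index, > 0.
#' @param angle_deg Scattering angle (degrees) in (0, 180]; 173 is the
#'   usual backscatter geometry.
#' @return q in 1/m.
#' @examples
#' scattering_vector(633, 1.33, 173)
#' @export
scattering_vector <- function(wavelength_nm, ref_index, angle_deg) {
  check_number(wavelength_nm, "wavelength_nm", lower = 0, strict_lower = TRUE)
  check_number(ref_index, "ref_index", lower = 0, strict_lower = TRUE)
  check_number(angle_deg, "angle_deg", lower = 0, upper = 180,
               strict_lower = TRUE)
  (4 * pi * ref_index / (wavelength_nm * 1e-9)) * sin(angle_deg * pi / 360)
}

#' Construct a DLS correlogram
#'
#' @param lags Lag times (s), strictly increasing, > 0.
#' @param g2 Baseline-normalized intensity autocorrelation at \code{lags}
#'   (tends to 1 at long lag).
#' @param beta Coherence (intercept) factor in (0, 1].
#' @param wavelength_nm,ref_index,angle_deg Optics; defaults are the
#'   633 nm / aqueous / backscatter configuration of a Zetasizer.
#' @param temperature_K Absolute temperature (K), default 298.15.
#' @param tracer_radius_nm Tracer particle radius (nm); default 250
#'   (500 nm polystyrene latex).
#' @param tol Allowed dip of g2 below 1 (noise), default 0.02.
#' @return A \code{correlogram} list.
#' @export
correlogram <- function(lags, g2, beta,
                        wavelength_nm = 633, ref_index = 1.33,
                        angle_deg = 173, temperature_K = 298.15,
                        tracer_radius_nm = 250, tol = 0.02) {
  if (length(lags) != length(g2))
    stop_ocunano("lags and g2 must have equal length", "ocunano_domain_error")
  if (any(lags <= 0) || any(diff(lags) <= 0))
    stop_ocunano("lags must be positive and strictly increasing",
                 "ocunano_domain_error")
  check_number(beta, "beta", lower = 0, upper = 1, strict_lower = TRUE)
  if (any(g2 < 1 - tol))
    stop_ocunano("g2 falls below 1 beyond noise tolerance",
                 "ocunano_domain_error")
  check_number(temperature_K, "temperature_K", lower = 0, strict_lower = TRUE)
  check_number(tracer_radius_nm, "tracer_radius_nm", lower = 0,
               strict_lower = TRUE)
  structure(list(lags = as.numeric(lags), g2 = as.numeric(g2), beta = beta,
                 wavelength_nm = wavelength_nm, ref_index = ref_index,
                 angle_deg = angle_deg, temperature_K = temperature_K,
                 tracer_radius_nm = tracer_radius_nm),
            class = "correlogram")
}

#' Tracer mean-squared displacement from a correlogram
#'
#' Siegert inversion \code{g1 = sqrt((g2 - 1) / beta)} followed by the
#' Gaussian-displacement relation \code{MSD = -(6 / q^2) ln g1}. Lags with
#' no usable signal are dropped: the retention threshold is 3 times the
#' noise SD of \code{g2 - 1} estimated from the long-lag baseline tail (or
#' a small absolute floor when the tail is noiseless).
#'
#' @param c A [correlogram].
#' @param baseline_frac Fraction of the longest lags used to estimate the
#'   baseline noise SD, default 0.1.
#' @param floor Minimum \code{(g2 - 1) / beta} retained regardless of the
#'   noise estimate, default 1e-6 (guards against log of underflowed
#'   correlations).
#' @return Data frame \code{lag_s, msd_m2} for retained lags.
#' @export
msd_from_g2 <- function(c, baseline_frac = 0.1, floor = 1e-6) {
  stopifnot(inherits(c, "correlogram"))
  if (c$beta <= 0)
    stop_ocunano("beta must be positive", "ocunano_domain_error")
  q <- scattering_vector(c$wavelength_nm, c$ref_index, c$angle_deg)
  sig <- c$g2 - 1
  n <- length(sig)
  ntail <- max(3L, ceiling(baseline_frac * n))
  tail_sd <- stats::sd(sig[(n - ntail + 1L):n])
  thresh <- max(3 * tail_sd, floor * c$beta, 0)
  keep <- sig > thresh
  if (!any(keep))
    stop_ocunano("no lags with signal above the noise floor",
                 "ocunano_insufficient_signal_error")
  g1sq <- sig[keep] / c$beta
  if (any(g1sq > 1)) {
    warn_ocunano(
      "g2 - 1 exceeds beta at some lags (beta set too low?); g1 clamped to 1",
      "ocunano_beta_warning")
    g1sq <- pmin(g1sq, 1)
  }
  msd <- -(6 / q^2) * log(sqrt(g1sq))
  data.frame(lag_s = c$lags[keep], msd_m2 = msd)
}

# Local log-log slope of the MSD, smoothed; centered differences with
# one-sided differences at the ends, then a moving average.
local_loglog_slope <- function(lag, msd, smooth_pts = 5L) {
  lx <- log(lag); ly <- log(msd)
  n <- length(lx)
  a <- numeric(n)
  a[1] <- (ly[2] - ly[1]) / (lx[2] - lx[1])
  a[n] <- (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1])
  if (n > 2)
    a[2:(n - 1)] <- (ly[3:n] - ly[1:(n - 2)]) / (lx[3:n] - lx[1:(n - 2)])
  if (smooth_pts > 1L && n >= smooth_pts) {
    k <- rep(1 / smooth_pts, smooth_pts)
    sm <- stats::filter(a, k, sides = 2)
    a[!is.na(sm)] <- sm[!is.na(sm)]
  }
  a
}

#' Viscoelastic spectra by the generalized Stokes-Einstein relation
#'
#' Mason's local power-law evaluation at \code{omega = 1/tau}: the local
#' log-log MSD slope \code{alpha} (clamped to [0, 1]) sets the phase,
#' \code{|G*| = kB T / (pi a MSD Gamma(1 + alpha))} the magnitude.
#'
#' @param msd Data frame \code{lag_s, msd_m2} from [msd_from_g2()], with
#'   at least 5 points spanning at least one decade of lag.
#' @param tracer_radius_nm Tracer radius (nm), > 0.
#' @param temperature_K Temperature (K), > 0.
#' @param smooth_pts Moving-average window for the local slope, default 5.
#' @return A \code{complex_modulus} data frame with columns
#'   \code{omega_rad_s, alpha, g_prime_Pa, g_dprime_Pa, eta_star_Pa_s},
#'   ordered by increasing frequency.
#' @examples
#' # water-like Newtonian fluid
#' msd <- data.frame(lag_s = 10^seq(-4, 0, length.out = 40))
#' D <- 1.380649e-23 * 298.15 / (6 * pi * 0.89e-3 * 250e-9)
#' msd$msd_m2 <- 6 * D * msd$lag_s
#' head(gser_moduli(msd, 250, 298.15))
#' @export
gser_moduli <- function(msd, tracer_radius_nm, temperature_K,
                        smooth_pts = 5L) {
  stopifnot(is.data.frame(msd), all(c("lag_s", "msd_m2") %in% names(msd)))
  if (any(msd$msd_m2 <= 0))
    stop_ocunano("MSD must be positive", "ocunano_domain_error")
  if (nrow(msd) < 5L || max(msd$lag_s) / min(msd$lag_s) < 10)
    stop_ocunano("GSER needs >= 5 MSD points spanning >= 1 decade of lag",
                 "ocunano_insufficient_data_error")
  check_number(tracer_radius_nm, "tracer_radius_nm", lower = 0,
               strict_lower = TRUE)
  check_number(temperature_K, "temperature_K", lower = 0, strict_lower = TRUE)
  a_m <- tracer_radius_nm * 1e-9
  alpha <- clamp(local_loglog_slope(msd$lag_s, msd$msd_m2, smooth_pts), 0, 1)
  gstar <- .kB * temperature_K / (pi * a_m * msd$msd_m2 * gamma(1 + alpha))
  omega <- 1 / msd$lag_s
  out <- data.frame(omega_rad_s = omega, alpha = alpha,
                    g_prime_Pa = gstar * cos(pi * alpha / 2),
                    g_dprime_Pa = gstar * sin(pi * alpha / 2))
  out$eta_star_Pa_s <- sqrt(out$g_prime_Pa^2 + out$g_dprime_Pa^2) / omega
  out <- out[order(out$omega_rad_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("complex_modulus", "data.frame")
  out
}

#' Mucoadhesion assessment from paired viscoelastic spectra
#'
#' Compares the spectra of a mucin dispersion with and without added
#' nanoparticles. Mucoadhesive interaction thickens the network: the
#' complex viscosity (and the elastic modulus) of the mixture rises above
#' plain mucin across frequencies. The mixture is classified mucoadhesive
#' when the median per-frequency eta* ratio exceeds \code{1 + threshold}.
#'
#' @param moduli_mucin \code{complex_modulus} of the plain mucin
#'   dispersion.
#' @param moduli_mix \code{complex_modulus} of mucin + nanoparticles.
#' @param threshold Relative viscosity increase called mucoadhesive,
#'   default 0.10.
#' @param rel_tol Relative frequency mismatch treated as the same grid
#'   point, default 1e-6.
#' @return List with \code{table} (per-omega \code{eta_ratio} and
#'   \code{g_prime_ratio}), \code{median_eta_ratio},
#'   \code{median_g_prime_ratio} and logical \code{mucoadhesive}.
#' @export
mucoadhesion_compare <- function(moduli_mucin, moduli_mix,
                                 threshold = 0.10, rel_tol = 1e-6) {
  stopifnot(inherits(moduli_mucin, "complex_modulus"),
            inherits(moduli_mix, "complex_modulus"))
  # match overlapping grid points
  om_a <- moduli_mucin$omega_rad_s
  om_b <- moduli_mix$omega_rad_s
  idx_b <- vapply(om_a, function(w) {
    j <- which.min(abs(om_b - w))
    if (abs(om_b[j] - w) <= rel_tol * w) j else NA_integer_
  }, integer(1))
  keep <- !is.na(idx_b)
  if (!any(keep))
    stop_ocunano("frequency grids do not overlap", "ocunano_domain_error")
  a <- moduli_mucin[keep, , drop = FALSE]
  b <- moduli_mix[idx_b[keep], , drop = FALSE]
  tab <- data.frame(omega_rad_s = a$omega_rad_s,
                    eta_ratio = b$eta_star_Pa_s / a$eta_star_Pa_s,
                    g_prime_ratio = ifelse(a$g_prime_Pa > 0,
                                           b$g_prime_Pa / a$g_prime_Pa,
                                           NA_real_))
  med_eta <- stats::median(tab$eta_ratio)
  list(table = tab,
       median_eta_ratio = med_eta,
       median_g_prime_ratio = stats::median(tab$g_prime_ratio, na.rm = TRUE),
       mucoadhesive = med_eta > 1 + threshold)
}

#' Rank formulations by mucoadhesive strength
#'
#' Convenience wrapper comparing several nanoparticle-spiked mucin spectra
#' against the same plain-mucin reference and ordering them by median
#' viscosity ratio (strongest thickening first).
#'
#' @param moduli_mucin Reference \code{complex_modulus}.
#' @param mixes Named list of \code{complex_modulus} objects.
#' @param threshold Passed to [mucoadhesion_compare()].
#' @return Data frame \code{label, median_eta_ratio, median_g_prime_ratio,
#'   mucoadhesive}, ordered by decreasing eta ratio.
#' @export
mucoadhesion_rank <- function(moduli_mucin, mixes, threshold = 0.10) {
  stopifnot(is.list(mixes), !is.null(names(mixes)))
  rows <- lapply(names(mixes), function(lab) {
    cmp <- mucoadhesion_compare(moduli_mucin, mixes[[lab]],
                                threshold = threshold)
    data.frame(label = lab, median_eta_ratio = cmp$median_eta_ratio,
               median_g_prime_ratio = cmp$median_g_prime_ratio,
               mucoadhesive = cmp$mucoadhesive, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$median_eta_ratio), , drop = FALSE]
}
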