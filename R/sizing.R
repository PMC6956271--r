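# Particle sizing from fluorescence micrographs.
#
# A fluorescent bead's equatorial intensity profile is close to Gaussian
# (the bead convolved with the point-spread function). Its full width at
# half maximum, FWHM = 2 sqrt(2 ln 2) sigma ~ 2.3548 sigma, is taken as
# the particle diameter. Populations of per-bead diameters are summarized
# as mean +/- SE, with an operational two-means rule to detect bimodal
# (aggregated) size populations.

FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Construct an intensity line profile
#'
#' @param positions Positions along the traced line (micrometers),
#'   strictly increasing; at least 7 samples.
#' @param intensities Non-negative intensities at \code{positions}.
#' @return An \code{intensity_profile} list.
#' @export
intensity_profile <- function(positions, intensities) {
  if (length(positions) != length(intensities))
    stop_ocunano("positions and intensities must have equal length",
                 "ocunano_domain_error")
  if (length(positions) < 7L)
    stop_ocunano("a profile needs at least 7 samples",
                 "ocunano_insufficient_data_error")
  if (any(diff(positions) <= 0))
    stop_ocunano("positions must be strictly increasing",
                 "ocunano_domain_error")
  if (any(intensities < 0))
    stop_ocunano("intensities must be non-negative", "ocunano_domain_error")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities)),
            class = "intensity_profile")
}

#' Particle diameter by Gaussian FWHM fitting
#'
#' Nonlinear least squares of \code{A exp(-(x - mu)^2 / (2 sigma^2)) + B}
#' to the profile; the FWHM of the best fit is the diameter. Fits that do
#' not converge, have no peak above background, or whose sigma is at or
#' below the sampling step are rejected as unresolved (particle below the
#' optical limit of the profile). Diameters near the diffraction limit
#' are flagged, not suppressed.
#'
#' @param profile An [intensity_profile].
#' @param diffraction_limit_um Diameters below this are flagged
#'   \code{"diffraction-limited"}; default 0.2.
#' @return List with \code{diameter_um}, \code{sigma_um}, \code{mu_um},
#'   \code{amplitude}, \code{background}, \code{flag} (\code{"ok"} or
#'   \code{"diffraction-limited"}).
#' @examples
#' x <- seq(-1, 1, by = 0.05)
#' p <- intensity_profile(x, 80 * exp(-x^2 / (2 * 0.1^2)) + 5)
#' fit_fwhm(p)$diameter_um # 0.2355
#' @export
fit_fwhm <- function(profile, diffraction_limit_um = 0.2) {
  stopifnot(inherits(profile, "intensity_profile"))
  x <- profile$positions; y <- profile$intensities
  b0 <- stats::quantile(y, 0.1, names = FALSE)
  a0 <- max(y) - b0
  spacing <- stats::median(diff(x))
  if (a0 <= sqrt(.Machine$double.eps) * max(1, max(y)))
    stop_ocunano("no peak above background: unresolved particle",
                 "ocunano_unresolved_particle_error")
  mu0 <- x[which.max(y)]
  # crude sigma start from the half-maximum crossing width
  above <- y >= b0 + a0 / 2
  s0 <- if (sum(above) >= 2) diff(range(x[above])) / FWHM_FACTOR else spacing
  s0 <- max(s0, spacing / 2)
  resid_fn <- function(p)
    y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = a0, mu = mu0, sigma = s0, B = b0),
      lower = c(0, min(x), spacing / 10, 0),
      upper = c(Inf, max(x), diff(range(x)), Inf),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4))
    stop_ocunano("Gaussian fit did not converge: unresolved particle",
                 "ocunano_unresolved_particle_error")
  co <- fit$par
  if (co[["sigma"]] <= spacing || co[["A"]] <= 0)
    stop_ocunano(
      "fitted peak at or below the sampling step: unresolved particle",
      "ocunano_unresolved_particle_error")
  d <- FWHM_FACTOR * co[["sigma"]]
  list(diameter_um = d, sigma_um = co[["sigma"]], mu_um = co[["mu"]],
       amplitude = co[["A"]], background = co[["B"]],
       flag = if (d < diffraction_limit_um) "diffraction-limited" else "ok")
}

#' Extract an equatorial line profile from an image
#'
#' Traces a line through the intensity centroid of a grayscale image along
#' the axis of larger apparent extent (second moment), emulating the manual
#' equatorial trace over a bead. For multi-bead work pass a cropped
#' region per bead.
#'
#' @param img Numeric matrix (grayscale image) or path to a PNG/TIFF file
#'   (read with the \pkg{png} / \pkg{tiff} packages when installed).
#' @param pixel_size_um Physical pixel size (micrometers), > 0.
#' @param width_px Width of the traced line in pixels (odd integer); rows
#'   within the band are averaged, as with a wide line selection in image
#'   software. Default 3.
#' @return An [intensity_profile] along the chosen axis.
#' @export
extract_profile <- function(img, pixel_size_um, width_px = 3L) {
  check_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  if (is.character(img)) img <- read_gray_image(img)
  stopifnot(is.matrix(img), is.numeric(img))
  w <- img - min(img)
  tot <- sum(w)
  if (tot <= 0)
    stop_ocunano("image has no signal", "ocunano_unresolved_particle_error")
  ri <- rowSums(w); ci <- colSums(w)
  r0 <- sum(seq_along(ri) * ri) / tot
  c0 <- sum(seq_along(ci) * ci) / tot
  # second moments along rows/cols decide the equatorial axis
  vr <- sum((seq_along(ri) - r0)^2 * ri) / tot
  vc <- sum((seq_along(ci) - c0)^2 * ci) / tot
  half <- (max(1L, as.integer(width_px)) - 1L) %/% 2L
  band <- function(center, n) max(1L, round(center) - half):min(n, round(center) + half)
  line <- if (vc >= vr) {
    colMeans(img[band(clamp(r0, 1, nrow(img)), nrow(img)), , drop = FALSE])
  } else {
    rowMeans(img[, band(clamp(c0, 1, ncol(img)), ncol(img)), drop = FALSE])
  }
  intensity_profile(seq_along(line) * pixel_size_um, line)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_ocunano("reading TIFF requires the 'tiff' package",
                   "ocunano_input_error")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop_ocunano("reading PNG requires the 'png' package",
                   "ocunano_input_error")
    png::readPNG(path)
  } else {
    stop_ocunano(sprintf("unsupported image format '%s'", ext),
                 "ocunano_input_error")
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Summarize per-bead diameters into size populations
#'
#' Reports one or two size populations as mean +/- SE. Bimodality is
#' decided operationally: the best two-means split of the sorted
#' diameters (minimum pooled within-group sum of squares, each group
#' >= 2 members) is accepted when the between/within variance ratio
#' exceeds \code{ratio_threshold}, or always when \code{expect_bimodal}.
#' Modes are reported larger-mean first.
#'
#' @param diameters Numeric vector of per-bead diameters (micrometers),
#'   at least 3.
#' @param expect_bimodal Force a two-mode split, default \code{FALSE}.
#' @param ratio_threshold Between/within variance ratio above which the
#'   split is accepted, default 4.
#' @return A \code{size_estimate}: list with \code{diameters_um} and
#'   \code{modes}, a data frame \code{mean_um, se_um, n} with 1 or 2 rows.
#' @examples
#' summarize_sizes(c(0.29, 0.30, 0.28, 0.70, 0.72, 0.68))
#' @export
summarize_sizes <- function(diameters, expect_bimodal = FALSE,
                            ratio_threshold = 4) {
  if (length(diameters) < 3L)
    stop_ocunano("size summary needs at least 3 diameters",
                 "ocunano_insufficient_data_error")
  if (any(diameters <= 0))
    stop_ocunano("diameters must be positive", "ocunano_domain_error")
  d <- sort(diameters)
  n <- length(d)

  mode_row <- function(v) data.frame(
    mean_um = mean(v),
    se_um = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
    n = length(v))

  best <- NULL
  if (n >= 4L) {
    wss <- vapply(2:(n - 2), function(k)
      sum((d[1:k] - mean(d[1:k]))^2) + sum((d[(k + 1):n] - mean(d[(k + 1):n]))^2),
      numeric(1))
    k <- (2:(n - 2))[which.min(wss)]
    lo <- d[1:k]; hi <- d[(k + 1):n]
    within <- min(wss) / (n - 2)
    between <- (length(lo) * (mean(lo) - mean(d))^2 +
                  length(hi) * (mean(hi) - mean(d))^2)
    ratio <- if (within > 0) between / within else Inf
    best <- list(lo = lo, hi = hi, ratio = ratio)
  }
  two_modes <- !is.null(best) && mean(best$hi) > mean(best$lo) &&
    (expect_bimodal || best$ratio > ratio_threshold)
  modes <- if (two_modes) {
    rbind(mode_row(best$hi), mode_row(best$lo)) # larger population first
  } else {
    mode_row(d)
  }
  rownames(modes) <- NULL
  structure(list(diameters_um = diameters, modes = modes,
                 bimodal = two_modes),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf("Size estimate from %d beads (%s):\n", length(x$diameters_um),
              if (x$bimodal) "bimodal" else "unimodal"))
  for (i in seq_len(nrow(x$modes)))
    cat(sprintf("  mode %d: %.2f +/- %.2f um (n = %d)\n", i,
                x$modes$mean_um[i], x$modes$se_um[i], x$modes$n[i]))
  invisible(x)
}

#' Size a set of profiles or bead images
#'
#' Maps [fit_fwhm()] over line profiles (or images via
#' [extract_profile()]) and summarizes with [summarize_sizes()].
#'
#' @param profiles List of [intensity_profile] objects, or of matrices /
#'   image paths when \code{pixel_size_um} is given.
#' @param pixel_size_um Pixel size for image inputs.
#' @param ... Passed to [summarize_sizes()].
#' @return A \code{size_estimate}; unresolved particles are dropped with a
#'   warning.
#' @export
size_particles <- function(profiles, pixel_size_um = NULL, ...) {
  fits <- lapply(profiles, function(p) {
    if (!inherits(p, "intensity_profile"))
      p <- extract_profile(p, pixel_size_um)
    tryCatch(fit_fwhm(p), ocunano_unresolved_particle_error = function(e) NULL)
  })
  drop <- vapply(fits, is.null, logical(1))
  if (any(drop))
    warn_ocunano(sprintf("%d unresolved particle(s) dropped", sum(drop)),
                 "ocunano_unresolved_dropped_warning")
  dia <- vapply(fits[!drop], `[[`, numeric(1), "diameter_um")
  summarize_sizes(dia, ...)
}
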