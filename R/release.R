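# Higuchi release kinetics from nanoparticle-containing thermogels.
#
# Diffusion-controlled release from a matrix follows the Higuchi model:
# cumulative percent released is linear in the square root of time,
# Q(t) = k * sqrt(t) + b, with a small intercept b. The slope k compares
# drug diffusivity across formulations.

#' Construct a cumulative release curve
#'
#' @param label Formulation label.
#' @param times Sampling times, strictly increasing, > 0. Units are
#'   whatever \code{time_unit} says (default minutes).
#' @param released_pct Cumulative percent released at \code{times}, each in
#'   \code{[0, 100 + tol]}; small non-monotonic dips (assay noise) are
#'   tolerated.
#' @param replicate Replicate index (integer), default 1.
#' @param time_unit \code{"min"} (default) or \code{"h"}; recorded so fits
#'   carry their unit.
#' @param tol Tolerance above 100 percent, default 1.
#' @return A \code{release_curve} list.
#' @export
release_curve <- function(label, times, released_pct, replicate = 1L,
                          time_unit = c("min", "h"), tol = 1) {
  time_unit <- match.arg(time_unit)
  if (length(times) != length(released_pct))
    stop_ocunano("times and released_pct must have equal length",
                 "ocunano_domain_error")
  if (any(times <= 0) || any(diff(times) <= 0))
    stop_ocunano("times must be positive and strictly increasing",
                 "ocunano_domain_error")
  if (any(released_pct < 0 - tol) || any(released_pct > 100 + tol))
    stop_ocunano("released_pct must lie in [0, 100] up to tolerance",
                 "ocunano_domain_error")
  structure(list(label = label, replicate = as.integer(replicate),
                 times = as.numeric(times),
                 released_pct = as.numeric(released_pct),
                 time_unit = time_unit),
            class = "release_curve")
}

#' Fit the Higuchi square-root-of-time model
#'
#' OLS of cumulative percent released on sqrt(time). An intercept outside
#' the band typically seen for diffusion-controlled thermogel release
#' (about -1 to +3 percent) flags the fit -- burst release or lag -- without
#' failing it.
#'
#' @param curve A [release_curve] with at least 4 points.
#' @param intercept_band Length-2 numeric flag band for the intercept
#'   (percent), default \code{c(-0.99, 2.88)}.
#' @return A \code{higuchi_fit} with \code{slope} (percent per sqrt time
#'   unit), \code{intercept} (percent), \code{r2}, \code{slope_se},
#'   \code{time_unit}, logical \code{intercept_flagged}.
#' @examples
#' tt <- seq(30, 300, by = 30)
#' fit_higuchi(release_curve("Ch NP+TSOH", tt, 3.34 * sqrt(tt) + 1.6))
#' @export
fit_higuchi <- function(curve, intercept_band = c(-0.99, 2.88)) {
  stopifnot(inherits(curve, "release_curve"))
  if (length(curve$times) < 4L)
    stop_ocunano("Higuchi fit needs at least 4 points",
                 "ocunano_insufficient_data_error")
  x <- sqrt(curve$times)
  fit <- stats::lm(curve$released_pct ~ x)
  co <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit)) # noiseless curves fit "too" well
  r2 <- if (stats::var(curve$released_pct) > 0) sm$r.squared else 1
  structure(list(label = curve$label, replicate = curve$replicate,
                 slope = unname(co[2L]), intercept = unname(co[1L]),
                 r2 = r2,
                 slope_se = tryCatch(sm$coefficients[2L, 2L],
                                     error = function(e) NA_real_),
                 time_unit = curve$time_unit,
                 intercept_flagged = unname(co[1L]) < intercept_band[1L] ||
                   unname(co[1L]) > intercept_band[2L]),
            class = "higuchi_fit")
}

#' @export
print.higuchi_fit <- function(x, ...) {
  cat(sprintf("Higuchi fit [%s]: slope %.3f %%/sqrt(%s), intercept %.2f%%, r2 %.3f%s\n",
              x$label, x$slope, x$time_unit, x$intercept, x$r2,
              if (x$intercept_flagged) " [intercept flagged]" else ""))
  invisible(x)
}

#' Predict cumulative release at a time
#'
#' @param fit A \code{higuchi_fit}.
#' @param t Time, >= 0, in the fit's time unit.
#' @return Predicted cumulative percent released, clamped to
#'   \code{[0, 100]}.
#' @examples
#' f <- structure(list(slope = 3.34, intercept = 1.6, time_unit = "min"),
#'                class = "higuchi_fit")
#' predict_release(f, 300) # 59.4
#' @export
predict_release <- function(fit, t) {
  stopifnot(inherits(fit, "higuchi_fit"))
  if (any(t < 0))
    stop_ocunano("t must be non-negative", "ocunano_domain_error")
  clamp(fit$slope * sqrt(t) + fit$intercept, 0, 100)
}

#' Compare Higuchi slopes of two formulations
#'
#' Two-sample two-sided Student's t-test on per-replicate slopes. With the
#' usual n = 3 replicates per formulation the equal-variance test is the
#' default; Welch is available.
#'
#' @param fits_a,fits_b Lists of \code{higuchi_fit} replicates (>= 2 each),
#'   or bare numeric slope vectors.
#' @param var.equal Equal-variance t (default \code{TRUE}) or Welch.
#' @param alpha Significance level, default 0.05.
#' @return List with \code{t}, \code{df}, \code{p}, \code{significant},
#'   \code{mean_a}, \code{mean_b}.
#' @examples
#' compare_slopes(c(2.43, 2.22, 2.64), c(3.34, 3.02, 3.66))
#' @export
compare_slopes <- function(fits_a, fits_b, var.equal = TRUE, alpha = 0.05) {
  as_slopes <- function(f) {
    if (is.numeric(f)) return(f)
    vapply(f, function(x) {
      stopifnot(inherits(x, "higuchi_fit")); x$slope
    }, numeric(1))
  }
  a <- as_slopes(fits_a); b <- as_slopes(fits_b)
  if (length(a) < 2L || length(b) < 2L)
    stop_ocunano("slope comparison needs >= 2 replicates per group",
                 "ocunano_insufficient_data_error")
  tt <- stats::t.test(a, b, var.equal = var.equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha,
       mean_a = mean(a), mean_b = mean(b))
}

#' Analyse a replicated release experiment
#'
#' Per-replicate Higuchi fits from a long-format table, summarised per
#' formulation (slope mean +/- SD, mean r2, predicted cumulative release
#' at a horizon), plus the pairwise slope-comparison p-value matrix.
#'
#' @param data Data frame with columns
#'   \code{label, replicate, time_min, released_pct}.
#' @param horizon_min Prediction horizon in minutes, default 300 (the
#'   5-hour release window).
#' @param var.equal Passed to [compare_slopes()].
#' @return List with \code{summary} (data frame per label), \code{fits}
#'   (list of per-replicate fits) and \code{p_matrix}.
#' @export
fit_release_experiment <- function(data, horizon_min = 300, var.equal = TRUE) {
  needed <- c("label", "replicate", "time_min", "released_pct")
  if (!all(needed %in% names(data)))
    stop_ocunano(sprintf("release input needs columns %s",
                         paste(needed, collapse = ",")),
                 "ocunano_input_error")
  labs <- unique(data$label)
  fits <- lapply(labs, function(lab) {
    sub <- data[data$label == lab, , drop = FALSE]
    lapply(split(sub, sub$replicate), function(r) {
      ord <- order(r$time_min)
      fit_higuchi(release_curve(lab, r$time_min[ord], r$released_pct[ord],
                                replicate = r$replicate[1L]))
    })
  })
  names(fits) <- labs
  summ <- do.call(rbind, lapply(labs, function(lab) {
    sl <- vapply(fits[[lab]], `[[`, numeric(1), "slope")
    mf <- structure(list(slope = mean(sl),
                         intercept = mean(vapply(fits[[lab]], `[[`,
                                                 numeric(1), "intercept")),
                         time_unit = "min"), class = "higuchi_fit")
    data.frame(label = lab, slope = mean(sl),
               slope_sd = if (length(sl) > 1) stats::sd(sl) else NA_real_,
               n_rep = length(sl),
               r2 = mean(vapply(fits[[lab]], `[[`, numeric(1), "r2")),
               cum_release_horizon = predict_release(mf, horizon_min),
               stringsAsFactors = FALSE)
  }))
  pm <- matrix(NA_real_, length(labs), length(labs),
               dimnames = list(labs, labs))
  if (length(labs) > 1) {
    for (i in seq_along(labs)[-length(labs)]) for (j in (i + 1):length(labs)) {
      si <- vapply(fits[[i]], `[[`, numeric(1), "slope")
      sj <- vapply(fits[[j]], `[[`, numeric(1), "slope")
      if (length(si) >= 2 && length(sj) >= 2) {
        p <- compare_slopes(si, sj, var.equal = var.equal)$p
        pm[i, j] <- pm[j, i] <- p
      }
    }
  }
  list(summary = summ, fits = fits, p_matrix = pm)
}
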