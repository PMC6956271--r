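# Dynamic-dialysis binding inference.
#
# In dynamic dialysis the donor compartment holds drug plus (dissolved
# polymer | nanoparticle dispersion); only free drug crosses the membrane
# into a sink. The donor concentration then decays as
#
#   ln(100 * C_d / C_d0) = ln(100) - Km * Ff * t
#
# where Km is the membrane (dialysis-rate) constant and Ff the free,
# non-interacting drug fraction. A plain-drug control has Ff = 1, so its
# slope magnitude calibrates Km; the ratio slope/Km for a formulation is
# its free fraction, and 100*(1 - Ff) is the reversibly bound percentage
# ("interaction percent").

#' Construct a dynamic-dialysis run
#'
#' @param label Run label.
#' @param role \code{"control"} (plain drug, free fraction 1) or
#'   \code{"formulation"}.
#' @param times Sampling times (h), strictly increasing, > 0; at least 3.
#' @param donor_conc Donor-phase drug concentrations at \code{times}
#'   (any consistent mass/volume unit), all > 0.
#' @param cd0 Donor concentration at t = 0. Defaults to the first
#'   concentration when the series starts at the earliest sample.
#' @param tol Relative tolerance allowed for \code{donor_conc > cd0}
#'   (measurement noise), default 0.05.
#' @return A \code{dialysis_run} list.
#' @export
dialysis_run <- function(label, role = c("control", "formulation"),
                         times, donor_conc, cd0 = donor_conc[1], tol = 0.05) {
  role <- match.arg(role)
  stopifnot(is.character(label), length(label) == 1L)
  if (length(times) != length(donor_conc))
    stop_ocunano("times and donor_conc must have equal length",
                 "ocunano_domain_error")
  if (length(times) < 3L)
    stop_ocunano("a dialysis run needs at least 3 time points",
                 "ocunano_insufficient_data_error")
  if (any(diff(times) <= 0) || any(times <= 0))
    stop_ocunano("times must be positive and strictly increasing",
                 "ocunano_domain_error")
  check_number(cd0, "cd0", lower = 0, strict_lower = TRUE)
  if (any(donor_conc > cd0 * (1 + tol)))
    stop_ocunano("donor concentration exceeds cd0 beyond tolerance",
                 "ocunano_domain_error")
  structure(list(label = label, role = role, times = as.numeric(times),
                 donor_conc = as.numeric(donor_conc), cd0 = cd0),
            class = "dialysis_run")
}

#' Fit the log-linear dynamic-dialysis model
#'
#' Ordinary least squares of \code{ln(100 * C_d / C_d0)} on time. The
#' intercept is fitted freely rather than pinned to its analytic value
#' \code{ln(100) = 4.605}; its deviation from 4.605 is a diagnostic for
#' mis-measured \code{cd0} or early non-linearity. A rising donor
#' concentration (positive slope) is physically impossible under sink
#' conditions and yields a \code{"warning"} status with the slope
#' magnitude still reported.
#'
#' @param run A [dialysis_run].
#' @return A \code{binding_fit} with \code{slope_mag} (h^-1),
#'   \code{intercept}, \code{r2}, \code{slope_se}, \code{status}; the
#'   binding quantities \code{km}, \code{ff}, \code{interaction_pct} are
#'   \code{NA} until completed by [bound_fraction()].
#' @seealso [calibrate_km()], [bound_fraction()]
#' @examples
#' tt <- seq(0.5, 5, by = 0.5)
#' run <- dialysis_run("control", "control", tt, 100 * exp(-0.44 * tt))
#' fit_log_linear(run)
#' @export
fit_log_linear <- function(run) {
  stopifnot(inherits(run, "dialysis_run"))
  if (any(run$donor_conc <= 0))
    stop_ocunano("donor concentrations must be positive for the log model",
                 "ocunano_domain_error")
  y <- log(100 * run$donor_conc / run$cd0)
  fit <- stats::lm(y ~ run$times)
  slope <- unname(stats::coef(fit)[2L])
  if (abs(slope) < 1e-12) slope <- 0 # numerically flat series
  status <- "ok"
  if (slope > 0) {
    warn_ocunano(sprintf(
      "%s: donor concentration rises with time (positive slope %.3g)",
      run$label, slope), "ocunano_rising_donor_warning")
    status <- "warning"
  }
  sm <- suppressWarnings(summary(fit)) # noiseless series fit "too" well
  r2 <- if (stats::var(y) > 0) sm$r.squared else NA_real_
  # slope SE undefined (0/0) on perfectly constant series
  se <- tryCatch(sm$coefficients[2L, 2L], error = function(e) NA_real_)
  structure(list(label = run$label, role = run$role,
                 slope_mag = abs(slope), intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2, slope_se = se, status = status,
                 km = NA_real_, ff = NA_real_, interaction_pct = NA_real_),
            class = "binding_fit")
}

#' Calibrate the membrane constant from the free-drug control
#'
#' The control run contains plain drug only, so its free fraction is 1 and
#' the fitted slope magnitude equals the dialysis-rate constant Km.
#'
#' @param control A \code{binding_fit} from a control run.
#' @return Km (h^-1).
#' @export
calibrate_km <- function(control) {
  stopifnot(inherits(control, "binding_fit"))
  if (!identical(control$role, "control"))
    stop_ocunano("Km must be calibrated from a control (plain drug) run",
                 "ocunano_domain_error")
  if (control$slope_mag <= 0)
    stop_ocunano("control slope is zero: no membrane transport, Km undefined",
                 "ocunano_degenerate_calibration_error")
  control$slope_mag
}

#' Complete a binding fit with free and bound fractions
#'
#' Computes the free fraction \code{Ff = slope_mag / Km} and the bound
#' ("interaction") percentage \code{100 * (1 - Ff)}. Ratios marginally
#' above 1 -- a formulation apparently dialysing faster than free drug,
#' which can only be noise -- are clamped to 1 with a warning.
#'
#' @param fit A \code{binding_fit} from [fit_log_linear()].
#' @param km Membrane constant (h^-1), > 0, from [calibrate_km()].
#' @return The completed \code{binding_fit} with \code{km}, \code{ff} and
#'   \code{interaction_pct} set (interaction kept at full precision;
#'   round at reporting time).
#' @examples
#' tt <- seq(0.5, 5, by = 0.5)
#' fit <- fit_log_linear(
#'   dialysis_run("QA-Ch", "formulation", tt, 100 * exp(-0.23 * tt)))
#' bound_fraction(fit, km = 0.44)$interaction_pct # 47.72...
#' @export
bound_fraction <- function(fit, km) {
  stopifnot(inherits(fit, "binding_fit"))
  check_number(km, "km", lower = 0, strict_lower = TRUE)
  ratio <- fit$slope_mag / km
  if (ratio > 1 + 1e-9) {
    warn_ocunano(sprintf(
      "%s: slope/Km = %.3f > 1; free fraction clamped to 1", fit$label, ratio),
      "ocunano_ff_clamp_warning")
  }
  fit$km <- km
  fit$ff <- clamp(ratio, 0, 1)
  fit$interaction_pct <- 100 * (1 - fit$ff)
  fit
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Dialysis fit [%s, %s]: |slope| %.3f h^-1, intercept %.3f, r2 %.3f\n",
              x$label, x$role, x$slope_mag, x$intercept, x$r2))
  if (!is.na(x$ff))
    cat(sprintf("  Km %.3f h^-1, free fraction %.3f, interaction %.1f%%\n",
                x$km, x$ff, x$interaction_pct))
  invisible(x)
}

#' Fit a replicated dynamic-dialysis experiment
#'
#' Per-replicate log-linear fits, replicate-averaged slopes (mean +/- SD),
#' Km calibration from the control label, free/bound fractions per
#' formulation, and Student's t (two-sided, equal variance) comparing each
#' formulation's replicate slopes with the control's. Pooled fitting
#' (all replicates in one regression) is available as an alternative.
#'
#' @param data Data frame with columns
#'   \code{label, role, replicate, time_h, donor_conc}. If no explicit
#'   t = 0 row exists, \code{cd0} is taken as the concentration at the
#'   smallest time of each replicate.
#' @param control_label Label of the control series. Defaults to the
#'   label whose role is \code{"control"}.
#' @param pooled If \code{TRUE}, fit one regression per label on pooled
#'   replicate points instead of averaging per-replicate slopes.
#' @param alpha Significance level for the slope comparison, default 0.05.
#' @return A \code{binding_table} data frame: one row per label with
#'   \code{slope_mag}, \code{slope_sd}, \code{n_rep}, \code{r2} (mean),
#'   \code{km}, \code{ff}, \code{interaction_pct}, \code{p_vs_control},
#'   \code{significant}.
#' @export
fit_binding_experiment <- function(data, control_label = NULL,
                                   pooled = FALSE, alpha = 0.05) {
  needed <- c("label", "role", "replicate", "time_h", "donor_conc")
  if (!all(needed %in% names(data)))
    stop_ocunano(sprintf("binding input needs columns %s",
                         paste(needed, collapse = ",")),
                 "ocunano_input_error")
  if (is.null(control_label)) {
    control_label <- unique(data$label[data$role == "control"])
    if (length(control_label) != 1L)
      stop_ocunano("exactly one control label is required",
                   "ocunano_input_error")
  }

  fit_one <- function(sub, label, role) {
    t0 <- sub$time_h == 0
    cd0 <- if (any(t0)) mean(sub$donor_conc[t0]) else sub$donor_conc[which.min(sub$time_h)][1]
    keep <- !t0
    ord <- order(sub$time_h[keep])
    run <- dialysis_run(label, role, sub$time_h[keep][ord],
                        sub$donor_conc[keep][ord], cd0 = cd0)
    fit_log_linear(run)
  }

  labs <- unique(data$label)
  per_label <- lapply(labs, function(lab) {
    sub <- data[data$label == lab, , drop = FALSE]
    role <- if (lab == control_label) "control" else "formulation"
    if (pooled) {
      reps <- split(sub, sub$replicate)
      # pool after normalizing each replicate by its own cd0
      pts <- do.call(rbind, lapply(reps, function(r) {
        t0 <- r$time_h == 0
        cd0 <- if (any(t0)) mean(r$donor_conc[t0]) else r$donor_conc[which.min(r$time_h)][1]
        data.frame(time_h = r$time_h[!t0],
                   y = log(100 * r$donor_conc[!t0] / cd0))
      }))
      fit <- stats::lm(y ~ time_h, data = pts)
      slope <- unname(stats::coef(fit)[2L])
      list(slopes = abs(slope), r2 = summary(fit)$r.squared,
           mean_slope = abs(slope), sd_slope = NA_real_, n = length(reps))
    } else {
      fits <- lapply(split(sub, sub$replicate), fit_one, label = lab, role = role)
      slopes <- vapply(fits, `[[`, numeric(1), "slope_mag")
      list(slopes = slopes, r2 = mean(vapply(fits, `[[`, numeric(1), "r2")),
           mean_slope = mean(slopes),
           sd_slope = if (length(slopes) > 1) stats::sd(slopes) else NA_real_,
           n = length(slopes))
    }
  })
  names(per_label) <- labs

  km <- per_label[[control_label]]$mean_slope
  if (km <= 0)
    stop_ocunano("control slope is zero: Km undefined",
                 "ocunano_degenerate_calibration_error")
  ctrl_slopes <- per_label[[control_label]]$slopes

  rows <- lapply(labs, function(lab) {
    pl <- per_label[[lab]]
    is_ctrl <- lab == control_label
    ff <- if (is_ctrl) NA_real_ else clamp(pl$mean_slope / km, 0, 1)
    p <- if (is_ctrl || length(pl$slopes) < 2L || length(ctrl_slopes) < 2L)
      NA_real_
    else stats::t.test(pl$slopes, ctrl_slopes, var.equal = TRUE)$p.value
    data.frame(label = lab,
               role = if (is_ctrl) "control" else "formulation",
               slope_mag = pl$mean_slope, slope_sd = pl$sd_slope,
               n_rep = pl$n, r2 = pl$r2, km = km, ff = ff,
               interaction_pct = if (is_ctrl) NA_real_ else 100 * (1 - ff),
               p_vs_control = p,
               significant = !is.na(p) & p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("binding_table", "data.frame")
  out
}

#' Interaction percentages from printed slope magnitudes
#'
#' Runs the full binding pipeline on exact exponential donor-decay curves
#' reconstructed from reported slope magnitudes: generate the noiseless
#' log-linear series for each formulation, fit it, calibrate Km from the
#' control, and compute the bound fraction. Useful to reproduce a reported
#' interaction table from its slope column.
#'
#' @param slopes Data frame with columns \code{label, role, slope_mag}
#'   (h^-1); exactly one \code{role == "control"} row.
#' @param times Sampling grid (h) used for the reconstructed curves.
#' @return Data frame \code{label, slope_mag, km, ff, interaction_pct}
#'   (interaction rounded to 1 decimal, as conventionally reported);
#'   control row has \code{NA} interaction.
#' @examples
#' tab <- utils::read.csv(system.file("extdata", "dialysis_slopes.csv",
#'                                    package = "ocunano"))
#' interaction_from_slopes(tab)
#' @export
interaction_from_slopes <- function(slopes, times = seq(0.5, 5, by = 0.5)) {
  stopifnot(all(c("label", "role", "slope_mag") %in% names(slopes)))
  ctrl <- which(slopes$role == "control")
  if (length(ctrl) != 1L)
    stop_ocunano("exactly one control row is required", "ocunano_input_error")
  fits <- lapply(seq_len(nrow(slopes)), function(i) {
    run <- gen_dialysis_run(km = slopes$slope_mag[i], ff = 1, cd0 = 100,
                            times = times, noise = 0, seed = 1L,
                            label = slopes$label[i],
                            role = slopes$role[i])
    fit_log_linear(run)
  })
  km <- calibrate_km(fits[[ctrl]])
  rows <- lapply(seq_along(fits), function(i) {
    if (i == ctrl)
      return(data.frame(label = slopes$label[i], slope_mag = fits[[i]]$slope_mag,
                        km = km, ff = NA_real_, interaction_pct = NA_real_))
    f <- bound_fraction(fits[[i]], km)
    data.frame(label = slopes$label[i], slope_mag = f$slope_mag, km = km,
               ff = f$ff, interaction_pct = round(f$interaction_pct, 1))
  })
  do.call(rbind, rows)
}
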