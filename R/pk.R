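# Sparse-sampling noncompartmental ocular pharmacokinetics.
#
# Aqueous-humor sampling is destructive in rabbits: each animal
# contributes one sample per time point, so the profile is a set of
# per-time means, SDs and group sizes rather than per-subject curves.
# The exposure metric is the linear trapezoidal AUC over 0-10 h. Because
# the trapezoidal AUC is a linear combination of the per-time means,
# AUC = sum_i w_i * Cbar_i, its sampling variance follows by propagation:
# Var(AUC) = sum_i w_i^2 * sd_i^2 / n_i (Bailer's method), which supports
# a z (or Satterthwaite t) comparison of two AUCs.

#' Construct a sparse-sampling PK profile
#'
#' @param label Formulation label.
#' @param times_h Sampling times (h), strictly increasing, first >= 0.
#' @param mean_conc Per-time mean concentrations (ug/mL), >= 0.
#' @param sd_conc Per-time SDs (ug/mL), >= 0; scalar recycled.
#' @param n_per_time Animals (eyes) per time point, >= 1; scalar recycled.
#' @return A \code{pk_profile} list.
#' @export
pk_profile <- function(label, times_h, mean_conc, sd_conc, n_per_time) {
  k <- length(times_h)
  sd_conc <- rep_len(sd_conc, k)
  n_per_time <- rep_len(as.integer(n_per_time), k)
  if (length(mean_conc) != k)
    stop_ocunano("times_h and mean_conc must have equal length",
                 "ocunano_domain_error")
  if (any(diff(times_h) <= 0) || times_h[1] < 0)
    stop_ocunano("times must be strictly increasing and start at >= 0",
                 "ocunano_domain_error")
  if (any(mean_conc < 0) || any(sd_conc < 0) || any(n_per_time < 1L))
    stop_ocunano("concentrations and SDs must be >= 0 and n >= 1",
                 "ocunano_domain_error")
  structure(list(label = label, times_h = as.numeric(times_h),
                 mean_conc = as.numeric(mean_conc),
                 sd_conc = as.numeric(sd_conc), n_per_time = n_per_time),
            class = "pk_profile")
}

# trapezoidal weights: endpoint w = half adjacent interval, interior
# w = half the span of the two adjacent intervals
trapezoid_weights <- function(times) {
  k <- length(times)
  w <- numeric(k)
  w[1] <- (times[2] - times[1]) / 2
  w[k] <- (times[k] - times[k - 1]) / 2
  if (k > 2) w[2:(k - 1)] <- (times[3:k] - times[1:(k - 2)]) / 2
  w
}

#' Trapezoidal AUC with sparse-sampling variance
#'
#' Linear trapezoidal AUC of a [pk_profile] over \code{[t_start, t_end]},
#' with variance propagated from the per-time SDs and group sizes. When
#' the profile lacks a t = 0 row and \code{t_start} is 0, a zero
#' concentration at t = 0 is prepended (topical instillation, no baseline
#' drug). Window bounds interior to the grid are handled by linear
#' interpolation of the mean profile (interpolated bounds carry the
#' variance of the bracketing points through the interpolation weights).
#'
#' @param profile A [pk_profile].
#' @param t_start,t_end Integration window (h), default 0-10.
#' @param prepend_zero Prepend C = 0 at t = 0 when absent, default TRUE.
#' @return An \code{auc_result}: list with \code{label}, \code{auc}
#'   (ug h/mL), \code{var_auc}, \code{sd_auc}, \code{auc_rel}
#'   (NA until [relative_auc()]), and the effective \code{times}/weights.
#' @examples
#' p <- pk_profile("TSOH", c(0, 2, 4, 6, 8, 10), rep(0.3, 6), 0.05, 6)
#' trapezoid_auc(p)$auc # 3.0
#' @export
trapezoid_auc <- function(profile, t_start = 0, t_end = 10,
                          prepend_zero = TRUE) {
  stopifnot(inherits(profile, "pk_profile"))
  tt <- profile$times_h; cc <- profile$mean_conc
  sd <- profile$sd_conc; nn <- profile$n_per_time
  if (prepend_zero && t_start == 0 && tt[1] > 0) {
    tt <- c(0, tt); cc <- c(0, cc); sd <- c(0, sd); nn <- c(nn[1], nn)
  }
  if (t_start < tt[1] || t_end > tt[length(tt)])
    stop_ocunano(sprintf("window [%g, %g] h not covered by data [%g, %g] h",
                         t_start, t_end, tt[1], tt[length(tt)]),
                 "ocunano_domain_error")
  # clip to the window, interpolating the bounds if needed
  interp_at <- function(t0) {
    i <- findInterval(t0, tt)
    if (tt[i] == t0) return(NULL)
    f <- (t0 - tt[i]) / (tt[i + 1] - tt[i])
    # interpolated point inherits propagated variance of its neighbours
    list(t = t0, c = (1 - f) * cc[i] + f * cc[i + 1],
         v = (1 - f)^2 * sd[i]^2 / nn[i] + f^2 * sd[i + 1]^2 / nn[i + 1])
  }
  inside <- tt >= t_start & tt <= t_end
  t_w <- tt[inside]; c_w <- cc[inside]
  v_w <- sd[inside]^2 / nn[inside]
  for (bound in list(interp_at(t_start), interp_at(t_end))) {
    if (!is.null(bound)) {
      pos <- sum(t_w < bound$t)
      t_w <- append(t_w, bound$t, after = pos)
      c_w <- append(c_w, bound$c, after = pos)
      v_w <- append(v_w, bound$v, after = pos)
    }
  }
  if (length(t_w) < 2L)
    stop_ocunano("fewer than 2 points in the integration window",
                 "ocunano_domain_error")
  w <- trapezoid_weights(t_w)
  structure(list(label = profile$label,
                 auc = sum(w * c_w), var_auc = sum(w^2 * v_w),
                 sd_auc = sqrt(sum(w^2 * v_w)), auc_rel = NA_real_,
                 times = t_w, weights = w,
                 window = c(t_start, t_end)),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC[%g-%g h] for %s: %.3g +/- %.2g ug h/mL%s\n",
              x$window[1], x$window[2], x$label, x$auc, x$sd_auc,
              if (!is.na(x$auc_rel)) sprintf(" (AUC_rel %.1f)", x$auc_rel)
              else ""))
  invisible(x)
}

#' Relative AUC versus a control formulation
#'
#' @param test,control \code{auc_result} objects (or lists with an
#'   \code{auc} element); the control AUC must be > 0.
#' @return The ratio \code{test$auc / control$auc} rounded to 1 decimal,
#'   the conventional reporting precision for relative ocular
#'   bioavailability.
#' @examples
#' relative_auc(list(auc = 2.32), list(auc = 0.62)) # 3.7
#' @export
relative_auc <- function(test, control) {
  if (is.null(control$auc) || control$auc <= 0)
    stop_ocunano("control AUC must be positive", "ocunano_domain_error")
  round(test$auc / control$auc, 1)
}

#' Compare two sparse-sampling AUCs
#'
#' Variance-propagation test for destructively sampled profiles:
#' \code{z = (AUC_a - AUC_b) / sqrt(Var_a + Var_b)} referred to the
#' standard normal (default) or to a t distribution with Satterthwaite
#' degrees of freedom assembled from the per-time variance contributions.
#'
#' @param a,b \code{auc_result} objects with variances set.
#' @param reference \code{"normal"} (default) or \code{"t"}.
#' @param df_a,df_b Optional per-profile data frames
#'   \code{contrib = w_i^2 sd_i^2 / n_i, n = n_i} for the Satterthwaite
#'   df; when absent under \code{reference = "t"} a conservative
#'   \code{min n - 1} style df cannot be formed and the normal reference
#'   is used with a warning.
#' @param alpha Significance level, default 0.05.
#' @return List with \code{statistic}, \code{df} (NA for normal),
#'   \code{p}, \code{significant}, \code{diff}.
#' @export
compare_auc <- function(a, b, reference = c("normal", "t"),
                        df_a = NULL, df_b = NULL, alpha = 0.05) {
  reference <- match.arg(reference)
  stopifnot(inherits(a, "auc_result"), inherits(b, "auc_result"))
  v <- a$var_auc + b$var_auc
  if (v <= 0)
    stop_ocunano("both AUC variances are zero: comparison degenerate",
                 "ocunano_degenerate_test_error")
  z <- (a$auc - b$auc) / sqrt(v)
  df <- NA_real_
  if (reference == "t") {
    if (is.null(df_a) || is.null(df_b)) {
      warn_ocunano("per-time contributions missing; using normal reference",
                   "ocunano_df_warning")
      reference <- "normal"
    } else {
      contrib <- c(df_a$contrib, df_b$contrib)
      nn <- c(df_a$n, df_b$n)
      df <- v^2 / sum(contrib^2 / pmax(nn - 1, 1))
    }
  }
  p <- if (reference == "normal") 2 * stats::pnorm(-abs(z))
  else 2 * stats::pt(-abs(z), df)
  list(statistic = z, df = df, p = p, significant = p < alpha,
       diff = a$auc - b$auc)
}

#' Per-time variance contributions of a trapezoidal AUC
#'
#' Helper producing the \code{contrib}/\code{n} table consumed by
#' [compare_auc()] under the t reference.
#'
#' @param profile A [pk_profile].
#' @param ... Passed to [trapezoid_auc()] (window, zero prepending).
#' @return Data frame \code{contrib, n}, one row per time point used.
#' @export
auc_contributions <- function(profile, ...) {
  res <- trapezoid_auc(profile, ...)
  tt <- profile$times_h
  if (res$times[1] == 0 && tt[1] > 0) {
    tt <- c(0, tt)
    sd <- c(0, profile$sd_conc); nn <- c(profile$n_per_time[1], profile$n_per_time)
  } else {
    sd <- profile$sd_conc; nn <- profile$n_per_time
  }
  keep <- tt %in% res$times
  w <- res$weights[match(tt[keep], res$times)]
  data.frame(contrib = w^2 * sd[keep]^2 / nn[keep], n = nn[keep])
}

#' Analyse a sparse-sampling PK experiment table
#'
#' Computes AUC (with variance), relative AUC versus the control label
#' and pairwise significance flags for a long-format per-time table.
#'
#' @param data Data frame with columns
#'   \code{label, time_h, mean_conc_ug_ml, sd_conc, n}.
#' @param control_label Label of the control profile.
#' @param t_start,t_end AUC window (h), default 0-10.
#' @param alpha Significance level, default 0.05.
#' @return List with \code{summary} (per-label data frame: auc, sd_auc,
#'   auc_rel, p_vs_control, significant), \code{results} (auc_result
#'   list) and \code{p_matrix}.
#' @export
fit_pk_experiment <- function(data, control_label = "Control",
                              t_start = 0, t_end = 10, alpha = 0.05) {
  needed <- c("label", "time_h", "mean_conc_ug_ml", "sd_conc", "n")
  if (!all(needed %in% names(data)))
    stop_ocunano(sprintf("PK input needs columns %s",
                         paste(needed, collapse = ",")),
                 "ocunano_input_error")
  labs <- unique(data$label)
  if (!control_label %in% labs)
    stop_ocunano(sprintf("control label '%s' not in data", control_label),
                 "ocunano_input_error")
  res <- lapply(labs, function(lab) {
    sub <- data[data$label == lab, , drop = FALSE]
    ord <- order(sub$time_h)
    p <- pk_profile(lab, sub$time_h[ord], sub$mean_conc_ug_ml[ord],
                    sub$sd_conc[ord], sub$n[ord])
    trapezoid_auc(p, t_start, t_end)
  })
  names(res) <- labs
  ctrl <- res[[control_label]]
  pm <- matrix(NA_real_, length(labs), length(labs),
               dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i < j) {
      p <- tryCatch(compare_auc(res[[i]], res[[j]], alpha = alpha)$p,
                    ocunano_degenerate_test_error = function(e) NA_real_)
      pm[i, j] <- pm[j, i] <- p
    }
  }
  summ <- do.call(rbind, lapply(labs, function(lab) {
    r <- res[[lab]]
    data.frame(label = lab, auc = r$auc, sd_auc = r$sd_auc,
               auc_rel = if (lab == control_label) NA_real_
               else relative_auc(r, ctrl),
               p_vs_control = if (lab == control_label) NA_real_
               else pm[lab, control_label],
               significant = if (lab == control_label) NA
               else pm[lab, control_label] < alpha,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, results = res, p_matrix = pm)
}
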