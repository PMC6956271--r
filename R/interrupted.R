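# Interrupted dialysis: three-phase drug mass balance.
#
# The dynamic-dialysis experiment is stopped at fixed times; the donor
# phase is centrifuged so the drug splits into three assayable pools:
# nanoparticle matrix (NPM), nanoparticle dispersion medium (DM) and the
# receiving phase (RP). DM and RP are assayed directly; the matrix pool is
# obtained by closure (difference from the known total load).

#' Three-phase drug partition at one interruption time
#'
#' @param total_mass Total drug load in the donor system (mg), > 0.
#' @param dm_mass Drug mass assayed in the dispersion medium (mg), >= 0.
#' @param rp_cum_mass Cumulative drug mass transported into the receiving
#'   phase by this time (mg), >= 0.
#' @param time_h Interruption time (h).
#' @param tolerance Relative mass-balance tolerance: \code{dm + rp} may
#'   exceed \code{total} by at most this fraction (assay error), default
#'   0.02.
#' @return A \code{phase_partition} list with \code{time_h},
#'   \code{pct_npm}, \code{pct_dm}, \code{pct_rp}; the three percentages
#'   sum to 100 by construction.
#' @examples
#' partition(6.25, 4.28, 1.00, time_h = 1)
#' @export
partition <- function(total_mass, dm_mass, rp_cum_mass, time_h,
                      tolerance = 0.02) {
  check_number(total_mass, "total_mass", lower = 0, strict_lower = TRUE)
  check_number(dm_mass, "dm_mass", lower = 0)
  check_number(rp_cum_mass, "rp_cum_mass", lower = 0)
  if (dm_mass + rp_cum_mass > total_mass * (1 + tolerance))
    stop_ocunano(sprintf(
      "mass balance violated at t = %g h: DM + RP = %.4g mg > total %.4g mg (+%.0f%% tolerance)",
      time_h, dm_mass + rp_cum_mass, total_mass, 100 * tolerance),
      "ocunano_mass_balance_error")
  pct_dm <- 100 * dm_mass / total_mass
  pct_rp <- 100 * rp_cum_mass / total_mass
  structure(list(time_h = time_h, pct_npm = 100 - pct_dm - pct_rp,
                 pct_dm = pct_dm, pct_rp = pct_rp),
            class = "phase_partition")
}

#' @export
print.phase_partition <- function(x, ...) {
  cat(sprintf("t = %g h: NPM %.1f%% | DM %.1f%% | RP %.1f%%\n",
              x$time_h, x$pct_npm, x$pct_dm, x$pct_rp))
  invisible(x)
}

#' Retention summary over a series of phase partitions
#'
#' Assesses the drug-retention claim for a nanoparticle matrix: the NPM
#' percentage is "constant" over a time window when its range (max - min)
#' does not exceed a tolerance in percentage points. A decreasing
#' receiving-phase pool (transport is cumulative and cannot reverse)
#' triggers a data-quality warning, not an error.
#'
#' @param partitions List of [partition()] results, times increasing;
#'   at least 2.
#' @param window Numeric length-2 time window (h) over which constancy is
#'   judged; default spans the whole series.
#' @param tolerance Maximum NPM range (percentage points) still called
#'   constant, default 5.
#' @return A list with \code{window}, \code{min}, \code{max}, \code{mean},
#'   \code{range} of NPM percent inside the window, and logical
#'   \code{constant}.
#' @export
retention_series <- function(partitions, window = NULL, tolerance = 5) {
  if (length(partitions) < 2L)
    stop_ocunano("retention assessment needs at least 2 partitions",
                 "ocunano_insufficient_data_error")
  stopifnot(all(vapply(partitions, inherits, logical(1), "phase_partition")))
  tt <- vapply(partitions, `[[`, numeric(1), "time_h")
  if (any(diff(tt) <= 0))
    stop_ocunano("partition times must be strictly increasing",
                 "ocunano_domain_error")
  rp <- vapply(partitions, `[[`, numeric(1), "pct_rp")
  if (any(diff(rp) < 0))
    warn_ocunano("receiving-phase percentage decreases with time",
                 "ocunano_rp_decrease_warning")
  if (is.null(window)) window <- range(tt)
  inside <- tt >= window[1] & tt <= window[2]
  if (!any(inside))
    stop_ocunano("no partitions inside the requested window",
                 "ocunano_insufficient_data_error")
  npm <- vapply(partitions, `[[`, numeric(1), "pct_npm")[inside]
  rng <- max(npm) - min(npm)
  list(window = window, min = min(npm), max = max(npm), mean = mean(npm),
       range = rng, constant = rng <= tolerance)
}

#' Mass-balance series from an interrupted-dialysis table
#'
#' Convenience wrapper mapping a data frame with columns
#' \code{time_h, total_mg, dm_mg, rp_cum_mg} to a list of partitions plus
#' a tidy percentage table.
#'
#' @param data Input data frame (one row per interruption time, sorted or
#'   not; it is sorted by time).
#' @param tolerance Passed to [partition()].
#' @return List with \code{partitions} (list) and \code{table}
#'   (data frame \code{time_h, pct_npm, pct_dm, pct_rp}).
#' @export
partition_series <- function(data, tolerance = 0.02) {
  needed <- c("time_h", "total_mg", "dm_mg", "rp_cum_mg")
  if (!all(needed %in% names(data)))
    stop_ocunano(sprintf("interrupted-dialysis input needs columns %s",
                         paste(needed, collapse = ",")),
                 "ocunano_input_error")
  data <- data[order(data$time_h), , drop = FALSE]
  parts <- lapply(seq_len(nrow(data)), function(i)
    partition(data$total_mg[i], data$dm_mg[i], data$rp_cum_mg[i],
              data$time_h[i], tolerance = tolerance))
  tab <- data.frame(time_h = vapply(parts, `[[`, numeric(1), "time_h"),
                    pct_npm = vapply(parts, `[[`, numeric(1), "pct_npm"),
                    pct_dm = vapply(parts, `[[`, numeric(1), "pct_dm"),
                    pct_rp = vapply(parts, `[[`, numeric(1), "pct_rp"))
  list(partitions = parts, table = tab)
}
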