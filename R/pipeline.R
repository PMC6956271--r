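# Reproducible pipeline driver: named stages over CSV inputs, structured
# configs (lists or YAML files), machine-readable summaries and a run log
# with package version, seed and config hash. A persisted config plus its
# seeds re-runs to identical outputs.

OCUNANO_STAGES <- c("binding", "interrupted", "release", "microrheo",
                    "sizing", "pk", "simulate")

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_ocunano(sprintf("config file '%s' not found", config),
                   "ocunano_input_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop_ocunano("config must be a list or a YAML file path",
                 "ocunano_input_error")
  config
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

read_stage_csv <- function(path, needed, stage) {
  if (is.null(path) || !file.exists(path %||% ""))
    stop_ocunano(sprintf("stage '%s': input file '%s' not found",
                         stage, path %||% "<missing>"),
                 "ocunano_input_error")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop_ocunano(sprintf("stage '%s': cannot parse '%s': %s",
                                        stage, path, conditionMessage(e)),
                                "ocunano_input_error"))
  if (!all(needed %in% names(df)))
    stop_ocunano(sprintf("stage '%s': '%s' must have columns %s",
                         stage, path, paste(needed, collapse = ",")),
                 "ocunano_input_error")
  df
}

write_log <- function(out_dir, stage, config, messages = character()) {
  lines <- c(
    sprintf("stage: %s", stage),
    sprintf("ocunano version: %s",
            as.character(utils::packageVersion("ocunano"))),
    sprintf("seed: %s", config$seed %||% "none"),
    sprintf("config md5: %s", config_hash(config)),
    messages)
  writeLines(lines, file.path(out_dir, sprintf("%s.log", stage)))
}

write_summary_json <- function(x, out_dir, stage) {
  path <- file.path(out_dir, sprintf("%s_summary.json", stage))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
  path
}

#' Run one named analysis stage
#'
#' Executes a single pipeline stage from a structured config, writing its
#' output tables, a machine-readable JSON summary and a log (package
#' version, seed, config hash) into \code{config$out_dir}. Identical
#' config + seed produces identical outputs.
#'
#' Stages and their config fields:
#' \describe{
#'   \item{binding}{\code{input}: CSV \code{label,role,replicate,time_h,
#'     donor_conc} for replicate fitting, or \code{slopes}: CSV
#'     \code{label,role,slope_mag} for slope-table reproduction.}
#'   \item{interrupted}{\code{input}: CSV \code{time_h,total_mg,dm_mg,
#'     rp_cum_mg}; optional \code{window}, \code{tolerance}.}
#'   \item{release}{\code{input}: CSV \code{label,replicate,time_min,
#'     released_pct}; optional \code{horizon_min}.}
#'   \item{microrheo}{\code{input}: CSV \code{lag_s,g2}; \code{optics}:
#'     list with \code{beta} and any of \code{wavelength_nm, ref_index,
#'     angle_deg, temperature_K, tracer_radius_nm}; optional
#'     \code{reference}: a second correlogram CSV (plain mucin) for a
#'     mucoadhesion verdict.}
#'   \item{sizing}{\code{input}: CSV \code{profile,position_um,intensity}
#'     (one line profile per \code{profile} id); optional
#'     \code{expect_bimodal}.}
#'   \item{pk}{\code{input}: CSV \code{label,time_h,mean_conc_ug_ml,
#'     sd_conc,n}; optional \code{control_label}, \code{t_start},
#'     \code{t_end}.}
#'   \item{simulate}{\code{kind}: one of dialysis/release/pk/dls;
#'     \code{params}: generator arguments; \code{seed}; writes the CSV the
#'     matching analysis stage reads.}
#' }
#'
#' @param stage Stage name, one of
#'   \code{binding, interrupted, release, microrheo, sizing, pk, simulate}.
#' @param config Named list or YAML file path. Must contain
#'   \code{out_dir}; stage-specific fields as above.
#' @return (Invisibly) the stage summary object; files are written under
#'   \code{config$out_dir}.
#' @export
run_stage <- function(stage, config) {
  if (!stage %in% OCUNANO_STAGES)
    stop_ocunano(sprintf("unknown stage '%s' (known: %s)", stage,
                         paste(OCUNANO_STAGES, collapse = ", ")),
                 "ocunano_usage_error")
  config <- load_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir))
    stop_ocunano("config must set out_dir", "ocunano_usage_error")
  # validate inputs before creating any output (no partial outputs)
  summary <- switch(stage,
    binding = stage_binding(config),
    interrupted = stage_interrupted(config),
    release = stage_release(config),
    microrheo = stage_microrheo(config),
    sizing = stage_sizing(config),
    pk = stage_pk(config),
    simulate = stage_simulate(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (art in summary$artifacts)
    utils::write.csv(art$data, file.path(out_dir, art$file), row.names = FALSE)
  summary$artifacts <- vapply(summary$artifacts, `[[`, character(1), "file")
  write_summary_json(summary, out_dir, stage)
  write_log(out_dir, stage, config, summary$log %||% character())
  invisible(summary)
}

stage_binding <- function(config) {
  if (!is.null(config$slopes)) {
    df <- read_stage_csv(config$slopes, c("label", "role", "slope_mag"),
                         "binding")
    tab <- interaction_from_slopes(df)
    list(stage = "binding", mode = "from-slopes", table = tab,
         artifacts = list(list(file = "binding_summary.csv", data = tab)))
  } else {
    df <- read_stage_csv(config$input,
                         c("label", "role", "replicate", "time_h",
                           "donor_conc"), "binding")
    tab <- fit_binding_experiment(df,
                                  control_label = config$control_label,
                                  pooled = isTRUE(config$pooled))
    list(stage = "binding", mode = "replicate-fits",
         table = as.data.frame(tab),
         artifacts = list(list(file = "binding_summary.csv",
                               data = as.data.frame(tab))))
  }
}

stage_interrupted <- function(config) {
  df <- read_stage_csv(config$input,
                       c("time_h", "total_mg", "dm_mg", "rp_cum_mg"),
                       "interrupted")
  ps <- partition_series(df, tolerance = config$mass_tolerance %||% 0.02)
  ret <- retention_series(ps$partitions, window = config$window,
                          tolerance = config$tolerance %||% 5)
  list(stage = "interrupted", retention = ret, table = ps$table,
       artifacts = list(list(file = "phase_partition.csv", data = ps$table)))
}

stage_release <- function(config) {
  df <- read_stage_csv(config$input,
                       c("label", "replicate", "time_min", "released_pct"),
                       "release")
  res <- fit_release_experiment(df,
                                horizon_min = config$horizon_min %||% 300)
  pm <- as.data.frame(res$p_matrix)
  pm <- cbind(label = rownames(res$p_matrix), pm)
  list(stage = "release", table = res$summary,
       p_matrix = res$p_matrix,
       artifacts = list(
         list(file = "release_summary.csv", data = res$summary),
         list(file = "release_p_matrix.csv", data = pm)))
}

stage_microrheo <- function(config) {
  optics <- config$optics %||% list()
  if (is.null(optics$beta))
    stop_ocunano("microrheo stage needs optics$beta", "ocunano_input_error")
  load_spec <- function(path) {
    df <- read_stage_csv(path, c("lag_s", "g2"), "microrheo")
    cg <- correlogram(df$lag_s, df$g2, beta = optics$beta,
                      wavelength_nm = optics$wavelength_nm %||% 633,
                      ref_index = optics$ref_index %||% 1.33,
                      angle_deg = optics$angle_deg %||% 173,
                      temperature_K = optics$temperature_K %||% 298.15,
                      tracer_radius_nm = optics$tracer_radius_nm %||% 250)
    gser_moduli(msd_from_g2(cg), cg$tracer_radius_nm, cg$temperature_K)
  }
  mod <- load_spec(config$input)
  out_tab <- data.frame(omega_rad_s = mod$omega_rad_s,
                        G_prime_Pa = mod$g_prime_Pa,
                        G_dprime_Pa = mod$g_dprime_Pa,
                        eta_star_Pa_s = mod$eta_star_Pa_s)
  summary <- list(stage = "microrheo",
                  artifacts = list(list(file = "moduli.csv",
                                        data = out_tab)))
  if (!is.null(config$reference)) {
    ref <- load_spec(config$reference)
    cmp <- mucoadhesion_compare(ref, mod,
                                threshold = config$threshold %||% 0.10)
    summary$median_eta_ratio <- cmp$median_eta_ratio
    summary$mucoadhesive <- cmp$mucoadhesive
  }
  summary
}

stage_sizing <- function(config) {
  df <- read_stage_csv(config$input,
                       c("profile", "position_um", "intensity"), "sizing")
  profs <- lapply(split(df, df$profile), function(p) {
    ord <- order(p$position_um)
    intensity_profile(p$position_um[ord], p$intensity[ord])
  })
  est <- size_particles(profs,
                        expect_bimodal = isTRUE(config$expect_bimodal))
  tab <- cbind(label = config$label %||% "sample",
               status = config$status %||% "",
               mode = seq_len(nrow(est$modes)), est$modes)
  list(stage = "sizing", bimodal = est$bimodal, table = tab,
       artifacts = list(list(file = "sizes.csv", data = tab)))
}

stage_pk <- function(config) {
  df <- read_stage_csv(config$input,
                       c("label", "time_h", "mean_conc_ug_ml", "sd_conc",
                         "n"), "pk")
  res <- fit_pk_experiment(df,
                           control_label = config$control_label %||% "Control",
                           t_start = config$t_start %||% 0,
                           t_end = config$t_end %||% 10)
  list(stage = "pk", table = res$summary,
       artifacts = list(list(file = "pk_summary.csv", data = res$summary)))
}

stage_simulate <- function(config) {
  kind <- config$kind
  params <- config$params %||% list()
  seed <- config$seed
  sim <- switch(kind %||% "",
    dialysis = {
      run <- do.call(gen_dialysis_run, c(params, list(seed = seed)))
      data.frame(label = run$label, role = run$role, replicate = 1L,
                 time_h = run$times, donor_conc = run$donor_conc)
    },
    release = {
      cv <- do.call(gen_release_curve, c(params, list(seed = seed)))
      data.frame(label = cv$label, replicate = cv$replicate,
                 time_min = cv$times, released_pct = cv$released_pct)
    },
    pk = {
      pr <- do.call(gen_pk_profile, c(params, list(seed = seed)))
      data.frame(label = pr$label, time_h = pr$times_h,
                 mean_conc_ug_ml = pr$mean_conc, sd_conc = pr$sd_conc,
                 n = pr$n_per_time)
    },
    dls = {
      cg <- do.call(gen_dls_g2, c(params, list(seed = seed)))
      data.frame(lag_s = cg$lags, g2 = cg$g2)
    },
    stop_ocunano(sprintf("unknown simulate kind '%s'", kind %||% ""),
                 "ocunano_usage_error"))
  file <- config$file %||% sprintf("sim_%s.csv", kind)
  list(stage = "simulate", kind = kind, n = nrow(sim),
       artifacts = list(list(file = file, data = sim)))
}

#' Run a multi-stage pipeline from one config
#'
#' Executes the listed stages in order (simulate stages first when
#' present, in the order given), writes each stage's artifacts under a
#' per-stage subdirectory of \code{config$out_dir} and a combined report
#' JSON cross-referencing formulation labels across stages.
#'
#' @param config Named list or YAML path with \code{out_dir} and
#'   \code{stages}: a list of entries, each a list with \code{stage} and
#'   that stage's config fields (paths relative to the caller's working
#'   directory).
#' @return (Invisibly) the combined report list; also written as
#'   \code{pipeline_report.json}.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  if (is.null(config$stages) || length(config$stages) == 0L)
    stop_ocunano("pipeline config must list at least one stage",
                 "ocunano_usage_error")
  out_dir <- config$out_dir
  if (is.null(out_dir))
    stop_ocunano("config must set out_dir", "ocunano_usage_error")
  results <- list()
  for (entry in config$stages) {
    st <- entry$stage
    entry$stage <- NULL
    entry$out_dir <- file.path(out_dir, st)
    entry$seed <- entry$seed %||% config$seed
    results[[st]] <- run_stage(st, entry)
  }
  # cross-reference formulation labels across stages that carry them
  labels <- lapply(results, function(r)
    if (!is.null(r$table$label)) sort(unique(as.character(r$table$label))))
  labels <- Filter(Negate(is.null), labels)
  shared <- if (length(labels) > 1) Reduce(intersect, labels) else NULL
  report <- list(stages = names(results),
                 shared_labels = shared,
                 results = results)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "pipeline_report.json"),
                       auto_unbox = TRUE, digits = 10, na = "null",
                       pretty = TRUE)
  invisible(report)
}
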