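#' End-to-end run configuration
#'
#' Bundles every tunable of the per-subject pipeline and the cohort-level
#' model fit. All defaults are the standard study conditions: density
#' exponent `S = 2.5`, band 0.009-0.08 Hz, scrub thresholds 0.5 mm FD and
#' 0.5% DVARS, 50 mm rotation radius.
#'
#' @param seed RNG seed for the whole run.
#' @param s density exponent of the `N = K^S` matching rule.
#' @param band numeric `c(low_hz, high_hz)` band-pass edges.
#' @param fd_thresh,dvars_thresh scrub thresholds (mm, percent).
#' @param rotation_radius mm, for FD computation.
#' @param cohort a [cohort_spec()] describing the subject sample.
#' @param candidates candidate covariates for the stepwise model.
#' @param outcome outcome column name.
#' @param aicc,hierarchy passed to [stepwise_select()].
#' @param imaging optional [modular_series_spec()]; when supplied,
#'   [run_cohort()] also simulates per-subject imaging + behaviour and runs
#'   the full per-subject pipeline.
#' @param nback optional [nback_session_spec()] used with `imaging`.
#' @param out_dir output directory for [run_cohort()] (created if needed), or
#'   `NULL` to skip writing files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, s = 2.5, band = c(0.009, 0.08),
                       fd_thresh = 0.5, dvars_thresh = 0.5,
                       rotation_radius = 50,
                       cohort = cohort_spec(),
                       candidates = c("e_local_task", "e_global_task",
                                      "mean_rt", "n_volumes_removed",
                                      "age_group"),
                       outcome = "dprime",
                       aicc = FALSE, hierarchy = FALSE,
                       imaging = NULL, nback = NULL,
                       out_dir = NULL) {
  if (s <= 0) stop("'s' must be > 0")
  if (length(band) != 2L || band[1] < 0 || band[1] >= band[2]) {
    stop("'band' must be c(low_hz, high_hz) with 0 <= low < high")
  }
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!is.null(imaging)) stopifnot(inherits(imaging, "modular_series_spec"))
  if (!is.null(nback)) stopifnot(inherits(nback, "nback_session_spec"))
  structure(list(seed = seed, s = s, band = band, fd_thresh = fd_thresh,
                 dvars_thresh = dvars_thresh,
                 rotation_radius = rotation_radius, cohort = cohort,
                 candidates = candidates, outcome = outcome, aicc = aicc,
                 hierarchy = hierarchy, imaging = imaging, nback = nback,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full per-subject pipeline
#'
#' Composes the per-subject stages in fixed order: band-pass filter, nuisance
#' regression (the six motion parameters plus the global mean signal), FD /
#' DVARS motion scrubbing, Pearson correlation, density-matched thresholding,
#' efficiency metrics, and 2-back behavioural scoring. DVARS is computed on
#' the filtered, regressed data but normalised by the raw-signal grand mean.
#'
#' @param ts raw [timeseries_matrix()] for one subject.
#' @param motion 6-column motion table aligned with `ts`.
#' @param trials 2-back trial log for the same subject.
#' @param config a [run_config()].
#' @param age_group 0 (young) or 1 (old), recorded in the subject row.
#' @param subject_id identifier recorded in the subject row.
#' @return A list with `record` (one-row data frame of SubjectRecord fields),
#'   `efficiency` (an `efficiency_result`) and `scrub` (a `scrub_report`).
#' @export
#' @examples
#' cfg <- run_config(cohort = cohort_spec(seed = 1))
#' ts <- generate_modular_timeseries(
#'   modular_series_spec(20, 4, 0.5, 0.05, n_frames = 160, tr = 2, seed = 3))
#' motion <- generate_motion_trace(160, seed = 3)
#' trials <- generate_nback_session(nback_session_spec(seed = 3))
#' run_subject(ts, motion, trials, cfg)$record
run_subject <- function(ts, motion, trials, config, age_group = 0L,
                        subject_id = "S001") {
  stopifnot(inherits(config, "run_config"))
  if (nrow(as.matrix(motion)) != n_frames(ts)) {
    stop("subject ", subject_id,
         ": motion table and time series disagree on frame count")
  }
  raw_mean <- mean(ts$values)
  filt <- bandpass_filter(ts, config$band[1], config$band[2])
  clean <- regress_nuisance(filt, cbind(as.matrix(motion),
                                        global = colMeans(ts$values)))
  sc <- scrub(clean, motion, fd_thresh = config$fd_thresh,
              dvars_thresh = config$dvars_thresh,
              rotation_radius = config$rotation_radius,
              baseline_mean = raw_mean)
  net <- threshold_to_density(correlation_matrix(sc$ts), s = config$s)
  eff <- efficiency(net)
  counts <- classify_trials(trials)
  rt <- mean_correct_rt(trials)
  record <- data.frame(subject_id = subject_id,
                       age_group = as.integer(age_group),
                       e_local_task = eff$e_local,
                       e_global_task = eff$e_global,
                       mean_rt = as.numeric(rt),
                       n_volumes_removed = sc$report$n_removed,
                       dprime = dprime(counts))
  list(record = record, efficiency = eff, scrub = sc$report)
}

#' Run a full cohort and fit the working-memory model
#'
#' Generates the subject cohort described by `config$cohort`, fits the
#' stepwise model of `config$outcome` on `config$candidates`, and (when
#' `config$out_dir` is set) writes `subjects.csv`, `modelfit.json` and a
#' `manifest.json` recording the configuration. If `config$imaging` is
#' supplied, per-subject imaging and 2-back sessions are additionally
#' simulated and pushed through [run_subject()]; pipeline-derived efficiency,
#' RT, motion and d' then replace the equation-based covariates, failed
#' subjects are logged and skipped, and `efficiency.csv` is written with the
#' per-subject network summaries. Re-running with the same config reproduces
#' every output.
#'
#' @param config a [run_config()].
#' @return A list with `subjects` (data frame), `fit` (a `stepwise_fit`),
#'   `failures` (character vector of failed subject ids) and `paths` (written
#'   files, if any).
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set_seed_if_given(config$seed)
  subjects <- generate_subject_cohort(config$cohort)
  failures <- character()
  eff_rows <- NULL
  if (!is.null(config$imaging)) {
    nback <- if (is.null(config$nback)) nback_session_spec() else config$nback
    rows <- vector("list", nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      res <- tryCatch({
        ts <- generate_modular_timeseries(config$imaging)
        motion <- generate_motion_trace(config$imaging$n_frames)
        trials <- generate_nback_session(nback)
        run_subject(ts, motion, trials, config,
                    age_group = subjects$age_group[i],
                    subject_id = subjects$subject_id[i])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("subject ", subjects$subject_id[i], " failed: ",
                conditionMessage(res))
        failures <- c(failures, subjects$subject_id[i])
      } else {
        rows[[i]] <- res$record
        eff_rows <- rbind(eff_rows,
                          data.frame(subject_id = subjects$subject_id[i],
                                     e_global = res$efficiency$e_global,
                                     e_local = res$efficiency$e_local,
                                     n_nodes = res$efficiency$n_nodes,
                                     n_edges = res$efficiency$n_edges))
      }
    }
    subjects <- do.call(rbind, rows)
    if (is.null(subjects) || nrow(subjects) == 0) {
      stop("all subjects failed; nothing to fit")
    }
  }
  fml <- stats::reformulate(config$candidates, response = config$outcome)
  fit <- stepwise_select(fml, subjects, aicc = config$aicc,
                         hierarchy = config$hierarchy)
  paths <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p_subj <- file.path(config$out_dir, "subjects.csv")
    utils::write.csv(subjects, p_subj, row.names = FALSE)
    p_fit <- file.path(config$out_dir, "modelfit.json")
    write_modelfit_json(fit, p_fit)
    p_manifest <- file.path(config$out_dir, "manifest.json")
    manifest <- list(
      package = "braineff",
      version = as.character(utils::packageVersion("braineff")),
      seed = config$seed, s = config$s, band = config$band,
      fd_thresh = config$fd_thresh, dvars_thresh = config$dvars_thresh,
      cohort = list(n_young = config$cohort$n_young,
                    n_old = config$cohort$n_old,
                    noise_sd = config$cohort$noise_sd),
      candidates = config$candidates, outcome = config$outcome,
      selected = fit$selected, failures = failures,
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA)
    paths <- c(subjects = p_subj, modelfit = p_fit, manifest = p_manifest)
    if (!is.null(eff_rows)) {
      p_eff <- file.path(config$out_dir, "efficiency.csv")
      utils::write.csv(eff_rows, p_eff, row.names = FALSE)
      paths <- c(paths, efficiency = p_eff)
    }
  }
  list(subjects = subjects, fit = fit, failures = failures, paths = paths)
}
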