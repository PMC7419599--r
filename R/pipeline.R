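# Trial bundles on disk and the simulate -> condition -> detect -> measure ->
# analyze orchestration.

bundle_schemas <- function() {
  list(
    emg = c("time", emg_channels()),
    force = c("time", paste0("p1_", c("fx", "fy", "fz", "mx", "my", "mz")),
              paste0("p2_", c("fx", "fy", "fz", "mx", "my", "mz"))),
    kin = c("time", "com_ap", "com_ml", "com_z",
            "ankle", "knee", "hip", "lumbar", "thorax", "shoulder", "elbow",
            "support_ap", "support_ml", "landing_ap", "landing_ml"),
    sensor = c("time", "state")
  )
}

#' Write one trial bundle to a directory
#'
#' Writes `emg.csv`, `force.csv`, `kin.csv`, `sensor.csv`, `meta.json` and,
#' when ground truth is supplied, `truth.json` (comma-separated, header row,
#' UTF-8, `.` decimal; times in seconds).
#'
#' @param recording A `trial_recording` (see [generate_trial()]).
#' @param path Directory to create/write into.
#' @param truth Optional ground-truth list to serialize as `truth.json`.
#' @return `path`, invisibly.
#' @export
write_trial_bundle <- function(recording, path, truth = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(recording$emg, file.path(path, "emg.csv"), progress = FALSE)
  readr::write_csv(recording$force, file.path(path, "force.csv"), progress = FALSE)
  readr::write_csv(recording$kin, file.path(path, "kin.csv"), progress = FALSE)
  readr::write_csv(recording$sensor, file.path(path, "sensor.csv"), progress = FALSE)
  jsonlite::write_json(recording$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    tr <- truth
    tr$events <- unclass(tr$events)
    tr$muscle_onsets <- as.list(tr$muscle_onsets)
    jsonlite::write_json(tr, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read one trial bundle from a directory
#'
#' Schema-validates every stream: a missing required column is an error
#' naming the file and column; unknown extra columns produce a warning and
#' are kept. A missing `meta.json` is an error.
#'
#' @param path Bundle directory.
#' @return A `trial_recording`; if `truth.json` is present it is attached as
#'   attribute `"truth"`.
#' @export
read_trial_bundle <- function(path) {
  if (!dir.exists(path)) abort_data(sprintf("bundle directory '%s' not found", path))
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file))
    abort_data(sprintf("missing meta.json in '%s'", path))
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  schemas <- bundle_schemas()
  streams <- lapply(names(schemas), function(nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) abort_data(sprintf("missing %s.csv in '%s'", nm, path))
    x <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(schemas[[nm]], names(x))
    if (length(miss))
      abort_data(sprintf("%s.csv: missing column(s) %s", nm,
                         paste(miss, collapse = ", ")))
    extra <- setdiff(names(x), schemas[[nm]])
    if (length(extra))
      warning(sprintf("%s.csv: ignoring unknown column(s) %s", nm,
                      paste(extra, collapse = ", ")), call. = FALSE)
    if (!all(vapply(x[schemas[[nm]]], is.numeric, logical(1))))
      abort_data(sprintf("%s.csv: non-numeric data in a required column", nm))
    x
  })
  names(streams) <- names(schemas)
  rec <- structure(c(streams, list(meta = meta)), class = "trial_recording")
  tf <- file.path(path, "truth.json")
  if (file.exists(tf))
    attr(rec, "truth") <- jsonlite::read_json(tf, simplifyVector = TRUE)
  rec
}

#' Simulate a cohort and write every trial bundle to disk
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory; one subdirectory per trial, named
#'   `<participant>_<condition>_t<trial>`.
#' @param truth Also write `truth.json` per trial (default TRUE).
#' @return Character vector of bundle paths, invisibly.
#' @export
simulate_cohort_bundles <- function(spec, out_dir, truth = TRUE) {
  design <- cohort_design(spec)
  paths <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    tr <- generate_trial(spec, design$group_i[i], design$part_i[i],
                         design$cond_i[i], design$trial_i[i])
    paths[i] <- file.path(out_dir, sprintf("%s_%s_t%d", design$participant[i],
                                           design$condition[i], design$trial[i]))
    write_trial_bundle(tr$recording, paths[i],
                       truth = if (truth) tr$truth else NULL)
  }
  invisible(paths)
}

# Condition one trial and extract its event timeline + movement metrics +
# per-channel EMG envelopes (unnormalized; normalization is a participant-
# level operation).
process_trial <- function(recording, filters = filter_spec(),
                          event_opts = list()) {
  meta <- recording$meta
  rates <- meta$rates
  kin <- recording$kin
  # smooth everything; remove the quiet-stance DC offset from the CoM only
  # (malleoli and joint angles must keep their absolute values)
  kin_s <- kin
  for (col in setdiff(names(kin), "time")) {
    kin_s[[col]] <- condition_kinematics(kin[[col]], filters, rate = rates$kin,
                                         remove_dc = col %in% c("com_ap", "com_ml"))
  }
  reach <- detect_reach_events(recording$sensor$state, rates$force)
  cop <- net_cop(recording$force)
  cop_args <- c(list(cop = cop, rate = rates$force),
                event_opts[intersect(names(event_opts),
                                     c("baseline_window", "k_sd", "sustain_s",
                                       "refine", "refine_s"))])
  cop_on <- do.call(detect_cop_onset, cop_args)
  bw <- meta$body_mass_kg * 9.81
  step <- detect_step_events(recording$force$p2_fz, rates$force, bw,
                             unload_frac = event_opts$unload_frac %||% 0.05,
                             load_frac = event_opts$load_frac %||% 0.05)
  events <- event_set(reach_on = reach[["reach_on"]],
                      reach_off = reach[["reach_off"]],
                      cop_on = cop_on, step_on = step[["step_on"]],
                      step_off = step[["step_off"]],
                      duration_s = meta$duration_s)
  mm <- trial_movement_metrics(kin_s, events)
  envelopes <- lapply(recording$emg[emg_channels()], condition_emg,
                      spec = filters, rate = rates$emg)
  list(meta = meta, events = events, movement = mm, envelopes = envelopes)
}

# Participant-level EMG step: normalize envelopes across all of the
# participant's trials per muscle, then detect onsets and compute the
# phase-windowed co-contraction indices.
participant_emg_metrics <- function(processed, onset = onset_params(),
                                    pairs = default_muscle_pairs(),
                                    cci_method = "weighted") {
  chans <- emg_channels()
  maxima <- vapply(chans, function(ch) {
    max(vapply(processed, function(p) max(p$envelopes[[ch]]), numeric(1)))
  }, numeric(1))
  dead <- names(maxima)[maxima <= 0]
  if (length(dead))
    abort_data(paste0("dead EMG channel(s): ", paste(dead, collapse = ", ")))
  rows <- list()
  for (p in processed) {
    env_n <- lapply(chans, function(ch) p$envelopes[[ch]] / maxima[[ch]])
    names(env_n) <- chans
    rate <- p$meta$rates$emg
    onsets <- vapply(env_n, detect_muscle_onset, numeric(1),
                     params = onset, rate = rate)
    lat <- onsets_relative_to_reach(onsets, p$events)
    cci <- lapply(seq_len(nrow(pairs)), function(i) {
      cci_by_phase(env_n[[pairs$agonist[i]]], env_n[[pairs$antagonist[i]]],
                   rate, p$events, method = cci_method)
    })
    cci_mean <- rowMeans(do.call(cbind, lapply(cci, `[[`, "cci")))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      participant = p$meta$participant, group = p$meta$group,
      condition = p$meta$condition, trial = p$meta$trial,
      metric = c(paste0("onset_", chans), paste0("cci_", c("i", "ii", "iii", "iv"))),
      value = c(unname(lat), unname(cci_mean))
    )
  }
  dplyr::bind_rows(rows)
}

trial_metric_rows <- function(p) {
  ev <- p$events
  vals <- c(
    cop_on = ev$cop_on - ev$reach_on,      # latencies relative to reach onset
    step_on = ev$step_on - ev$reach_on,
    step_off = ev$step_off - ev$reach_on,
    unlist(p$movement[1, setdiff(names(p$movement),
                                 c("prep_acc_sign_ap", "prep_acc_sign_ml"))]),
    vas_likely = p$meta$vas_likely,
    vas_concern = p$meta$vas_concern
  )
  tibble::tibble(
    participant = p$meta$participant, group = p$meta$group,
    condition = p$meta$condition, trial = p$meta$trial,
    metric = names(vals), value = unname(vals)
  )
}

qc_flags <- function(p) {
  flags <- character(0)
  if (is.finite(p$events$cop_on) && is.finite(p$events$step_on) &&
      p$events$cop_on > p$events$step_on)
    flags <- c(flags, "cop_after_step")
  if (!is.finite(p$events$cop_on)) flags <- c(flags, "no_cop_onset")
  tibble::tibble(
    participant = p$meta$participant, condition = p$meta$condition,
    trial = p$meta$trial, status = "ok",
    flags = paste(flags, collapse = ";")
  )
}

#' Run the full analysis over a synthetic cohort or a bundle directory
#'
#' Streams the cohort participant by participant (generating trials from the
#' spec, or reading bundles from `bundles_dir`), conditions every stream,
#' detects the event timeline, computes movement and EMG metrics, and runs
#' the mixed-ANOVA layer with family-wise alphas. A failing trial is flagged
#' in the QC table and excluded; the run continues.
#'
#' @param spec A [cohort_spec()] (used to generate trials unless
#'   `bundles_dir` is given).
#' @param bundles_dir Optional directory of trial bundles to analyze instead
#'   of generating.
#' @param filters A [filter_spec()].
#' @param onset An [onset_params()].
#' @param event_opts Named list of event-detector overrides (`k_sd`,
#'   `sustain_s`, `refine`, `unload_frac`, `load_frac`, ...).
#' @param pairs Muscle-pair table (default [default_muscle_pairs()]).
#' @param cci_method `"weighted"` or `"ratio"`.
#' @param posthoc Run Bonferroni post hocs for significant omnibus effects
#'   (default TRUE).
#' @return List with `cohort_metrics` (long tibble), `anova`, `posthoc`,
#'   `qc`, `n_analyzed`, `n_failed`.
#' @export
analyze_cohort <- function(spec = cohort_spec(), bundles_dir = NULL,
                           filters = filter_spec(), onset = onset_params(),
                           event_opts = list(), pairs = default_muscle_pairs(),
                           cci_method = "weighted", posthoc = TRUE) {
  if (is.null(bundles_dir)) {
    design <- cohort_design(spec)
    load_trial <- function(i) {
      generate_trial(spec, design$group_i[i], design$part_i[i],
                     design$cond_i[i], design$trial_i[i])$recording
    }
  } else {
    dirs <- list.dirs(bundles_dir, recursive = FALSE)
    if (!length(dirs)) abort_data(sprintf("no trial bundles under '%s'", bundles_dir))
    metas <- lapply(dirs, function(d)
      jsonlite::read_json(file.path(d, "meta.json"), simplifyVector = TRUE))
    design <- tibble::tibble(
      participant = vapply(metas, `[[`, "", "participant"),
      group = vapply(metas, `[[`, "", "group"),
      condition = vapply(metas, `[[`, "", "condition"),
      trial = vapply(metas, function(m) as.integer(m$trial), integer(1)),
      path = dirs)
    load_trial <- function(i) read_trial_bundle(design$path[i])
  }
  metric_rows <- list()
  qc_rows <- list()
  n_failed <- 0L
  for (pid in unique(design$participant)) {
    idx <- which(design$participant == pid)
    processed <- list()
    for (i in idx) {
      p <- tryCatch(
        process_trial(load_trial(i), filters = filters, event_opts = event_opts),
        error = function(e) e)
      if (inherits(p, "error")) {
        n_failed <- n_failed + 1L
        qc_rows[[length(qc_rows) + 1L]] <- tibble::tibble(
          participant = pid, condition = design$condition[i],
          trial = design$trial[i], status = "failed",
          flags = conditionMessage(p))
        next
      }
      processed[[length(processed) + 1L]] <- p
      qc_rows[[length(qc_rows) + 1L]] <- qc_flags(p)
      metric_rows[[length(metric_rows) + 1L]] <- trial_metric_rows(p)
    }
    if (length(processed))
      metric_rows[[length(metric_rows) + 1L]] <-
        participant_emg_metrics(processed, onset = onset, pairs = pairs,
                                cci_method = cci_method)
  }
  cohort_metrics <- dplyr::bind_rows(metric_rows)
  anova <- analyze_cohort_metrics(cohort_metrics)
  ph <- NULL
  if (posthoc && nrow(anova)) {
    sig <- anova[anova$significant &
                   anova$effect %in% c("condition", "condition:group"), ]
    ph_rows <- lapply(seq_len(nrow(sig)), function(i) {
      m <- sig$metric[i]
      dm <- aggregate_trials(
        cohort_metrics[cohort_metrics$metric == m, ], dv = "value")
      out <- posthoc_pairwise(dm, dv = "value", omnibus_p = sig$p[i],
                              alpha = sig$alpha_adj[i],
                              between = sig$effect[i] == "condition:group")
      out$metric <- m
      out$effect <- sig$effect[i]
      out
    })
    ph <- dplyr::bind_rows(ph_rows)
  }
  list(cohort_metrics = cohort_metrics, anova = anova, posthoc = ph,
       qc = dplyr::bind_rows(qc_rows),
       n_analyzed = nrow(design) - n_failed, n_failed = n_failed)
}

#' Load and validate a pipeline configuration
#'
#' A single YAML document (or equivalent named list) mirroring the
#' configuration surface: `cohort:` (fields of [cohort_spec()], with
#' `effects:`/`noise:` subsections), `filters:` ([filter_spec()] fields),
#' `onset:` ([onset_params()] fields), `events:` (detector thresholds),
#' `cci:` (`method`), and `seed`. Unknown keys are rejected.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated list with fully-built component specs.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_config(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  known <- c("cohort", "filters", "onset", "events", "cci", "seed", "out_dir",
             "bundles_dir", "write_bundles")
  bad <- setdiff(names(config), known)
  if (length(bad))
    abort_config(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  cohort_args <- config$cohort %||% list()
  if (!is.null(config$seed)) cohort_args$seed <- config$seed
  if (!is.null(cohort_args$effects))
    cohort_args$effects <- do.call(effect_config, cohort_args$effects)
  if (!is.null(cohort_args$noise))
    cohort_args$noise <- do.call(noise_config, cohort_args$noise)
  spec <- do.call(cohort_spec, cohort_args)
  list(
    spec = spec,
    filters = do.call(filter_spec, config$filters %||% list()),
    onset = do.call(onset_params, config$onset %||% list()),
    events = config$events %||% list(),
    cci_method = (config$cci %||% list())$method %||% "weighted",
    out_dir = config$out_dir,
    bundles_dir = config$bundles_dir,
    write_bundles = isTRUE(config$write_bundles)
  )
}

#' Run the configured pipeline end to end
#'
#' simulate (optional bundle writing) -> condition -> detect -> measure ->
#' analyze, writing `cohort_metrics.csv`, `anova_results.csv`,
#' `posthoc_results.csv`, `qc.csv` and `manifest.json` to the output
#' directory. Deterministic given config + seed.
#'
#' @param config Path to a YAML config, or a named list (see
#'   [pipeline_config()]).
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return The [analyze_cohort()] result, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) abort_config("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (cfg$write_bundles && is.null(cfg$bundles_dir)) {
    cfg$bundles_dir <- file.path(out_dir, "bundles")
    simulate_cohort_bundles(cfg$spec, cfg$bundles_dir)
  }
  res <- analyze_cohort(spec = cfg$spec, bundles_dir = cfg$bundles_dir,
                        filters = cfg$filters, onset = cfg$onset,
                        event_opts = cfg$events, cci_method = cfg$cci_method)
  readr::write_csv(res$cohort_metrics, file.path(out_dir, "cohort_metrics.csv"),
                   progress = FALSE)
  readr::write_csv(res$anova, file.path(out_dir, "anova_results.csv"),
                   progress = FALSE)
  if (!is.null(res$posthoc))
    readr::write_csv(res$posthoc, file.path(out_dir, "posthoc_results.csv"),
                     progress = FALSE)
  readr::write_csv(res$qc, file.path(out_dir, "qc.csv"), progress = FALSE)
  cfg_file <- tempfile(fileext = ".rds")
  saveRDS(cfg[c("spec", "filters", "onset", "events", "cci_method")], cfg_file,
          version = 2)
  manifest <- list(
    package_version = as.character(utils::packageVersion("postprime")),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = cfg$spec$seed,
    n_analyzed = res$n_analyzed, n_failed = res$n_failed,
    created = "run"
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
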