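# End-to-end orchestration: simulate -> connect -> detect -> measure ->
# compare, with a JSON run manifest. A single master seed determines
# every stochastic stage (generation, optimizer visit orders,
# bootstraps), so a re-run with the same config reproduces all numeric
# outputs byte-identically.

#' Default run configuration
#'
#' Analysis defaults follow the printed design: the five bands, 10-s
#' windows, the (gamma, omega) preset (1.1364, 0.5), a 100-iteration
#' detection ensemble, 10,000-draw group bootstraps and a 1,000 x 30
#' subject-level CoV bootstrap. Simulation sizes (subjects per group,
#' layers per session) are desk-scale stand-ins for the unavailable
#' recordings and are deliberately small; any override is echoed into
#' the run manifest.
#'
#' @param ... Named overrides of the defaults.
#' @return A `run_config` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    bands = default_bands(),
    analysis_band = "alpha",        # band used for detection/metrics
    window_seconds = 10,
    gamma = 1.1364,
    omega = 0.5,
    n_iterations = 100,
    bootstrap_n = 10000,
    cov_n_replicas = 1000,
    cov_replica_size = 30,
    threshold_grid = seq(0, 1, by = 0.01),
    min_pairs = 10,
    seed = 1,
    # simulation stage (desk-scale)
    n_per_group = 8,
    switch_rates = c(NC = 0.3, C = 0.1),
    contexts = c("social_media", "in_person"),
    n_nodes = 20,
    n_layers = 30,
    n_communities = 2,
    rate = 256,
    sim_band = c(8, 13),
    coupling = 0.9,
    noise_sd = 0.5,
    n_subjects_questionnaire = 132,
    questionnaire_marginals = list(no_change_after_sm = 75,
                                   no_change_after_inperson = 97,
                                   no_change_both = 56)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    param_error("unknown config keys: %s", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  # list-valued keys are replaced wholesale, not merged
  for (key in intersect(names(over), "questionnaire_marginals"))
    cfg[[key]] <- over[[key]]
  structure(cfg, class = "run_config", overrides = names(over))
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Run the full pipeline
#'
#' Stages: `simulate` (cohort with planted schedules + questionnaires),
#' `behavior` (change coding and transition statistics), `connect`
#' (wPLI stacks + temporal CoV), `detect` (detection ensemble per
#' session), `metrics` (ensemble-mean flexibility / allegiance /
#' intermittence), `compare` (bootstrap group comparisons, threshold
#' curve, CoV context comparison). Artifacts are delimited text and
#' JSON under `out_dir`.
#'
#' @param config A [default_run_config()] (or override list from it).
#' @param out_dir Output directory (created; must not be an existing
#'   non-empty run unless `overwrite`).
#' @param overwrite Allow writing into an existing directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         overwrite = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    param_error("output directory %s exists and is non-empty", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  timings <- list()
  clock <- function(stage, expr) {
    s <- Sys.time()
    r <- force(expr)
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), s,
                                                   units = "secs")), 3)
    r
  }

  ## simulate ---------------------------------------------------------
  say("stage simulate")
  cohort <- clock("simulate", simulate_cohort(
    n_per_group = config$n_per_group, switch_rates = config$switch_rates,
    contexts = config$contexts, n_nodes = config$n_nodes,
    n_layers = config$n_layers, n_communities = config$n_communities,
    rate = config$rate, window_seconds = config$window_seconds,
    band = config$sim_band, coupling = config$coupling,
    noise_sd = config$noise_sd, seed = config$seed))
  quest <- simulate_questionnaires(config$n_subjects_questionnaire,
                                   config$questionnaire_marginals,
                                   seed = derive_seed(config$seed, 999L))
  dir.create(file.path(out_dir, "simulate"), showWarnings = FALSE)
  manifest_sessions <- do.call(rbind, lapply(cohort$sessions, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               context = s$context, stringsAsFactors = FALSE)))
  write.csv(manifest_sessions,
            file.path(out_dir, "simulate", "cohort_manifest.csv"),
            row.names = FALSE)
  for (s in cohort$sessions) {
    base <- sprintf("%s_%s", s$subject_id, s$context)
    utils::write.table(s$schedule$labels,
                       file.path(out_dir, "simulate",
                                 paste0(base, "_truth_labels.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  write.csv(quest, file.path(out_dir, "simulate", "questionnaires.csv"),
            row.names = FALSE)

  ## behavior ---------------------------------------------------------
  say("stage behavior")
  coding <- clock("behavior", aggregate_changes(quest))
  trans <- transition_statistics(coding)
  dir.create(file.path(out_dir, "behavior"), showWarnings = FALSE)
  write.csv(coding, file.path(out_dir, "behavior", "coding.csv"),
            row.names = FALSE)
  write_json(trans, file.path(out_dir, "behavior", "transitions.json"))

  ## connect ----------------------------------------------------------
  say("stage connect (wPLI, %d sessions)", length(cohort$sessions))
  band <- config$bands[[config$analysis_band]]
  connect <- clock("connect", lapply(cohort$sessions, function(s) {
    series <- connectivity_series(s$recording, list(band),
                                  config$window_seconds)[[1]]
    list(session = s, series = series, cov = temporal_cov(series))
  }))

  ## detect + metrics -------------------------------------------------
  say("stage detect (%d iterations/session)", config$n_iterations)
  detect <- clock("detect", lapply(seq_along(connect), function(i) {
    cs <- connect[[i]]
    params <- multilayer_params(config$gamma, config$omega,
                                config$n_iterations,
                                seed = derive_seed(config$seed, 5000L + i))
    ens <- repeat_detection(cs$series, params)
    list(ensemble = ens,
         flex = ensemble_mean(lapply(ens, function(e) flexibility(e)$xi)),
         alleg = ensemble_mean(lapply(ens, allegiance)),
         inter = ensemble_mean(lapply(ens, intermittence)))
  }))
  dir.create(file.path(out_dir, "metrics"), showWarnings = FALSE)
  flex_tab <- do.call(rbind, lapply(seq_along(detect), function(i) {
    s <- connect[[i]]$session
    data.frame(subject_id = s$subject_id, group = s$group,
               context = s$context, sensor = names(detect[[i]]$flex),
               flexibility = unname(detect[[i]]$flex),
               stringsAsFactors = FALSE)
  }))
  write.csv(flex_tab, file.path(out_dir, "metrics", "flexibility.csv"),
            row.names = FALSE)
  pair_tab <- do.call(rbind, lapply(seq_along(detect), function(i) {
    s <- connect[[i]]$session
    tab <- pair_metric_table(detect[[i]]$alleg, detect[[i]]$inter)
    tab$subject_id <- s$subject_id
    tab$group <- s$group
    tab$context <- s$context
    tab
  }))
  write.csv(pair_tab, file.path(out_dir, "metrics", "pair_metrics.csv"),
            row.names = FALSE)
  cov_tab <- do.call(rbind, lapply(connect, function(cs)
    data.frame(subject_id = cs$session$subject_id,
               group = cs$session$group, context = cs$session$context,
               value = cs$cov$session_mean, stringsAsFactors = FALSE)))
  write.csv(cov_tab, file.path(out_dir, "metrics", "session_cov.csv"),
            row.names = FALSE)

  ## compare ----------------------------------------------------------
  say("stage compare")
  stats_dir <- file.path(out_dir, "stats")
  dir.create(stats_dir, showWarnings = FALSE)
  compare <- clock("compare", {
    sm <- flex_tab[flex_tab$context == config$contexts[1], ]
    flex_wide <- do.call(rbind, lapply(split(sm, sm$subject_id), function(d)
      setNames(d$flexibility, d$sensor)[montage_subset(sm$sensor)]))
    grp <- vapply(split(sm, sm$subject_id),
                  function(d) d$group[1], "")
    # map group names of the cohort (NC/C) directly
    fc <- flexibility_comparison(flex_wide, grp, n = config$bootstrap_n,
                                 seed = derive_seed(config$seed, 7001L))
    pc <- pair_tab[pair_tab$context == config$contexts[1], ]
    curve <- intermittence_curve(pc, thresholds = config$threshold_grid,
                                 n = config$bootstrap_n,
                                 seed = derive_seed(config$seed, 7002L),
                                 min_pairs = config$min_pairs)
    covc <- cov_comparison(cov_tab, n_replicas = config$cov_n_replicas,
                           replica_size = config$cov_replica_size,
                           seed = derive_seed(config$seed, 7003L))
    list(flexibility = fc, curve = curve, cov = covc)
  })
  write.csv(compare$flexibility,
            file.path(stats_dir, "flexibility_comparison.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(compare$curve),
            file.path(stats_dir, "intermittence_curve.csv"),
            row.names = FALSE)
  write.csv(compare$cov, file.path(stats_dir, "cov_comparison.csv"),
            row.names = FALSE)
  write_json(list(significant_fraction =
                    attr(compare$curve, "significant_fraction"),
                  band = band$name),
             file.path(stats_dir, "summary.json"))

  ## manifest ---------------------------------------------------------
  manifest <- list(
    package = "phasecomm",
    version = as.character(utils::packageVersion("phasecomm")),
    seed = config$seed,
    config = config_echo(config),
    overrides = attr(config, "overrides"),
    stage_seconds = timings,
    total_seconds = round(as.numeric(difftime(Sys.time(), t0,
                                              units = "secs")), 3)
  )
  write_json(manifest, file.path(out_dir, "manifest.json"))
  say("done in %.1f s", manifest$total_seconds)
  invisible(list(cohort = cohort, coding = coding, transitions = trans,
                 connect = connect, detect = detect, compare = compare,
                 manifest = manifest))
}

# serializable echo of a config (band objects flattened)
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$bands <- lapply(cfg$bands, function(b)
    list(name = b$name, low = b$low, high = b$high))
  cfg
}

montage_subset <- function(sensors) unique(sensors)

#' Validate pipeline input files
#'
#' Checks recording text files (readable, positive rate, unique labels,
#' montage membership, finite samples) and questionnaire tables
#' (required columns). Unreadable files and non-positive rates are
#' fatal; unknown or missing montage labels are warnings.
#'
#' @param recording_paths Character vector of recording TSV paths.
#' @param questionnaire_paths Character vector of questionnaire CSV
#'   paths.
#' @return Data frame of issues (`level` "fatal"/"warning", `path`,
#'   `message`); zero rows when everything is well-formed.
#' @export
validate_inputs <- function(recording_paths = character(),
                            questionnaire_paths = character()) {
  issues <- list()
  add <- function(level, path, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      level = level, path = path, message = msg, stringsAsFactors = FALSE)
  for (p in recording_paths) {
    if (!file.exists(p)) { add("fatal", p, "file not found"); next }
    rec <- tryCatch(read_eeg_text(p), error = function(e) e)
    if (inherits(rec, "error")) {
      add("fatal", p, conditionMessage(rec)); next
    }
    if (rec$rate <= 0) add("fatal", p, "non-positive sampling rate")
    unknown <- setdiff(rec$labels, montage_1020())
    if (length(unknown))
      add("warning", p, paste("labels outside 10-20 montage:",
                              paste(unknown, collapse = ", ")))
    missing <- setdiff(montage_1020(), rec$labels)
    if (length(missing) && length(unknown) == 0)
      add("warning", p, paste("montage sensors missing:",
                              paste(missing, collapse = ", ")))
  }
  need <- c("subject_id", "timepoint", unlist(scenario_fields))
  for (p in questionnaire_paths) {
    if (!file.exists(p)) { add("fatal", p, "file not found"); next }
    tab <- tryCatch(utils::read.csv(p, nrows = 5), error = function(e) e)
    if (inherits(tab, "error")) {
      add("fatal", p, conditionMessage(tab)); next
    }
    miss <- setdiff(need, names(tab))
    if (length(miss))
      add("fatal", p, paste("missing columns:",
                            paste(miss, collapse = ", ")))
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(level = character(), path = character(),
                  message = character(), stringsAsFactors = FALSE)
}
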