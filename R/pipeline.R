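# End-to-end orchestration: simulate -> preprocess -> TRP -> microstates ->
# statistics, from one config and one master seed, with a JSON report.

#' Default pipeline configuration
#'
#' @param n_participants Participants to simulate.
#' @param seed Master seed (every random stage derives a named stream from it).
#' @param ... Overrides for any configuration entry (study entries go in
#'   `study`).
#' @return Named list: `study` (a [study_config()]), `bands` (TRP bands, Hz),
#'   `microstate_band`, `epoch_seconds`, `k_range`, `restarts`, `group_k`,
#'   `n_perm`, `select_k_scope` (`"first_run"`, `"all"` or `"none"`), and
#'   stage toggles `run_trp`, `run_microstates`, `run_stats`.
#' @export
pipeline_config <- function(n_participants = 4, seed = 1L, ...) {
  cfg <- list(
    study = study_config(n_participants = n_participants),
    seed = seed,
    bands = list(lower_alpha = c(8, 10), upper_alpha = c(10, 12)),
    microstate_band = c(1, 30),
    epoch_seconds = 2,
    k_range = 1:10,
    restarts = 100L,
    group_k = 6L,
    n_perm = 5000L,
    select_k_scope = "first_run",
    run_trp = TRUE,
    run_microstates = TRUE,
    run_stats = TRUE
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "study") cfg$study <- utils::modifyList(cfg$study, dots$study)
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()] list.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the config list.
#' @export
write_pipeline_config <- function(config, path) {
  out <- config
  out$study$condition_coverage_bias <-
    apply(config$study$condition_coverage_bias, 1L, as.list, simplify = FALSE)
  # yaml drops the names of named atomic vectors; write them as maps
  for (nm in c("time_means", "time_sds"))
    out$study[[nm]] <- as.list(config$study[[nm]])
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  st <- raw$study %||% list()
  # YAML maps come back as lists; restore the vector/matrix shapes
  for (nm in c("time_means", "time_sds")) {
    if (!is.null(st[[nm]])) st[[nm]] <- unlist(st[[nm]])
  }
  for (nm in c("time_range")) {
    if (!is.null(st[[nm]])) st[[nm]] <- as.numeric(unlist(st[[nm]]))
  }
  if (!is.null(st$condition_coverage_bias)) {
    st$condition_coverage_bias <-
      do.call(rbind, lapply(st$condition_coverage_bias, unlist))
  }
  cfg$study <- utils::modifyList(cfg$study, st)
  for (nm in setdiff(names(raw), "study")) {
    v <- raw[[nm]]
    cfg[[nm]] <- if (nm %in% c("bands")) lapply(v, unlist)
                 else if (is.list(v)) unlist(v) else v
  }
  cfg$k_range <- as.integer(cfg$k_range)
  cfg
}

# Filter + re-reference + epoch all recordings of a study in one band.
.study_epochs <- function(study, band, epoch_seconds = 2) {
  lapply(study$recordings, function(rec)
    epoch_and_reject(rereference_average(bandpass_filter(rec, band)),
                     study$montage, epoch_seconds = epoch_seconds))
}

#' Microstate stage: per-run fits, model selection, hierarchy, parameters
#'
#' @param study An `eeg_study`.
#' @param config A [pipeline_config()].
#' @return List: `epochs` (1-30 Hz epochs per recording), `run_models`,
#'   `select_k` (per selected run: `best_k` and CV curve), `hierarchy`,
#'   `global` (lettered global model), `parameters` (data frame per
#'   participant/condition/run/class), `pc_templates` (aligned
#'   participant-by-condition templates, for TANOVA).
#' @export
stage_microstates <- function(study, config = pipeline_config()) {
  seed <- config$seed
  epochs <- .study_epochs(study, config$microstate_band, config$epoch_seconds)
  peak_sets <- lapply(epochs, gfp_peak_maps)

  run_models <- vector("list", length(peak_sets))
  for (i in seq_along(peak_sets)) {
    r <- study$index[i, ]
    run_models[[i]] <- fit_modified_kmeans(
      peak_sets[[i]], config$group_k, restarts = config$restarts,
      seed = seed_stream(seed, sprintf("fit/p%d/%s/r%d", r$participant,
                                       r$condition, r$run)))
  }

  sel <- switch(config$select_k_scope,
                none = integer(0),
                first_run = 1L,
                all = seq_along(peak_sets),
                stop("unknown select_k_scope: ", config$select_k_scope))
  select_res <- lapply(sel, function(i) {
    r <- study$index[i, ]
    s <- select_k(peak_sets[[i]], config$k_range, config$restarts,
                  seed = seed_stream(seed, sprintf("selectk/p%d/%s/r%d",
                                                   r$participant, r$condition,
                                                   r$run)))
    list(participant = r$participant, condition = r$condition, run = r$run,
         best_k = s$best_k, cv = s$cv)
  })

  hier <- aggregate_hierarchy(run_models, study$index)
  global <- assign_class_letters(hier$global)

  params <- list()
  for (i in seq_along(epochs)) {
    seg <- backfit_labels(epochs[[i]], global)
    pp <- compute_parameters(seg)
    r <- study$index[i, ]
    pp$participant <- r$participant; pp$condition <- r$condition; pp$run <- r$run
    params[[i]] <- pp
  }
  params <- do.call(rbind, params)
  params$letter <- global$labels[params$class]

  # participant x condition templates aligned to the global model
  perms <- .permutations(global$K)
  pc_templates <- lapply(hier$participant_condition, function(m) {
    b <- .best_permutation(global$templates, m$templates, perms)
    sweep(m$templates[, b$perm, drop = FALSE], 2L, b$signs, "*")
  })

  list(epochs = epochs, run_models = run_models, select_k = select_res,
       hierarchy = hier, global = global, parameters = params,
       pc_templates = pc_templates)
}

#' TRP stage: band power and regional log power changes per band
#'
#' @inheritParams stage_microstates
#' @return List per band: `trp` (channel table) and `regions`.
#' @export
stage_trp <- function(study, config = pipeline_config()) {
  out <- list()
  for (b in names(config$bands)) {
    pow <- study_band_power(study, config$bands[[b]],
                            epoch_seconds = config$epoch_seconds)
    trp <- compute_trp(pow)
    out[[b]] <- list(trp = trp, regions = aggregate_regions(trp, study$montage))
  }
  out
}

#' Statistics stage
#'
#' Runs the study's statistical families on pipeline outputs: RM-ANOVA on
#' normalized completion times (condition factor), 3 x 5 x 2 RM-ANOVA
#' (condition x area x hemisphere) per TRP band, 4 x K RM-ANOVA on microstate
#' coverage and duration, and the two-factor plus class-wise TANOVAs on
#' participant-by-condition topographies.
#'
#' @param study An `eeg_study`.
#' @param trp_res [stage_trp()] output (or `NULL` to skip).
#' @param ms_res [stage_microstates()] output (or `NULL` to skip).
#' @param config A [pipeline_config()].
#' @return Named list of result data frames.
#' @export
stage_stats <- function(study, trp_res, ms_res, config = pipeline_config()) {
  seed <- config$seed
  out <- list()

  tn <- normalize_times(study$times, family = "all", average = TRUE)
  out$times_anova <- rm_anova_gg(tn, within = "condition", value = "normalized")
  out$times_raw_anova <- rm_anova_gg(
    stats::aggregate(seconds ~ participant + condition, study$times, mean),
    within = "condition", value = "seconds")

  if (!is.null(trp_res)) {
    out$trp_anova <- do.call(rbind, lapply(names(trp_res), function(b) {
      d <- trp_res[[b]]$regions
      a <- rm_anova_gg(d, within = c("condition", "area", "hemisphere"),
                       value = "trp")
      a$band <- b
      a
    }))
  }

  if (!is.null(ms_res)) {
    pm_cov <- stats::aggregate(coverage ~ participant + condition + class,
                               data = ms_res$parameters, FUN = mean)
    out$coverage_anova <- rm_anova_gg(pm_cov, within = c("condition", "class"),
                                      value = "coverage")
    pm_dur <- stats::aggregate(duration_ms ~ participant + condition + class,
                               data = ms_res$parameters, FUN = mean)
    out$duration_anova <- tryCatch(
      rm_anova_gg(pm_dur, within = c("condition", "class"),
                  value = "duration_ms"),
      error = function(e) {
        warning("duration RM-ANOVA skipped: ", conditionMessage(e))
        NULL
      })

    # topography TANOVAs on aligned participant x condition templates
    pcs <- ms_res$pc_templates
    ids <- do.call(rbind, strsplit(names(pcs), "/"))
    participants <- unique(ids[, 1])
    conds <- intersect(condition_levels(), unique(ids[, 2]))
    K <- ms_res$global$K
    nch <- nrow(ms_res$global$templates)
    arr <- array(NA_real_, c(length(participants), length(conds), K, nch))
    for (i in seq_along(pcs)) {
      p <- match(ids[i, 1], participants); cz <- match(ids[i, 2], conds)
      arr[p, cz, , ] <- t(pcs[[i]])
    }
    out$tanova <- tanova(arr, c("condition", "class"), n_perm = config$n_perm,
                         seed = seed_stream(seed, "tanova/two_factor"))
    cw <- lapply(seq_len(K), function(k) {
      r <- tanova(arr[, , k, ], "condition", n_perm = config$n_perm,
                  seed = seed_stream(seed, paste0("tanova/class", k)))
      r$effect <- paste0("condition | class ", ms_res$global$labels[k])
      r
    })
    out$tanova_classwise <- do.call(rbind, cw)
  }
  out
}

#' Run the full pipeline and write a report directory
#'
#' Executes simulate (or load) -> preprocess -> TRP -> microstates -> stats
#' and writes stage CSVs plus `report.json`, stamped with the configuration
#' hash and seed. Identical config and seed produce a byte-identical
#' `report.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param study Optional pre-built `eeg_study` (skips simulation).
#' @param input_dir Optional study directory to load instead of simulating.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         study = NULL, input_dir = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, ...) {
    message(sprintf("[eegms] %-12s %6.1fs %s", stage,
                    proc.time()[["elapsed"]] - t0, sprintf(...)))
  }
  if (is.null(study)) {
    study <- if (!is.null(input_dir)) read_study(input_dir)
             else generate_study(config$study, seed = config$seed)
  }
  log_stage("simulate", "%d recordings, %d participants",
            length(study$recordings), length(unique(study$index$participant)))

  trp_res <- NULL
  if (isTRUE(config$run_trp)) {
    trp_res <- stage_trp(study, config)
    for (b in names(trp_res)) {
      utils::write.csv(trp_res[[b]]$trp,
                       file.path(out_dir, paste0("trp_", b, ".csv")),
                       row.names = FALSE)
      utils::write.csv(trp_res[[b]]$regions,
                       file.path(out_dir, paste0("trp_regions_", b, ".csv")),
                       row.names = FALSE)
    }
    log_stage("trp", "%d bands", length(trp_res))
  }

  ms_res <- NULL
  if (isTRUE(config$run_microstates)) {
    ms_res <- stage_microstates(study, config)
    utils::write.csv(ms_res$parameters,
                     file.path(out_dir, "microstate_parameters.csv"),
                     row.names = FALSE)
    tplout <- data.frame(channel = study$montage$channel,
                         ms_res$global$templates)
    names(tplout)[-1] <- ms_res$global$labels
    utils::write.csv(tplout, file.path(out_dir, "global_templates.csv"),
                     row.names = FALSE)
    log_stage("microstates", "global K = %d", ms_res$global$K)
  }

  stats_res <- NULL
  if (isTRUE(config$run_stats)) {
    stats_res <- stage_stats(study, trp_res, ms_res, config)
    for (nm in names(stats_res))
      utils::write.csv(stats_res[[nm]],
                       file.path(out_dir, paste0("stats_", nm, ".csv")),
                       row.names = FALSE)
    log_stage("stats", "%d result tables", length(stats_res))
  }

  report <- list(
    config_hash = content_hash(config),
    seed = config$seed,
    n_participants = length(unique(study$index$participant)),
    n_recordings = length(study$recordings),
    selected_k = if (!is.null(ms_res)) lapply(ms_res$select_k, function(s)
      list(participant = s$participant, condition = s$condition, run = s$run,
           best_k = s$best_k, cv = as.list(s$cv))) else NULL,
    global_templates = if (!is.null(ms_res)) {
      m <- ms_res$global$templates
      colnames(m) <- ms_res$global$labels
      unname(as.data.frame(m))
    } else NULL,
    global_labels = if (!is.null(ms_res)) ms_res$global$labels else NULL,
    parameters = if (!is.null(ms_res)) ms_res$parameters else NULL,
    trp_regions = if (!is.null(trp_res)) lapply(trp_res, function(b)
      stats::aggregate(trp ~ condition + area + hemisphere, b$regions, mean))
      else NULL,
    stats = stats_res,
    times_mean_s = as.list(tapply(study$times$seconds, study$times$condition,
                                  mean))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  log_stage("report", "written to %s", file.path(out_dir, "report.json"))
  invisible(report)
}
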