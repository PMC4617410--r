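# End-to-end orchestration: a declarative run configuration, subcommand
# pipelines writing flat TSV/JSON artifacts, and seed/provenance logging.

#' Build a run configuration
#'
#' Collects every tunable of the analysis tracks with the conventional
#' defaults: 256 s high-pass, Wiener deconvolution noise level 0.02,
#' B = 1000 bootstraps with 50 voxel-subsampling repeats, k = 15 voxels and
#' xi = 0.2 for the discriminant analyses, k = 5 voxels and 1-20 states for
#' the HMM track. Every random operation of a pipeline consumes a seed
#' derived deterministically from `seed`.
#'
#' @param data,events,out_dir input time-series path, events path, output
#'   directory.
#' @param tr sampling interval (s).
#' @param highpass_cutoff_s high-pass cutoff (s).
#' @param deconvolve run Wiener deconvolution?
#' @param noise_level Wiener regularization.
#' @param B bootstrap replicates.
#' @param repeats voxel-subsampling repeats.
#' @param scheme bootstrap scheme for the stats track.
#' @param min_shift minimum cycle shift (volumes).
#' @param n_subsample_voxels subset size for [subsampled_statistic()]
#'   (`NULL` = all voxels, no subsampling).
#' @param grouping grouping scheme name for the contrast track.
#' @param lda_k,lda_xi voxel count and shrinkage for the LDA track.
#' @param hmm_k,hmm_m_range,hmm_restarts,hmm_tol voxel count, state sweep
#'   and EM controls for the HMM track.
#' @param lags lag/lead grid (volumes).
#' @param seed master seed.
#' @param simulate list of overrides for the `simulate` subcommand
#'   (`n_participants`, plus [task_design()] / [generator_config()]
#'   arguments).
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(data = NULL, events = NULL, out_dir = "stageseg-out",
                       tr = 1.8, highpass_cutoff_s = 256,
                       deconvolve = FALSE, noise_level = 0.02,
                       B = 1000, repeats = 50, scheme = "block", min_shift = 3,
                       n_subsample_voxels = NULL,
                       grouping = "memory_load", lda_k = 15, lda_xi = 0.2,
                       hmm_k = 5, hmm_m_range = 1:20, hmm_restarts = 5,
                       hmm_tol = 1e-5, lags = -5:5, seed = 1,
                       simulate = list()) {
  cfg <- list(
    data = data, events = events, out_dir = out_dir, tr = tr,
    highpass_cutoff_s = highpass_cutoff_s, deconvolve = deconvolve,
    noise_level = noise_level, B = B, repeats = repeats, scheme = scheme,
    min_shift = min_shift, n_subsample_voxels = n_subsample_voxels,
    grouping = grouping, lda_k = lda_k, lda_xi = lda_xi, hmm_k = hmm_k,
    hmm_m_range = hmm_m_range, hmm_restarts = hmm_restarts,
    hmm_tol = hmm_tol, lags = lags, seed = seed, simulate = simulate
  )
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round trip: a written configuration reloads to an equal object.
#'
#' @param path YAML file path.
#' @param config a [run_config()].
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$hmm_m_range <- as.integer(raw$hmm_m_range)
  raw$lags <- as.integer(raw$lags)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

pipeline_log <- function(out_dir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = file.path(out_dir, "stageseg.log"), append = TRUE)
}

write_artifact_json <- function(x, out_dir, name, config) {
  x$master_seed <- config$seed
  x$config_hash <- config_hash(config)
  jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

write_artifact_tsv <- function(df, out_dir, name, config) {
  df$master_seed <- config$seed
  df$config_hash <- config_hash(config)
  readr::write_tsv(df, file.path(out_dir, name))
}

load_run_inputs <- function(config) {
  if (is.null(config$data) || is.null(config$events)) {
    abort("Config must provide `data` and `events` paths (run `simulate` first).")
  }
  bold <- read_roi_timeseries(config$data)
  labels <- read_events(config$events, tr = config$tr, n_volumes = nrow(bold))
  list(bold = bold, labels = labels)
}

# Preprocessing applied before the supervised/unsupervised tracks.
preprocess_for_analysis <- function(bold, labels, config) {
  x <- standardize_detrend_filter(bold, tr = config$tr,
                                  highpass_cutoff_s = config$highpass_cutoff_s)
  if (isTRUE(config$deconvolve)) {
    x <- deconvolve_hrf(x, tr = config$tr, noise_level = config$noise_level)
  }
  x <- subtract_control_means(x, labels)
  ex <- exclude_error_timepoints(x, labels)
  task <- ex$labels$label %in% task_stage_labels()
  list(
    bold = ex$bold[task, , drop = FALSE],
    labels = ex$labels[task, , drop = FALSE],
    bold_full = ex$bold, labels_full = ex$labels
  )
}

#' Run an analysis pipeline
#'
#' Subcommands:
#' * `simulate` — generate a synthetic participant (labels + BOLD) into
#'   `out_dir` and point the config at it;
#' * `preprocess` — write the preprocessed matrix and per-volume labels;
#' * `stats` — voxel-subsampled MANOVA statistics with pooled bootstrap;
#' * `lag` — lag/lead profile of T2;
#' * `errors` — per-trial T2 with error-trial flags;
#' * `contrast` — grouping contrast (Mahalanobis, block bootstrap);
#' * `lda` — k-medoids + Fisher LDA projections for the grouping;
#' * `hmm` — k-medoids, AIC state-count selection, Viterbi, Matching Index
#'   with significance;
#' * `all` — every analysis track in sequence.
#'
#' Every artifact embeds the master seed and a hash of the configuration;
#' re-running with an identical configuration reproduces outputs.
#'
#' @param subcommand one of the names above.
#' @param config a [run_config()].
#' @return (invisibly) a named list of artifact paths.
#' @export
run_pipeline <- function(subcommand, config) {
  subcommands <- c("simulate", "preprocess", "stats", "lag", "errors",
                   "contrast", "lda", "hmm", "all")
  if (!subcommand %in% subcommands) {
    abort(sprintf("Unknown subcommand '%s'. Use one of: %s.",
                  subcommand, paste(subcommands, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  pipeline_log(config$out_dir, sprintf(
    "stageseg %s | subcommand=%s seed=%d config=%s",
    as.character(utils::packageVersion("stageseg")), subcommand, config$seed,
    config_hash(config)
  ))

  if (subcommand == "simulate") {
    sim <- config$simulate
    design <- do.call(task_design, c(
      list(tr = config$tr),
      sim[intersect(names(sim), names(formals(task_design)))]
    ))
    gen <- do.call(generator_config,
                   sim[intersect(names(sim), names(formals(generator_config)))])
    labels <- simulate_task_labels(design, seed = derive_seed(config$seed, "labels"))
    bold <- simulate_bold(labels, gen, seed = derive_seed(config$seed, "bold"))
    data_path <- file.path(config$out_dir, "bold.tsv")
    events_path <- file.path(config$out_dir, "events.tsv")
    write_roi_timeseries(bold, data_path)
    write_events(labels, events_path, tr = config$tr)
    config$data <- data_path
    config$events <- events_path
    write_run_config(config, file.path(config$out_dir, "config.yaml"))
    pipeline_log(config$out_dir, sprintf(
      "simulated %d volumes x %d voxels", nrow(bold), ncol(bold)))
    return(invisible(list(data = data_path, events = events_path,
                          config = file.path(config$out_dir, "config.yaml"))))
  }

  inputs <- load_run_inputs(config)
  prep <- preprocess_for_analysis(inputs$bold, inputs$labels, config)

  run_one <- function(what) {
    switch(what,
      preprocess = {
        p1 <- file.path(config$out_dir, "preprocessed.tsv")
        write_roi_timeseries(prep$bold_full, p1)
        write_artifact_tsv(prep$labels_full, config$out_dir, "labels.tsv", config)
        pipeline_log(config$out_dir, sprintf(
          "preprocessed %d volumes (%d task volumes)",
          nrow(prep$bold_full), nrow(prep$bold)))
        list(preprocessed = p1)
      },
      stats = {
        n_sub <- config$n_subsample_voxels %||% ncol(prep$bold)
        sr <- subsampled_statistic(
          prep$bold, prep$labels, statistic = "t2",
          n_voxels = min(n_sub, ncol(prep$bold)), repeats = config$repeats,
          B = config$B, scheme = config$scheme,
          seed = derive_seed(config$seed, "stats"),
          min_shift = config$min_shift
        )
        write_artifact_tsv(tidy(sr), config$out_dir, "stats.tsv", config)
        readr::write_tsv(tibble::tibble(bootstrap_value = sr$bootstrap_values),
                         file.path(config$out_dir, "stats_bootstrap.tsv"))
        pipeline_log(config$out_dir, sprintf(
          "stats: normalized T2 = %.3f, p = %.4g (pooled bootstrap n = %d)",
          sr$normalized, sr$p_value, length(sr$bootstrap_values)))
        list(stats = file.path(config$out_dir, "stats.tsv"))
      },
      lag = {
        lp <- lag_profile(prep$bold_full, prep$labels_full, lags = config$lags)
        out <- tibble::as_tibble(lp)
        out$peak_lag <- peak_lag(lp)
        write_artifact_tsv(out, config$out_dir, "lag_profile.tsv", config)
        pipeline_log(config$out_dir, sprintf("lag: peak at %d", peak_lag(lp)))
        list(lag = file.path(config$out_dir, "lag_profile.tsv"))
      },
      errors = {
        pt <- per_trial_statistics(prep$bold, prep$labels)
        write_artifact_tsv(pt, config$out_dir, "per_trial_t2.tsv", config)
        pipeline_log(config$out_dir, sprintf(
          "errors: %d trials (%d error)", nrow(pt), sum(pt$error_trial)))
        list(errors = file.path(config$out_dir, "per_trial_t2.tsv"))
      },
      contrast = {
        grp <- choice_grouping(prep$labels, scheme = config$grouping,
                               seed = derive_seed(config$seed, "grouping"))
        ct <- grouping_contrast(prep$bold, prep$labels, grp, B = config$B,
                                seed = derive_seed(config$seed, "contrast"))
        write_artifact_tsv(tidy(ct), config$out_dir, "contrast.tsv", config)
        pipeline_log(config$out_dir, sprintf(
          "contrast (%s): normalized MD = %.3f, p = %.4g",
          config$grouping, ct$normalized, ct$p_value))
        list(contrast = file.path(config$out_dir, "contrast.tsv"))
      },
      lda = {
        vox <- kmedoids_select(prep$bold, k = min(config$lda_k, ncol(prep$bold)))
        grp <- choice_grouping(prep$labels, scheme = config$grouping,
                               seed = derive_seed(config$seed, "grouping"))
        gr <- grouping_rows(prep$labels, grp[grp$instance == 1, ])
        xg <- as_bold_matrix(prep$bold)[gr$row, vox, drop = FALSE]
        fit <- fit_fisher_lda(xg, gr$class, xi = config$lda_xi)
        pooled <- project_and_pool(list(fit),
                                   list(list(bold = xg, label = gr$class)))
        write_artifact_tsv(pooled, config$out_dir, "lda_projections.tsv", config)
        pipeline_log(config$out_dir, sprintf(
          "lda: %d voxels, class separation %.3f (z)",
          length(vox),
          abs(diff(tapply(pooled$projection_z, pooled$class, mean)))))
        list(lda = file.path(config$out_dir, "lda_projections.tsv"))
      },
      hmm = {
        vox <- kmedoids_select(prep$bold_full, k = min(config$hmm_k, ncol(prep$bold_full)))
        obs <- as_bold_matrix(prep$bold_full)[, vox, drop = FALSE]
        selection <- model_selection(
          obs, m_range = config$hmm_m_range, trial = prep$labels_full,
          n_restarts = config$hmm_restarts, tol = config$hmm_tol,
          seed = derive_seed(config$seed, "hmm")
        )
        model <- selection$best_model
        states <- viterbi_decode(model, obs, trial = prep$labels_full)
        mres <- matching_significance(
          states, prep$labels_full, B = config$B,
          min_shift = config$min_shift,
          seed = derive_seed(config$seed, "matching")
        )
        write_artifact_json(list(
          A = model$A, pi = model$pi, means = model$means, vars = model$vars,
          logLik = model$loglik, AIC = stats::AIC(model),
          selected_m = selection$selected_m,
          aic_curve = selection$curve,
          matching_index = mres$matching_index,
          p_values = mres$p_values
        ), config$out_dir, "hmm.json", config)
        write_artifact_tsv(
          tibble::tibble(
            volume = prep$labels_full$volume, state = states,
            mapped_class = unname(mres$state_to_class[as.character(states)]),
            label = prep$labels_full$label
          ),
          config$out_dir, "viterbi.tsv", config
        )
        pipeline_log(config$out_dir, sprintf(
          "hmm: selected m = %d, Matching Index = %.1f%%",
          selection$selected_m, mres$matching_index))
        list(hmm = file.path(config$out_dir, "hmm.json"))
      }
    )
  }

  todo <- if (subcommand == "all") {
    c("preprocess", "stats", "lag", "errors", "contrast", "lda", "hmm")
  } else {
    subcommand
  }
  for (what in todo) artifacts <- c(artifacts, run_one(what))
  invisible(artifacts)
}
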