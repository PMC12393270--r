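# End-to-end orchestration: simulate (or ingest) -> fit & compare ->
# behavioral summaries -> latent-state analyses -> hierarchical group
# comparison, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' A small demonstration configuration: a 4 + 4 subject cohort, two
#' sessions of 200 trials each, standard-vs-avgRPE model comparison and
#' all analyses enabled at desk scale.
#'
#' @return Named list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_a = 4, n_b = 4, sessions = 2, trials_per_session = 200,
                  model_id = "asym5", invalid_rate = 0.005),
    task = list(),
    fit = list(models = c("standard", "avgrpe"), n_restarts = 10),
    latent = list(ksweep = TRUE, correlation = TRUE, mediansplit = TRUE),
    hierarchical = list(enabled = TRUE, chains = 2, draws = 1000,
                        warmup = 500)
  )
}

validate_pipeline_config <- function(config) {
  config <- modifyList(default_pipeline_config(), config)
  if (!is.numeric(config$seed)) stop("config$seed must be an integer")
  bad <- setdiff(config$fit$models, model_ids())
  if (length(bad)) stop("unknown model id(s) in config: ",
                        paste(bad, collapse = ", "))
  if (!config$cohort$model_id %in% model_ids()) {
    stop("unknown cohort model id: ", config$cohort$model_id)
  }
  config
}

#' Latent traces for every session from per-session fits
#'
#' Evaluates the model's latent trace for each session at that session's
#' fitted parameters and returns a single trace table row-aligned with the
#' valid trials of `trials` (sessions must be contiguous in the table).
#'
#' @param trials trial table.
#' @param fits data.frame from [fit_sessions()] for `model_id`.
#' @param model_id model identifier.
#' @return Data frame of latent columns, one row per valid trial.
#' @export
latent_traces <- function(trials, fits, model_id) {
  info <- model_info(model_id)
  has_subj <- "subject_id" %in% names(trials)
  key <- if (has_subj) paste(trials$subject_id, trials$session_id, sep = "\r")
         else as.character(trials$session_id)
  fit_key <- if (has_subj && "subject_id" %in% names(fits)) {
    paste(fits$subject_id, fits$session_id, sep = "\r")
  } else as.character(fits$session_id)
  out <- lapply(unique(key), function(k) {
    i <- match(k, fit_key)
    if (is.na(i)) stop("no fit for session key ", k)
    params <- as.numeric(fits[i, info$par_names])
    session_nll(trials[key == k, , drop = FALSE], model_id, params)$trace
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a ground-truth cohort (or ingest a supplied trial
#' table), (2) per-session model fitting and BIC comparison, (3)
#' win-stay/lose-shift summaries, action-difference scores and the
#' perseveration curve, (4) k-sweep, latent-choice regressions and the
#' median-split interaction, (5) hierarchical two-group comparison with
#' directed Bayes factors. All outputs are CSV (plus a JSON manifest)
#' under `out_dir`; every CSV carries the manifest hash in a header
#' comment. All randomness derives from `config$seed`.
#'
#' @param config named list (see [default_pipeline_config()]) or the path
#'   to a YAML file with the same structure.
#' @param out_dir output directory, created if needed.
#' @param trials optional pre-existing trial table (skips simulation; the
#'   hierarchical stage then requires a `groups` entry in `config`).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("dynaprl_run_"), trials = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- hash_object(config)
  results <- list(manifest = list(config_hash = hash, seed = config$seed))

  set.seed(config$seed)
  task_cfg <- do.call(task_config, config$task)

  # -- stage 1: data
  if (is.null(trials)) {
    spec <- do.call(cohort_spec, config$cohort)
    coh <- generate_cohort(spec, task_cfg)
    trials <- coh$trials
    groups <- coh$groups
    write_trials(coh$truth, file.path(out_dir, "truth.csv"), hash)
    write_csv_commented(groups, file.path(out_dir, "groups.csv"), hash)
  } else {
    groups <- config$groups
  }
  write_trials(trials, file.path(out_dir, "trials.csv"), hash)
  results$trials <- trials

  # -- stage 2: fitting and model comparison
  cmp <- compare_models(trials, config$fit$models,
                        n_restarts = config$fit$n_restarts)
  write_csv_commented(cmp$session_bic, file.path(out_dir, "bic.csv"), hash)
  write_csv_commented(cmp$subject_summary,
                      file.path(out_dir, "bic_summary.csv"), hash)
  fits <- lapply(setNames(nm = unique(c(config$fit$models,
                                        "standard", "avgrpe", "grs"))),
                 function(m) fit_sessions(trials, m,
                                          n_restarts = config$fit$n_restarts))
  write_csv_commented(fits[[config$fit$models[1]]],
                      file.path(out_dir, "fits.csv"), hash)
  results$comparison <- cmp
  results$fits <- fits

  # -- stage 3: model-independent behavior
  events <- classify_events(trials)
  behav <- summarize_stay_shift(events,
                                c("phase", "block_type", "action_class"))
  write_csv_commented(behav, file.path(out_dir, "behavior_summary.csv"), hash)
  ads <- action_difference_scores(events)
  write_csv_commented(ads, file.path(out_dir, "action_difference.csv"), hash)
  pcurve <- perseveration_curve(trials)
  write_csv_commented(pcurve, file.path(out_dir, "perseveration.csv"), hash)
  results$behavior <- list(summary = behav, action_difference = ads,
                           perseveration = pcurve)

  # -- stage 4: latent-state analyses
  if (isTRUE(config$latent$ksweep) || isTRUE(config$latent$correlation) ||
      isTRUE(config$latent$mediansplit)) {
    tr_std <- latent_traces(trials, fits$standard, "standard")
    tr_avg <- latent_traces(trials, fits$avgrpe, "avgrpe")
    tr_grs <- latent_traces(trials, fits$grs, "grs")
    if (isTRUE(config$latent$ksweep)) {
      ks <- k_sweep(trials, tr_std)
      write_csv_commented(ks$grid, file.path(out_dir, "ksweep.csv"), hash)
      results$ksweep <- ks
    }
    if (isTRUE(config$latent$correlation)) {
      corr <- rbind(
        latent_choice_correlation(trials, tr_avg, "abs_avgrpe", "WS"),
        latent_choice_correlation(trials, tr_avg, "abs_avgrpe", "LS"),
        latent_choice_correlation(trials, tr_grs, "rtrace", "WS"),
        latent_choice_correlation(trials, tr_grs, "rtrace", "LS"))
      write_csv_commented(corr, file.path(out_dir, "latent_correlation.csv"),
                          hash)
      results$latent_correlation <- corr
    }
    if (isTRUE(config$latent$mediansplit)) {
      ms <- median_split_interaction(trials, tr_avg, tr_grs)
      write_csv_commented(ms, file.path(out_dir, "median_split.csv"), hash)
      results$median_split <- ms
    }
  }

  # -- stage 5: hierarchical group comparison
  if (isTRUE(config$hierarchical$enabled) && !is.null(groups)) {
    hier <- fit_hierarchical(trials, groups,
                             chains = config$hierarchical$chains,
                             draws = config$hierarchical$draws,
                             warmup = config$hierarchical$warmup,
                             seed = config$seed)
    write_csv_commented(hier$summary,
                        file.path(out_dir, "posterior_summary.csv"), hash)
    results$hierarchical <- hier
  }

  results$manifest$outputs <- setdiff(list.files(out_dir), "manifest.json")
  results$manifest$file_md5 <- as.list(
    tools::md5sum(file.path(out_dir, results$manifest$outputs)))
  names(results$manifest$file_md5) <- results$manifest$outputs
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
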