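# Ground-truth-known synthetic cohorts: two groups of agents with
# specified parameter differences playing the dynaPRL task.

#' Specify a two-group synthetic cohort
#'
#' Group A subjects draw each parameter from
#' `Normal(mean + delta / 2, sd)` and group B from
#' `Normal(mean - delta / 2, sd)`, truncated to the model's bounds by
#' resampling (draws are clipped after 50 attempts). The default emulates
#' a study cohort of 9 + 5 subjects under the asymmetric five-parameter
#' model, with group A learning faster from both outcome types and
#' retaining less of the unchosen value after losses.
#'
#' @param n_a,n_b subjects per group.
#' @param sessions,trials_per_session per-subject task exposure.
#' @param model_id generative model.
#' @param par_means,par_sds,par_deltas named numeric vectors over the
#'   model's parameters (defaults provided for `asym5`).
#' @param invalid_rate fraction of trials marked invalid (omitted
#'   responses; excluded from all analyses).
#' @return List of class `dynaprl_cohort_spec`.
#' @export
cohort_spec <- function(n_a = 9, n_b = 5, sessions = 5,
                        trials_per_session = 300, model_id = "asym5",
                        par_means = NULL, par_sds = NULL, par_deltas = NULL,
                        invalid_rate = 0.005) {
  info <- model_info(model_id)
  defaults <- switch(model_id,
    asym5 = list(
      means = c(alpha_pos = 0.40, alpha_neg = 0.30, gamma_pos = 0.90,
                gamma_neg = 0.75, beta = 4),
      sds = c(alpha_pos = 0.08, alpha_neg = 0.08, gamma_pos = 0.05,
              gamma_neg = 0.08, beta = 0.8),
      deltas = c(alpha_pos = 0.15, alpha_neg = 0.05, gamma_pos = 0,
                 gamma_neg = -0.20, beta = 0)),
    standard = list(means = c(alpha = 0.35, beta = 4),
                    sds = c(alpha = 0.1, beta = 0.8),
                    deltas = c(alpha = 0, beta = 0)),
    avgrpe = list(means = c(alpha = 0.35, beta = 4, hW = 0.5),
                  sds = c(alpha = 0.08, beta = 0.8, hW = 0.08),
                  deltas = c(alpha = 0, beta = 0, hW = 0)),
    grs = list(means = c(alpha = 0.35, beta = 4, alphaR = 0.3, wR = 0.7),
               sds = c(alpha = 0.08, beta = 0.8, alphaR = 0.08, wR = 0.1),
               deltas = c(alpha = 0, beta = 0, alphaR = 0, wR = 0)))
  if (is.null(par_means)) par_means <- defaults$means
  if (is.null(par_sds)) par_sds <- defaults$sds
  if (is.null(par_deltas)) par_deltas <- defaults$deltas
  for (v in list(par_means, par_sds, par_deltas)) {
    if (!all(info$par_names %in% names(v))) {
      stop("parameter vectors must name all of: ",
           paste(info$par_names, collapse = ", "))
    }
  }
  # feasibility: group means +- delta/2 must sit inside the bounds
  for (s in c(1, -1)) {
    m <- par_means[info$par_names] + s * par_deltas[info$par_names] / 2
    if (any(m <= info$lower | m >= info$upper)) {
      stop("group mean delta pushes a parameter mean out of bounds")
    }
  }
  if (invalid_rate < 0 || invalid_rate >= 1) stop("invalid_rate in [0,1)")
  structure(list(n_a = n_a, n_b = n_b, sessions = sessions,
                 trials_per_session = trials_per_session,
                 model_id = model_id, par_means = par_means,
                 par_sds = par_sds, par_deltas = par_deltas,
                 invalid_rate = invalid_rate),
            class = "dynaprl_cohort_spec")
}

draw_subject_params <- function(spec, sign) {
  info <- model_info(spec$model_id)
  p <- numeric(info$n_params)
  for (i in seq_len(info$n_params)) {
    nm <- info$par_names[i]
    m <- spec$par_means[[nm]] + sign * spec$par_deltas[[nm]] / 2
    s <- spec$par_sds[[nm]]
    for (try in 1:50) {
      x <- rnorm(1, m, s)
      if (x > info$lower[i] && x < info$upper[i]) break
    }
    p[i] <- min(max(x, info$lower[i] + 1e-4), info$upper[i] - 1e-9)
  }
  setNames(p, info$par_names)
}

#' Generate a two-group synthetic cohort with known ground truth
#'
#' Samples per-subject parameters from the group distributions, simulates
#' every session in the dynaPRL environment, and marks a small fraction of
#' trials invalid (omissions). Deterministic for a fixed RNG state.
#'
#' @param spec a [cohort_spec()].
#' @param config a [task_config()].
#' @return List with `trials` (all subjects' trial tables, with
#'   `subject_id`), `groups` (subject-to-group map), and `truth`
#'   (per-subject generative parameters).
#' @export
#' @examples
#' set.seed(7)
#' coh <- generate_cohort(cohort_spec(n_a = 2, n_b = 2, sessions = 1,
#'                                    trials_per_session = 50))
#' table(coh$groups$group)
generate_cohort <- function(spec, config = task_config()) {
  n <- spec$n_a + spec$n_b
  ids <- sprintf("S%02d", seq_len(n))
  grp <- rep(c("A", "B"), c(spec$n_a, spec$n_b))
  sign <- ifelse(grp == "A", 1, -1)
  truth <- NULL
  all_trials <- vector("list", n)
  for (j in seq_len(n)) {
    params <- draw_subject_params(spec, sign[j])
    truth <- rbind(truth, data.frame(subject_id = ids[j], group = grp[j],
                                     as.data.frame(as.list(params)),
                                     stringsAsFactors = FALSE))
    tr <- simulate_agent(spec$model_id, params, config,
                         n_sessions = spec$sessions,
                         trials_per_session = spec$trials_per_session)
    if (spec$invalid_rate > 0) {
      tr$valid <- runif(nrow(tr)) >= spec$invalid_rate
    }
    all_trials[[j]] <- cbind(subject_id = ids[j], tr,
                             stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, all_trials),
       groups = data.frame(subject_id = ids, group = grp,
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Hand-built mini-session fixtures
#'
#' Tiny sessions with fully worked expected values, used by the test
#' suite's oracle checks and handy as documentation of the trial-table
#' format.
#'
#' @return Named list of small trial tables: `ws_ls_4trial` (the four-trial
#'   stay/shift example), `rtrace_3trial` (two rewards then a loss; reward
#'   trace 0, 0.5, 0.75 under `alphaR = 0.5`), `std_3trial` (standard-model
#'   hand trace), and `all_invalid` (every trial invalid).
#' @export
make_fixtures <- function() {
  base <- function(ch, out, btype = "HC", better = "A1") {
    n <- length(ch)
    data.frame(session_id = 1L, trial_index = seq_len(n), block_id = 1L,
               block_type = btype, block_trial_index = seq_len(n),
               choice = ch, outcome = out,
               reward_volume = ifelse(out == 1, 33, 0),
               better_action = better, valid = TRUE,
               stringsAsFactors = FALSE)
  }
  f <- list(
    ws_ls_4trial = base(c("A1", "A1", "A2", "A2"), c(1L, 0L, 1L, 0L)),
    rtrace_3trial = base(c("A1", "A1", "A1"), c(1L, 1L, 0L)),
    std_3trial = base(c("A1", "A2", "A1"), c(1L, 0L, 1L)),
    all_invalid = transform(base(c("A1", "A2"), c(1L, 0L)), valid = FALSE)
  )
  f
}
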