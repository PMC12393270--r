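# dynaPRL / PRL task environments.
#
# Two levers (A1 = left, A2 = right). dynaPRL sessions are built from
# blocks of three types differing in reward-probability contrast:
#   HC  0.80 / 0.10   high contrast, low stochasticity
#   LC  0.60 / 0.30   low contrast
#   NC  0.45 / 0.45   no contrast
# Blocks switch every 15-30 trials with two transition rules: a no-contrast
# block is never followed by another, and the better side never repeats
# across consecutive contrast blocks.

#' Task configuration for the dynaPRL environment
#'
#' @param block_menu named list of length-2 probability vectors
#'   (better, worse) keyed by block type. The default low-contrast block is
#'   0.60/0.30; pass `LC = c(0.6, 0.1)` for the steeper variant.
#' @param min_len,max_len bounds on the scheduled block length (trials);
#'   lengths are drawn uniformly on `[min_len, max_len]`.
#' @param consecutive_error_defer number of consecutive incorrect choices
#'   in a contrast block that holds a due transition back.
#' @param error_rule `"defer"` (default) delays a scheduled transition
#'   while the agent is in a run of `consecutive_error_defer` errors;
#'   `"none"` disables the rule.
#' @param magnitude_onset within-block trial after which the
#'   reward-magnitude manipulation can occur (HC/LC only).
#' @param magnitude_fraction fraction of eligible rewarded trials whose
#'   volume is halved or doubled (equal odds).
#' @param volumes named reward volumes in microlitres
#'   (`standard`, `halved`, `doubled`).
#' @param no_nc_repeat,no_better_repeat the two transition constraints.
#' @return A list of class `dynaprl_config`.
#' @export
task_config <- function(block_menu = list(HC = c(0.80, 0.10),
                                          LC = c(0.60, 0.30),
                                          NC = c(0.45, 0.45)),
                        min_len = 15L, max_len = 30L,
                        consecutive_error_defer = 4L,
                        error_rule = c("defer", "none"),
                        magnitude_onset = 12L,
                        magnitude_fraction = 0.40,
                        volumes = c(standard = 33, halved = 16, doubled = 66),
                        no_nc_repeat = TRUE, no_better_repeat = TRUE) {
  error_rule <- match.arg(error_rule)
  if (length(block_menu) == 0) stop("block menu must not be empty")
  for (nm in names(block_menu)) {
    p <- block_menu[[nm]]
    if (length(p) != 2 || any(p < 0) || any(p > 1)) {
      stop("block '", nm, "' needs two probabilities in [0,1]")
    }
    if (p[1] < p[2]) stop("block '", nm, "': better probability below worse")
  }
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (magnitude_fraction < 0 || magnitude_fraction > 1) {
    stop("magnitude_fraction must be in [0,1]")
  }
  structure(list(block_menu = block_menu,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 consecutive_error_defer = as.integer(consecutive_error_defer),
                 error_rule = error_rule,
                 magnitude_onset = as.integer(magnitude_onset),
                 magnitude_fraction = magnitude_fraction,
                 volumes = volumes,
                 no_nc_repeat = no_nc_repeat,
                 no_better_repeat = no_better_repeat),
            class = "dynaprl_config")
}

is_contrast <- function(block_type, config) {
  p <- config$block_menu[[block_type]]
  p[1] > p[2]
}

#' Construct a block specification
#'
#' @param block_type a key of the configuration's block menu.
#' @param better_side `"left"`, `"right"` or `"none"` (no-contrast blocks).
#' @param scheduled_length scheduled block length in trials.
#' @param config a [task_config()].
#' @return List of class `dynaprl_block` with fields `block_type`,
#'   `p_reward_better`, `p_reward_worse`, `better_side`, `scheduled_length`.
#' @export
block_spec <- function(block_type, better_side, scheduled_length, config) {
  p <- config$block_menu[[block_type]]
  if (is.null(p)) stop("block type '", block_type, "' not in menu")
  contrast <- p[1] > p[2]
  if (contrast && !better_side %in% c("left", "right")) {
    stop("contrast block needs better_side 'left' or 'right'")
  }
  if (!contrast) better_side <- "none"
  if (scheduled_length < config$min_len || scheduled_length > config$max_len) {
    stop("scheduled_length outside [min_len, max_len]")
  }
  structure(list(block_type = block_type,
                 p_reward_better = p[1], p_reward_worse = p[2],
                 better_side = better_side,
                 scheduled_length = as.integer(scheduled_length)),
            class = "dynaprl_block")
}

#' Draw the next block subject to the transition constraints
#'
#' A no-contrast block is never drawn directly after another, and the
#' better side of a contrast block differs from the previous contrast
#' block's better side. Scheduled length is uniform on
#' `[min_len, max_len]`. Uses R's RNG.
#'
#' @param history list of previous [block_spec()]s (may be empty).
#' @param config a [task_config()].
#' @return A new `dynaprl_block`.
#' @export
draw_next_block <- function(history, config) {
  if (length(config$block_menu) == 0) stop("block menu must not be empty")
  prev <- if (length(history)) history[[length(history)]] else NULL
  types <- names(config$block_menu)
  if (!is.null(prev) && config$no_nc_repeat && !is_contrast(prev$block_type, config)) {
    types <- types[vapply(types, is_contrast, logical(1), config = config)]
    if (!length(types)) stop("transition constraints leave no eligible block type")
  }
  btype <- if (length(types) == 1) types else sample(types, 1)
  sides <- c("left", "right")
  if (is_contrast(btype, config)) {
    if (!is.null(prev) && config$no_better_repeat &&
        prev$better_side %in% sides) {
      sides <- setdiff(sides, prev$better_side)
    }
    side <- if (length(sides) == 1) sides else sample(sides, 1)
  } else side <- "none"
  len <- sample(seq.int(config$min_len, config$max_len), 1)
  block_spec(btype, side, len, config)
}

#' Sample one trial outcome from a block
#'
#' Draws the Bernoulli outcome for `choice` under the block's reward
#' probabilities and applies the reward-magnitude manipulation: on
#' rewarded HC/LC trials after `magnitude_onset` trials of the block, with
#' probability `magnitude_fraction` the volume is halved or doubled with
#' equal odds, otherwise standard. The binary outcome used by the learning
#' models is unaffected by volume.
#'
#' @param block a `dynaprl_block`.
#' @param choice `"A1"` (left) or `"A2"` (right).
#' @param block_trial_index 1-based trial index within the block.
#' @param config a [task_config()].
#' @return List with `outcome` (0/1), `reward_volume` (microlitres) and
#'   `better_action` (`"A1"`, `"A2"` or `"none"`).
#' @export
step_trial <- function(block, choice, block_trial_index, config) {
  if (!choice %in% c("A1", "A2")) stop("choice must be 'A1' or 'A2'")
  if (block_trial_index < 1) stop("block_trial_index must be >= 1")
  better_action <- switch(block$better_side,
                          left = "A1", right = "A2", none = "none")
  p <- if (better_action == "none" || choice == better_action) {
    block$p_reward_better
  } else block$p_reward_worse
  outcome <- rbinom(1, 1, p)
  volume <- 0
  if (outcome == 1) {
    volume <- config$volumes[["standard"]]
    eligible <- is_contrast(block$block_type, config) &&
      block_trial_index > config$magnitude_onset
    if (eligible && runif(1) < config$magnitude_fraction) {
      volume <- if (runif(1) < 0.5) config$volumes[["halved"]]
                else config$volumes[["doubled"]]
    }
  }
  list(outcome = as.integer(outcome), reward_volume = unname(volume),
       better_action = better_action)
}

#' Decide whether a block transitions after the current trial
#'
#' A transition is due once `trials_elapsed` reaches the scheduled length.
#' Under the default `"defer"` rule a due transition in a contrast block is
#' held back while the last `consecutive_error_defer` choices were all
#' incorrect, so that contingencies are not switched mid-failure.
#'
#' @param block a `dynaprl_block`.
#' @param trials_elapsed number of trials completed in the block.
#' @param recent_outcomes_correct logical vector of per-trial correctness,
#'   most recent last (only the tail is inspected).
#' @param config a [task_config()].
#' @return TRUE when the block should switch.
#' @export
maybe_transition <- function(block, trials_elapsed, recent_outcomes_correct,
                             config) {
  if (trials_elapsed < 1) stop("trials_elapsed must be >= 1")
  if (trials_elapsed < block$scheduled_length) return(FALSE)
  if (config$error_rule == "defer" && is_contrast(block$block_type, config)) {
    k <- config$consecutive_error_defer
    rec <- recent_outcomes_correct
    if (length(rec) >= k && all(!tail(rec, k))) return(FALSE)
  }
  TRUE
}

# ---- generative agents (internal) --------------------------------------

agent_state_new <- function(model_id, params) {
  params <- validate_params(model_id, params)
  list(model_id = model_id, params = params,
       V = c(0, 0), avgrpe = 0, rtrace = 0, prev_R = NA_integer_)
}

agent_choice_prob <- function(state) {
  softmax_choice_prob(state$V, state$params[["beta"]])[1]
}

agent_learn <- function(state, choice, R) {
  p <- state$params
  switch(state$model_id,
    standard = {
      u <- standard_update(state$V, choice, R, p[["alpha"]])
      state$V <- u$V
    },
    avgrpe = {
      u <- avg_rpe_update(state$V, state$avgrpe, choice, R,
                          p[["alpha"]], p[["hW"]])
      state$V <- u$V; state$avgrpe <- u$avgrpe
    },
    grs = {
      u <- grs_update(state$V, state$rtrace, state$prev_R, choice, R,
                      p[["alpha"]], p[["alphaR"]], p[["wR"]],
                      first_trial = is.na(state$prev_R))
      state$V <- u$V; state$rtrace <- u$rtrace
    },
    asym5 = {
      u <- asym_update(state$V, choice, R, p[["alpha_pos"]], p[["alpha_neg"]],
                       p[["gamma_pos"]], p[["gamma_neg"]])
      state$V <- u$V
    })
  state$prev_R <- as.integer(R)
  state
}

#' Simulate an RL agent playing the dynaPRL task
#'
#' Generative counterpart of [session_nll()]: at each trial the agent's
#' choice is sampled from the softmax of its current action values, the
#' environment returns the outcome, and the agent updates its latent state
#' with the same learning rule the likelihood evaluates. Deterministic for
#' a fixed RNG state.
#'
#' @param model_id,params model identifier and parameter vector.
#' @param config a [task_config()].
#' @param n_sessions,trials_per_session cohort shape.
#' @param session_offset integer added to session ids (for multi-subject
#'   tables).
#' @return A trial table: one row per trial with columns `session_id`,
#'   `trial_index`, `block_id`, `block_type`, `block_trial_index`, `choice`,
#'   `outcome`, `reward_volume`, `better_action`, `valid`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- simulate_agent("standard", c(alpha = 0.4, beta = 3),
#'                      task_config(), n_sessions = 1,
#'                      trials_per_session = 60)
#' head(tr)
simulate_agent <- function(model_id, params, config = task_config(),
                           n_sessions = 1, trials_per_session = 300,
                           session_offset = 0L) {
  params <- validate_params(model_id, params)
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    out[[s]] <- simulate_dynaprl_session(model_id, params, config,
                                         trials_per_session,
                                         session_id = s + session_offset)
  }
  do.call(rbind, out)
}

simulate_dynaprl_session <- function(model_id, params, config, n_trials,
                                     session_id = 1L) {
  state <- agent_state_new(model_id, params)
  history <- list(draw_next_block(list(), config))
  block <- history[[1]]
  block_id <- 1L
  bt <- 0L
  correct_run <- logical(0)

  choice <- character(n_trials); outcome <- integer(n_trials)
  volume <- numeric(n_trials); btype <- character(n_trials)
  bid <- integer(n_trials); btrial <- integer(n_trials)
  better <- character(n_trials)

  for (t in seq_len(n_trials)) {
    bt <- bt + 1L
    p1 <- agent_choice_prob(state)
    ch <- if (runif(1) < p1) 1L else 2L
    ch_lab <- c("A1", "A2")[ch]
    res <- step_trial(block, ch_lab, bt, config)
    state <- agent_learn(state, ch, res$outcome)

    choice[t] <- ch_lab; outcome[t] <- res$outcome
    volume[t] <- res$reward_volume; btype[t] <- block$block_type
    bid[t] <- block_id; btrial[t] <- bt; better[t] <- res$better_action

    is_correct <- res$better_action == "none" || ch_lab == res$better_action
    correct_run <- c(tail(correct_run, config$consecutive_error_defer - 1L),
                     is_correct)
    if (maybe_transition(block, bt, correct_run, config)) {
      block <- draw_next_block(history, config)
      history[[length(history) + 1L]] <- block
      block_id <- block_id + 1L
      bt <- 0L
      correct_run <- logical(0)
    }
  }

  data.frame(session_id = session_id, trial_index = seq_len(n_trials),
             block_id = bid, block_type = btype, block_trial_index = btrial,
             choice = choice, outcome = outcome, reward_volume = volume,
             better_action = better, valid = TRUE,
             stringsAsFactors = FALSE)
}

#' Simulate a probabilistic reversal learning (PRL) training session
#'
#' Single-reversal-rule variant used in training: one lever is rewarded at
#' 0.70, the other at 0.10. A reversal becomes eligible when an
#' exponential moving average of correctness (8-trial convention,
#' smoothing 2/9) exceeds 0.75; once eligible it occurs with probability
#' 0.10 per trial and is forced if it has not occurred within 20 eligible
#' trials.
#'
#' @param model_id,params the simulated agent.
#' @param n_trials session length.
#' @param p_better,p_worse reward probabilities of the two levers.
#' @param threshold performance threshold on the EMA of correctness.
#' @param ema_n EMA window convention (smoothing `2/(ema_n + 1)`).
#' @param p_reversal per-trial reversal probability once eligible.
#' @param force_after eligible trials after which a reversal is forced.
#' @param session_id session identifier.
#' @return A trial table as in [simulate_agent()] with block type `"PRL"`;
#'   `block_id` increments at each reversal.
#' @export
run_prl_session <- function(model_id, params, n_trials = 300,
                            p_better = 0.70, p_worse = 0.10,
                            threshold = 0.75, ema_n = 8L,
                            p_reversal = 0.10, force_after = 20L,
                            session_id = 1L) {
  state <- agent_state_new(model_id, params)
  lambda <- 2 / (ema_n + 1)
  better <- sample(c("A1", "A2"), 1)
  ema <- 0; eligible_count <- 0L; block_id <- 1L; bt <- 0L

  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    bt <- bt + 1L
    p1 <- agent_choice_prob(state)
    ch <- if (runif(1) < p1) 1L else 2L
    ch_lab <- c("A1", "A2")[ch]
    p <- if (ch_lab == better) p_better else p_worse
    R <- rbinom(1, 1, p)
    state <- agent_learn(state, ch, R)
    rows[[t]] <- data.frame(session_id = session_id, trial_index = t,
                            block_id = block_id, block_type = "PRL",
                            block_trial_index = bt, choice = ch_lab,
                            outcome = R, reward_volume = ifelse(R == 1, 33, 0),
                            better_action = better, valid = TRUE,
                            stringsAsFactors = FALSE)
    ema <- ema + lambda * ((ch_lab == better) - ema)
    reverse <- FALSE
    if (ema > threshold) {
      eligible_count <- eligible_count + 1L
      reverse <- runif(1) < p_reversal || eligible_count >= force_after
    }
    if (reverse) {
      better <- setdiff(c("A1", "A2"), better)
      block_id <- block_id + 1L
      bt <- 0L
      eligible_count <- 0L
      ema <- 0
    }
  }
  do.call(rbind, rows)
}
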