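# The four reinforcement-learning models.
#
# All models share the softmax choice rule and binary rewards R in {0,1}.
# Latent state (action values, running traces) resets at session start and
# is carried across block transitions within a session.

#' Model registry
#'
#' Metadata for the four supported reinforcement-learning models:
#' `standard` (delta-rule with learning rate alpha and inverse temperature
#' beta), `avgrpe` (value updated by an exponentially averaged RPE with
#' history weight `hW`), `grs` (RPE augmented by an exponential moving
#' average of past rewards, the global reward state), and `asym5`
#' (valence-specific learning rates `alpha_pos`/`alpha_neg` for the chosen
#' action and retention factors `gamma_pos`/`gamma_neg` for the unchosen
#' action; value decay rate is `1 - gamma`).
#'
#' @param model_id one of `"standard"`, `"avgrpe"`, `"grs"`, `"asym5"`.
#' @return A list with elements `code` (internal integer), `par_names`,
#'   `lower`, `upper` (box bounds used by the fitter) and `n_params`.
#' @export
#' @examples
#' model_info("avgrpe")$par_names
model_info <- function(model_id) {
  reg <- list(
    standard = list(
      code = 1L, par_names = c("alpha", "beta"),
      lower = c(1e-6, 0), upper = c(1 - 1e-6, .BETA_MAX)),
    avgrpe = list(
      code = 2L, par_names = c("alpha", "beta", "hW"),
      lower = c(1e-6, 0, 0), upper = c(1 - 1e-6, .BETA_MAX, 0.75)),
    grs = list(
      code = 3L, par_names = c("alpha", "beta", "alphaR", "wR"),
      lower = c(1e-6, 0, 0, -1), upper = c(1 - 1e-6, .BETA_MAX, 1, 1)),
    asym5 = list(
      code = 4L,
      par_names = c("alpha_pos", "alpha_neg", "gamma_pos", "gamma_neg", "beta"),
      lower = c(1e-6, 1e-6, 1e-6, 1e-6, 0),
      upper = c(1 - 1e-6, 1 - 1e-6, 1, 1, .BETA_MAX))
  )
  info <- reg[[model_id]]
  if (is.null(info)) {
    stop("unknown model_id '", model_id, "'; expected one of: ",
         paste(names(reg), collapse = ", "))
  }
  info$model_id <- model_id
  info$n_params <- length(info$par_names)
  info
}

#' @rdname model_info
#' @export
model_ids <- function() c("standard", "avgrpe", "grs", "asym5")

validate_params <- function(model_id, params) {
  info <- model_info(model_id)
  params <- as.numeric(params)
  if (length(params) != info$n_params) {
    stop(model_id, " expects ", info$n_params, " parameters (",
         paste(info$par_names, collapse = ", "), ")")
  }
  if (any(!is.finite(params))) stop("non-finite parameter value")
  bad <- params < info$lower - 1e-12 | params > info$upper + 1e-12
  if (any(bad)) {
    stop("parameter out of bounds: ",
         paste(info$par_names[bad], "=", signif(params[bad], 4), collapse = ", "))
  }
  names(params) <- info$par_names
  params
}

#' Softmax choice probabilities for a two-action value pair
#'
#' @param values numeric length-2 vector of action values.
#' @param beta inverse temperature, `beta >= 0`; 0 gives random choice.
#' @return Length-2 probability vector summing to 1.
#' @export
#' @examples
#' softmax_choice_prob(c(1, 0), beta = 2)
softmax_choice_prob <- function(values, beta) {
  if (length(values) != 2 || any(!is.finite(values)) || !is.finite(beta)) {
    stop("values must be two finite numbers and beta finite")
  }
  if (beta < 0) stop("beta must be >= 0")
  e <- exp((values - max(values)) * beta)
  e / sum(e)
}

#' Single-trial value updates
#'
#' One step of each model's learning rule, exposed for inspection and for
#' step-by-step cross-checks of the session-level likelihood filter.
#' `V` is a length-2 value vector, `choice` is 1 or 2, `R` is the binary
#' outcome.
#'
#' @param V numeric length-2 action values.
#' @param choice chosen action index (1 or 2).
#' @param R binary outcome (0 or 1).
#' @param alpha learning rate in (0,1).
#' @return `standard_update`: list with `V` (updated values) and `rpe`.
#' @export
#' @examples
#' standard_update(c(0, 0), choice = 1, R = 1, alpha = 0.5)
standard_update <- function(V, choice, R, alpha) {
  stopifnot(R %in% c(0, 1), choice %in% c(1, 2))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  rpe <- R - V[choice]
  V[choice] <- V[choice] + alpha * rpe
  list(V = V, rpe = rpe)
}

#' @rdname standard_update
#' @param avgrpe_prev previous trial's averaged RPE (0 at session start).
#' @param hW history weight in [0, 0.75]; at `hW = 0` the rule reduces to
#'   the standard delta rule.
#' @return `avg_rpe_update`: list with `V`, `rpe` and `avgrpe`; the value
#'   moves by the averaged RPE itself.
#' @export
avg_rpe_update <- function(V, avgrpe_prev, choice, R, alpha, hW) {
  stopifnot(R %in% c(0, 1), choice %in% c(1, 2))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (hW < 0 || hW > 0.75) stop("hW must be in [0, 0.75]")
  rpe <- R - V[choice]
  avgrpe <- alpha * rpe + hW * avgrpe_prev
  V[choice] <- V[choice] + avgrpe
  list(V = V, rpe = rpe, avgrpe = avgrpe)
}

#' @rdname standard_update
#' @param rtrace_prev previous reward trace (global reward state).
#' @param R_prev previous trial's binary outcome (the trace is updated from
#'   the outcome one trial back; at session start the trace keeps its
#'   initial value).
#' @param alphaR reward-history weight in [0,1].
#' @param wR reward-trace weight in [-1,1]; `wR = 0` reduces to standard.
#' @param first_trial logical; TRUE on the first trial of a session.
#' @return `grs_update`: list with `V`, `rpe` and `rtrace`.
#' @export
grs_update <- function(V, rtrace_prev, R_prev, choice, R, alpha, alphaR, wR,
                       first_trial = FALSE) {
  stopifnot(R %in% c(0, 1), choice %in% c(1, 2))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (alphaR < 0 || alphaR > 1) stop("alphaR must be in [0,1]")
  if (wR < -1 || wR > 1) stop("wR must be in [-1,1]")
  rtrace <- if (first_trial) rtrace_prev
            else rtrace_prev + (R_prev - rtrace_prev) * alphaR
  rpe <- R + wR * rtrace - V[choice]
  V[choice] <- V[choice] + alpha * rpe
  list(V = V, rpe = rpe, rtrace = rtrace)
}

#' @rdname standard_update
#' @param alpha_pos,alpha_neg learning rates after wins and losses.
#' @param gamma_pos,gamma_neg retention factors applied to the unchosen
#'   action's value after wins and losses (decay rate `1 - gamma`).
#' @return `asym_update`: list with `V` and `rpe` (computed pre-update).
#' @export
asym_update <- function(V, choice, R, alpha_pos, alpha_neg,
                        gamma_pos, gamma_neg) {
  stopifnot(R %in% c(0, 1), choice %in% c(1, 2))
  for (a in c(alpha_pos, alpha_neg)) {
    if (a <= 0 || a >= 1) stop("learning rates must be in (0,1)")
  }
  for (g in c(gamma_pos, gamma_neg)) {
    if (g <= 0 || g > 1) stop("retention factors must be in (0,1]")
  }
  unchosen <- 3L - choice
  rpe <- R - V[choice]
  if (R == 1) {
    V[choice] <- V[choice] + alpha_pos * rpe
    V[unchosen] <- V[unchosen] * gamma_pos
  } else {
    V[choice] <- V[choice] + alpha_neg * rpe
    V[unchosen] <- V[unchosen] * gamma_neg
  }
  list(V = V, rpe = rpe)
}

# ---- session-level likelihood ------------------------------------------

# Map a trial table to the integer vectors the C++ filter consumes.
# Invalid trials are dropped; sessions are kept in first-appearance order.
prepare_trials <- function(trials) {
  req <- c("session_id", "choice", "outcome")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if ("valid" %in% names(trials)) trials <- trials[as.logical(trials$valid), , drop = FALSE]
  if (nrow(trials) == 0) stop("no valid trials")
  choice <- match(as.character(trials$choice), c("A1", "A2"))
  if (any(is.na(choice))) stop("choice must be 'A1' or 'A2'")
  outcome <- as.integer(trials$outcome)
  if (any(!outcome %in% c(0L, 1L))) stop("outcome must be 0 or 1")
  session <- as.integer(factor(trials$session_id,
                               levels = unique(trials$session_id)))
  list(choice = as.integer(choice), outcome = outcome, session = session,
       trials = trials)
}

#' Session negative log-likelihood and latent trace
#'
#' Evaluates one model's negative log-likelihood on a trial table and
#' returns the trial-aligned latent trace (action values, RPE, averaged
#' RPE, reward trace, and the probability assigned to the taken action).
#' Values reset at each session start and are carried across block
#' transitions within a session. Choice probabilities are floored at 1e-9
#' inside the log.
#'
#' @param trials a trial table (see [simulate_agent()]); invalid trials are
#'   excluded.
#' @param model_id model identifier, see [model_info()].
#' @param params named or positional parameter vector for the model.
#' @param with_trace return the latent trace alongside the nLL.
#' @return List with `nll` and, if requested, `trace`: a data.frame with
#'   columns `V1`, `V2`, `rpe`, `avgrpe`, `rtrace`, `p_choice`, row-aligned
#'   with the valid trials.
#' @export
#' @examples
#' tr <- data.frame(session_id = 1, choice = c("A1", "A1", "A2"),
#'                  outcome = c(1, 0, 1), valid = TRUE)
#' session_nll(tr, "standard", c(alpha = 0.5, beta = 1))$nll
session_nll <- function(trials, model_id, params, with_trace = TRUE) {
  params <- validate_params(model_id, params)
  info <- model_info(model_id)
  d <- prepare_trials(trials)
  out <- cpp_rl_filter(d$choice, d$outcome, d$session, info$code,
                       unname(params), with_trace)
  res <- list(nll = out$nll, model_id = model_id, params = params,
              n_obs = length(d$choice))
  if (with_trace) {
    tr <- as.data.frame(out$trace)
    names(tr) <- c("V1", "V2", "rpe", "avgrpe", "rtrace", "p_choice")
    tr$abs_avgrpe <- abs(tr$avgrpe)
    res$trace <- tr
  }
  res
}
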