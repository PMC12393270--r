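# Per-session maximum-likelihood fitting and BIC model comparison.

#' Bayesian Information Criterion
#'
#' `BIC = 2 * nLL + nParams * log(nObs)` (natural log).
#'
#' @param nll negative log-likelihood.
#' @param n_params number of free parameters.
#' @param n_obs number of observations (valid trials); must be >= 1.
#' @return The BIC value.
#' @export
#' @examples
#' bic(10, 2, 100)  # 20 + 2 * log(100)
bic <- function(nll, n_params, n_obs) {
  if (any(n_obs < 1)) stop("n_obs must be >= 1")
  2 * nll + n_params * log(n_obs)
}

#' Fit one model to one session by multi-restart maximum likelihood
#'
#' Bounded quasi-Newton optimization (`optim`, L-BFGS-B) from
#' `n_restarts` starting points. Candidate starts are drawn uniformly
#' within the parameter bounds and pre-screened by their objective value
#' (`screen_factor * n_restarts` candidates; the `n_restarts` best launch
#' an optimization), which avoids the flat high-beta/zero-alpha plateau
#' that traps starts far from the data. A Nelder-Mead fallback runs when a
#' restart fails; the restart with the lowest negative log-likelihood
#' wins. Deterministic for a fixed RNG state.
#'
#' @param trials trial table for a single session (invalid trials are
#'   dropped).
#' @param model_id model identifier, see [model_info()].
#' @param n_restarts number of random restarts.
#' @param min_trials minimum number of valid trials required.
#' @param screen_factor candidate starts drawn per restart slot.
#' @return A `dynaprl_fit` list: `model_id`, `params`, `nll`, `n_obs`,
#'   `n_params`, `bic`, `n_restarts`, `converged`.
#' @export
fit_session <- function(trials, model_id, n_restarts = 10, min_trials = 20,
                        screen_factor = 5) {
  info <- model_info(model_id)
  d <- prepare_trials(trials)
  n_obs <- length(d$choice)
  if (n_obs < min_trials) {
    stop("session has ", n_obs, " valid trials; need >= ", min_trials)
  }

  objective <- function(par) {
    cpp_rl_nll(d$choice, d$outcome, d$session, info$code, par)
  }

  n_cand <- max(n_restarts, ceiling(screen_factor * n_restarts))
  cand <- matrix(runif(n_cand * info$n_params), n_cand, info$n_params,
                 byrow = TRUE)
  cand <- sweep(sweep(cand, 2, info$upper - info$lower, `*`),
                2, info$lower, `+`)
  cand_val <- apply(cand, 1, objective)
  cand <- cand[order(cand_val)[seq_len(n_restarts)], , drop = FALSE]

  best <- NULL
  n_ok <- 0L
  for (r in seq_len(n_restarts)) {
    start <- cand[r, ]
    fit <- tryCatch(
      optim(start, objective, method = "L-BFGS-B",
            lower = info$lower, upper = info$upper),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch({
        nm <- optim(start, function(p) {
          objective(pmin(pmax(p, info$lower), info$upper))
        }, method = "Nelder-Mead")
        nm$par <- pmin(pmax(nm$par, info$lower), info$upper)
        nm$convergence <- 1L
        nm
      }, error = function(e) NULL)
    }
    if (is.null(fit) || !is.finite(fit$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all restarts failed for model ", model_id)

  params <- setNames(as.numeric(best$par), info$par_names)
  structure(list(model_id = model_id, params = params, nll = best$value,
                 n_obs = n_obs, n_params = info$n_params,
                 bic = bic(best$value, info$n_params, n_obs),
                 n_restarts = n_restarts,
                 converged = n_ok == n_restarts && best$convergence == 0L),
            class = "dynaprl_fit")
}

#' @export
print.dynaprl_fit <- function(x, ...) {
  cat("RL model fit:", x$model_id, "\n")
  cat("  nLL =", format(x$nll, digits = 6), " BIC =",
      format(x$bic, digits = 6), " n =", x$n_obs,
      if (!x$converged) " [not fully converged]" else "", "\n")
  cat("  params:", paste(names(x$params), signif(x$params, 4),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Fit a model to every session of a trial table
#'
#' @param trials trial table possibly containing several sessions (and
#'   subjects, via a `subject_id` column).
#' @param model_id model identifier.
#' @param n_restarts random restarts per session.
#' @param min_trials minimum valid trials per session; shorter sessions are
#'   skipped with a message.
#' @return Data frame with one row per fitted session: identifiers,
#'   parameter estimates, `nll`, `n_obs` and `bic`.
#' @export
fit_sessions <- function(trials, model_id, n_restarts = 10, min_trials = 20) {
  has_subj <- "subject_id" %in% names(trials)
  key <- if (has_subj) paste(trials$subject_id, trials$session_id, sep = "\r")
         else as.character(trials$session_id)
  info <- model_info(model_id)
  rows <- lapply(unique(key), function(k) {
    tr <- trials[key == k, , drop = FALSE]
    n_valid <- sum(as.logical(tr$valid))
    if (n_valid < min_trials) {
      message("skipping session with ", n_valid, " valid trials")
      return(NULL)
    }
    fit <- fit_session(tr, model_id, n_restarts, min_trials)
    out <- data.frame(session_id = tr$session_id[1], model_id = model_id,
                      nll = fit$nll, n_obs = fit$n_obs, bic = fit$bic,
                      converged = fit$converged, stringsAsFactors = FALSE)
    if (has_subj) out <- cbind(subject_id = tr$subject_id[1], out)
    cbind(out, as.data.frame(as.list(fit$params)))
  })
  do.call(rbind, rows)
}

#' Compare models by session-level BIC
#'
#' Fits each model to every session and reports per-session BIC, and per
#' subject (or per dataset when no `subject_id` column exists) the mean
#' and summed BIC per model plus the winning model. Ties in mean BIC go to
#' the model with fewer parameters.
#'
#' @param trials trial table.
#' @param model_ids character vector of at least one model identifier.
#' @param n_restarts random restarts per session fit.
#' @param min_trials minimum valid trials per session.
#' @return List with `session_bic` (long data frame), `subject_summary`
#'   (mean/sum BIC per subject x model), and, when more than one model is
#'   supplied, `winners` (per-subject winning model) and `winner_counts`.
#' @export
compare_models <- function(trials, model_ids, n_restarts = 10,
                           min_trials = 20) {
  if (length(model_ids) < 1) stop("supply at least one model id")
  fits <- lapply(model_ids, function(m) {
    f <- fit_sessions(trials, m, n_restarts, min_trials)
    f[, intersect(c("subject_id", "session_id", "model_id", "nll", "n_obs",
                    "bic"), names(f))]
  })
  session_bic <- do.call(rbind, fits)
  if (!"subject_id" %in% names(session_bic)) session_bic$subject_id <- "all"

  agg <- aggregate(bic ~ subject_id + model_id, session_bic, mean)
  names(agg)[3] <- "mean_bic"
  agg$sum_bic <- aggregate(bic ~ subject_id + model_id, session_bic,
                           sum)$bic
  out <- list(session_bic = session_bic, subject_summary = agg)

  if (length(model_ids) >= 2) {
    n_par <- vapply(model_ids, function(m) model_info(m)$n_params, numeric(1))
    winners <- vapply(split(agg, agg$subject_id), function(g) {
      # parsimony tie-break: order by mean BIC, then by parameter count
      g <- g[order(g$mean_bic, n_par[g$model_id]), ]
      g$model_id[1]
    }, character(1))
    out$winners <- data.frame(subject_id = names(winners),
                              winner = unname(winners),
                              stringsAsFactors = FALSE)
    out$winner_counts <- table(factor(winners, levels = model_ids))
  }
  out
}

# ---- recovery experiments ----------------------------------------------

#' Generative regimes for the model-recovery experiment
#'
#' Parameter distributions used when simulating each model for the
#' generator-by-fitter confusion analysis. Regimes are chosen so that each
#' model's distinctive mechanism is behaviorally expressed (a large
#' history weight for the avgRPE model; a fast, strong reward trace for
#' the GRS model, with a negative trace weight so that reward history
#' sharpens rather than rescales the value contrast; pronounced valence
#' asymmetry for the five-parameter model) — a confusion analysis
#' evaluates the fitting machinery in regimes where the models are
#' distinguishable in principle.
#'
#' @return Named list per model of `means` and `sds` vectors.
#' @export
recovery_regimes <- function() {
  list(
    standard = list(means = c(alpha = 0.35, beta = 4),
                    sds = c(alpha = 0.10, beta = 0.8)),
    avgrpe = list(means = c(alpha = 0.35, beta = 4, hW = 0.55),
                  sds = c(alpha = 0.08, beta = 0.8, hW = 0.08)),
    grs = list(means = c(alpha = 0.40, beta = 4, alphaR = 0.50, wR = -0.90),
               sds = c(alpha = 0.08, beta = 0.8, alphaR = 0.08, wR = 0.04)),
    asym5 = list(means = c(alpha_pos = 0.45, alpha_neg = 0.20,
                           gamma_pos = 0.90, gamma_neg = 0.50, beta = 4),
                 sds = c(alpha_pos = 0.06, alpha_neg = 0.05,
                         gamma_pos = 0.04, gamma_neg = 0.08, beta = 0.8))
  )
}

#' Generator-by-fitter model-recovery confusion matrix
#'
#' Simulates `n_subjects` agents from each generating model (under
#' [recovery_regimes()]), fits all four models to every subject's
#' sessions, and counts the per-subject BIC winner.
#'
#' @param n_subjects synthetic subjects per generating model.
#' @param sessions,trials_per_session per-subject task exposure.
#' @param models models to simulate from and fit (default all four).
#' @param n_restarts restarts per session fit.
#' @return List with `confusion` (generator x winner count matrix) and
#'   `diagonally_dominant` (TRUE when every row's largest entry is on the
#'   diagonal).
#' @export
model_recovery <- function(n_subjects = 25, sessions = 2,
                           trials_per_session = 500,
                           models = model_ids(), n_restarts = 10) {
  regimes <- recovery_regimes()
  conf <- matrix(0L, length(models), length(models),
                 dimnames = list(generator = models, winner = models))
  for (g in models) {
    r <- regimes[[g]]
    spec <- cohort_spec(n_a = ceiling(n_subjects / 2),
                        n_b = floor(n_subjects / 2),
                        sessions = sessions,
                        trials_per_session = trials_per_session,
                        model_id = g, par_means = r$means, par_sds = r$sds,
                        par_deltas = setNames(rep(0, length(r$means)),
                                              names(r$means)),
                        invalid_rate = 0)
    coh <- generate_cohort(spec)
    cmp <- compare_models(coh$trials, models, n_restarts = n_restarts)
    conf[g, ] <- as.integer(cmp$winner_counts[models])
  }
  dom <- all(vapply(seq_along(models), function(i) {
    which.max(conf[i, ]) == i
  }, logical(1)))
  list(confusion = conf, diagonally_dominant = dom)
}

#' True-versus-recovered parameter correlation for the standard model
#'
#' Simulates sessions with parameters drawn uniformly from plausible
#' behavioral ranges, refits each session, and reports the Pearson
#' correlation between true and recovered parameters.
#'
#' @param n_sessions number of independent sessions.
#' @param trials_per_session trials per session.
#' @param alpha_range,beta_range generative parameter ranges.
#' @param n_restarts restarts per fit.
#' @return List with `r_alpha`, `r_beta` and the `table` of true and
#'   recovered values.
#' @export
parameter_recovery <- function(n_sessions = 100, trials_per_session = 400,
                               alpha_range = c(0.1, 0.8),
                               beta_range = c(1, 8), n_restarts = 10) {
  true_a <- runif(n_sessions, alpha_range[1], alpha_range[2])
  true_b <- runif(n_sessions, beta_range[1], beta_range[2])
  rec <- t(vapply(seq_len(n_sessions), function(i) {
    tr <- simulate_agent("standard", c(alpha = true_a[i], beta = true_b[i]),
                         n_sessions = 1,
                         trials_per_session = trials_per_session)
    fit_session(tr, "standard", n_restarts = n_restarts)$params
  }, numeric(2)))
  tab <- data.frame(true_alpha = true_a, true_beta = true_b,
                    fit_alpha = rec[, 1], fit_beta = rec[, 2])
  list(r_alpha = cor(tab$true_alpha, tab$fit_alpha),
       r_beta = cor(tab$true_beta, tab$fit_beta), table = tab)
}
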