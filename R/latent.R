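# Trial-by-trial latent-state analyses: the k-weighted RPE sweep, logistic
# regressions of stay/shift behavior on |avgRPE| and the reward trace, and
# the median-split interaction of the two.

#' Weighted blend of current and previous reward prediction error
#'
#' `wRPE_t = k * RPE_t + (1 - k) * RPE_{t-1}` with `k` in `[0.5, 1]`;
#' `k = 1` uses only the current trial's RPE. On the first trial of a
#' session the previous RPE is taken to be 0.
#'
#' @param rpe_t,rpe_prev current and previous RPE.
#' @param k current-trial weight in [0.5, 1].
#' @return The weighted RPE.
#' @export
#' @examples
#' weighted_rpe(1, -1, 0.8)  # 0.6
weighted_rpe <- function(rpe_t, rpe_prev, k) {
  if (any(k < 0.5 | k > 1)) stop("k must be in [0.5, 1]")
  k * rpe_t + (1 - k) * rpe_prev
}

# wRPE series for a whole table: previous RPE lagged within session.
wrpe_series <- function(rpe, session_key, k) {
  n <- length(rpe)
  prev <- c(0, rpe[-n])
  prev[c(TRUE, session_key[-1] != session_key[-n])] <- 0
  weighted_rpe(rpe, prev, k)
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x)) / s
}

# Binomial logistic regression slope of a binary response on a z-scored
# predictor. Returns NA coefficient for degenerate cells.
logit_slope <- function(y, x, min_events = 30) {
  ok <- is.finite(x) & !is.na(y)
  y <- y[ok]; x <- x[ok]
  if (length(y) < min_events || length(unique(y)) < 2) {
    return(list(coef = NA_real_, se = NA_real_, n = length(y),
                flagged = TRUE))
  }
  z <- zscore(x)
  if (all(is.na(z))) {
    return(list(coef = NA_real_, se = NA_real_, n = length(y),
                flagged = TRUE))
  }
  fit <- suppressWarnings(glm(y ~ z, family = binomial()))
  co <- summary(fit)$coefficients
  list(coef = unname(co["z", "Estimate"]), se = unname(co["z", "Std. Error"]),
       n = length(y), flagged = FALSE)
}

#' Sweep of the RPE-history weight k against stay/shift behavior
#'
#' For every `k` on the grid `[0.5, 1]` in steps of 0.025 (21 points),
#' builds the weighted RPE series from a standard-model latent trace,
#' z-scores it, and regresses the stay (on win trials) or shift (on loss
#' trials) indicator on it by binomial logistic regression. The best `k`
#' per behavior is the one with the largest absolute coefficient.
#'
#' @param trials trial table (valid trials, chronological).
#' @param latent latent trace aligned to the valid trials, as returned by
#'   `session_nll(..., with_trace = TRUE)$trace` for the standard model
#'   (only the `rpe` column is used).
#' @param k_grid grid of weights.
#' @param min_events minimum events per class before a cell is flagged.
#' @return List of class `dynaprl_ksweep`: `grid` (data.frame with `k`,
#'   `coef_ws`, `coef_ls`, event counts), `best_k_ws`, `best_k_ls`.
#' @export
k_sweep <- function(trials, latent, k_grid = seq(0.5, 1, by = 0.025),
                    min_events = 30) {
  ev <- stay_events_with_predictor(trials, latent$rpe)
  win <- ev$outcome_class == "win"
  rows <- lapply(k_grid, function(k) {
    w <- wrpe_series(ev$pred, ev$sess, k)
    ws <- logit_slope(ev$stay[win], w[win], min_events)
    ls <- logit_slope(1 - ev$stay[!win], w[!win], min_events)
    data.frame(k = k, coef_ws = ws$coef, n_ws = ws$n,
               coef_ls = ls$coef, n_ls = ls$n)
  })
  grid <- do.call(rbind, rows)
  best <- function(co) {
    if (all(is.na(co))) NA_real_ else grid$k[which.max(abs(co))]
  }
  structure(list(grid = grid, best_k_ws = best(grid$coef_ws),
                 best_k_ls = best(grid$coef_ls)),
            class = "dynaprl_ksweep")
}

# Align trials with a latent predictor and build the stay indicator.
# Returns one row per trial with a successor in the same session.
stay_events_with_predictor <- function(trials, predictor) {
  if ("valid" %in% names(trials)) {
    keep <- as.logical(trials$valid)
    trials <- trials[keep, , drop = FALSE]
  }
  if (nrow(trials) != length(predictor)) {
    stop("latent trace is not aligned with the valid trials (",
         nrow(trials), " vs ", length(predictor), ")")
  }
  has_subj <- "subject_id" %in% names(trials)
  sess <- if (has_subj) paste(trials$subject_id, trials$session_id,
                              sep = "\r")
          else as.character(trials$session_id)
  n <- nrow(trials)
  cur <- which(seq_len(n) < n & sess[pmin(seq_len(n) + 1L, n)] == sess)
  better <- as.character(trials$better_action[cur])
  data.frame(
    sess = sess[cur],
    pred = predictor[cur],
    stay = as.integer(as.character(trials$choice[cur]) ==
                        as.character(trials$choice[cur + 1L])),
    outcome_class = ifelse(trials$outcome[cur] == 1, "win", "loss"),
    phase = ifelse(trials$block_trial_index[cur] <= EARLY_PHASE_TRIALS,
                   "early", "late"),
    block_type = as.character(trials$block_type[cur]),
    action_class = ifelse(better == "none", "none",
                          ifelse(as.character(trials$choice[cur]) == better,
                                 "better", "worse")),
    stringsAsFactors = FALSE)
}

#' Logistic regression of stay/shift behavior on a latent predictor
#'
#' Regresses the trial-by-trial win-stay (or lose-shift) indicator on a
#' z-scored latent quantity — the unsigned averaged RPE from the avgRPE
#' model or the reward trace (global reward state) from the GRS model —
#' within strata. Following the analysis the machinery was built for, the
#' default restricts to better actions in the late phase, stratified by
#' block type.
#'
#' @param trials trial table.
#' @param latent latent trace aligned to the valid trials (from the
#'   appropriate fitted model).
#' @param predictor `"abs_avgrpe"` or `"rtrace"`.
#' @param outcome `"WS"` (stay on win trials) or `"LS"` (shift on loss
#'   trials).
#' @param action_class,phase restriction filters (`NULL` to keep all).
#' @param stratify_by stratifier columns (default block type).
#' @param min_events minimum events per stratum.
#' @return Data frame with the strata, `coef` (log-odds slope per SD of
#'   the predictor), `se`, `n`, `flagged`.
#' @export
latent_choice_correlation <- function(trials, latent,
                                      predictor = c("abs_avgrpe", "rtrace"),
                                      outcome = c("WS", "LS"),
                                      action_class = "better",
                                      phase = "late",
                                      stratify_by = "block_type",
                                      min_events = 30) {
  predictor <- match.arg(predictor)
  outcome <- match.arg(outcome)
  ev <- stay_events_with_predictor(trials, latent[[predictor]])
  if (!is.null(action_class)) ev <- ev[ev$action_class %in% action_class, ]
  if (!is.null(phase)) ev <- ev[ev$phase %in% phase, ]
  ev <- if (outcome == "WS") {
    transform(ev[ev$outcome_class == "win", ], y = stay)
  } else {
    transform(ev[ev$outcome_class == "loss", ], y = 1 - stay)
  }
  key <- if (length(stratify_by)) {
    interaction(ev[stratify_by], drop = TRUE, sep = "\r", lex.order = TRUE)
  } else factor(rep("all", nrow(ev)))
  rows <- lapply(levels(key), function(kk) {
    e <- ev[key == kk, , drop = FALSE]
    fit <- logit_slope(e$y, e$pred, min_events)
    out <- if (length(stratify_by)) e[1, stratify_by, drop = FALSE]
           else data.frame(stratum = "all")
    out$outcome <- outcome; out$predictor <- predictor
    out$coef <- fit$coef; out$se <- fit$se; out$n <- fit$n
    out$flagged <- fit$flagged
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median-split interaction of reward state and uncertainty
#'
#' Restricts to better-action late-phase win trials, median-splits the
#' reward trace (GRS) and the unsigned averaged RPE within the analyzed
#' set, and reports the win-stay probability in each of the four cells.
#' Ties at the median go to the "low" cell.
#'
#' @param trials trial table.
#' @param latent_avgrpe latent trace from the fitted avgRPE model
#'   (supplies `abs_avgrpe`).
#' @param latent_grs latent trace from the fitted GRS model (supplies
#'   `rtrace`).
#' @param by_block_type split separately within each block type.
#' @param min_cell cells with fewer trials are flagged.
#' @return Data frame with (optionally `block_type`,) `grs_level`,
#'   `avgrpe_level`, `p_ws`, `n`, `flagged`.
#' @export
median_split_interaction <- function(trials, latent_avgrpe, latent_grs,
                                     by_block_type = TRUE, min_cell = 10) {
  ev <- stay_events_with_predictor(trials, latent_avgrpe$abs_avgrpe)
  ev$grs <- stay_events_with_predictor(trials, latent_grs$rtrace)$pred
  ev <- ev[ev$action_class == "better" & ev$phase == "late" &
             ev$outcome_class == "win", , drop = FALSE]
  groups <- if (by_block_type) split(ev, ev$block_type) else list(all = ev)
  rows <- lapply(names(groups), function(g) {
    e <- groups[[g]]
    if (!nrow(e)) return(NULL)
    med_grs <- median(e$grs)
    med_unc <- median(e$pred)
    lev_grs <- ifelse(e$grs > med_grs, "high", "low")
    lev_unc <- ifelse(e$pred > med_unc, "high", "low")
    cells <- expand.grid(grs_level = c("high", "low"),
                         avgrpe_level = c("high", "low"),
                         stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- lev_grs == cells$grs_level[i] & lev_unc == cells$avgrpe_level[i]
      data.frame(grs_level = cells$grs_level[i],
                 avgrpe_level = cells$avgrpe_level[i],
                 p_ws = if (any(sel)) mean(e$stay[sel]) else NA_real_,
                 n = sum(sel), flagged = sum(sel) < min_cell,
                 stringsAsFactors = FALSE)
    }))
    if (by_block_type) cbind(block_type = g, out) else out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
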