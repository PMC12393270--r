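# Model-independent win-stay / lose-shift analyses.
#
# A trial is a "win-stay" if it was rewarded and the next valid trial in
# the same session repeats the choice; a "lose-shift" if it was
# unrewarded and the next choice differs. Probabilities are computed as
# pooled event counts over pooled win/loss counts (micro-average across
# sessions). The early phase of a block is its first 6 trials; the late
# phase runs from trial 7 to the block's end. Stay/shift pairs may span a
# block transition (the outcome trial determines the stratum) but never a
# session boundary.

EARLY_PHASE_TRIALS <- 6L

#' Classify every trial into a stay/shift event
#'
#' @param trials a trial table; invalid trials are removed before pairing,
#'   so events pair consecutive *valid* trials of a session.
#' @return Data frame with one row per trial that has a successor in the
#'   same session: `session_id`, `trial_index`, `block_type`,
#'   `outcome_class` (`"win"`/`"loss"`), `next_action_relation`
#'   (`"stay"`/`"shift"`), `phase` (`"early"`/`"late"`), `action_class`
#'   (`"better"`/`"worse"`/`"none"`), plus `subject_id` when present.
#' @export
#' @examples
#' tr <- data.frame(session_id = 1, trial_index = 1:4,
#'                  block_type = "HC", block_trial_index = 1:4,
#'                  choice = c("A1", "A1", "A2", "A2"),
#'                  outcome = c(1, 0, 1, 0),
#'                  better_action = "A1", valid = TRUE)
#' classify_events(tr)
classify_events <- function(trials) {
  if ("valid" %in% names(trials)) {
    trials <- trials[as.logical(trials$valid), , drop = FALSE]
  }
  n <- nrow(trials)
  if (n < 2) return(empty_events(trials))
  has_subj <- "subject_id" %in% names(trials)
  sess_key <- if (has_subj) paste(trials$subject_id, trials$session_id,
                                  sep = "\r")
              else as.character(trials$session_id)
  cur <- seq_len(n - 1)
  nxt <- cur + 1L
  keep <- sess_key[cur] == sess_key[nxt]
  cur <- cur[keep]; nxt <- nxt[keep]
  if (!length(cur)) return(empty_events(trials))

  better <- as.character(trials$better_action[cur])
  action_class <- ifelse(better == "none", "none",
                         ifelse(as.character(trials$choice[cur]) == better,
                                "better", "worse"))
  ev <- data.frame(
    session_id = trials$session_id[cur],
    trial_index = trials$trial_index[cur],
    block_type = as.character(trials$block_type[cur]),
    outcome_class = ifelse(trials$outcome[cur] == 1, "win", "loss"),
    next_action_relation = ifelse(as.character(trials$choice[cur]) ==
                                    as.character(trials$choice[nxt]),
                                  "stay", "shift"),
    phase = ifelse(trials$block_trial_index[cur] <= EARLY_PHASE_TRIALS,
                   "early", "late"),
    action_class = action_class,
    stringsAsFactors = FALSE)
  if (has_subj) ev <- cbind(subject_id = trials$subject_id[cur], ev)
  ev
}

empty_events <- function(trials) {
  ev <- data.frame(session_id = trials$session_id[0],
                   trial_index = integer(0), block_type = character(0),
                   outcome_class = character(0),
                   next_action_relation = character(0),
                   phase = character(0), action_class = character(0),
                   stringsAsFactors = FALSE)
  if ("subject_id" %in% names(trials)) {
    ev <- cbind(subject_id = trials$subject_id[0], ev)
  }
  ev
}

#' Stratified win-stay / lose-shift probabilities
#'
#' Pools event counts across sessions within each stratum first, then
#' divides: `p(WS) = #win-stays / #wins`, `p(LS) = #lose-shifts / #losses`.
#' Strata with zero denominator are reported as `NA` with their counts.
#'
#' @param events output of [classify_events()].
#' @param stratify_by character vector drawn from `"phase"`,
#'   `"block_type"`, `"action_class"`, `"subject_id"`; empty for overall
#'   probabilities.
#' @return Data frame with the stratifiers plus `n_win`, `n_ws`, `p_ws`,
#'   `n_loss`, `n_ls`, `p_ls`.
#' @export
summarize_stay_shift <- function(events, stratify_by = character(0)) {
  bad <- setdiff(stratify_by, c("phase", "block_type", "action_class",
                                "subject_id"))
  if (length(bad)) stop("unknown stratifier(s): ", paste(bad, collapse = ", "))
  if (!nrow(events)) {
    out <- events[, stratify_by, drop = FALSE]
    out$n_win <- integer(0); out$n_ws <- integer(0); out$p_ws <- numeric(0)
    out$n_loss <- integer(0); out$n_ls <- integer(0); out$p_ls <- numeric(0)
    return(out)
  }
  key <- if (length(stratify_by)) {
    interaction(events[stratify_by], drop = TRUE, sep = "\r", lex.order = TRUE)
  } else factor(rep("all", nrow(events)))
  rows <- lapply(levels(key), function(k) {
    e <- events[key == k, , drop = FALSE]
    win <- e$outcome_class == "win"
    n_win <- sum(win)
    n_ws <- sum(win & e$next_action_relation == "stay")
    n_loss <- sum(!win)
    n_ls <- sum(!win & e$next_action_relation == "shift")
    out <- if (length(stratify_by)) e[1, stratify_by, drop = FALSE]
           else data.frame(row.names = 1)
    out$n_win <- n_win; out$n_ws <- n_ws
    out$p_ws <- if (n_win > 0) n_ws / n_win else NA_real_
    out$n_loss <- n_loss; out$n_ls <- n_ls
    out$p_ls <- if (n_loss > 0) n_ls / n_loss else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Action-difference scores (better minus worse)
#'
#' Difference in stay/shift probability between the better and the worse
#' action within each (phase, block type) stratum; larger magnitudes mean
#' more asymmetric weighting of wins and losses between the two actions.
#'
#' @param events output of [classify_events()].
#' @return Data frame with `phase`, `block_type`, `d_ws`
#'   (`p_ws(better) - p_ws(worse)`) and `d_ls`.
#' @export
action_difference_scores <- function(events) {
  s <- summarize_stay_shift(events,
                            c("phase", "block_type", "action_class"))
  s <- s[s$action_class %in% c("better", "worse"), , drop = FALSE]
  keys <- unique(s[, c("phase", "block_type")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    g <- s[s$phase == keys$phase[i] & s$block_type == keys$block_type[i], ]
    b <- g[g$action_class == "better", ]
    w <- g[g$action_class == "worse", ]
    data.frame(phase = keys$phase[i], block_type = keys$block_type[i],
               d_ws = if (nrow(b) && nrow(w)) b$p_ws - w$p_ws else NA_real_,
               d_ls = if (nrow(b) && nrow(w)) b$p_ls - w$p_ls else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Perseveration curve around block transitions
#'
#' For each block transition, the probability (across transitions) that
#' the choice at a given trial offset equals the *pre-transition* better
#' action. Offsets `-n_pre..-1` are the last trials of the outgoing block;
#' offsets `1..n_post` are the first trials of the incoming block. For
#' transitions out of a no-contrast block one action is chosen at random
#' as "correct" (uses R's RNG).
#'
#' @param trials trial table.
#' @param n_pre,n_post window sizes (defaults 5 and 12).
#' @return Data frame with `offset`, `p_persev`, `n_blocks`.
#' @export
perseveration_curve <- function(trials, n_pre = 5, n_post = 12) {
  if ("valid" %in% names(trials)) {
    trials <- trials[as.logical(trials$valid), , drop = FALSE]
  }
  has_subj <- "subject_id" %in% names(trials)
  sess_key <- if (has_subj) paste(trials$subject_id, trials$session_id,
                                  sep = "\r")
              else as.character(trials$session_id)
  offsets <- c(seq.int(-n_pre, -1), seq.int(1, n_post))
  hits <- setNames(numeric(length(offsets)), offsets)
  counts <- setNames(numeric(length(offsets)), offsets)

  for (sk in unique(sess_key)) {
    tr <- trials[sess_key == sk, , drop = FALSE]
    n <- nrow(tr)
    # transition points: first row of each new block
    starts <- which(c(FALSE, tr$block_id[-1] != tr$block_id[-n]))
    for (st in starts) {
      prev_better <- as.character(tr$better_action[st - 1])
      if (prev_better == "none") prev_better <- sample(c("A1", "A2"), 1)
      for (i in seq_along(offsets)) {
        off <- offsets[i]
        idx <- if (off < 0) st + off else st + off - 1L
        if (idx < 1 || idx > n) next
        # pre-window must stay in the outgoing block, post-window in the new
        if (off < 0 && tr$block_id[idx] != tr$block_id[st - 1]) next
        if (off > 0 && tr$block_id[idx] != tr$block_id[st]) next
        counts[i] <- counts[i] + 1
        hits[i] <- hits[i] + (as.character(tr$choice[idx]) == prev_better)
      }
    }
  }
  data.frame(offset = offsets,
             p_persev = ifelse(counts > 0, hits / counts, NA_real_),
             n_blocks = as.integer(counts))
}
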