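# Independent oracles used by several test files. These deliberately
# re-derive quantities with plain, step-by-step R so they share no code
# with the package's implementation.

# Random mini-session generator for counting oracles.
random_mini_session <- function(session_id, n = NULL) {
  if (is.null(n)) n <- sample(2:20, 1)
  btype <- sample(c("HC", "LC", "NC"), 1)
  better <- if (btype == "NC") "none" else sample(c("A1", "A2"), 1)
  data.frame(session_id = session_id, trial_index = seq_len(n),
             block_id = 1L, block_type = btype,
             block_trial_index = seq_len(n),
             choice = sample(c("A1", "A2"), n, replace = TRUE),
             outcome = sample(0:1, n, replace = TRUE),
             reward_volume = 0, better_action = better,
             valid = runif(n) > 0.05, stringsAsFactors = FALSE)
}

# Brute-force stay/shift probabilities by explicit loops.
brute_force_ws_ls <- function(trials, phase = NULL, block_type = NULL,
                              action_class = NULL) {
  n_win <- 0L; n_ws <- 0L; n_loss <- 0L; n_ls <- 0L
  for (s in unique(trials$session_id)) {
    tr <- trials[trials$session_id == s & trials$valid, , drop = FALSE]
    if (nrow(tr) < 2) next
    for (i in seq_len(nrow(tr) - 1)) {
      ph <- if (tr$block_trial_index[i] <= 6) "early" else "late"
      ac <- if (tr$better_action[i] == "none") "none"
            else if (tr$choice[i] == tr$better_action[i]) "better"
            else "worse"
      if (!is.null(phase) && ph != phase) next
      if (!is.null(block_type) && tr$block_type[i] != block_type) next
      if (!is.null(action_class) && ac != action_class) next
      stay <- tr$choice[i + 1] == tr$choice[i]
      if (tr$outcome[i] == 1) {
        n_win <- n_win + 1L
        if (stay) n_ws <- n_ws + 1L
      } else {
        n_loss <- n_loss + 1L
        if (!stay) n_ls <- n_ls + 1L
      }
    }
  }
  list(n_win = n_win, n_ws = n_ws,
       p_ws = if (n_win > 0) n_ws / n_win else NA_real_,
       n_loss = n_loss, n_ls = n_ls,
       p_ls = if (n_loss > 0) n_ls / n_loss else NA_real_)
}

# Step-by-step standard-model session trace with scalar arithmetic.
hand_standard_trace <- function(choice, outcome, alpha, beta) {
  V <- c(0, 0)
  nll <- 0
  for (t in seq_along(choice)) {
    e1 <- exp(beta * V[1]); e2 <- exp(beta * V[2])
    p <- if (choice[t] == 1) e1 / (e1 + e2) else e2 / (e1 + e2)
    nll <- nll - log(p)
    rpe <- outcome[t] - V[choice[t]]
    V[choice[t]] <- V[choice[t]] + alpha * rpe
  }
  list(nll = nll, V = V)
}
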