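test_that("the four-trial example classifies as WS, LS, WS", {
  tr <- make_fixtures()$ws_ls_4trial
  ev <- classify_events(tr)
  expect_equal(nrow(ev), 3)  # last trial has no successor
  expect_equal(ev$outcome_class, c("win", "loss", "win"))
  expect_equal(ev$next_action_relation, c("stay", "shift", "stay"))
  s <- summarize_stay_shift(ev)
  expect_equal(s$p_ws, 1)  # 2 / 2
  expect_equal(s$p_ls, 1)  # 1 / 1
  expect_equal(s$n_win, 2)
  expect_equal(s$n_loss, 1)
})

test_that("degenerate sessions are handled without crashing", {
  # all rewarded, same choice: p_ws = 1, p_ls undefined
  tr <- data.frame(session_id = 1, trial_index = 1:5, block_id = 1,
                   block_type = "HC", block_trial_index = 1:5,
                   choice = "A1", outcome = 1, reward_volume = 33,
                   better_action = "A1", valid = TRUE)
  s <- summarize_stay_shift(classify_events(tr))
  expect_equal(s$p_ws, 1)
  expect_true(is.na(s$p_ls))
  expect_equal(s$n_loss, 0)
  # single-trial session yields no events
  expect_equal(nrow(classify_events(tr[1, ])), 0)
  # all-invalid session propagates to empty summaries
  allinv <- make_fixtures()$all_invalid
  ev <- classify_events(allinv)
  expect_equal(nrow(ev), 0)
  expect_equal(nrow(summarize_stay_shift(ev, "block_type")), 0)
})

test_that("pooled stratified probabilities match brute-force enumeration", {
  set.seed(20)
  sessions <- do.call(rbind, lapply(1:1000, random_mini_session))
  ev <- classify_events(sessions)
  # overall
  bf <- brute_force_ws_ls(sessions)
  s <- summarize_stay_shift(ev)
  expect_identical(c(s$n_win, s$n_ws, s$n_loss, s$n_ls),
                   c(bf$n_win, bf$n_ws, bf$n_loss, bf$n_ls))
  expect_equal(s$p_ws, bf$p_ws)
  expect_equal(s$p_ls, bf$p_ls)
  # every (phase, block, action) stratum
  s3 <- summarize_stay_shift(ev, c("phase", "block_type", "action_class"))
  for (i in seq_len(nrow(s3))) {
    bf <- brute_force_ws_ls(sessions, phase = s3$phase[i],
                            block_type = s3$block_type[i],
                            action_class = s3$action_class[i])
    expect_equal(s3$p_ws[i], bf$p_ws)
    expect_equal(s3$p_ls[i], bf$p_ls)
    expect_lte(s3$n_ws[i], s3$n_win[i])
    expect_lte(s3$n_ls[i], s3$n_loss[i])
  }
  # early + late counts add up to the stratum-free totals
  by_phase <- summarize_stay_shift(ev, "phase")
  expect_equal(sum(by_phase$n_win), s$n_win)
  expect_equal(sum(by_phase$n_loss), s$n_loss)
})

test_that("stay/shift classification is invariant to action relabeling", {
  set.seed(21)
  sessions <- do.call(rbind, lapply(1:100, random_mini_session))
  swapped <- sessions
  swapped$choice <- ifelse(sessions$choice == "A1", "A2", "A1")
  swapped$better_action <- ifelse(sessions$better_action == "none", "none",
                                  ifelse(sessions$better_action == "A1",
                                         "A2", "A1"))
  s1 <- summarize_stay_shift(classify_events(sessions),
                             c("phase", "block_type", "action_class"))
  s2 <- summarize_stay_shift(classify_events(swapped),
                             c("phase", "block_type", "action_class"))
  expect_equal(s1, s2)
})

test_that("asymmetric loss decay raises WS and lowers LS", {
  set.seed(22)
  asym <- simulate_agent("asym5", c(0.4, 0.4, 1, 0.5, 4), n_sessions = 15,
                         trials_per_session = 300)
  sym <- simulate_agent("asym5", c(0.4, 0.4, 1, 1, 4), n_sessions = 15,
                        trials_per_session = 300)
  sa <- summarize_stay_shift(classify_events(asym))
  ss <- summarize_stay_shift(classify_events(sym))
  expect_gt(sa$p_ws, ss$p_ws)
  expect_lt(sa$p_ls, ss$p_ls)
})

test_that("action-difference scores separate better from worse actions", {
  set.seed(23)
  perf <- simulate_agent("standard", c(alpha = 0.35, beta = 3),
                         n_sessions = 20, trials_per_session = 300)
  ev <- classify_events(perf)
  s <- summarize_stay_shift(ev, c("phase", "block_type", "action_class"))
  late_hc <- s[s$phase == "late" & s$block_type == "HC" &
                 s$action_class != "none", ]
  expect_gt(late_hc$p_ws[late_hc$action_class == "better"],
            late_hc$p_ws[late_hc$action_class == "worse"])
  expect_lt(late_hc$p_ls[late_hc$action_class == "better"],
            late_hc$p_ls[late_hc$action_class == "worse"])
  ads <- action_difference_scores(ev)
  row <- ads[ads$phase == "late" & ads$block_type == "HC", ]
  expect_gt(row$d_ws, 0)
  expect_lt(row$d_ls, 0)
})

test_that("perseveration curve matches agent style", {
  # an agent that never switches perseveres at 1.0 on every offset
  cfg <- task_config()
  set.seed(24)
  tr <- simulate_agent("standard", c(alpha = 1e-5, beta = 20),
                       n_sessions = 2, trials_per_session = 300)
  # with near-zero learning values stay equal; force constant choice
  tr$choice <- "A1"
  pc <- perseveration_curve(tr)
  hc_starts <- !is.na(pc$p_persev)
  # wherever the pre-transition block had a defined better action the
  # curve is 1 when that action was A1 and 0 otherwise; on average over
  # random sides it cannot dip below 0 — instead check a handmade table:
  hand <- data.frame(session_id = 1, trial_index = 1:8, block_id = rep(1:2, each = 4),
                     block_type = "HC", block_trial_index = rep(1:4, 2),
                     choice = "A1", outcome = 0, reward_volume = 0,
                     better_action = rep(c("A1", "A2"), each = 4),
                     valid = TRUE)
  pc2 <- perseveration_curve(hand, n_pre = 3, n_post = 4)
  expect_equal(pc2$p_persev[pc2$n_blocks > 0],
               rep(1, sum(pc2$n_blocks > 0)))
  # a random agent perseveres at chance
  set.seed(25)
  rnd <- simulate_agent("standard", c(alpha = 0.5, beta = 0),
                        n_sessions = 10, trials_per_session = 400)
  pc3 <- perseveration_curve(rnd)
  expect_true(all(abs(pc3$p_persev - 0.5) < 0.12))
  # a learning agent starts high and adapts below chance post-reversal
  set.seed(26)
  learner <- simulate_agent("standard", c(alpha = 0.5, beta = 6),
                            n_sessions = 30, trials_per_session = 300)
  pc4 <- perseveration_curve(learner)
  expect_gt(mean(pc4$p_persev[pc4$offset < 0]), 0.7)
  expect_lt(min(pc4$p_persev[pc4$offset > 0]), 0.5)
})
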