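test_that("block transitions honor the no-repeat constraints", {
  cfg <- task_config()
  set.seed(1)
  history <- list(draw_next_block(list(), cfg))
  for (i in 1:2000) {
    history[[i + 1]] <- draw_next_block(history, cfg)
  }
  types <- vapply(history, `[[`, character(1), "block_type")
  sides <- vapply(history, `[[`, character(1), "better_side")
  lens <- vapply(history, `[[`, integer(1), "scheduled_length")
  # no NC -> NC
  expect_false(any(types[-1] == "NC" & types[-length(types)] == "NC"))
  # better side never repeats across consecutive contrast blocks
  contrast <- sides != "none"
  rep_side <- sides[-1] == sides[-length(sides)] &
    contrast[-1] & contrast[-length(sides)]
  expect_false(any(rep_side))
  # scheduled length spans exactly [15, 30] and is close to uniform
  expect_equal(range(lens), c(15L, 30L))
  chi <- chisq.test(table(factor(lens, levels = 15:30)))
  expect_gt(chi$p.value, 0.01)
})

test_that("draw_next_block after a neutral block yields a contrast block", {
  cfg <- task_config()
  set.seed(2)
  nc <- block_spec("NC", "none", 20, cfg)
  for (i in 1:50) {
    expect_true(draw_next_block(list(nc), cfg)$block_type %in% c("HC", "LC"))
  }
  hc_left <- block_spec("HC", "left", 20, cfg)
  for (i in 1:50) {
    nxt <- draw_next_block(list(hc_left), cfg)
    # a neutral block may follow; a contrast block must flip sides
    if (nxt$better_side != "none") expect_identical(nxt$better_side, "right")
  }
  expect_error(draw_next_block(list(), task_config(block_menu = list())),
               "menu")
})

test_that("trial outcomes follow the block reward probabilities", {
  cfg <- task_config()
  set.seed(3)
  hc <- block_spec("HC", "left", 20, cfg)
  out <- replicate(10000, step_trial(hc, "A1", 1, cfg)$outcome)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.8) / 10000
  expect_gt(mean(out), ci[1])
  expect_lt(mean(out), ci[2])
  nc <- block_spec("NC", "none", 20, cfg)
  out_nc1 <- replicate(4000, step_trial(nc, "A1", 1, cfg)$outcome)
  out_nc2 <- replicate(4000, step_trial(nc, "A2", 1, cfg)$outcome)
  expect_equal(mean(c(out_nc1, out_nc2)), 0.45, tolerance = 0.025)
})

test_that("reward magnitude manipulation kicks in late in contrast blocks", {
  cfg <- task_config()
  set.seed(4)
  hc <- block_spec("HC", "left", 20, cfg)
  vols <- replicate(8000, step_trial(hc, "A1", 20, cfg)$reward_volume)
  vols <- vols[vols > 0]
  expect_true(all(vols %in% c(16, 33, 66)))
  expect_equal(mean(vols != 33), 0.40, tolerance = 0.03)
  expect_equal(mean(vols == 16), mean(vols == 66), tolerance = 0.03)
  # before onset, and in neutral blocks, volume is always standard
  early <- replicate(500, step_trial(hc, "A1", 12, cfg)$reward_volume)
  expect_true(all(early %in% c(0, 33)))
  nc <- block_spec("NC", "none", 20, cfg)
  nc_late <- replicate(500, step_trial(nc, "A1", 25, cfg)$reward_volume)
  expect_true(all(nc_late %in% c(0, 33)))
  # losses carry zero volume
  expect_true(all(vols != 0))
  expect_error(step_trial(hc, "A1", 0, cfg), "block_trial_index")
})

test_that("scheduled transitions defer during consecutive-error runs", {
  cfg <- task_config()
  blk <- block_spec("HC", "left", 15, cfg)
  expect_false(maybe_transition(blk, 14, rep(TRUE, 14), cfg))
  expect_true(maybe_transition(blk, 15, rep(TRUE, 15), cfg))
  # four consecutive errors at schedule end: deferred in contrast blocks
  expect_false(maybe_transition(blk, 15, c(rep(TRUE, 11), rep(FALSE, 4)), cfg))
  # three errors do not defer
  expect_true(maybe_transition(blk, 15, c(rep(TRUE, 12), rep(FALSE, 3)), cfg))
  # neutral blocks never defer
  nc <- block_spec("NC", "none", 15, cfg)
  expect_true(maybe_transition(nc, 15, rep(FALSE, 15), cfg))
  # the rule can be disabled
  cfg_off <- task_config(error_rule = "none")
  expect_true(maybe_transition(blk, 15, rep(FALSE, 15), cfg_off))
  expect_error(maybe_transition(blk, 0, logical(0), cfg), "trials_elapsed")
})

test_that("simulated sessions partition into contiguous blocks", {
  set.seed(5)
  tr <- simulate_agent("standard", c(0.4, 3), n_sessions = 3,
                       trials_per_session = 400)
  for (s in unique(tr$session_id)) {
    one <- tr[tr$session_id == s, ]
    expect_equal(one$trial_index, seq_len(nrow(one)))
    # block ids are non-decreasing and block_trial_index restarts at 1
    expect_true(all(diff(one$block_id) %in% c(0L, 1L)))
    for (b in unique(one$block_id)) {
      expect_equal(one$block_trial_index[one$block_id == b],
                   seq_len(sum(one$block_id == b)))
    }
  }
  # a deferral-free run never exceeds max_len
  cfg_off <- task_config(error_rule = "none")
  set.seed(6)
  tr2 <- simulate_agent("standard", c(0.4, 3), cfg_off, n_sessions = 2,
                        trials_per_session = 400)
  lens <- table(paste(tr2$session_id, tr2$block_id))
  expect_true(all(lens <= 30))
})

test_that("identical seeds reproduce identical trial tables", {
  set.seed(99)
  a <- simulate_agent("asym5", c(0.4, 0.3, 0.9, 0.7, 4), n_sessions = 2,
                      trials_per_session = 100)
  set.seed(99)
  b <- simulate_agent("asym5", c(0.4, 0.3, 0.9, 0.7, 4), n_sessions = 2,
                      trials_per_session = 100)
  expect_identical(a, b)
})

test_that("PRL training sessions reverse after sustained performance", {
  set.seed(7)
  # fast, exploitative learner: reaches the threshold and reverses
  tr <- run_prl_session("standard", c(alpha = 0.7, beta = 15),
                        n_trials = 400)
  expect_gt(max(tr$block_id), 1)
  # reversals only after runs of correct choices; blocks are contiguous
  expect_true(all(diff(tr$block_id) %in% c(0L, 1L)))
  # per-trial reversal probability near 0.10 once eligible: with a strong
  # agent most post-threshold trials are eligible, so block lengths after
  # the first approximate 8 (re-learn) + geometric(0.1) truncated at 20
  n_rev <- max(tr$block_id) - 1
  expect_gt(n_rev, 5)
  # the better action label flips at each reversal
  flips <- tapply(tr$better_action, tr$block_id, function(x) unique(x))
  expect_true(all(flips[-1] != flips[-length(flips)]))
})
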