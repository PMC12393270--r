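test_that("softmax choice probabilities behave as a softmax should", {
  expect_equal(softmax_choice_prob(c(0, 0), 5), c(0.5, 0.5))
  expect_equal(softmax_choice_prob(c(5, -3), 0), c(0.5, 0.5))
  p <- softmax_choice_prob(c(1, 0), 2)
  expect_equal(p[1], exp(2) / (exp(2) + 1), tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.8808, 0.1192))
  # translation invariance and normalization
  expect_equal(softmax_choice_prob(c(1, 0) + 17, 2), p, tolerance = 1e-12)
  expect_equal(sum(softmax_choice_prob(rnorm(2), runif(1, 0, 10))), 1,
               tolerance = 1e-12)
  expect_error(softmax_choice_prob(c(Inf, 0), 1), "finite")
})

test_that("single-trial updates match hand-evaluated values", {
  u <- standard_update(c(0, 0), choice = 1, R = 1, alpha = 0.5)
  expect_equal(u$rpe, 1)
  expect_equal(u$V, c(0.5, 0))
  u <- standard_update(c(0.5, 0.2), choice = 1, R = 0, alpha = 0.2)
  expect_equal(u$rpe, -0.5)
  expect_equal(u$V, c(0.4, 0.2))
  expect_error(standard_update(c(0, 0), 1, 1, alpha = 1.2), "alpha")

  # averaged-RPE recursion: forced RPE = 1 twice gives 0.5 then 0.75
  u1 <- avg_rpe_update(c(0, 0), 0, choice = 1, R = 1, alpha = 0.5, hW = 0.5)
  expect_equal(u1$avgrpe, 0.5)
  u2 <- avg_rpe_update(c(0, 0), u1$avgrpe, choice = 1, R = 1,
                       alpha = 0.5, hW = 0.5)
  expect_equal(u2$avgrpe, 0.75)
  # zero-RPE fixed point freezes values
  u3 <- avg_rpe_update(c(1, 0), 0, choice = 1, R = 1, alpha = 0.3, hW = 0.5)
  expect_equal(u3$avgrpe, 0)
  expect_equal(u3$V, c(1, 0))
  expect_error(avg_rpe_update(c(0, 0), 0, 1, 1, 0.5, hW = 0.9), "hW")

  # reward-trace recursion limits
  g <- grs_update(c(0, 0), 0.4, R_prev = 1, choice = 1, R = 1,
                  alpha = 0.3, alphaR = 1, wR = 0.5)
  expect_equal(g$rtrace, 1)   # one-back tracking
  g <- grs_update(c(0, 0), 0.4, R_prev = 1, choice = 1, R = 1,
                  alpha = 0.3, alphaR = 0, wR = 0.5)
  expect_equal(g$rtrace, 0.4) # frozen trace
  # two rewards under alphaR = 0.5: 0 -> 0.5 -> 0.75
  g1 <- grs_update(c(0, 0), 0, NA, 1, 1, 0.3, 0.5, 0.5, first_trial = TRUE)
  g2 <- grs_update(g1$V, g1$rtrace, 1, 1, 1, 0.3, 0.5, 0.5)
  g3 <- grs_update(g2$V, g2$rtrace, 1, 1, 0, 0.3, 0.5, 0.5)
  expect_equal(c(g1$rtrace, g2$rtrace, g3$rtrace), c(0, 0.5, 0.75))

  # asymmetric updates, win and loss branches
  a <- asym_update(c(0, 0.5), choice = 1, R = 1, alpha_pos = 0.6,
                   alpha_neg = 0.2, gamma_pos = 0.8, gamma_neg = 0.5)
  expect_equal(a$V, c(0.6, 0.4))
  a <- asym_update(c(0.5, 0.5), choice = 1, R = 0, alpha_pos = 0.6,
                   alpha_neg = 0.2, gamma_pos = 0.8, gamma_neg = 0.5)
  expect_equal(a$V, c(0.4, 0.25))
})

test_that("session nLL matches an independent step-by-step trace", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 30
    tr <- data.frame(session_id = 1, trial_index = 1:n,
                     choice = sample(c("A1", "A2"), n, replace = TRUE),
                     outcome = sample(0:1, n, replace = TRUE), valid = TRUE)
    alpha <- runif(1, 0.1, 0.9); beta <- runif(1, 0.5, 6)
    oracle <- hand_standard_trace(match(tr$choice, c("A1", "A2")),
                                  tr$outcome, alpha, beta)
    got <- session_nll(tr, "standard", c(alpha, beta))
    expect_equal(got$nll, oracle$nll, tolerance = 1e-12)
    expect_equal(as.numeric(tail(got$trace, 1)[c("V1", "V2")]),
                 oracle$V, tolerance = 1e-12)
  }
})

test_that("session nLL limiting cases", {
  one <- data.frame(session_id = 1, choice = "A1", outcome = 1, valid = TRUE)
  expect_equal(session_nll(one, "standard", c(0.5, 3))$nll, log(2),
               tolerance = 1e-12)
  set.seed(2)
  n <- 57
  tr <- data.frame(session_id = 1,
                   choice = sample(c("A1", "A2"), n, replace = TRUE),
                   outcome = sample(0:1, n, replace = TRUE), valid = TRUE)
  expect_equal(session_nll(tr, "standard", c(0.5, 0))$nll, n * log(2),
               tolerance = 1e-10)
  expect_error(session_nll(tr[0, ], "standard", c(0.5, 1)), "valid")
})

test_that("generative agent and likelihood filter share one model", {
  # probability the filter assigns to simulated choices must match the
  # generative policy: high-beta agents earn low nLL at their own params
  set.seed(33)
  for (m in model_ids()) {
    pars <- switch(m, standard = c(0.4, 4), avgrpe = c(0.4, 4, 0.5),
                   grs = c(0.4, 4, 0.3, 0.6), asym5 = c(0.4, 0.3, 0.9, 0.7, 4))
    tr <- simulate_agent(m, pars, n_sessions = 2, trials_per_session = 150)
    res <- session_nll(tr, m, pars)
    expect_equal(nrow(res$trace), 300)
    expect_true(all(res$trace$p_choice > 0 & res$trace$p_choice < 1))
    # latent state resets per session: trace of both sessions separately
    # concatenates to the joint filter trace
    t1 <- session_nll(tr[tr$session_id == 1, ], m, pars)
    t2 <- session_nll(tr[tr$session_id == 2, ], m, pars)
    expect_equal(t1$nll + t2$nll, res$nll, tolerance = 1e-10)
    expect_equal(rbind(t1$trace, t2$trace), res$trace, tolerance = 1e-12)
  }
})

test_that("reward trace stays within [0,1] under binary rewards", {
  set.seed(4)
  tr <- simulate_agent("grs", c(0.5, 3, 0.7, 0.9), n_sessions = 3,
                       trials_per_session = 200)
  trace <- session_nll(tr, "grs", c(0.5, 3, 0.7, 0.9))$trace
  expect_true(all(trace$rtrace >= 0 & trace$rtrace <= 1))
})

test_that("parameter validation enforces model bounds", {
  expect_error(validate_params <- session_nll(
    data.frame(session_id = 1, choice = "A1", outcome = 1, valid = TRUE),
    "avgrpe", c(0.5, 3, 0.8)), "hW")
  expect_error(session_nll(
    data.frame(session_id = 1, choice = "A1", outcome = 1, valid = TRUE),
    "grs", c(0.5, 3, 0.5, 1.5)), "wR")
  expect_error(model_info("qlearn"), "unknown model_id")
})
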