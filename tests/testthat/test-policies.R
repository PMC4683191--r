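test_that("WSLS stays after wins and shifts after losses", {
  expect_equal(wsls_prob(history_state(1, 1), list(gamma_w = 0.91,
                                                   gamma_l = 0.5)), 0.91)
  expect_equal(wsls_prob(history_state(2, 0), list(gamma_w = 0.5,
                                                   gamma_l = 0.54)), 0.54)
  expect_equal(wsls_prob(history_state(), list(gamma_w = 1, gamma_l = 1)),
               0.5)
})

test_that("the count-state classifier covers every sign configuration", {
  cases <- list(
    list(S = c(0, 0), F = c(0, 0), want = "EQUAL"),
    list(S = c(2, 1), F = c(1, 1), want = "ARM1_BETTER"),
    list(S = c(2, 2), F = c(0, 1), want = "ARM1_BETTER"),
    list(S = c(1, 2), F = c(1, 1), want = "ARM2_BETTER"),
    list(S = c(1, 1), F = c(2, 0), want = "ARM2_BETTER"),
    list(S = c(3, 1), F = c(2, 0), want = "EXPLORE_EXPLOIT"),
    list(S = c(1, 3), F = c(0, 2), want = "EXPLORE_EXPLOIT"))
  for (cs in cases) {
    got <- classify_arm_state(history_state(S = cs$S, F = cs$F))
    expect_equal(got$state, cs$want)
  }
  ee <- classify_arm_state(history_state(S = c(3, 1), F = c(2, 0)))
  expect_equal(ee$exploit_arm, 1)
  expect_equal(ee$explore_arm, 2)
})

test_that("tau-Switch explores before tau and exploits after", {
  p <- list(gamma_tau = 0.9, tau = 5)
  expect_equal(tau_switch_prob(history_state(), 1, p), 0.5)
  expect_equal(tau_switch_prob(history_state(S = c(2, 1), F = c(1, 1)), 3, p),
               0.9)
  ee <- history_state(S = c(3, 1), F = c(2, 0))   # exploit = 1
  expect_equal(tau_switch_prob(ee, 2, p), 1 - 0.9)  # explore phase: arm 2
  expect_equal(tau_switch_prob(ee, 5, p), 0.9)      # t = tau: exploit
  expect_equal(tau_switch_prob(ee, 7, p), 0.9)
})

test_that("epsilon-Greedy picks the greater estimated rate", {
  expect_equal(epsilon_greedy_prob(0.7, 0.3, list(epsilon = 0.1)), 0.9)
  expect_equal(epsilon_greedy_prob(0.3, 0.7, list(epsilon = 0)), 0)
  expect_equal(epsilon_greedy_prob(0.5, 0.5, list(epsilon = 0.3)), 0.5)
})

test_that("Softmax interpolates random, matching and maximizing", {
  expect_equal(softmax_prob(0.6, 0.4, list(b = 1)), 0.6)
  expect_equal(softmax_prob(0.6, 0.4, list(b = 0)), 0.5)
  expect_equal(softmax_prob(0.6, 0.4, list(b = 2)), 0.36 / 0.52)
  expect_equal(softmax_prob(0, 0, list(b = 3)), 0.5)
  expect_gt(softmax_prob(0.6, 0.4, list(b = 50)), 0.999)
})

test_that("Softmax is monotone in the rate and in the exponent", {
  mus <- seq(0.05, 0.95, by = 0.05)
  p_of_mu <- sapply(mus, function(m) softmax_prob(m, 0.4, list(b = 2)))
  expect_true(all(diff(p_of_mu) > 0))
  bs <- seq(0, 10, by = 0.5)
  p_of_b <- sapply(bs, function(b) softmax_prob(0.6, 0.4, list(b = b)))
  expect_true(all(diff(p_of_b) > 0))
})

test_that("knowledge-gradient value matches hand enumeration and limits", {
  p1 <- dbm_params(1, 0.5)
  b <- make_generic_prior(p1, 2001)
  # Beta(2,2) both arms, gamma = 1: E[max(0.6, 0.5)]*0.5 + 0.5*max(0.4, 0.5)
  # - 0.5 = 0.05
  expect_equal(kg_value(b, 1, p1), 0.05, tolerance = 1e-4)
  expect_equal(kg_value(b, 1, p1), kg_value(b, 2, p1), tolerance = 1e-12)

  # no uncertainty: point masses on both arms -> zero value
  bp <- b
  bp$w[, ] <- 0; bp$w[1201, 1] <- 1; bp$w[801, 2] <- 1
  expect_equal(kg_value(bp, 1, p1), 0, tolerance = 1e-12)

  # gamma = 0: next-trial means are (r, r) regardless of outcome, with r
  # taken as the discretized generic prior's mean
  p0 <- dbm_params(0, 0.3)
  b2 <- make_generic_prior(dbm_params(0, 0.3), 501)
  r_disc <- sum(b2$grid * b2$q0)
  b2 <- bayes_update(b2, 1, 1)
  mu <- belief_means(b2)
  expect_equal(kg_value(b2, 1, p0), r_disc - max(mu), tolerance = 1e-10)
})

test_that("kg_value agrees with a brute-force two-outcome enumeration", {
  dbm <- dbm_params(0.7, 0.4)
  b <- make_generic_prior(dbm, 201)
  b <- bayes_update(b, 1, 1)
  b <- bayes_update(b, 2, 0)
  for (arm in 1:2) {
    mu <- sum(b$grid * b$w[, arm])
    oth <- 3 - arm
    nm <- function(out) {
      lik <- if (out == 1) b$grid else 1 - b$grid
      w_ch <- b$w[, arm] * lik
      w_ch <- w_ch / sum(w_ch)
      w_ch <- dbm$gamma * w_ch + (1 - dbm$gamma) * b$q0
      w_ot <- dbm$gamma * b$w[, oth] + (1 - dbm$gamma) * b$q0
      max(sum(b$grid * w_ch), sum(b$grid * w_ot))
    }
    want <- mu * nm(1) + (1 - mu) * nm(0) - max(sum(b$grid * b$w[, 1]),
                                                sum(b$grid * b$w[, 2]))
    expect_equal(kg_value(b, arm, dbm), want, tolerance = 1e-8)
  }
})

test_that("KG choice rule uses the horizon-clamped score", {
  dbm <- dbm_params(1, 0.5)
  b <- bayes_update(make_generic_prior(dbm, 501), 1, 1)  # mu1 > mu2
  # last trial: horizon weight 0, KG arm = greedy arm
  expect_equal(kg_prob(b, t = 16, T_horizon = 16, dbm,
                       list(gamma_kg = 0.9)), 0.9)
  expect_equal(kg_prob(b, t = 16, T_horizon = 16, dbm, list(gamma_kg = 1)), 1)
  expect_equal(kg_prob(b, t = 2, T_horizon = 16, dbm, list(gamma_kg = 0.5)),
               0.5)
})

test_that("choice probabilities are proper and policies dispatch correctly", {
  dbm <- dbm_params(0.6, 0.4)
  b <- bayes_update(make_generic_prior(dbm, 301), 2, 1)
  hist <- history_state(2, 1, S = c(0, 1), F = c(0, 0))
  specs <- list(policy_spec("WSLS", gamma_w = 0.9, gamma_l = 0.8),
                policy_spec("EPS_GREEDY", epsilon = 0.2),
                policy_spec("TAU_SWITCH", gamma_tau = 0.8, tau = 4),
                policy_spec("SOFTMAX", b = 3),
                policy_spec("KG", gamma_kg = 0.85))
  for (sp in specs) {
    p <- policy_choice_prob(sp, b, hist, t = 3, T_horizon = 16, dbm)
    expect_gte(p, 0); expect_lte(p, 1)
  }
  expect_equal(policy_choice_prob(specs[[4]], b, hist, 3, 16, dbm),
               softmax_prob(belief_means(b)[1], belief_means(b)[2],
                            list(b = 3)))
})

test_that("WSLS and tau-Switch ignore the belief state", {
  dbm <- dbm_params(0.6, 0.4)
  b1 <- make_generic_prior(dbm, 101)
  b2 <- bayes_update(bayes_update(b1, 1, 1), 1, 1)   # perturbed beliefs
  hist <- history_state(1, 1, S = c(2, 0), F = c(0, 0))
  for (sp in list(policy_spec("WSLS", gamma_w = 0.7, gamma_l = 0.6),
                  policy_spec("TAU_SWITCH", gamma_tau = 0.8, tau = 4))) {
    expect_identical(policy_choice_prob(sp, b1, hist, 4, 16, dbm),
                     policy_choice_prob(sp, b2, hist, 4, 16, dbm))
  }
})

test_that("at the final trial KG ranks arms like epsilon-Greedy", {
  dbm <- dbm_params(0.8, 0.3)
  set.seed(5)
  for (i in 1:10) {
    b <- make_generic_prior(dbm, 201)
    for (k in 1:4) b <- bayes_update(b, sample(2, 1), rbinom(1, 1, 0.5))
    mu <- belief_means(b)
    if (abs(mu[1] - mu[2]) < 1e-9) next
    kg_pick <- kg_prob(b, 16, 16, dbm, list(gamma_kg = 1))
    greedy_pick <- epsilon_greedy_prob(mu[1], mu[2], list(epsilon = 0))
    expect_equal(kg_pick, greedy_pick)
  }
})

test_that("policy specifications validate their parameters", {
  expect_error(policy_spec("WSLS", gamma_w = 0.9), "gamma_l")
  expect_error(policy_spec("SOFTMAX", b = -1), "b must be")
  expect_error(policy_spec("EPS_GREEDY", epsilon = 1.2), "epsilon")
  expect_error(policy_spec("TAU_SWITCH", gamma_tau = 0.5, tau = 2.5), "tau")
  expect_error(policy_spec("NOPE", x = 1))
})
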