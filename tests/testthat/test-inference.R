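dbm65 <- dbm_params(0.6, 0.5)

test_that("degenerate parameter settings give exactly N log(1/2)", {
  d <- generate_fixture(seed = 2)
  n <- nrow(d)
  expect_equal(subject_policy_loglik(d, policy_spec("SOFTMAX", b = 0),
                                     dbm65, 201), n * log(0.5))
  expect_equal(subject_policy_loglik(d, policy_spec("WSLS", gamma_w = 0.5,
                                                    gamma_l = 0.5),
                                     dbm65, 201), n * log(0.5))
})

test_that("the softmax likelihood matches a trial-by-trial oracle", {
  d <- generate_fixture(seed = 1)
  mu <- oracle_belief_means(d, 0.6, 0.5, grid_size = 1001)
  b <- 2
  p1 <- mu[, 1]^b / (mu[, 1]^b + mu[, 2]^b)
  want <- sum(log(ifelse(d$choice == 1, p1, 1 - p1)))
  got <- subject_policy_loglik(d, policy_spec("SOFTMAX", b = 2), dbm65, 1001)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("WSLS marginal equals the closed-form polynomial integral", {
  # 1 game x 3 trials: win then stay, loss then stay.
  # L(gw, gl) = 0.5 * gw * (1 - gl); integral over the unit square = 1/8
  d <- hand_dataset(choice = c(1L, 1L, 1L), reward = c(1L, 0L, 1L))
  got <- integrate_policy(d, "WSLS", dbm65, inference_config(grid_size = 101))
  expect_equal(got, 0.5 * (1 / 2) * (1 / 2), tolerance = 1e-10)

  # 1 game x 2 trials, win then shift: L = 0.5 * (1 - gw) -> 1/4
  d2 <- hand_dataset(choice = c(1L, 2L), reward = c(1L, 0L))
  expect_equal(integrate_policy(d2, "WSLS", dbm65,
                                inference_config(grid_size = 101)),
               0.25, tolerance = 1e-10)
})

test_that("a policy with constant likelihood integrates to that constant", {
  # single-trial games: every policy's choice probability is 0.5 everywhere
  d <- hand_dataset(choice = c(1L, 2L, 1L), reward = c(1L, 0L, 1L),
                    n_trials = 1)
  cfg <- inference_config(grid_size = 101)
  for (pid in c("WSLS", "EPS_GREEDY", "TAU_SWITCH", "SOFTMAX", "KG"))
    expect_equal(integrate_policy(d, pid, dbm65, cfg), 0.5^3,
                 tolerance = 1e-9)
})

test_that("quadrature marginals match Monte-Carlo prior integration", {
  a <- agent_spec("s", "G", dbm_params(0.6, 0.4),
                  policy_spec("SOFTMAX", b = 4))
  d <- simulate_subject(a, task_config(n_games = 6, n_trials = 8), seed = 3)
  dbm <- dbm_params(0.6, 0.4)
  cfg <- inference_config(grid_size = 501)
  for (pid in c("WSLS", "EPS_GREEDY", "TAU_SWITCH", "SOFTMAX", "KG")) {
    mc <- mc_integrate(d, pid, dbm, n_draws = 2000, seed = 11,
                       grid_size = 501)
    quad <- integrate_policy(d, pid, dbm, cfg, log = TRUE)
    quad_w <- exp(quad - mc$scale)
    expect_lt(abs(quad_w - mc$mean_w), 3 * mc$se_w)
  }
})

test_that("the subject marginal averages the five policies", {
  d <- generate_fixture(seed = 4)
  cfg <- inference_config(grid_size = 201)
  per <- sapply(c("WSLS", "EPS_GREEDY", "TAU_SWITCH", "SOFTMAX", "KG"),
                function(p) integrate_policy(d, p, dbm65, cfg))
  got <- subject_marginal(d, dbm65, cfg)
  expect_equal(got, mean(per), tolerance = 1e-12)
  expect_gte(got, max(per) / 5)
  expect_lte(got, max(per))
})

test_that("group surfaces add per-subject log marginals", {
  d <- generate_fixture(seed = 5)
  cfg <- inference_config(gamma_grid = c(0.2, 0.6, 1), r_grid = c(0.3, 0.7),
                          grid_size = 201)
  one <- grid_search_group(list(d), cfg)
  d2 <- d; d2$subject_id <- "copy"
  three <- grid_search_group(list(d, d2, d), cfg)
  expect_equal(three$loglik, 3 * one$loglik, tolerance = 1e-9)
  # surface entries equal direct subject marginals
  for (i in seq_along(cfg$gamma_grid)) for (j in seq_along(cfg$r_grid)) {
    expect_equal(one$loglik[i, j],
                 subject_marginal(d, dbm_params(cfg$gamma_grid[i],
                                                cfg$r_grid[j]),
                                  cfg, log = TRUE), tolerance = 1e-9)
  }
})

test_that("estimates are invariant to subject order and arm relabeling", {
  cfg <- inference_config(gamma_grid = c(0.3, 0.6, 0.9),
                          r_grid = c(0.2, 0.5, 0.8), grid_size = 201)
  specs <- default_cohort_specs("G", n = 3)
  d <- simulate_cohort(specs, task_config(n_games = 3, n_trials = 6),
                       master_seed = 7)
  subs <- split(d, d$subject_id)
  s1 <- grid_search_group(subs, cfg)
  s2 <- grid_search_group(rev(subs), cfg)
  expect_equal(s1$loglik, s2$loglik, tolerance = 1e-10)
  flipped <- d
  flipped$choice <- 3 - flipped$choice
  s3 <- grid_search_group(flipped, cfg)
  expect_equal(s1$loglik, s3$loglik, tolerance = 1e-9)
})

test_that("surface moments are the lattice posterior's moments", {
  cfg <- inference_config()
  blank <- matrix(-1e6, 11, 11)
  surf <- structure(list(loglik = blank, gamma_grid = cfg$gamma_grid,
                         r_grid = cfg$r_grid), class = "grid_surface")
  # single-cell concentration
  s1 <- surf; s1$loglik[7, 4] <- 0   # gamma = 0.6, r = 0.3
  m1 <- surface_moments(s1)
  expect_equal(unname(m1$mean), c(0.6, 0.3))
  expect_equal(unname(m1$var), c(0, 0))
  # uniform surface
  s2 <- surf; s2$loglik[] <- -42
  m2 <- surface_moments(s2)
  expect_equal(unname(m2$mean), c(0.5, 0.5))
  # two equal cells at gamma 0.4 / 0.8: mean 0.6, var 0.04
  s3 <- surf; s3$loglik[c(5, 9), 6] <- 3.7
  m3 <- surface_moments(s3)
  expect_equal(unname(m3$mean[1]), 0.6)
  expect_equal(unname(m3$var[1]), 0.04)
})

test_that("group comparison builds the pooled two-sample CI", {
  cfg <- inference_config()
  base <- matrix(-1e6, 11, 11)
  mk <- function(cells, vals) {
    s <- structure(list(loglik = base, gamma_grid = cfg$gamma_grid,
                        r_grid = cfg$r_grid), class = "grid_surface")
    s$loglik[cells] <- vals
    s
  }
  sA <- mk(cbind(c(5, 9), c(6, 6)), c(0, 0))  # gamma in {0.4, 0.8}
  sB <- mk(cbind(c(3, 7), c(6, 6)), c(0, 0))  # gamma in {0.2, 0.6}
  ci <- compare_groups_dbm(sA, sB, 16, 16)
  g <- ci[ci$parameter == "gamma", ]
  # means 0.6 vs 0.4, both variances 0.04, pooled SE = sqrt(0.04 * 2/16)
  expect_equal(g$diff, 0.2)
  expect_equal(g$se, sqrt(0.04 * 2 / 16), tolerance = 1e-12)
  expect_equal(g$df, 30)
  expect_equal(round(g$t_crit, 2), 2.04)
  expect_equal(g$lower, 0.2 - g$t_crit * g$se)
  same <- compare_groups_dbm(sA, sA, 16, 16)
  expect_equal(same$diff, c(0, 0))
  expect_error(compare_groups_dbm(sA, sB, 1, 16), "n >= 2")
})

test_that("uninformative data yield a uniform policy posterior", {
  d <- hand_dataset(choice = c(1L, 2L, 2L, 1L), reward = c(1L, 0L, 1L, 0L),
                    n_trials = 1)   # all single-trial games
  asg <- assign_policy(d, dbm65, inference_config(grid_size = 101))
  expect_equal(unname(asg$posterior), rep(0.2, 5), tolerance = 1e-9)
  expect_equal(sum(asg$posterior), 1)
})

test_that("the moment-based KG likelihood agrees with the full-grid rule", {
  # the inference engine scores KG choices from belief moments; replaying
  # the subject with the enumeration-based kg_prob must give the same
  # per-trial probabilities
  d <- generate_fixture(seed = 8)
  dbm <- dbm_params(0.6, 0.4)
  spec <- policy_spec("KG", gamma_kg = 0.85)
  ll_engine <- subject_policy_loglik(d, spec, dbm, 401)
  grid_size <- 401
  prior <- make_generic_prior(dbm, grid_size)
  ll_point <- 0
  for (g in split(d, d$game)) {
    belief <- prior
    for (t in seq_len(nrow(g))) {
      if (t > 1) belief <- propagate_prior(belief, dbm)
      p1 <- kg_prob(belief, g$trial[t], max(g$trial), dbm, spec$params)
      p_obs <- if (g$choice[t] == 1) p1 else 1 - p1
      ll_point <- ll_point + log(max(p_obs, 1e-12))
      belief <- bayes_update(belief, g$choice[t], g$reward[t])
    }
  }
  expect_equal(ll_engine, ll_point, tolerance = 1e-8)
})

test_that("policy parameter MLEs match a dense grid scan", {
  d <- generate_fixture(seed = 6)
  cfg <- inference_config(grid_size = 201)
  fit <- fit_policy_params(d, "SOFTMAX", dbm65, cfg)
  bs <- seq(0, 20, by = 1e-3)
  lls <- vapply(bs, function(b)
    subject_policy_loglik(d, policy_spec("SOFTMAX", b = b), dbm65, 201),
    numeric(1))
  expect_gte(fit$loglik + 1e-6, max(lls))

  fitw <- fit_policy_params(d, "WSLS", dbm65, cfg)
  gw <- seq(0, 1, by = 1e-3)
  llw <- vapply(gw, function(g)
    subject_policy_loglik(d, policy_spec("WSLS", gamma_w = g,
                                         gamma_l = fitw$params$gamma_l),
                          dbm65, 201), numeric(1))
  expect_gte(fitw$loglik + 1e-6, max(llw))
})

test_that("anti-greedy choices drive the softmax MLE to the zero boundary", {
  # always choosing the believed-worse arm makes the likelihood decreasing
  # in b, so the MLE sits at b = 0 and is flagged
  n <- 16
  d <- hand_dataset(choice = c(1L, rep(2L, n - 1)),
                    reward = c(1L, rep(0L, n - 1)))
  fit <- fit_policy_params(d, "SOFTMAX", dbm_params(1, 0.5),
                           inference_config(grid_size = 201))
  expect_lt(fit$params$b, 1e-3)
  expect_true(fit$boundary)
})

test_that("WSLS parameters are recovered consistently on long records", {
  a <- agent_spec("w", "G", dbm_params(0.6, 0.5),
                  policy_spec("WSLS", gamma_w = 0.9, gamma_l = 0.5))
  d <- simulate_subject(a, task_config(n_games = 200, n_trials = 16),
                        seed = 21)
  fit <- fit_policy_params(d, "WSLS", dbm_params(0.6, 0.5),
                           inference_config(grid_size = 201))
  expect_lt(abs(fit$params$gamma_w - 0.9), 0.05)
  expect_lt(abs(fit$params$gamma_l - 0.5), 0.05)
})
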