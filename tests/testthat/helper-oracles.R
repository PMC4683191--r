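# Independent second implementations used as oracles. These are written as
# plain per-trial loops over explicit probability vectors, sharing only the
# documented discretization convention (cell masses from pbeta increments at
# midpoint boundaries) with the package implementation.

# Discretized Beta masses, coded independently.
oracle_beta_masses <- function(a, b, grid) {
  g <- length(grid)
  if (a <= 0) return(c(1, rep(0, g - 1)))
  if (b <= 0) return(c(rep(0, g - 1), 1))
  edges <- numeric(g + 1)
  edges[1] <- 0
  edges[g + 1] <- 1
  for (i in 2:g) edges[i] <- (grid[i - 1] + grid[i]) / 2
  m <- numeric(g)
  for (i in seq_len(g)) m[i] <- pbeta(edges[i + 1], a, b) - pbeta(edges[i], a, b)
  m / sum(m)
}

# Trial-wise prior means for one subject under the DBM, brute force.
oracle_belief_means <- function(data, gamma, r, grid_size,
                                prior_strength = 4) {
  grid <- seq(0, 1, length.out = grid_size)
  q0 <- oracle_beta_masses(prior_strength * r, prior_strength * (1 - r), grid)
  n <- nrow(data)
  mu <- matrix(NA_real_, n, 2)
  w <- list(q0, q0)
  for (i in seq_len(n)) {
    if (data$trial[i] == 1) {
      w <- list(q0, q0)
    } else {
      for (m in 1:2) w[[m]] <- gamma * w[[m]] + (1 - gamma) * q0
    }
    for (m in 1:2) mu[i, m] <- sum(grid * w[[m]])
    ch <- data$choice[i]
    lik <- if (data$reward[i] == 1) grid else 1 - grid
    new_w <- w[[ch]] * lik
    if (sum(new_w) > 0) w[[ch]] <- new_w / sum(new_w)
  }
  mu
}

# Conjugate Beta posterior prior-means (the gamma = 1 closed form): on each
# trial the prior mean for arm m is (a0 + S_m) / (a0 + b0 + S_m + F_m) with
# within-game counts.
conjugate_means <- function(data, r, prior_strength = 4) {
  a0 <- prior_strength * r
  b0 <- prior_strength * (1 - r)
  n <- nrow(data)
  mu <- matrix(NA_real_, n, 2)
  s <- c(0, 0); f <- c(0, 0)
  for (i in seq_len(n)) {
    if (data$trial[i] == 1) { s <- c(0, 0); f <- c(0, 0) }
    for (m in 1:2) mu[i, m] <- (a0 + s[m]) / (a0 + b0 + s[m] + f[m])
    ch <- data$choice[i]
    if (data$reward[i] == 1) s[ch] <- s[ch] + 1 else f[ch] <- f[ch] + 1
  }
  mu
}

# A small deterministic behavioral table built by hand (no simulation).
hand_dataset <- function(choice, reward, n_trials = length(choice),
                         subject_id = "h1", group = "G") {
  n_games <- length(choice) / n_trials
  data.frame(subject_id = subject_id, group = group,
             game = rep(seq_len(n_games), each = n_trials),
             trial = rep(seq_len(n_trials), times = n_games),
             choice = choice, reward = reward, stringsAsFactors = FALSE)
}

# Monte-Carlo prior integration of a policy's likelihood for one subject;
# returns the log marginal estimate and the MC standard error of the
# marginal (on the likelihood scale, relative to exp(max)).
mc_integrate <- function(data, policy_id, dbm, n_draws, seed,
                         grid_size = 1001) {
  set.seed(seed)
  n_trials <- max(data$trial)
  lls <- vapply(seq_len(n_draws), function(i) {
    pars <- switch(policy_id,
                   WSLS = list(gamma_w = runif(1), gamma_l = runif(1)),
                   EPS_GREEDY = list(epsilon = runif(1)),
                   TAU_SWITCH = list(gamma_tau = runif(1),
                                     tau = sample(n_trials, 1)),
                   SOFTMAX = list(b = rgamma(1, shape = 1, scale = 10)),
                   KG = list(gamma_kg = runif(1)))
    subject_policy_loglik(data, do.call(policy_spec, c(list(policy_id), pars)),
                          dbm, grid_size = grid_size)
  }, numeric(1))
  m <- max(lls)
  w <- exp(lls - m)
  list(log_marginal = m + log(mean(w)), scale = m,
       mean_w = mean(w), se_w = sd(w) / sqrt(n_draws))
}
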