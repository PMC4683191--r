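#' Bandit task configuration
#'
#' Describes the two-armed bandit design: a session of `n_games` independent
#' games of `n_trials` trials each. At the start of every game each arm's
#' reward rate is drawn i.i.d. from a Beta(`reward_alpha`, `reward_beta`)
#' distribution and then held fixed for the game; every choice pays 1 point
#' with that arm's rate, else 0.
#'
#' The defaults (20 games of 16 trials, Beta(2, 2) rates with mean 0.5 and
#' standard deviation ~0.22) match the study design this package analyses.
#'
#' @param n_games number of games per session.
#' @param n_trials trials per game (the decision horizon `T`).
#' @param reward_alpha,reward_beta shape parameters of the Beta distribution
#'   the true arm reward rates are drawn from.
#' @return an object of class `task_config`.
#' @examples
#' task_config()
#' task_config(n_games = 2, n_trials = 4)
#' @export
task_config <- function(n_games = 20, n_trials = 16,
                        reward_alpha = 2, reward_beta = 2) {
  stop_if_not(is.numeric(n_games) && n_games >= 1, "n_games must be >= 1")
  stop_if_not(is.numeric(n_trials) && n_trials >= 1, "n_trials must be >= 1")
  stop_if_not(reward_alpha > 0 && reward_beta > 0,
              "reward_alpha and reward_beta must be positive")
  structure(list(n_games = as.integer(n_games),
                 n_trials = as.integer(n_trials),
                 n_arms = 2L,
                 reward_alpha = reward_alpha,
                 reward_beta = reward_beta),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("Two-armed bandit task: %d games x %d trials, arm rates ~ Beta(%g, %g)\n",
              x$n_games, x$n_trials, x$reward_alpha, x$reward_beta))
  invisible(x)
}

#' Draw true per-game arm reward rates
#'
#' Samples, for each game, the pair of true arm reward rates i.i.d. from the
#' task's Beta distribution. With `enforce_distinct = TRUE` a rejection step
#' redraws any game whose two rates coincide; with continuous draws ties have
#' probability zero, so the flag is off by default.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param enforce_distinct redraw games with exactly equal rates.
#' @return a `n_games x 2` matrix of reward rates in (0, 1).
#' @examples
#' rates <- sample_game_rates(task_config(), seed = 1)
#' colMeans(rates)
#' @export
sample_game_rates <- function(config = task_config(), seed,
                              enforce_distinct = FALSE) {
  stop_if_not(inherits(config, "task_config"), "config must be a task_config")
  stop_if_not(is.numeric(seed) && length(seed) == 1, "seed must be an integer")
  set.seed(as.integer(seed))
  n <- config$n_games
  rates <- matrix(stats::rbeta(2 * n, config$reward_alpha, config$reward_beta),
                  ncol = 2)
  if (enforce_distinct) {
    while (any(tie <- rates[, 1] == rates[, 2])) {
      rates[tie, ] <- stats::rbeta(2 * sum(tie),
                                   config$reward_alpha, config$reward_beta)
    }
  }
  colnames(rates) <- c("rate_arm1", "rate_arm2")
  rates
}

#' Effective memory window of the Dynamic Belief Model
#'
#' Under the DBM the reward rate is believed to reset with probability
#' `1 - gamma` per trial, so the believed run length between changes is
#' geometric with mean `1 / (1 - gamma)` trials — the learner's effective
#' memory window.
#'
#' @param gamma stability parameter in \[0, 1).
#' @return expected number of trials between believed change-points.
#' @examples
#' dbm_timescale(0.6)  # 2.5 trials
#' @export
dbm_timescale <- function(gamma) {
  stop_if_not(all(gamma >= 0 & gamma < 1), "gamma must be in [0, 1)")
  1 / (1 - gamma)
}
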