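#' Dynamic Belief Model parameters
#'
#' The DBM is an iterative Bayesian learner that assumes each arm's reward
#' rate stays the same from one trial to the next with probability `gamma`
#' (the stability parameter) and otherwise resets to a draw from a generic
#' Beta prior with mean `r`. The prior's concentration is fixed at
#' `prior_strength = alpha0 + beta0` (default 4), so `alpha0 = 4 r` and
#' `beta0 = 4 (1 - r)`. `gamma = 1` recovers standard conjugate
#' Beta-Bernoulli updating (the Fixed Belief Model); smaller `gamma` produces
#' exponential discounting of past outcomes.
#'
#' `r = 0` and `r = 1` make the generic Beta improper; they are implemented
#' as point masses at 0 and 1 (the distributional limit), which keeps the
#' full inference lattice evaluable.
#'
#' @param gamma per-trial probability the reward rate stays unchanged, in
#'   \[0, 1\].
#' @param r mean of the generic prior, in \[0, 1\].
#' @param prior_strength sum `alpha0 + beta0` of the generic Beta prior.
#' @return an object of class `dbm_params`.
#' @examples
#' dbm_params(gamma = 0.6, r = 0.4)
#' @export
dbm_params <- function(gamma, r, prior_strength = 4) {
  stop_if_not(is.numeric(gamma) && gamma >= 0 && gamma <= 1,
              "gamma must be in [0, 1]")
  stop_if_not(is.numeric(r) && r >= 0 && r <= 1, "r must be in [0, 1]")
  stop_if_not(prior_strength > 0, "prior_strength must be positive")
  structure(list(gamma = gamma, r = r, prior_strength = prior_strength),
            class = "dbm_params")
}

#' @export
print.dbm_params <- function(x, ...) {
  cat(sprintf("DBM learner: gamma = %g, r = %g (Beta(%g, %g) generic prior)\n",
              x$gamma, x$r, x$prior_strength * x$r,
              x$prior_strength * (1 - x$r)))
  invisible(x)
}

# Probability masses of Beta(a, b) on an equally spaced grid: exact cell
# integrals with cell boundaries at midpoints between grid points
# (midpoint-mass convention; robust to improper endpoint densities).
discretize_beta <- function(a, b, grid) {
  g <- length(grid)
  if (a <= 0) { w <- numeric(g); w[1] <- 1; return(w) }   # point mass at 0
  if (b <= 0) { w <- numeric(g); w[g] <- 1; return(w) }   # point mass at 1
  bounds <- c(0, (grid[-g] + grid[-1]) / 2, 1)
  w <- diff(stats::pbeta(bounds, a, b))
  w / sum(w)
}

#' Initialize the discretized generic-prior belief
#'
#' Builds the belief state both arms start every game with: the generic
#' Beta(`4r`, `4(1-r)`) prior discretized onto `grid_size` equally spaced
#' support points in \[0, 1\] (probability masses, normalized per arm).
#'
#' @param params a [dbm_params()].
#' @param grid_size number of support points (>= 3); the package default used
#'   throughout inference is 1001.
#' @return an object of class `dbm_belief` with elements `grid` (support) and
#'   `w` (a `grid_size x 2` matrix of per-arm probability masses).
#' @examples
#' b <- make_generic_prior(dbm_params(0.6, 0.4), grid_size = 101)
#' belief_means(b)  # both close to 0.4
#' @export
make_generic_prior <- function(params, grid_size = 1001) {
  stop_if_not(inherits(params, "dbm_params"), "params must be dbm_params")
  stop_if_not(grid_size >= 3, "grid_size must be >= 3")
  grid <- seq(0, 1, length.out = grid_size)
  a <- params$prior_strength * params$r
  b <- params$prior_strength * (1 - params$r)
  q0 <- discretize_beta(a, b, grid)
  structure(list(grid = grid, w = cbind(q0, q0, deparse.level = 0), q0 = q0),
            class = "dbm_belief")
}

#' Per-arm means of a belief state
#'
#' The mean of the current belief over an arm's reward rate is the
#' "estimated reward rate" that learning-dependent decision policies consume.
#'
#' @param belief a `dbm_belief`.
#' @return numeric length-2 vector `c(mu1, mu2)`.
#' @export
belief_means <- function(belief) {
  as.numeric(crossprod(belief$w, belief$grid))
}

# Second moments E[theta^2] per arm (used by the knowledge-gradient value).
belief_second_moments <- function(belief) {
  as.numeric(crossprod(belief$w, belief$grid^2))
}

#' Propagate a belief through one DBM transition
#'
#' Between trials each arm's belief is mixed with the generic prior:
#' new weights `= gamma * old + (1 - gamma) * q0`, applied to both arms
#' (the unchosen arm's belief also relaxes toward the generic prior). With
#' `gamma = 1` the belief is unchanged; with `gamma = 0` it resets to the
#' generic prior.
#'
#' @param belief a normalized `dbm_belief` (last trial's posterior).
#' @param params a [dbm_params()].
#' @return the propagated `dbm_belief` (this trial's prior).
#' @export
propagate_prior <- function(belief, params) {
  stop_if_not(inherits(belief, "dbm_belief"), "belief must be a dbm_belief")
  g <- params$gamma
  q0 <- belief$q0
  belief$w <- g * belief$w + (1 - g) * cbind(q0, q0, deparse.level = 0)
  belief
}

#' Bayesian update of the chosen arm's belief
#'
#' Multiplies the chosen arm's weights pointwise by the Bernoulli likelihood
#' of the observed outcome — `theta` for a reward, `1 - theta` for none —
#' and renormalizes. The unchosen arm is untouched. If the observation has
#' zero probability under the current belief (possible only for point-mass
#' beliefs at `r` in `{0, 1}`) the belief is left unchanged; the likelihood
#' floor downstream absorbs the impossible observation.
#'
#' @param belief a normalized `dbm_belief` (this trial's prior).
#' @param chosen_arm 1 or 2.
#' @param outcome 0 (no reward) or 1 (reward).
#' @return the posterior `dbm_belief`.
#' @export
bayes_update <- function(belief, chosen_arm, outcome) {
  stop_if_not(chosen_arm %in% c(1, 2), "chosen_arm must be 1 or 2")
  stop_if_not(outcome %in% c(0, 1), "outcome must be 0 or 1")
  lik <- if (outcome == 1) belief$grid else 1 - belief$grid
  w <- belief$w[, chosen_arm] * lik
  s <- sum(w)
  if (s > 0) belief$w[, chosen_arm] <- w / s
  belief
}

#' Run the DBM filter over one subject's choice/outcome sequence
#'
#' Computes, for every trial, the prior belief the subject holds at choice
#' time: beliefs reset to the generic prior at each game start; between
#' trials both arms' beliefs are propagated through the DBM mixture; after
#' each choice the chosen arm's belief is updated with the observed outcome.
#' The emitted means are the pre-outcome (prior) estimated reward rates that
#' decision policies consume.
#'
#' @param data one subject's trials: a data frame with columns `game`,
#'   `trial`, `choice` (1/2) and `reward` (0/1), complete and ordered by
#'   (`game`, `trial`).
#' @param params a [dbm_params()].
#' @param grid_size belief grid resolution.
#' @return a data frame with columns `game`, `trial`, `mu1`, `mu2` (prior
#'   means) and `m2_1`, `m2_2` (prior second moments, used by the
#'   knowledge-gradient lookahead).
#' @examples
#' d <- generate_fixture(seed = 1)
#' run_beliefs(d, dbm_params(gamma = 1, r = 0.5), grid_size = 201)
#' @export
run_beliefs <- function(data, params, grid_size = 1001) {
  arr <- subject_arrays(data)
  tr <- belief_trace_lattice(arr$choice, arr$reward, arr$trial,
                             params$gamma, params$r, grid_size,
                             params$prior_strength)
  data.frame(game = arr$game, trial = arr$trial,
             mu1 = tr$mu1[, 1], mu2 = tr$mu2[, 1],
             m2_1 = tr$m21[, 1], m2_2 = tr$m22[, 1])
}

# Validate and extract one subject's trial arrays, enforcing ordering and
# completeness (contiguous games, trials 1..n within each game).
subject_arrays <- function(data) {
  need <- c("game", "trial", "choice", "reward")
  stop_if_not(all(need %in% names(data)),
              paste("data must have columns", paste(need, collapse = ", ")))
  stop_if_not(all(data$choice %in% c(1, 2)), "choice must be 1 or 2")
  stop_if_not(all(data$reward %in% c(0, 1)), "reward must be 0 or 1")
  o <- order(data$game, data$trial)
  if (!identical(o, seq_len(nrow(data))))
    stop("trials must be ordered by (game, trial)", call. = FALSE)
  tab <- table(data$game)
  if (length(unique(tab)) > 1)
    stop("all games must have the same number of trials", call. = FALSE)
  if (!all(data$trial == rep(seq_len(tab[1]), length(tab))))
    stop("trial indices must run 1..n_trials within each game", call. = FALSE)
  list(game = data$game, trial = data$trial,
       choice = as.integer(data$choice), reward = as.integer(data$reward),
       n_trials = as.integer(tab[1]))
}
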