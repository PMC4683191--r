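#' Decision-policy specification
#'
#' One of the five candidate policies a subject may use to turn beliefs (and
#' within-game history) into a choice:
#' \describe{
#'   \item{`WSLS`}{Win-Stay/Lose-Shift: repeat the last arm after a reward
#'     with probability `gamma_w`, switch after a loss with probability
#'     `gamma_l`; ignores beliefs.}
#'   \item{`EPS_GREEDY`}{choose the arm with the greater estimated reward
#'     rate with probability `1 - epsilon`, otherwise the other arm.}
#'   \item{`TAU_SWITCH`}{a count-based explore-then-exploit heuristic with
#'     switch point `tau` and execution accuracy `gamma_tau`; ignores
#'     beliefs.}
#'   \item{`SOFTMAX`}{choose arm 1 with probability
#'     `mu1^b / (mu1^b + mu2^b)`; `b = 0` is random, `b = 1` probability
#'     matching, large `b` maximizing.}
#'   \item{`KG`}{knowledge gradient: a one-step-lookahead exploration bonus
#'     added to the immediate reward rate, executed with accuracy
#'     `gamma_kg`.}
#' }
#'
#' @param policy_id one of `"WSLS"`, `"EPS_GREEDY"`, `"TAU_SWITCH"`,
#'   `"SOFTMAX"`, `"KG"`.
#' @param ... the policy's parameters: `gamma_w`, `gamma_l` (WSLS);
#'   `epsilon` (EPS_GREEDY); `gamma_tau`, `tau` (TAU_SWITCH); `b` (SOFTMAX);
#'   `gamma_kg` (KG).
#' @return an object of class `policy_spec`.
#' @examples
#' policy_spec("WSLS", gamma_w = 0.9, gamma_l = 0.85)
#' policy_spec("SOFTMAX", b = 7)
#' @export
policy_spec <- function(policy_id, ...) {
  policy_id <- match.arg(policy_id, POLICY_IDS)
  pars <- list(...)
  need <- switch(policy_id,
                 WSLS = c("gamma_w", "gamma_l"),
                 EPS_GREEDY = "epsilon",
                 TAU_SWITCH = c("gamma_tau", "tau"),
                 SOFTMAX = "b",
                 KG = "gamma_kg")
  stop_if_not(setequal(names(pars), need),
              sprintf("%s requires exactly parameters: %s", policy_id,
                      paste(need, collapse = ", ")))
  unit <- intersect(names(pars), c("gamma_w", "gamma_l", "epsilon",
                                   "gamma_tau", "gamma_kg"))
  for (nm in unit)
    stop_if_not(pars[[nm]] >= 0 && pars[[nm]] <= 1,
                sprintf("%s must be in [0, 1]", nm))
  if (policy_id == "SOFTMAX")
    stop_if_not(pars$b >= 0, "b must be >= 0")
  if (policy_id == "TAU_SWITCH")
    stop_if_not(pars$tau >= 1 && pars$tau == round(pars$tau),
                "tau must be a positive integer")
  structure(list(policy_id = policy_id, params = pars), class = "policy_spec")
}

POLICY_IDS <- c("WSLS", "EPS_GREEDY", "TAU_SWITCH", "SOFTMAX", "KG")

#' @export
print.policy_spec <- function(x, ...) {
  cat(sprintf("Policy %s(%s)\n", x$policy_id,
              paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}

#' Within-game history state
#'
#' The history the learning-independent policies consume: the previous
#' choice and outcome of the current game (absent on trial 1) and the
#' per-arm success/failure counts accumulated so far within the game.
#' History resets at every game boundary.
#'
#' @param prev_choice,prev_outcome previous trial's arm (1/2) and outcome
#'   (0/1), or `NA` on a game's first trial.
#' @param S,F length-2 vectors of per-arm success and failure counts.
#' @return an object of class `history_state`.
#' @export
history_state <- function(prev_choice = NA, prev_outcome = NA,
                          S = c(0, 0), F = c(0, 0)) {
  stop_if_not(all(S >= 0) && all(F >= 0), "counts must be nonnegative")
  structure(list(prev_choice = prev_choice, prev_outcome = prev_outcome,
                 S = S, F = F), class = "history_state")
}

#' Win-Stay/Lose-Shift choice probability
#'
#' After a reward the previous arm is repeated with probability `gamma_w`;
#' after a loss the other arm is chosen with probability `gamma_l`. With no
#' history (a game's first trial) both arms are equally likely.
#'
#' @param history a [history_state()].
#' @param params list with `gamma_w`, `gamma_l`.
#' @return probability of choosing arm 1.
#' @export
wsls_prob <- function(history, params) {
  if (is.na(history$prev_choice)) return(0.5)
  p_repeat <- if (history$prev_outcome == 1) params$gamma_w else 1 - params$gamma_l
  if (history$prev_choice == 1) p_repeat else 1 - p_repeat
}

#' Classify the within-game count state of the two arms
#'
#' Implements the tau-Switch policy's three-way state rule on the success
#' and failure counts (S1, S2, F1, F2): the arms are `EQUAL` when both count
#' pairs tie; arm 1 is `ARM1_BETTER` when `S1 > S2` with `F1 <= F2` or
#' `F1 < F2` with `S1 >= S2` (symmetrically for arm 2); and when one arm has
#' strictly more successes *and* strictly more failures it is the exploit
#' option (`EXPLORE_EXPLOIT`). The nine sign configurations of
#' `(S1 - S2, F1 - F2)` are exhaustively covered; the classifier is total,
#' and anything else (unreachable) defaults to `EQUAL`.
#'
#' @param history a [history_state()].
#' @return a list with `state` (one of `"EQUAL"`, `"ARM1_BETTER"`,
#'   `"ARM2_BETTER"`, `"EXPLORE_EXPLOIT"`) and, for the last, `exploit_arm`
#'   and `explore_arm`.
#' @export
classify_arm_state <- function(history) {
  ds <- sign(history$S[1] - history$S[2])
  df <- sign(history$F[1] - history$F[2])
  if (ds == 0 && df == 0) return(list(state = "EQUAL"))
  if (ds > 0 && df > 0)
    return(list(state = "EXPLORE_EXPLOIT", exploit_arm = 1, explore_arm = 2))
  if (ds < 0 && df < 0)
    return(list(state = "EXPLORE_EXPLOIT", exploit_arm = 2, explore_arm = 1))
  # remaining: one arm dominates (more successes with no more failures, or
  # fewer failures with no fewer successes)
  if ((ds > 0 && df <= 0) || (df < 0 && ds >= 0))
    return(list(state = "ARM1_BETTER"))
  if ((ds < 0 && df >= 0) || (df > 0 && ds <= 0))
    return(list(state = "ARM2_BETTER"))
  list(state = "EQUAL")
}

#' tau-Switch choice probability
#'
#' In the `EQUAL` state the choice is random. When one arm dominates, the
#' better arm is chosen with probability `gamma_tau`. In the
#' explore/exploit state the explore arm is chosen with probability
#' `gamma_tau` before the switch point `tau`, and the exploit arm with
#' probability `gamma_tau` from trial `tau` onward.
#'
#' @param history a [history_state()].
#' @param t current 1-based trial index within the game.
#' @param params list with `gamma_tau` and integer `tau`.
#' @return probability of choosing arm 1.
#' @export
tau_switch_prob <- function(history, t, params) {
  st <- classify_arm_state(history)
  g <- params$gamma_tau
  target <- switch(st$state,
                   EQUAL = return(0.5),
                   ARM1_BETTER = 1,
                   ARM2_BETTER = 2,
                   EXPLORE_EXPLOIT =
                     if (t < params$tau) st$explore_arm else st$exploit_arm)
  if (target == 1) g else 1 - g
}

#' epsilon-Greedy choice probability
#'
#' @param mu1,mu2 estimated reward rates of the two arms.
#' @param params list with `epsilon`.
#' @return probability of choosing arm 1 (0.5 on an exact tie).
#' @export
epsilon_greedy_prob <- function(mu1, mu2, params) {
  if (isTRUE(all.equal(mu1, mu2, tolerance = 1e-12))) return(0.5)
  if (mu1 > mu2) 1 - params$epsilon else params$epsilon
}

#' Softmax choice probability
#'
#' `Pr(arm 1) = mu1^b / (mu1^b + mu2^b)`. `b = 0` gives random choice,
#' `b = 1` probability matching, and the probability approaches the
#' indicator of the larger rate as `b` grows. Both rates zero (possible
#' under a point-mass prior at 0) is defined as 0.5.
#'
#' @param mu1,mu2 estimated reward rates in \[0, 1\].
#' @param params list with `b >= 0`.
#' @return probability of choosing arm 1.
#' @export
softmax_prob <- function(mu1, mu2, params) {
  b <- params$b
  if (mu1 == 0 && mu2 == 0) return(0.5)
  if (b == 0) return(0.5)
  # compute in logs for large b
  l1 <- b * log(max(mu1, PROB_FLOOR))
  l2 <- b * log(max(mu2, PROB_FLOOR))
  1 / (1 + exp(l2 - l1))
}

#' Knowledge-gradient value of sampling an arm
#'
#' The expected improvement, after one more observation of arm `m`, of the
#' best estimated reward rate: the two possible outcomes (reward with
#' predictive probability `mu_m`, no reward otherwise) are enumerated, the
#' chosen arm's belief is Bayes-updated, both arms are propagated through
#' the DBM transition into the next trial, and the expected max-over-arms
#' next-trial mean minus the current max-over-arms mean is returned.
#'
#' @param belief a normalized `dbm_belief`.
#' @param arm 1 or 2.
#' @param dbm a [dbm_params()].
#' @return the scalar knowledge-gradient value `v_m`.
#' @examples
#' b <- make_generic_prior(dbm_params(gamma = 1, r = 0.5), 2001)
#' kg_value(b, 1, dbm_params(gamma = 1, r = 0.5))  # ~0.05 for Beta(2,2)
#' @export
kg_value <- function(belief, arm, dbm) {
  mu <- belief_means(belief)
  p_win <- mu[arm]
  next_max <- function(outcome) {
    post <- bayes_update(belief, arm, outcome)
    nxt <- propagate_prior(post, dbm)
    max(belief_means(nxt))
  }
  e_max <- 0
  if (p_win > 0) e_max <- e_max + p_win * next_max(1)
  if (p_win < 1) e_max <- e_max + (1 - p_win) * next_max(0)
  e_max - max(mu)
}

#' Knowledge-gradient choice probability
#'
#' The deterministic KG arm maximizes `mu_m + (T - t - 1) v_m`, where the
#' horizon factor is clamped at zero on the final trial; the KG arm is then
#' chosen with execution accuracy `gamma_kg` (0.5 on an exact score tie).
#'
#' @param belief a normalized `dbm_belief`.
#' @param t current 1-based trial index; `T_horizon` the game length.
#' @param T_horizon trials per game.
#' @param dbm a [dbm_params()].
#' @param params list with `gamma_kg`.
#' @return probability of choosing arm 1.
#' @export
kg_prob <- function(belief, t, T_horizon, dbm, params) {
  mu <- belief_means(belief)
  h <- max(T_horizon - t - 1, 0)
  score <- mu + h * c(kg_value(belief, 1, dbm), kg_value(belief, 2, dbm))
  if (isTRUE(all.equal(score[1], score[2], tolerance = 1e-12))) return(0.5)
  if (score[1] > score[2]) params$gamma_kg else 1 - params$gamma_kg
}

#' Choice probability under any policy
#'
#' Dispatches to the policy-specific rule given the current belief state and
#' within-game history. On a game's first trial all policies reduce to 0.5
#' (beliefs are symmetric and the history-based policies have no history).
#'
#' @param spec a [policy_spec()].
#' @param belief a `dbm_belief` (ignored by WSLS and tau-Switch).
#' @param history a [history_state()].
#' @param t current trial index within the game.
#' @param T_horizon trials per game.
#' @param dbm a [dbm_params()] (used by KG's lookahead).
#' @return probability of choosing arm 1.
#' @export
policy_choice_prob <- function(spec, belief, history, t, T_horizon, dbm) {
  stop_if_not(inherits(spec, "policy_spec"), "spec must be a policy_spec")
  switch(spec$policy_id,
         WSLS = wsls_prob(history, spec$params),
         TAU_SWITCH = tau_switch_prob(history, t, spec$params),
         EPS_GREEDY = {
           mu <- belief_means(belief)
           epsilon_greedy_prob(mu[1], mu[2], spec$params)
         },
         SOFTMAX = {
           mu <- belief_means(belief)
           softmax_prob(mu[1], mu[2], spec$params)
         },
         KG = kg_prob(belief, t, T_horizon, dbm, spec$params),
         stop("unknown policy id", call. = FALSE))
}
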