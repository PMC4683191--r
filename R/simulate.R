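#' Simulated agent specification
#'
#' Bundles the learner (DBM parameters), the decision policy, and the
#' subject/group identifiers of one synthetic subject.
#'
#' @param subject_id unique identifier.
#' @param group group label (e.g. `"MDI"`, `"HCS"`).
#' @param dbm a [dbm_params()].
#' @param policy a [policy_spec()].
#' @return an object of class `agent_spec`.
#' @examples
#' agent_spec("s01", "HCS", dbm_params(0.6, 0.4), policy_spec("SOFTMAX", b = 7))
#' @export
agent_spec <- function(subject_id, group, dbm, policy) {
  stop_if_not(inherits(dbm, "dbm_params"), "dbm must be dbm_params")
  stop_if_not(inherits(policy, "policy_spec"), "policy must be a policy_spec")
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group), dbm = dbm, policy = policy),
            class = "agent_spec")
}

#' Simulate one subject's bandit session
#'
#' Draws true arm reward rates per game from the task's Beta distribution,
#' then plays each game with an agent whose beliefs follow the DBM and whose
#' choices are drawn from its policy's choice probability. Beliefs and
#' within-game history reset at every game boundary; a game's first choice
#' is uniform (symmetric beliefs, no history). The generating ground truth
#' (true rates and the agent spec) is attached as attributes so recovery
#' experiments can score estimates, but is never part of the behavioral
#' columns.
#'
#' @param agent an [agent_spec()].
#' @param config a [task_config()].
#' @param seed integer seed; the session is deterministic given it.
#' @param grid_size belief grid resolution used by the simulated learner.
#' @return a data frame with columns `subject_id`, `group`, `game`, `trial`,
#'   `choice`, `reward`, with attributes `rates` (true per-game rates) and
#'   `agent`.
#' @examples
#' a <- agent_spec("s01", "HCS", dbm_params(0.6, 0.4),
#'                 policy_spec("WSLS", gamma_w = 0.9, gamma_l = 0.85))
#' d <- simulate_subject(a, task_config(n_games = 2, n_trials = 4), seed = 1)
#' @export
simulate_subject <- function(agent, config = task_config(), seed,
                             grid_size = 1001) {
  stop_if_not(inherits(agent, "agent_spec"), "agent must be an agent_spec")
  rates <- sample_game_rates(config, seed = seed)
  # sample_game_rates seeded the stream; continue from it for choices
  n_g <- config$n_games; n_t <- config$n_trials
  n <- n_g * n_t
  choice <- integer(n); reward <- integer(n)
  prior <- make_generic_prior(agent$dbm, grid_size)
  k <- 0L
  for (g in seq_len(n_g)) {
    belief <- prior
    hist <- history_state()
    for (t in seq_len(n_t)) {
      if (t > 1L) belief <- propagate_prior(belief, agent$dbm)
      p1 <- if (t == 1L) 0.5 else
        policy_choice_prob(agent$policy, belief, hist, t, n_t, agent$dbm)
      ch <- if (stats::runif(1) < p1) 1L else 2L
      rw <- stats::rbinom(1, 1, rates[g, ch])
      k <- k + 1L
      choice[k] <- ch; reward[k] <- rw
      belief <- bayes_update(belief, ch, rw)
      S <- hist$S; F <- hist$F
      if (rw == 1L) S[ch] <- S[ch] + 1L else F[ch] <- F[ch] + 1L
      hist <- history_state(prev_choice = ch, prev_outcome = rw, S = S, F = F)
    }
  }
  out <- data.frame(subject_id = agent$subject_id, group = agent$group,
                    game = rep(seq_len(n_g), each = n_t),
                    trial = rep(seq_len(n_t), times = n_g),
                    choice = choice, reward = reward,
                    stringsAsFactors = FALSE)
  attr(out, "rates") <- rates
  attr(out, "agent") <- agent
  out
}

#' Simulate a cohort of subjects
#'
#' One session per agent. Each subject's RNG stream is derived from the
#' master seed plus a stable hash of the subject id, so adding or removing
#' a subject never perturbs the others' data.
#'
#' @param group_specs list of [agent_spec()] with unique subject ids.
#' @param config a [task_config()].
#' @param master_seed integer master seed.
#' @param grid_size belief grid resolution for the simulated learners.
#' @return a data frame of all subjects' trials, with attribute `truth`: a
#'   per-subject list of true rates and generating agent specs.
#' @examples
#' specs <- default_cohort_specs("HCS", n = 4)
#' d <- simulate_cohort(specs, task_config(n_games = 2, n_trials = 4), 1)
#' @export
simulate_cohort <- function(group_specs, config = task_config(), master_seed,
                            grid_size = 1001) {
  stop_if_not(length(group_specs) >= 1, "group_specs must be nonempty")
  ids <- vapply(group_specs, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop("duplicate subject_id in group_specs", call. = FALSE)
  sims <- lapply(group_specs, function(a)
    simulate_subject(a, config, seed = subject_seed(master_seed, a$subject_id),
                     grid_size = grid_size))
  out <- do.call(rbind, sims)
  rownames(out) <- NULL
  attr(out, "truth") <- stats::setNames(lapply(sims, function(s)
    list(rates = attr(s, "rates"), agent = attr(s, "agent"))), ids)
  out
}

#' Default cohort composition for recovery experiments
#'
#' The simulated study condition: `n` subjects sharing group-level DBM
#' parameters, half using a strongly identified Win-Stay/Lose-Shift policy
#' and half a strongly maximizing Softmax policy.
#'
#' @param group group label.
#' @param n subjects (default 16, the study's group size).
#' @param gamma,r group DBM parameters (defaults 0.6 and 0.4).
#' @param gamma_w,gamma_l WSLS stay/shift parameters for the WSLS half.
#' @param b Softmax exponent for the Softmax half.
#' @param prefix subject-id prefix.
#' @return list of [agent_spec()].
#' @export
default_cohort_specs <- function(group, n = 16, gamma = 0.6, r = 0.4,
                                 gamma_w = 0.9, gamma_l = 0.85, b = 7,
                                 prefix = group) {
  dbm <- dbm_params(gamma, r)
  n_wsls <- floor(n / 2)
  lapply(seq_len(n), function(i) {
    pol <- if (i <= n_wsls)
      policy_spec("WSLS", gamma_w = gamma_w, gamma_l = gamma_l)
    else policy_spec("SOFTMAX", b = b)
    agent_spec(sprintf("%s%02d", prefix, i), group, dbm, pol)
  })
}

#' Tiny fixed dataset for examples and fast checks
#'
#' A single subject's 2-game x 4-trial session from a Softmax agent with
#' `b = 2` learning at `gamma = 0.6, r = 0.5`; small enough that beliefs
#' and likelihoods are hand-checkable, and deterministic given the seed.
#'
#' @param seed integer seed.
#' @return a subject data frame (see [simulate_subject()]).
#' @examples
#' generate_fixture(seed = 1)
#' @export
generate_fixture <- function(seed = 1) {
  simulate_subject(
    agent_spec("fix01", "FIX", dbm_params(0.6, 0.5),
               policy_spec("SOFTMAX", b = 2)),
    task_config(n_games = 2, n_trials = 4), seed = seed, grid_size = 201)
}
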