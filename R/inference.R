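#' Inference configuration
#'
#' Settings for the hierarchical marginal-likelihood analysis: the discrete
#' (gamma, r) lattice the group learning parameters are searched over, the
#' belief grid resolution, and the quadrature resolution used to integrate
#' policy parameters against their priors. The parameter priors are fixed by
#' the model: a symmetric Dirichlet(1,1,1,1,1) over the five policies
#' (marginal prior 1/5 each), uniform priors on the unit interval for
#' `gamma_w`, `gamma_l`, `epsilon`, `gamma_tau` and `gamma_kg`, a flat
#' Gamma prior with mean 10 and standard deviation 10 (shape 1, scale 10)
#' for the Softmax exponent `b`, and a discrete uniform over `1..T` for
#' `tau`.
#'
#' @param gamma_grid,r_grid lattice values for the DBM stability and generic
#'   prior mean (defaults: 0 to 1 in increments of 0.1).
#' @param grid_size belief grid resolution (default 1001).
#' @param quadrature_nodes Gauss-Legendre nodes per continuous parameter
#'   dimension (>= 8).
#' @param policy_prior Dirichlet concentration over the five policies.
#' @return an object of class `inference_config`.
#' @examples
#' inference_config()
#' @export
inference_config <- function(gamma_grid = seq(0, 1, by = 0.1),
                             r_grid = seq(0, 1, by = 0.1),
                             grid_size = 1001,
                             quadrature_nodes = 24,
                             policy_prior = rep(1, 5)) {
  stop_if_not(all(gamma_grid >= 0 & gamma_grid <= 1), "gamma_grid in [0,1]")
  stop_if_not(all(r_grid >= 0 & r_grid <= 1), "r_grid in [0,1]")
  stop_if_not(quadrature_nodes >= 8, "quadrature_nodes must be >= 8")
  stop_if_not(length(policy_prior) == 5 && all(policy_prior > 0),
              "policy_prior must be 5 positive concentrations")
  structure(list(gamma_grid = sort(gamma_grid), r_grid = sort(r_grid),
                 grid_size = as.integer(grid_size),
                 quadrature_nodes = as.integer(quadrature_nodes),
                 policy_prior = policy_prior),
            class = "inference_config")
}

#' Log-likelihood of a subject's choices under one policy
#'
#' Runs the DBM filter at the given learning parameters and sums, over
#' trials, the log probability the policy assigns to the subject's actual
#' choice. Per-trial probabilities are floored at `1e-12` so deterministic
#' parameter corners give very poor but finite values.
#'
#' @param data one subject's trials (columns `game`, `trial`, `choice`,
#'   `reward`).
#' @param policy a [policy_spec()].
#' @param dbm a [dbm_params()].
#' @param grid_size belief grid resolution.
#' @return total log-likelihood (scalar).
#' @examples
#' d <- generate_fixture(seed = 1)
#' subject_policy_loglik(d, policy_spec("SOFTMAX", b = 2), dbm_params(0.6, 0.5))
#' @export
subject_policy_loglik <- function(data, policy, dbm, grid_size = 1001) {
  arr <- subject_arrays(data)
  tr <- belief_trace_lattice(arr$choice, arr$reward, arr$trial,
                             dbm$gamma, dbm$r, grid_size, dbm$prior_strength)
  sum(clamp_log(policy_trial_probs(arr, tr, policy, dbm)))
}

# Per-trial probability of the observed choice under a fixed policy
# parameter setting (single lattice point).
policy_trial_probs <- function(arr, tr, policy, dbm) {
  n <- length(arr$choice)
  chose1 <- arr$choice == 1L
  mu1 <- tr$mu1[, 1]; mu2 <- tr$mu2[, 1]
  p1 <- switch(policy$policy_id,
    WSLS = {
      first <- arr$trial == 1L
      prev <- c(NA_integer_, arr$choice[-n])
      prev_rew <- c(NA_integer_, arr$reward[-n])
      p_rep <- ifelse(prev_rew == 1L, policy$params$gamma_w,
                      1 - policy$params$gamma_l)
      out <- ifelse(prev == 1L, p_rep, 1 - p_rep)
      out[first] <- 0.5
      out
    },
    TAU_SWITCH = tau_targets(arr, policy$params$tau, policy$params$gamma_tau),
    EPS_GREEDY = {
      tie <- abs(mu1 - mu2) <= 1e-12
      ifelse(tie, 0.5, ifelse(mu1 > mu2, 1 - policy$params$epsilon,
                              policy$params$epsilon))
    },
    SOFTMAX = {
      b <- policy$params$b
      l1 <- b * log(pmax(mu1, PROB_FLOOR))
      l2 <- b * log(pmax(mu2, PROB_FLOOR))
      ifelse(b == 0 | abs(mu1 - mu2) <= 1e-12, 0.5, 1 / (1 + exp(l2 - l1)))
    },
    KG = {
      kg <- kg_arm_lattice(tr, arr$trial, arr$n_trials, dbm$gamma, dbm$r)
      ifelse(kg$tie[, 1], 0.5, ifelse(kg$arm1[, 1], policy$params$gamma_kg,
                                      1 - policy$params$gamma_kg))
    })
  if (policy$policy_id %in% c("WSLS", "EPS_GREEDY", "SOFTMAX", "KG")) {
    ifelse(chose1, p1, 1 - p1)
  } else {
    p1   # tau_targets already returns prob of the observed choice
  }
}

# Probability of the observed choice per trial for tau-Switch at (tau,
# gamma_tau).
tau_targets <- function(arr, tau, gamma_tau) {
  n <- length(arr$choice)
  probs <- numeric(n)
  s <- c(0L, 0L); f <- c(0L, 0L)
  for (t in seq_len(n)) {
    if (arr$trial[t] == 1L) { s <- c(0L, 0L); f <- c(0L, 0L) }
    st <- classify_arm_state(history_state(S = s, F = f))
    target <- switch(st$state,
                     EQUAL = NA_integer_,
                     ARM1_BETTER = 1L,
                     ARM2_BETTER = 2L,
                     EXPLORE_EXPLOIT =
                       if (arr$trial[t] < tau) st$explore_arm else st$exploit_arm)
    probs[t] <- if (is.na(target)) 0.5 else
      if (arr$choice[t] == target) gamma_tau else 1 - gamma_tau
    a <- arr$choice[t]
    if (arr$reward[t] == 1L) s[a] <- s[a] + 1L else f[a] <- f[a] + 1L
  }
  probs
}

#' Marginal likelihood of a subject's data under one policy
#'
#' Integrates the choice likelihood over the policy's parameters against
#' their prior: Gauss-Legendre quadrature for the continuous parameters
#' (via the inverse-CDF transform for the Softmax exponent's Gamma prior),
#' and a discrete uniform sum over `tau`.
#'
#' @param data one subject's trials.
#' @param policy_id one of the five policy identifiers.
#' @param dbm a [dbm_params()].
#' @param config an [inference_config()].
#' @param log return the log marginal likelihood (default `FALSE`).
#' @return scalar marginal likelihood (or its log).
#' @export
integrate_policy <- function(data, policy_id, dbm, config = inference_config(),
                             log = FALSE) {
  policy_id <- match.arg(policy_id, POLICY_IDS)
  arr <- subject_arrays(data)
  tr <- belief_trace_lattice(arr$choice, arr$reward, arr$trial,
                             dbm$gamma, dbm$r, config$grid_size,
                             dbm$prior_strength)
  lm <- unname(policy_log_marginals(arr, tr, dbm$gamma, dbm$r,
                                    config)[1, policy_id])
  if (log) lm else exp(lm)
}

#' Marginal likelihood of a subject's data averaged over the five policies
#'
#' The Dirichlet(1,...,1) prior over policy identity yields a marginal prior
#' of 1/5 per policy, so the subject-level marginal likelihood is the
#' average of the five per-policy marginals.
#'
#' @inheritParams integrate_policy
#' @return scalar marginal likelihood (or its log).
#' @export
subject_marginal <- function(data, dbm, config = inference_config(),
                             log = FALSE) {
  arr <- subject_arrays(data)
  tr <- belief_trace_lattice(arr$choice, arr$reward, arr$trial,
                             dbm$gamma, dbm$r, config$grid_size,
                             dbm$prior_strength)
  lm <- policy_log_marginals(arr, tr, dbm$gamma, dbm$r, config)[1, ]
  out <- logsumexp(lm) - log(5)
  if (log) out else exp(out)
}

split_subjects <- function(data) {
  stop_if_not("subject_id" %in% names(data), "data must have subject_id")
  split(data, data$subject_id, drop = TRUE)
}

#' Group-level grid search for the DBM learning parameters
#'
#' For every lattice point (gamma, r), sums over the group's subjects the
#' log marginal likelihood of their choices (policy identity and policy
#' parameters integrated out), and returns the surface together with its
#' maximal marginal-likelihood estimate. Ties in the argmax are broken
#' toward larger gamma, then larger r.
#'
#' @param group_data a data frame of trials for one group (with
#'   `subject_id`), or a list of per-subject data frames.
#' @param config an [inference_config()].
#' @param group optional group label stored on the surface.
#' @return an object of class `grid_surface`: the log marginal-likelihood
#'   matrix (`gamma` rows, `r` columns), the grids, the estimate
#'   `c(gamma, r)`, the group label, and the subject count.
#' @export
grid_search_group <- function(group_data, config = inference_config(),
                              group = NULL) {
  subs <- if (is.data.frame(group_data)) split_subjects(group_data) else group_data
  stop_if_not(length(subs) >= 1, "group must contain at least one subject")
  lattice <- expand.grid(gamma = config$gamma_grid, r = config$r_grid,
                         KEEP.OUT.ATTRS = FALSE)
  total <- numeric(nrow(lattice))
  for (d in subs) {
    arr <- subject_arrays(d)
    tr <- belief_trace_lattice(arr$choice, arr$reward, arr$trial,
                               lattice$gamma, lattice$r, config$grid_size)
    lm <- policy_log_marginals(arr, tr, lattice$gamma, lattice$r, config)
    total <- total + (apply(lm, 1, logsumexp) - log(5))
  }
  surf <- matrix(total, nrow = length(config$gamma_grid),
                 dimnames = list(gamma = config$gamma_grid,
                                 r = config$r_grid))
  best <- which(total == max(total))
  # tie-break toward larger gamma, then larger r
  best <- best[order(lattice$gamma[best], lattice$r[best],
                     decreasing = TRUE)][1]
  structure(list(loglik = surf,
                 gamma_grid = config$gamma_grid, r_grid = config$r_grid,
                 estimate = c(gamma = lattice$gamma[best], r = lattice$r[best]),
                 group = group, n_subjects = length(subs)),
            class = "grid_surface")
}

#' @export
print.grid_surface <- function(x, ...) {
  cat(sprintf("Marginal log-likelihood surface%s: %d x %d lattice, %d subjects\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$gamma_grid), length(x$r_grid), x$n_subjects))
  cat(sprintf("  maximal marginal-likelihood estimate: gamma = %g, r = %g\n",
              x$estimate["gamma"], x$estimate["r"]))
  invisible(x)
}

#' Surface as -2 log likelihood
#'
#' The display convention for group surfaces: smaller is better fitting.
#'
#' @param surface a `grid_surface`.
#' @return matrix of `-2 * log` marginal likelihood.
#' @export
neg2_loglik <- function(surface) -2 * surface$loglik

#' Moments of the lattice posterior over (gamma, r)
#'
#' Treats the exponentiated surface as an (unnormalized) posterior over the
#' lattice under a uniform prior and computes the mean and variance of gamma
#' and of r in closed form — the exact expectation of a resampling estimate
#' from the same distribution.
#'
#' @param surface a `grid_surface`.
#' @return a list with `mean` and `var`, each named `c(gamma, r)`.
#' @export
surface_moments <- function(surface) {
  ll <- as.vector(surface$loglik)
  stop_if_not(any(is.finite(ll)), "surface has no finite entries")
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  g <- rep(surface$gamma_grid, times = length(surface$r_grid))
  r <- rep(surface$r_grid, each = length(surface$gamma_grid))
  mg <- sum(w * g); mr <- sum(w * r)
  list(mean = c(gamma = mg, r = mr),
       var = c(gamma = sum(w * (g - mg)^2), r = sum(w * (r - mr)^2)))
}

#' Group comparison of DBM parameters via surface moments
#'
#' Builds, for gamma and for r, a two-sample confidence interval on the
#' difference of the groups' posterior-surface means, using the
#' surface-moment variances, the actual group sizes, a pooled standard
#' error, and the two-sample t critical value with `n_A + n_B - 2` degrees
#' of freedom.
#'
#' @param surface_A,surface_B `grid_surface` objects for the two groups.
#' @param n_A,n_B group sizes (>= 2).
#' @param conf confidence level.
#' @return data frame with one row per parameter: difference of means
#'   (A minus B), pooled standard error, critical t, lower and upper bounds.
#' @export
compare_groups_dbm <- function(surface_A, surface_B, n_A, n_B, conf = 0.95) {
  stop_if_not(n_A >= 2 && n_B >= 2, "both groups must have n >= 2")
  ma <- surface_moments(surface_A)
  mb <- surface_moments(surface_B)
  df <- n_A + n_B - 2
  tcrit <- critical_t(df, alpha = 1 - conf)
  out <- lapply(c("gamma", "r"), function(p) {
    pooled <- ((n_A - 1) * ma$var[p] + (n_B - 1) * mb$var[p]) / df
    se <- sqrt(pooled * (1 / n_A + 1 / n_B))
    diff <- ma$mean[p] - mb$mean[p]
    data.frame(parameter = p, diff = unname(diff), se = unname(se),
               df = df, t_crit = tcrit,
               lower = unname(diff - tcrit * se),
               upper = unname(diff + tcrit * se))
  })
  do.call(rbind, out)
}

#' Posterior policy classification for one subject
#'
#' With the group learning parameters fixed (the two-stage procedure), the
#' posterior probability of each policy is proportional to its marginal
#' likelihood times the 1/5 prior; the MAP policy is returned alongside.
#'
#' @param data one subject's trials.
#' @param dbm_hat the group's fitted [dbm_params()].
#' @param config an [inference_config()].
#' @return list with `posterior` (named 5-vector summing to 1) and `map`
#'   (policy id).
#' @export
assign_policy <- function(data, dbm_hat, config = inference_config()) {
  arr <- subject_arrays(data)
  tr <- belief_trace_lattice(arr$choice, arr$reward, arr$trial,
                             dbm_hat$gamma, dbm_hat$r, config$grid_size,
                             dbm_hat$prior_strength)
  lm <- policy_log_marginals(arr, tr, dbm_hat$gamma, dbm_hat$r, config)[1, ]
  lp <- lm + log(config$policy_prior / sum(config$policy_prior))
  post <- exp(lp - logsumexp(lp))
  list(posterior = post / sum(post), map = POLICY_IDS[which.max(lp)])
}

#' Maximum-likelihood policy parameters for one subject
#'
#' Maximizes the subject's choice log-likelihood over the assigned policy's
#' parameter support: 1-D golden-section search (with endpoint checks) for
#' the unit-interval parameters, a multi-start bounded search for the
#' Softmax exponent, and an exhaustive sweep over `tau` for tau-Switch.
#' A maximizer within `1e-3` of the support boundary is flagged.
#'
#' @param data one subject's trials.
#' @param policy_id the policy to fit.
#' @param dbm_hat the group's fitted [dbm_params()].
#' @param config an [inference_config()].
#' @param b_max upper search bound for the Softmax exponent.
#' @return list with `params` (named list), `loglik`, and `boundary`
#'   (logical flag).
#' @export
fit_policy_params <- function(data, policy_id, dbm_hat,
                              config = inference_config(), b_max = 50) {
  policy_id <- match.arg(policy_id, POLICY_IDS)
  arr <- subject_arrays(data)
  tr <- belief_trace_lattice(arr$choice, arr$reward, arr$trial,
                             dbm_hat$gamma, dbm_hat$r, config$grid_size,
                             dbm_hat$prior_strength)
  ll_for <- function(pars) {
    sp <- do.call(policy_spec, c(list(policy_id), pars))
    sum(clamp_log(policy_trial_probs(arr, tr, sp, dbm_hat)))
  }
  opt1d <- function(f, lower, upper, starts = 3) {
    # multi-start golden-section over subintervals plus endpoint candidates
    cuts <- seq(lower, upper, length.out = starts + 1)
    cand <- lapply(seq_len(starts), function(i)
      stats::optimize(f, c(cuts[i], cuts[i + 1]), maximum = TRUE))
    vals <- vapply(cand, `[[`, numeric(1), "objective")
    best <- cand[[which.max(vals)]]
    ends <- c(lower, upper)
    evals <- vapply(ends, f, numeric(1))
    if (max(evals) > best$objective)
      list(par = ends[which.max(evals)], value = max(evals))
    else list(par = best$maximum, value = best$objective)
  }
  res <- switch(policy_id,
    WSLS = {
      # log-likelihood separates in gamma_w and gamma_l
      ow <- opt1d(function(g) ll_for(list(gamma_w = g, gamma_l = 0.5)), 0, 1)
      ol <- opt1d(function(g) ll_for(list(gamma_w = ow$par, gamma_l = g)), 0, 1)
      list(params = list(gamma_w = ow$par, gamma_l = ol$par),
           loglik = ll_for(list(gamma_w = ow$par, gamma_l = ol$par)))
    },
    EPS_GREEDY = {
      o <- opt1d(function(e) ll_for(list(epsilon = e)), 0, 1)
      list(params = list(epsilon = o$par), loglik = o$value)
    },
    TAU_SWITCH = {
      per_tau <- lapply(seq_len(arr$n_trials), function(tau) {
        o <- opt1d(function(g) ll_for(list(gamma_tau = g, tau = tau)), 0, 1)
        list(tau = tau, gamma_tau = o$par, value = o$value)
      })
      best <- per_tau[[which.max(vapply(per_tau, `[[`, numeric(1), "value"))]]
      list(params = list(gamma_tau = best$gamma_tau, tau = best$tau),
           loglik = best$value)
    },
    SOFTMAX = {
      o <- opt1d(function(b) ll_for(list(b = b)), 0, b_max, starts = 5)
      list(params = list(b = o$par), loglik = o$value)
    },
    KG = {
      o <- opt1d(function(g) ll_for(list(gamma_kg = g)), 0, 1)
      list(params = list(gamma_kg = o$par), loglik = o$value)
    })
  cont <- unlist(res$params[setdiff(names(res$params), "tau")])
  lims <- ifelse(names(cont) == "b", b_max, 1)
  res$boundary <- any(cont <= 1e-3 | cont >= lims - 1e-3)
  res$policy_id <- policy_id
  res
}
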