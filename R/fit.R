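#' Fit the learning + decision-policy model to bandit behavior
#'
#' The package's main estimator. For each group in the data it (stage 1)
#' estimates the group-level DBM learning parameters (gamma, r) by maximal
#' marginal likelihood over the discrete lattice, with each subject's policy
#' identity and policy parameters integrated out; then (stage 2), holding
#' the group estimate fixed, classifies every subject's decision policy by
#' posterior probability and estimates the MAP policy's parameters by
#' maximum likelihood.
#'
#' @param data trial-level behavior: a data frame with columns
#'   `subject_id`, `group`, `game`, `trial`, `choice` (1/2), `reward` (0/1),
#'   ordered by (subject, game, trial) — e.g. from [simulate_cohort()] or
#'   [read_behavior_csv()].
#' @param config an [inference_config()].
#' @return an object of class `bandit_fit` with components
#'   \describe{
#'     \item{groups}{per-group list: `surface` (a `grid_surface`),
#'       `estimate` (gamma, r), `moments` (surface mean/variance),
#'       `subjects` (policy posteriors, MAP policy, MLE parameters).}
#'     \item{subjects}{all groups' subject table combined.}
#'     \item{config}{the configuration used.}
#'   }
#'   Methods: `print`, `summary`, `coef`, `logLik`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' specs <- c(default_cohort_specs("HCS", n = 4),
#'            default_cohort_specs("MDI", n = 4, r = 0.1, b = 1.5))
#' d <- simulate_cohort(specs, task_config(n_games = 4, n_trials = 8), 1)
#' fit <- bandit_fit(d, inference_config(grid_size = 201))
#' coef(fit)
#' }
#' @export
bandit_fit <- function(data, config = inference_config()) {
  stop_if_not(all(c("subject_id", "group") %in% names(data)),
              "data must have subject_id and group columns")
  groups <- unique(data$group)
  gfits <- lapply(groups, function(g) {
    gd <- data[data$group == g, , drop = FALSE]
    surface <- grid_search_group(gd, config, group = g)
    dbm_hat <- dbm_params(surface$estimate["gamma"], surface$estimate["r"])
    subs <- split_subjects(gd)
    rows <- lapply(names(subs), function(id) {
      asg <- assign_policy(subs[[id]], dbm_hat, config)
      mle <- fit_policy_params(subs[[id]], asg$map, dbm_hat, config)
      list(id = id, asg = asg, mle = mle)
    })
    post <- t(vapply(rows, function(r) r$asg$posterior, numeric(5)))
    colnames(post) <- paste0("p_", POLICY_IDS)
    subjects <- data.frame(
      subject_id = vapply(rows, `[[`, character(1), "id"),
      group = g,
      map_policy = vapply(rows, function(r) r$asg$map, character(1)),
      post,
      loglik = vapply(rows, function(r) r$mle$loglik, numeric(1)),
      boundary = vapply(rows, function(r) r$mle$boundary, logical(1)),
      stringsAsFactors = FALSE)
    subjects$params <- lapply(rows, function(r) r$mle$params)
    list(group = g, surface = surface, estimate = surface$estimate,
         moments = surface_moments(surface), dbm = dbm_hat,
         subjects = subjects)
  })
  names(gfits) <- groups
  structure(list(groups = gfits,
                 subjects = do.call(rbind, lapply(gfits, `[[`, "subjects")),
                 config = config, call = match.call()),
            class = "bandit_fit")
}

#' @export
print.bandit_fit <- function(x, ...) {
  cat("Two-armed bandit learning + decision-policy fit\n\n")
  for (g in x$groups) {
    cat(sprintf("Group %s (%d subjects): gamma = %g, r = %g\n",
                g$group, g$surface$n_subjects,
                g$estimate["gamma"], g$estimate["r"]))
    tab <- table(factor(g$subjects$map_policy, levels = POLICY_IDS))
    cat("  policies:", paste(names(tab)[tab > 0], tab[tab > 0],
                             sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.bandit_fit <- function(object, ...) {
  t(vapply(object$groups, `[[`, numeric(2), "estimate"))
}

#' @export
logLik.bandit_fit <- function(object, ...) {
  val <- sum(vapply(object$groups, function(g) max(g$surface$loglik),
                    numeric(1)))
  structure(val, df = 2 * length(object$groups), class = "logLik")
}

#' @describeIn bandit_fit group comparison summary: surface-moment
#'   confidence intervals on the DBM parameter differences, the policy-count
#'   contingency test, and pooled t-tests on the fitted policy parameters
#'   (computed when the fit has exactly two groups).
#' @param object,x a `bandit_fit`.
#' @param ... unused.
#' @export
summary.bandit_fit <- function(object, ...) {
  out <- list(fit = object)
  gs <- object$groups
  if (length(gs) == 2) {
    out$dbm_comparison <- compare_groups_dbm(
      gs[[1]]$surface, gs[[2]]$surface,
      nrow(gs[[1]]$subjects), nrow(gs[[2]]$subjects))
    out$policy_report <- group_policy_report(object$subjects)
  }
  class(out) <- "summary.bandit_fit"
  out
}

#' @export
print.summary.bandit_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$dbm_comparison)) {
    gs <- names(x$fit$groups)
    cat(sprintf("\nDBM parameter comparison (%s - %s), surface-moment CI:\n",
                gs[1], gs[2]))
    print(x$dbm_comparison, row.names = FALSE)
  }
  if (!is.null(x$policy_report)) {
    cat("\nPolicy usage:\n")
    print(x$policy_report$counts)
    cat(sprintf("WSLS proportion chi-square = %.2f (df = %d, p = %.3g)\n",
                x$policy_report$chisq$statistic, x$policy_report$chisq$df,
                x$policy_report$chisq$p_value))
    if (nrow(x$policy_report$t_tests))
      print(x$policy_report$t_tests, row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn bandit_fit heat maps of the group surfaces on the
#'   `-2 log` marginal-likelihood scale (darker = better fit).
#' @export
plot.bandit_fit <- function(x, ...) {
  gs <- x$groups
  op <- graphics::par(mfrow = c(1, length(gs)))
  on.exit(graphics::par(op))
  for (g in gs) {
    z <- neg2_loglik(g$surface)
    graphics::image(g$surface$gamma_grid, g$surface$r_grid, z,
                    col = gray.colors(64, start = 0, end = 1),
                    xlab = expression(gamma), ylab = "r",
                    main = sprintf("%s  (-2 log marginal likelihood)",
                                   g$group), ...)
    graphics::points(g$estimate["gamma"], g$estimate["r"], pch = 4,
                     col = "red", lwd = 2)
  }
  invisible(x)
}

#' @describeIn bandit_fit simulate new cohorts from the fitted model: each
#'   subject replays the task with the group's fitted DBM parameters and
#'   their MAP policy at its MLE parameters.
#' @param nsim number of simulated cohorts.
#' @param seed master seed for the simulated cohorts.
#' @param task a [task_config()] for the simulated sessions.
#' @export
simulate.bandit_fit <- function(object, nsim = 1, seed = 1,
                                task = task_config(), ...) {
  specs <- lapply(seq_len(nrow(object$subjects)), function(i) {
    row <- object$subjects[i, ]
    g <- object$groups[[row$group]]
    agent_spec(row$subject_id, row$group, g$dbm,
               do.call(policy_spec, c(list(row$map_policy), row$params[[1]])))
  })
  sims <- lapply(seq_len(nsim), function(k)
    simulate_cohort(specs, task, master_seed = seed + k - 1))
  if (nsim == 1) sims[[1]] else sims
}

#' Group statistics on fitted decision policies
#'
#' From a subject-level policy table (as produced by [bandit_fit()]),
#' builds the 2x2 WSLS-vs-other count table with its Pearson chi-square
#' test, and pooled two-sample t-tests on the fitted WSLS parameters
#' (among WSLS users) and the Softmax exponent (among Softmax users).
#'
#' @param subjects data frame with columns `subject_id`, `group`,
#'   `map_policy` and a `params` list-column of MLE parameters.
#' @return list with `counts` (policy-by-group table), `chisq`, and
#'   `t_tests` (data frame; empty when a parameter has fewer than two users
#'   per group).
#' @export
group_policy_report <- function(subjects) {
  groups <- unique(subjects$group)
  stop_if_not(length(groups) == 2, "policy report requires exactly 2 groups")
  counts <- table(factor(subjects$group, levels = groups),
                  factor(subjects$map_policy, levels = POLICY_IDS))
  wsls_tab <- cbind(WSLS = counts[, "WSLS"],
                    other = rowSums(counts) - counts[, "WSLS"])
  chisq <- proportion_chisq(wsls_tab)
  param_of <- function(rows, nm) vapply(rows$params, function(p)
    if (!is.null(p[[nm]])) p[[nm]] else NA_real_, numeric(1))
  tt <- list()
  for (spec in list(c("WSLS", "gamma_w"), c("WSLS", "gamma_l"),
                    c("SOFTMAX", "b"))) {
    users <- subjects[subjects$map_policy == spec[1], , drop = FALSE]
    a <- param_of(users[users$group == groups[1], , drop = FALSE], spec[2])
    b <- param_of(users[users$group == groups[2], , drop = FALSE], spec[2])
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) >= 2 && length(b) >= 2) {
      r <- two_sample_t(a, b)
      tt[[length(tt) + 1]] <- data.frame(
        policy = spec[1], parameter = spec[2],
        mean_A = r$mean_A, mean_B = r$mean_B,
        t = r$statistic, df = r$df, p_value = r$p_value)
    }
  }
  list(counts = counts, chisq = chisq,
       t_tests = if (length(tt)) do.call(rbind, tt) else
         data.frame(policy = character(), parameter = character(),
                    mean_A = numeric(), mean_B = numeric(), t = numeric(),
                    df = numeric(), p_value = numeric()))
}
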