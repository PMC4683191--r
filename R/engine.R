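# Vectorized likelihood engine.
#
# The grid marginal-likelihood computation evaluates, for every lattice point
# (gamma, r), the DBM belief trajectory implied by a subject's observed
# choices and outcomes, and then the marginal likelihood of those choices
# under each of the five policies with policy parameters integrated against
# their priors. Everything here is vectorized across the lattice: belief
# weights are carried as grid_size x L matrices (one column per lattice
# point) so a whole surface costs one pass over the trials.

# DBM filter over one subject's sequence, simultaneously for L (gamma, r)
# pairs. Emits per-trial prior means and second moments per arm (n x L).
belief_trace_lattice <- function(choice, reward, trial, gamma, r,
                                 grid_size = 1001, prior_strength = 4) {
  n <- length(choice)
  L <- length(gamma)
  stopifnot(length(r) == L)
  grid <- seq(0, 1, length.out = grid_size)
  Q0 <- vapply(r, function(rr)
    discretize_beta(prior_strength * rr, prior_strength * (1 - rr), grid),
    numeric(grid_size))
  GammaM <- matrix(gamma, grid_size, L, byrow = TRUE)
  Q0g <- Q0 * (1 - GammaM)
  mu1 <- mu2 <- m21 <- m22 <- matrix(0, n, L)
  W1 <- W2 <- Q0
  for (t in seq_len(n)) {
    if (trial[t] == 1L) {
      W1 <- Q0
      W2 <- Q0
    } else {
      W1 <- W1 * GammaM + Q0g
      W2 <- W2 * GammaM + Q0g
    }
    Wt1 <- W1 * grid
    Wt2 <- W2 * grid
    mu1[t, ] <- .colSums(Wt1, grid_size, L)
    mu2[t, ] <- .colSums(Wt2, grid_size, L)
    m21[t, ] <- .colSums(Wt1 * grid, grid_size, L)
    m22[t, ] <- .colSums(Wt2 * grid, grid_size, L)
    if (choice[t] == 1L) {
      W <- if (reward[t] == 1L) Wt1 else W1 - Wt1
      s <- .colSums(W, grid_size, L)
      dead <- s <= 0           # impossible observation under point-mass belief
      if (any(dead)) { W[, dead] <- W1[, dead]; s[dead] <- 1 }
      W1 <- W * rep(1 / s, each = grid_size)
    } else {
      W <- if (reward[t] == 1L) Wt2 else W2 - Wt2
      s <- .colSums(W, grid_size, L)
      dead <- s <= 0
      if (any(dead)) { W[, dead] <- W2[, dead]; s[dead] <- 1 }
      W2 <- W * rep(1 / s, each = grid_size)
    }
  }
  list(mu1 = mu1, mu2 = mu2, m21 = m21, m22 = m22)
}

# Per-trial Bernoulli classification counts for the history-based policies
# (independent of beliefs, hence of the lattice).
#
# WSLS: trials following a win where the subject stayed/shifted, trials
# following a loss where the subject shifted/stayed, and first trials.
# tau-Switch: for each candidate tau, trials where the choice matched/missed
# the policy's target arm, plus tie (EQUAL-state and first) trials.
static_policy_counts <- function(choice, reward, trial, n_trials) {
  n <- length(choice)
  first <- trial == 1L
  prev <- c(NA_integer_, choice[-n])
  prev_rew <- c(NA_integer_, reward[-n])
  stay <- !first & choice == prev
  win <- !first & prev_rew == 1L
  wsls <- c(win_stay  = sum(win & stay),
            win_shift = sum(win & !stay),
            loss_shift = sum(!first & !win & !stay),
            loss_stay  = sum(!first & !win & stay),
            tie = sum(first))

  # within-game pre-trial success/failure counts per arm
  S1 <- S2 <- F1 <- F2 <- integer(n)
  s <- c(0L, 0L); f <- c(0L, 0L)
  for (t in seq_len(n)) {
    if (trial[t] == 1L) { s <- c(0L, 0L); f <- c(0L, 0L) }
    S1[t] <- s[1]; S2[t] <- s[2]; F1[t] <- f[1]; F2[t] <- f[2]
    a <- choice[t]
    if (reward[t] == 1L) s[a] <- s[a] + 1L else f[a] <- f[a] + 1L
  }
  ds <- sign(S1 - S2); df <- sign(F1 - F2)
  equal <- ds == 0L & df == 0L
  ee1 <- ds > 0L & df > 0L        # arm 1 exploit, arm 2 explore
  ee2 <- ds < 0L & df < 0L
  better1 <- !equal & !ee1 & !ee2 & ((ds > 0 & df <= 0) | (df < 0 & ds >= 0))
  better2 <- !equal & !ee1 & !ee2 & !better1

  tau_counts <- matrix(0L, n_trials, 3,
                       dimnames = list(NULL, c("match", "miss", "tie")))
  base_target <- ifelse(better1, 1L, ifelse(better2, 2L, NA_integer_))
  for (tau in seq_len(n_trials)) {
    target <- base_target
    explore_phase <- trial < tau
    target[ee1] <- ifelse(explore_phase[ee1], 2L, 1L)
    target[ee2] <- ifelse(explore_phase[ee2], 1L, 2L)
    tie <- is.na(target)
    tau_counts[tau, ] <- c(sum(!tie & choice == target),
                           sum(!tie & choice != target), sum(tie))
  }
  list(wsls = wsls, tau = tau_counts, n = n)
}

# log of the integral over [0,1] of g^a (1-g)^b under a uniform prior, by
# Gauss-Legendre quadrature, plus c ties at probability 0.5.
log_marg_bernoulli <- function(a, b, c, nodes) {
  c * log(0.5) +
    logsumexp(a * log(nodes$x) + b * log1p(-nodes$x), lw = log(nodes$w))
}

# Softmax log-likelihood of the observed choices for one value of b,
# vectorized over lattice columns. mu_c / mu_o: chosen / other arm's
# estimated rate (n x L).
softmax_loglik_b <- function(b, log_mu_c, log_mu_o) {
  l1 <- b * log_mu_c
  l2 <- b * log_mu_o
  m <- pmax(l1, l2)
  plog <- l1 - (m + log(exp(l1 - m) + exp(l2 - m)))
  .colSums(pmax(plog, log(PROB_FLOOR)), nrow(log_mu_c), ncol(log_mu_c))
}

# Knowledge-gradient deterministic arm per trial per lattice point, from the
# belief moments in closed form. A Bernoulli observation moves a belief's
# mean to E[theta^2]/mu (reward) or (mu - E[theta^2])/(1 - mu) (no reward),
# and the DBM transition then shrinks every mean toward r by factor gamma;
# only means are needed for the KG score, so the full grid enumeration of
# kg_value() collapses to these moment identities.
kg_arm_lattice <- function(tr, trial, n_trials, gamma, r) {
  n <- nrow(tr$mu1)
  L <- ncol(tr$mu1)
  G <- matrix(gamma, n, L, byrow = TRUE)
  Rk <- matrix((1 - gamma) * r, n, L, byrow = TRUE)
  nxt <- function(x) G * x + Rk
  post_win <- function(mu, m2) ifelse(mu > 0, m2 / mu, 0)
  post_loss <- function(mu, m2) ifelse(mu < 1, (mu - m2) / (1 - mu), 1)
  cur_max <- pmax(tr$mu1, tr$mu2)
  v <- function(mu_m, m2_m, mu_j) {
    other <- nxt(mu_j)
    mu_m * pmax(nxt(post_win(mu_m, m2_m)), other) +
      (1 - mu_m) * pmax(nxt(post_loss(mu_m, m2_m)), other) - cur_max
  }
  h <- pmax(n_trials - trial - 1, 0)
  s1 <- tr$mu1 + h * v(tr$mu1, tr$m21, tr$mu2)
  s2 <- tr$mu2 + h * v(tr$mu2, tr$m22, tr$mu1)
  list(arm1 = s1 > s2 + 1e-12, arm2 = s2 > s1 + 1e-12,
       tie = abs(s1 - s2) <= 1e-12)
}

# Log marginal likelihood of one subject's choices under each policy, with
# policy parameters integrated against their priors, for every lattice
# point. `tr` is the belief trace from belief_trace_lattice() at the same
# lattice. Returns an L x 5 matrix (columns in POLICY_IDS order).
policy_log_marginals <- function(arr, tr, gamma, r, config) {
  n <- length(arr$choice)
  L <- length(gamma)
  nodes <- gl_nodes(config$quadrature_nodes)
  out <- matrix(NA_real_, L, 5, dimnames = list(NULL, POLICY_IDS))

  sc <- static_policy_counts(arr$choice, arr$reward, arr$trial, arr$n_trials)
  # WSLS: uniform priors on gamma_w and gamma_l; the likelihood factorizes,
  # so the tensor-product quadrature is the product of two 1-D integrals.
  w <- sc$wsls
  out[, "WSLS"] <- w[["tie"]] * log(0.5) +
    logsumexp(w[["win_stay"]] * log(nodes$x) +
                w[["win_shift"]] * log1p(-nodes$x), lw = log(nodes$w)) +
    logsumexp(w[["loss_shift"]] * log(nodes$x) +
                w[["loss_stay"]] * log1p(-nodes$x), lw = log(nodes$w))
  # tau-Switch: discrete uniform over tau in 1..T, uniform gamma_tau.
  tau_margs <- apply(sc$tau, 1, function(ct)
    log_marg_bernoulli(ct[1], ct[2], ct[3], nodes))
  out[, "TAU_SWITCH"] <- logsumexp(tau_margs) - log(length(tau_margs))

  chose1 <- arr$choice == 1L
  # epsilon-Greedy: match = chose the higher-mean arm.
  dmu <- tr$mu1 - tr$mu2
  tie <- abs(dmu) <= 1e-12
  match <- ((dmu > 0) == chose1) & !tie
  a <- colSums(match)
  cties <- colSums(tie)
  b_ <- n - a - cties
  out[, "EPS_GREEDY"] <- vapply(seq_len(L), function(l)
    log_marg_bernoulli(b_[l], a[l], cties[l], nodes), numeric(1))
  # match contributes (1 - eps): reuse the helper with roles swapped above.

  # Softmax: Gamma(shape 1, scale 10) prior on b, integrated by GL quadrature
  # on the inverse-CDF transform u -> qgamma(u).
  log_mu1 <- log(pmax(tr$mu1, PROB_FLOOR))
  log_mu2 <- log(pmax(tr$mu2, PROB_FLOOR))
  log_mu_c <- log_mu1 * chose1 + log_mu2 * (!chose1)
  log_mu_o <- log_mu1 * (!chose1) + log_mu2 * chose1
  b_nodes <- stats::qgamma(nodes$x, shape = 1, scale = 10)
  sm <- vapply(b_nodes, softmax_loglik_b, numeric(L),
               log_mu_c = log_mu_c, log_mu_o = log_mu_o)
  if (L == 1L) sm <- matrix(sm, nrow = 1L)
  out[, "SOFTMAX"] <- apply(sm, 1, logsumexp, lw = log(nodes$w))

  # KG: uniform prior on gamma_kg; match = chose the deterministic KG arm.
  kg <- kg_arm_lattice(tr, arr$trial, arr$n_trials, gamma, r)
  kmatch <- (kg$arm1 & chose1) | (kg$arm2 & !chose1)
  ka <- colSums(kmatch)
  kt <- colSums(kg$tie)
  kb <- n - ka - kt
  out[, "KG"] <- vapply(seq_len(L), function(l)
    log_marg_bernoulli(ka[l], kb[l], kt[l], nodes), numeric(1))
  out
}
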