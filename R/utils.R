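# Internal numerical helpers shared across modules.

# Numerically stable log(sum(exp(x))); optional log-weights lw of same length.
logsumexp <- function(x, lw = NULL) {
  if (!is.null(lw)) x <- x + lw
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Legendre nodes/weights on [0, 1].
gl_nodes <- function(n) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  list(x = gl$x, w = gl$w)
}

# Per-trial choice probabilities are clamped here before logging so that
# deterministic-corner parameters yield very poor but finite likelihoods.
PROB_FLOOR <- 1e-12

clamp_log <- function(p) log(pmax(p, PROB_FLOOR))

# Stable 31-bit polynomial hash of a string, used to derive per-subject RNG
# streams from a master seed: adding a subject never perturbs the others.
hash_string <- function(s) {
  codes <- utf8ToInt(as.character(s))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

subject_seed <- function(master_seed, subject_id) {
  as.integer((as.numeric(master_seed) %% 2147483647 + hash_string(subject_id)) %%
               2147483647)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
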