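# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# AUC by exhaustive enumeration of all case-control pairs
auc_brute <- function(predicted, observed) {
  cases <- predicted[observed == 1]
  controls <- predicted[observed == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# closed-form log odds ratio of a saturated 2x2 table
logor_closed <- function(a, b, c, d) log((a * d) / (b * c))

# expand a 2x2 table (exposed cases/non-cases a/b, unexposed c/d) into
# per-record exposure and outcome vectors
counts_to_vectors <- function(a, b, c, d) {
  list(x = rep(c(1, 1, 0, 0), c(a, b, c, d)),
       y = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}

# brute-force maximum-likelihood for logit(p) = b0 + b1 * x by iterated
# grid refinement; independent of IRLS
grid_logistic <- function(x, y, lim = 10, rounds = 6, pts = 41) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  c0 <- 0; c1 <- 0; w <- lim
  for (r in seq_len(rounds)) {
    g0 <- seq(c0 - w, c0 + w, length.out = pts)
    g1 <- seq(c1 - w, c1 + w, length.out = pts)
    vals <- outer(g0, g1, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    c0 <- g0[best[1]]; c1 <- g1[best[2]]
    w <- w * 2.2 / (pts - 1) # keep a margin around the refined cell
  }
  c(b0 = c0, b1 = c1)
}

# a tiny well-spread prediction set for classification tests
toy_prediction_set <- function() {
  prediction_set(predicted = c(0.05, 0.10, 0.20, 0.40, 0.60, 0.90),
                 observed = c(0, 0, 1, 0, 1, 1))
}

# simulate a calibrated prediction set: outcomes drawn from their own
# predicted probabilities
calibrated_ps <- function(n, seed, shift = 0) {
  set.seed(seed)
  p <- stats::rbeta(n, 1.2, 60) # rare-event risk profile
  p <- pmin(pmax(p, 1e-4), 0.5)
  y <- stats::rbinom(n, 1, p)
  prediction_set(pmin(pmax(p + shift, 1e-6), 1 - 1e-6), y)
}

# the three group-indicator columns for a cohort data.frame
group_indicators <- function(group) {
  cbind(group2 = as.numeric(group == 2),
        group3 = as.numeric(group == 3),
        group4 = as.numeric(group == 4))
}
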