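# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (enumeration / brute force) and share no code with the
# implementations they check.

# Brute-force minimiser of 1/2||Ax - b||^2 over the probability simplex by
# grid search: a coarse global pass followed by a fine local pass around
# the coarse optimum (the objective is convex, so local refinement is
# sound). Resolution of the fine pass is `step_fine`.
oracle_simplex_grid <- function(A, b, step_coarse = 0.01, step_fine = 0.001) {
  obj <- function(X) {
    R <- X %*% t(A)
    0.5 * rowSums((R - matrix(b, nrow(X), length(b), byrow = TRUE))^2)
  }
  mk_grid <- function(lo, hi, step) {
    g <- lapply(seq_len(3), function(i) seq(max(0, lo[i]), min(1, hi[i]), by = step))
    X <- as.matrix(expand.grid(g))
    s <- rowSums(X)
    X <- X[s <= 1 + 1e-12, , drop = FALSE]
    cbind(X, pmax(0, 1 - rowSums(X)))
  }
  Xc <- mk_grid(c(0, 0, 0), c(1, 1, 1), step_coarse)
  oc <- obj(Xc)
  xb <- Xc[which.min(oc), 1:3]
  Xf <- mk_grid(xb - 1.5 * step_coarse, xb + 1.5 * step_coarse, step_fine)
  of <- obj(Xf)
  k <- which.min(of)
  list(x = Xf[k, ], obj = of[k])
}

# Exhaustive DTW: enumerate all monotone alignments between two short
# series recursively and return the minimum total |a_i - b_j| cost.
oracle_dtw_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(n, m)
}

# Exhaustive search over all deterministic stage-dependent policies of a
# small known MDP; returns the optimal expected total cost and one optimal
# policy (T x S matrix of action indices). Expected cost evaluated exactly
# by forward propagation of the state distribution.
oracle_enumerate_policies <- function(model) {
  S <- model$S; A <- model$A; T <- model$horizon
  n_dec <- S * T
  stopifnot(A^n_dec <= 2e5)
  best_J <- Inf; best_pol <- NULL
  pol <- matrix(1L, T, S)
  idx <- rep(1L, n_dec)
  repeat {
    pol[] <- idx
    mu <- model$mu0
    J <- 0
    for (t in seq_len(T)) {
      a_of <- pol[t, ]
      J <- J + sum(mu * model$cost[cbind(t, seq_len(S), a_of)])
      mu2 <- numeric(S)
      for (s in seq_len(S)) {
        if (mu[s] > 0) mu2 <- mu2 + mu[s] * model$P[s, a_of[s], ]
      }
      mu <- mu2
    }
    if (J < best_J - 1e-15) { best_J <- J; best_pol <- pol + 0L }
    k <- 1L
    while (k <= n_dec) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= A) break
      idx[k] <- 1L
      k <- k + 1L
    }
    if (k > n_dec) break
  }
  list(J = best_J, policy = best_pol)
}

# A small, fully specified 2-state / 2-action / T = 2 MDP with asymmetric
# dynamics and costs (no ties), used by the DP and PMD oracle tests.
toy_mdp_2s2a <- function() {
  P <- array(0, c(2, 2, 2))
  P[1, 1, ] <- c(0.8, 0.2)
  P[1, 2, ] <- c(0.3, 0.7)
  P[2, 1, ] <- c(0.5, 0.5)
  P[2, 2, ] <- c(0.1, 0.9)
  cost <- array(0, c(2, 2, 2))  # T x S x A
  cost[1, , ] <- matrix(c(1.0, 0.2,
                          0.6, 1.5), 2, 2, byrow = TRUE)
  cost[2, , ] <- matrix(c(0.4, 1.1,
                          2.0, 0.3), 2, 2, byrow = TRUE)
  mdp_model(P, cost, horizon = 2, mu0 = c(0.6, 0.4))
}

# Shared fixture: synthetic elemental dataset -> per-type KDE models.
fixture_feed_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata/elemental_synthetic_268.csv",
                          package = "adcontrol")
      cache <<- fit_feed_models(read_elemental_csv(path))
    }
    cache
  }
})
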