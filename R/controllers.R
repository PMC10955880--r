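# Control policies for the digester MDP: finite-horizon backward dynamic
# programming, a discrete PID baseline, and policy mirror descent (PMD)
# with Monte-Carlo / TD Q estimation and the closed-form KL update.
#
# Orientation convention: costs are minimised everywhere; value tables are
# cost-to-go (the reward-maximising form is the same recursion with max
# and negated costs).

#' Specify a known finite-horizon tabular MDP
#'
#' A fully enumerable model used for exact dynamic programming, exact
#' policy evaluation, and the brute-force oracles in the test suite.
#'
#' @param P Transition array `[S, A, S']` (stationary), each `P[s, a, ]` a
#'   probability vector.
#' @param cost Stage cost: `S x A` matrix (stationary) or `[T, S, A]` array.
#' @param horizon Number of stages T.
#' @param mu0 Initial-state distribution (default uniform).
#' @return Object of class `mdp_model`.
#' @export
mdp_model <- function(P, cost, horizon, mu0 = NULL) {
  S <- dim(P)[1]; A <- dim(P)[2]
  stopifnot(dim(P)[3] == S, horizon >= 1)
  rs <- apply(P, c(1, 2), sum)
  stopifnot(max(abs(rs - 1)) < 1e-9)
  if (length(dim(cost)) == 2) {
    cost <- aperm(array(cost, dim = c(S, A, horizon)), c(3, 1, 2))
  }
  stopifnot(all(dim(cost) == c(horizon, S, A)))
  if (is.null(mu0)) mu0 <- rep(1 / S, S)
  structure(list(P = P, cost = cost, horizon = horizon, mu0 = mu0,
                 S = S, A = A), class = "mdp_model")
}

#' Backward dynamic programming on a known model
#'
#' Solves the finite-horizon Bellman recursion from the terminal stage
#' backwards: terminal cost-to-go is identically zero, and at each stage
#' the value is the minimum over actions of immediate cost plus expected
#' next-stage value. Ties break to the lowest action index.
#'
#' @param model An [mdp_model()].
#' @return List: `value` (`(T+1) x S`, cost-to-go), `policy` (`T x S`
#'   integer greedy actions), `Q` (`T x S x A`).
#' @export
backward_dp <- function(model) {
  stopifnot(inherits(model, "mdp_model"))
  S <- model$S; A <- model$A; T <- model$horizon
  value <- matrix(0, T + 1, S)
  policy <- matrix(NA_integer_, T, S)
  Q <- array(NA_real_, c(T, S, A))
  Pm <- matrix(model$P, nrow = S * A)  # (s,a) rows over s'
  for (t in T:1) {
    ev <- Pm %*% value[t + 1, ]
    for (s in seq_len(S)) {
      q <- model$cost[t, s, ] + ev[s + S * (seq_len(A) - 1)]
      Q[t, s, ] <- q
      policy[t, s] <- which.min(q)
      value[t, s] <- q[policy[t, s]]
    }
  }
  list(value = value, policy = policy, Q = Q)
}

#' Exact evaluation of a (possibly stochastic, stage-varying) policy
#'
#' @param model An [mdp_model()].
#' @param policy `T x S x A` array of action probabilities, `S x A` matrix
#'   (stationary), or `T x S` integer matrix of deterministic actions.
#' @return List: `J` (expected total cost from `mu0`), `value`
#'   (`(T+1) x S`), `Q` (`T x S x A`).
#' @export
evaluate_policy <- function(model, policy) {
  stopifnot(inherits(model, "mdp_model"))
  S <- model$S; A <- model$A; T <- model$horizon
  pol <- .as_policy_array(policy, T, S, A)
  value <- matrix(0, T + 1, S)
  Q <- array(NA_real_, c(T, S, A))
  Pm <- matrix(model$P, nrow = S * A)
  for (t in T:1) {
    ev <- Pm %*% value[t + 1, ]
    for (s in seq_len(S)) {
      q <- model$cost[t, s, ] + ev[s + S * (seq_len(A) - 1)]
      Q[t, s, ] <- q
      value[t, s] <- sum(pol[t, s, ] * q)
    }
  }
  list(J = sum(model$mu0 * value[1, ]), value = value, Q = Q)
}

.as_policy_array <- function(policy, T, S, A) {
  if (is.array(policy) && length(dim(policy)) == 3) {
    stopifnot(all(dim(policy) == c(T, S, A)))
    return(policy)
  }
  if (is.matrix(policy) && !is.integer(policy[1, 1]) && ncol(policy) == A &&
      nrow(policy) == S) {
    out <- array(NA_real_, c(T, S, A))
    for (t in seq_len(T)) out[t, , ] <- policy
    return(out)
  }
  # deterministic T x S integer actions
  stopifnot(all(dim(policy) == c(T, S)))
  out <- array(0, c(T, S, A))
  for (t in seq_len(T)) for (s in seq_len(S)) out[t, s, policy[t, s]] <- 1
  out
}

#' Estimate an empirical MDP model of the digester from rollouts
#'
#' Runs episodes under uniformly random actions, pools the observed
#' transitions across stages (the reactor dynamics are treated as
#' stationary over the horizon), and returns empirical transition
#' frequencies on the environment's state grid. State-action pairs never
#' visited borrow the distribution of the nearest visited state (Euclidean
#' distance of grid centers) under the same action; the number of borrowed
#' pairs is reported.
#'
#' @param env A [digester_env()].
#' @param n_episodes Number of exploration episodes.
#' @param seed Integer seed.
#' @param explore `"walk"` (default): the exploratory action performs a
#'   persistent random walk on the action grid (steps of at most
#'   `walk_step` indices per control interval), which covers the
#'   quasi-steady operating regimes a controller actually visits;
#'   `"uniform"`: i.i.d. uniform actions.
#' @param walk_step Maximum index change per step for walk exploration.
#' @param shrink Pseudo-count weight for shrinking each (state, action)
#'   transition/cost estimate toward the pooled estimate over states
#'   sharing the same current-observation bin (same action). Sparsely
#'   visited pairs inherit the pooled behaviour; well visited pairs keep
#'   their own statistics.
#' @return List: `P` (`S x A x S'`), `visited` (`S x A` logical),
#'   `n_borrowed` (pairs with no own data), `n_sa` (own sample counts),
#'   `cost_of_target` (function(target_t) -> S x A expected immediate
#'   tracking cost), `ybar`.
#' @export
estimate_empirical_mdp <- function(env, n_episodes, seed = 1,
                                   explore = c("walk", "uniform"),
                                   walk_step = 2L, shrink = 5) {
  explore <- match.arg(explore)
  S <- env$n_states(); A <- env$n_actions()
  grid <- env$state_grid
  sizes <- lengths(grid)
  n1 <- sizes[1]
  # group index: states sharing all but the y_prev component
  grp_of <- 1L + (seq_len(S) - 1L) %/% n1
  G <- max(grp_of)
  counts <- array(0, c(S, A, S))
  gcounts <- array(0, c(G, A, S))
  ys <- vector("list", S * A)   # own next-y samples
  gys <- vector("list", G * A)  # pooled next-y samples
  set.seed(seed)
  for (ep in seq_len(n_episodes)) {
    s <- env$reset(seed = .derive_seed(seed, ep))
    a <- sample.int(A, 1)
    for (t in seq_len(env$horizon)) {
      if (explore == "uniform") {
        a <- sample.int(A, 1)
      } else {
        a <- max(1L, min(A, a + sample.int(2L * walk_step + 1L, 1) -
                           walk_step - 1L))
      }
      out <- env$step(a)
      g <- grp_of[s]
      counts[s, a, out$s_idx] <- counts[s, a, out$s_idx] + 1
      gcounts[g, a, out$s_idx] <- gcounts[g, a, out$s_idx] + 1
      ys[[s + S * (a - 1)]] <- c(ys[[s + S * (a - 1)]], out$y)
      gys[[g + G * (a - 1)]] <- c(gys[[g + G * (a - 1)]], out$y)
      s <- out$s_idx
    }
  }
  n_sa <- apply(counts, c(1, 2), sum)
  ng <- apply(gcounts, c(1, 2), sum)
  visited <- n_sa > 0
  # fallback for groups with no data under an action: nearest group by
  # current-observation center (then remaining coordinates)
  rep_state <- match(seq_len(G), grp_of)
  gcent <- t(vapply(rep_state, function(s) grid_center(grid, s),
                    numeric(length(grid))))[, -1, drop = FALSE]
  scl <- apply(gcent, 2, function(z) max(stats::sd(z), 1e-12))
  gcn <- sweep(gcent, 2, scl, "/")
  gsrc <- matrix(NA_integer_, G, A)
  for (a in seq_len(A)) {
    vis <- which(ng[, a] > 0)
    if (!length(vis)) stop("action ", a, " never sampled; increase episodes",
                           call. = FALSE)
    for (g in seq_len(G)) {
      if (ng[g, a] > 0) { gsrc[g, a] <- g; next }
      d2 <- rowSums((gcn[vis, , drop = FALSE] -
                       matrix(gcn[g, ], length(vis), ncol(gcn), byrow = TRUE))^2)
      gsrc[g, a] <- vis[which.min(d2)]
    }
  }
  P <- array(0, c(S, A, S))
  ysamples <- vector("list", S * A)
  wsamples <- vector("list", S * A)  # sample weights (own = 1, pooled < 1)
  n_borrowed <- 0L
  for (s in seq_len(S)) {
    g <- grp_of[s]
    for (a in seq_len(A)) {
      gs <- gsrc[g, a]
      pg <- gcounts[gs, a, ] / sum(gcounts[gs, a, ])
      if (visited[s, a]) {
        P[s, a, ] <- (counts[s, a, ] + shrink * pg) / (n_sa[s, a] + shrink)
        own <- ys[[s + S * (a - 1)]]
        pool <- gys[[gs + G * (a - 1)]]
        ysamples[[s + S * (a - 1)]] <- c(own, pool)
        wsamples[[s + S * (a - 1)]] <-
          c(rep(1, length(own)), rep(shrink / length(pool), length(pool)))
      } else {
        n_borrowed <- n_borrowed + 1L
        P[s, a, ] <- pg
        ysamples[[s + S * (a - 1)]] <- gys[[gs + G * (a - 1)]]
        wsamples[[s + S * (a - 1)]] <-
          rep(1, length(gys[[gs + G * (a - 1)]]))
      }
    }
  }
  cost_of_target <- function(target_t) {
    m <- matrix(NA_real_, S, A)
    for (s in seq_len(S)) for (a in seq_len(A)) {
      yy <- ysamples[[s + S * (a - 1)]]
      ww <- wsamples[[s + S * (a - 1)]]
      m[s, a] <- sum(ww * abs(yy - target_t)) / sum(ww)
    }
    m
  }
  list(P = P, visited = visited, n_borrowed = n_borrowed, n_sa = n_sa,
       cost_of_target = cost_of_target)
}

#' Fit a stochastic one-step observation model from exploration rollouts
#'
#' Runs persistent-random-walk exploration episodes and regresses the next
#' window-average biogas observation on the current observation level,
#' slope, and commanded total flow (quadratic response surface with
#' level-flow interaction). The residual standard deviation captures the
#' feed-composition-driven process noise.
#'
#' @param env A [digester_env()].
#' @param n_episodes Exploration episodes.
#' @param seed Integer seed.
#' @param walk_step Maximum action-index change per step.
#' @return List: `fit` (lm), `sigma` (residual sd), `data`, `predict`
#'   (function(y, dy, u) -> mean next observation).
#' @export
fit_transition_model <- function(env, n_episodes, seed = 1, walk_step = 2L,
                                 burn_in = 2L) {
  A <- env$n_actions()
  u_of <- rowSums(env$action_grid)
  set.seed(seed)
  rows <- vector("list", n_episodes * env$horizon)
  k <- 0L
  for (ep in seq_len(n_episodes)) {
    env$reset(seed = .derive_seed(seed, ep))
    ob <- env$obs()
    y <- ob[2]; dy <- ob[1]
    a <- sample.int(A, 1)
    for (t in seq_len(env$horizon)) {
      a <- max(1L, min(A, a + sample.int(2L * walk_step + 1L, 1) - walk_step - 1L))
      out <- env$step(a)
      # the first observations mix instantaneous and window-average rates;
      # keep only on-manifold transitions
      if (t > burn_in) {
        k <- k + 1L
        rows[[k]] <- c(y = y, dy = dy, u = u_of[a], ynext = out$y)
      }
      dy <- out$y - y
      y <- out$y
    }
  }
  df <- as.data.frame(do.call(rbind, rows[seq_len(k)]))
  fit <- stats::lm(ynext ~ y + I(y^2) + dy + u + I(u^2) + u:y, data = df)
  sigma <- stats::sd(stats::residuals(fit))
  list(fit = fit, sigma = sigma, data = df,
       predict = function(y, dy, u) {
         as.numeric(stats::predict(fit, data.frame(y = y, dy = dy, u = u)))
       })
}

# E|X - 0| for X ~ N(m, sd): folded-normal mean
.enorm_abs <- function(m, sd) {
  sd * sqrt(2 / pi) * exp(-m^2 / (2 * sd^2)) + m * (1 - 2 * stats::pnorm(-m / sd))
}

#' Backward DP for biogas target tracking from sampled transitions
#'
#' Learns a one-step observation model from exploration rollouts and
#' solves the finite-horizon Bellman recursion exactly on the discretised
#' state space. Two model estimators are available: `"regression"`
#' (default, [fit_transition_model()]: Gaussian next-observation model,
#' sample-efficient and smooth -- stage costs are the closed-form folded-
#' normal expected tracking error) and `"tabular"`
#' ([estimate_empirical_mdp()]: empirical transition frequencies with
#' shrinkage, assumption-free but data-hungry).
#'
#' @param env A tracking-mode [digester_env()].
#' @param target Target biogas series, length `env$horizon`.
#' @param n_episodes Exploration episodes for model estimation.
#' @param seed Integer seed.
#' @param method `"regression"` or `"tabular"`.
#' @return List as [backward_dp()], plus the fitted model (`transition` or
#'   `empirical`).
#' @export
backward_dp_sampled <- function(env, target, n_episodes = 50, seed = 1,
                                method = c("regression", "tabular")) {
  method <- match.arg(method)
  S <- env$n_states(); A <- env$n_actions(); T <- env$horizon
  if (method == "tabular") {
    emp <- estimate_empirical_mdp(env, n_episodes, seed)
    cost <- array(NA_real_, c(T, S, A))
    for (lev in unique(target)) {
      m <- emp$cost_of_target(lev)
      for (t in which(target == lev)) cost[t, , ] <- m
    }
    model <- mdp_model(emp$P, cost, T)
    fit <- backward_dp(model)
    return(c(fit, list(empirical = emp)))
  }
  tm <- fit_transition_model(env, n_episodes, seed)
  grid <- env$state_grid
  dy_c <- grid[[1]]; y_c <- grid[[2]]
  n_dy <- length(dy_c); n_y <- length(y_c)
  extra <- if (length(grid) > 2) prod(lengths(grid)[-(1:2)]) else 1
  w <- diff(y_c[1:2])
  edges <- c(-Inf, y_c[-n_y] + w / 2, Inf)
  u_of <- rowSums(env$action_grid)
  centers <- t(vapply(seq_len(S), function(s) grid_center(grid, s),
                      numeric(length(grid))))
  P <- array(0, c(S, A, S))
  mu <- matrix(NA_real_, S, A)
  for (s in seq_len(S)) {
    yv <- centers[s, 2]; dyv <- centers[s, 1]
    rest <- (s - 1L) %/% (n_dy * n_y)  # non-observation coordinates kept fixed
    for (a in seq_len(A)) {
      m <- tm$predict(yv, dyv, u_of[a])
      mu[s, a] <- m
      pj <- diff(stats::pnorm(edges, mean = m, sd = tm$sigma))
      for (j in seq_len(n_y)) {
        dyb <- which.min(abs(dy_c - (y_c[j] - yv)))
        s2 <- dyb + n_dy * (j - 1L) + n_dy * n_y * rest
        P[s, a, s2] <- P[s, a, s2] + pj[j]
      }
    }
  }
  cost <- array(NA_real_, c(T, S, A))
  for (t in seq_len(T)) {
    cost[t, , ] <- .enorm_abs(mu - target[t], tm$sigma)
  }
  model <- mdp_model(P, cost, T)
  fit <- backward_dp(model)
  c(fit, list(transition = tm, target = target, u_of = u_of,
              state_grid = grid))
}

#' Continuous-observation greedy action from a DP fit
#'
#' One-step lookahead at the continuous observation (no feedback
#' quantisation): immediate folded-normal expected tracking cost from the
#' fitted transition model plus the DP value table at the successor bins.
#' Falls back to the tabulated greedy policy for tabular fits.
#'
#' @param dp_fit Fit from [backward_dp_sampled()] (regression method).
#' @param t Stage index.
#' @param y,dy Continuous current observation and slope.
#' @return Action index.
#' @export
dp_greedy_action <- function(dp_fit, t, y, dy) {
  tm <- dp_fit$transition
  grid <- dp_fit$state_grid
  dy_c <- grid[[1]]; y_c <- grid[[2]]
  n_dy <- length(dy_c); n_y <- length(y_c)
  w <- diff(y_c[1:2])
  edges <- c(-Inf, y_c[-n_y] + w / 2, Inf)
  Tq <- nrow(dp_fit$policy)
  vnext <- dp_fit$value[min(t + 1, Tq + 1), ]
  target_t <- dp_fit$target[t]
  best <- 1L; best_q <- Inf
  for (a in seq_along(dp_fit$u_of)) {
    m <- tm$predict(y, dy, dp_fit$u_of[a])
    q <- .enorm_abs(m - target_t, tm$sigma)
    pj <- diff(stats::pnorm(edges, mean = m, sd = tm$sigma))
    for (j in seq_len(n_y)) {
      if (pj[j] == 0) next
      dyb <- which.min(abs(dy_c - (y_c[j] - y)))
      q <- q + pj[j] * vnext[dyb + n_dy * (j - 1L)]
    }
    if (q < best_q - 1e-12) { best_q <- q; best <- a }
  }
  best
}

#' Discrete PID controller step
#'
#' Standard positional PID with clamped output and clamped (anti-windup)
#' integral. The scalar command is a total feed flow; [pid_action()] maps
#' it to the nearest action on a flow grid.
#'
#' @param config List: gains `Kp`, `Ki`, `Kd`, sampling period `dt`, output
#'   clamps `u_min`/`u_max`, integral clamp `i_max`, steady-state `bias`.
#' @param ctrl_state List with `integral` and `e_prev` (use
#'   [pid_init_state()] at episode start).
#' @param error Setpoint minus measurement (here: target minus biogas rate).
#' @return List: `u` (clamped command), `state` (updated controller state),
#'   `u_raw`.
#' @export
pid_step <- function(config, ctrl_state, error) {
  dt <- config$dt
  stopifnot(dt > 0)
  integral <- ctrl_state$integral + error * dt
  integral <- max(min(integral, config$i_max), -config$i_max)
  deriv <- if (is.na(ctrl_state$e_prev)) 0 else (error - ctrl_state$e_prev) / dt
  u <- config$bias + config$Kp * error + config$Ki * integral + config$Kd * deriv
  u_cl <- max(min(u, config$u_max), config$u_min)
  list(u = u_cl, u_raw = u,
       state = list(integral = integral, e_prev = error))
}

#' @rdname pid_step
#' @export
pid_init_state <- function() list(integral = 0, e_prev = NA_real_)

#' Default PID configuration for the digester
#'
#' Gains were fixed by a coarse grid search minimising tracking MAE on a
#' nominal (uncertainty-free) episode; see the tuning script shipped in
#' `scripts/`.
#'
#' @param u_max Maximum total feed flow, m3 d-1.
#' @param bias Steady-state feed flow, m3 d-1.
#' @return Config list for [pid_step()].
#' @export
pid_default_config <- function(u_max = 200, bias = 60) {
  list(Kp = 0.02, Ki = 0.01, Kd = 0.005, dt = 1,
       u_min = 0, u_max = u_max, i_max = 2000, bias = bias)
}

#' Map a scalar total-flow command to a feed action
#'
#' Picks the action-grid row whose total flow is nearest the command,
#' breaking ties toward the configured mixing ratio (equal thirds by
#' default).
#'
#' @param u Total flow command, m3 d-1.
#' @param action_grid Matrix of flow triples.
#' @param ratio Preferred mixing proportions (normalised internally).
#' @return Action row index.
#' @export
pid_action <- function(u, action_grid, ratio = c(1, 1, 1)) {
  ratio <- ratio / sum(ratio)
  tot <- rowSums(action_grid)
  cand <- which(abs(tot - u) == min(abs(tot - u)))
  if (length(cand) == 1) return(cand)
  mix <- action_grid[cand, , drop = FALSE] / pmax(tot[cand], 1e-12)
  cand[which.min(rowSums((mix - matrix(ratio, length(cand), 3, byrow = TRUE))^2))]
}

#' Kullback-Leibler divergence between two policy rows
#'
#' @param p,q Probability vectors over the same action set; `q` must be
#'   positive wherever `p` is.
#' @return `sum(p * log(p / q))`, zero iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  sup <- p > 0
  if (any(q[sup] == 0)) stop("support violation: q = 0 where p > 0", call. = FALSE)
  sum(p[sup] * log(p[sup] / q[sup]))
}

#' Closed-form policy mirror descent update
#'
#' With a uniform initial policy, KL Bregman divergence, and zero convex
#' regulariser, the PMD proximal step has the closed form
#' `pi' propto exp{(log pi - eta * Q) / (eta * tau + 1)}` applied row by
#' row; with `tau = 0` this is the classic multiplicative-weights /
#' mirror-descent update `pi' propto pi * exp(-eta * Q)`. Overflow is
#' guarded by max-subtraction before exponentiation.
#'
#' @param policy `S x A` matrix of action probabilities (rows sum to 1).
#' @param Q `S x A` matrix of Q-values (cost orientation: larger is worse).
#' @param eta Step size (> 0).
#' @param tau Perturbation coefficient (>= 0).
#' @param policy0 Optional initial policy; the closed form assumes it is
#'   uniform and this is checked if supplied.
#' @return Updated `S x A` policy matrix.
#' @export
pmd_update <- function(policy, Q, eta, tau = 0, policy0 = NULL) {
  stopifnot(eta > 0, tau >= 0, all(dim(policy) == dim(Q)))
  if (!is.null(policy0) &&
      max(abs(policy0 - 1 / ncol(policy))) > 1e-9) {
    stop("closed-form update assumes a uniform initial policy", call. = FALSE)
  }
  lg <- (log(pmax(policy, 1e-300)) - eta * Q) / (eta * tau + 1)
  lg <- lg - apply(lg, 1, max)
  w <- exp(lg)
  w / rowSums(w)
}

#' Estimate the Q-function of a policy from on-policy rollouts
#'
#' Runs `n_episodes` episodes following `policy` and estimates the
#' stage-wise Q-table either by every-visit Monte-Carlo averaging of
#' cost-to-go (default; a bias-free batch analogue of the conditional TD
#' estimators used for PMD) or by on-policy TD(0) (SARSA-style) with step
#' size `alpha`. Pairs never visited keep `q_init`; the count is returned.
#'
#' @param env Environment (a [digester_env()] or [mdp_env()]).
#' @param policy `T x S x A` array (or `S x A` matrix, applied at every
#'   stage) of action probabilities.
#' @param n_episodes Episode budget.
#' @param method `"mc"` or `"td"`.
#' @param alpha TD step size.
#' @param q_init Initial Q value for unvisited pairs.
#' @param impute `"row-mean"` (default): after estimation, pairs never
#'   visited in a (stage, state) row take the mean of that row's visited
#'   entries, so the policy update neither rewards nor punishes untried
#'   actions; `"none"` keeps `q_init`.
#' @param seed Integer seed.
#' @return List: `Q` (`T x S x A`), `visits`, `n_unvisited`, `avg_cost`
#'   (mean episode total cost).
#' @export
estimate_q <- function(env, policy, n_episodes, method = c("mc", "td"),
                       alpha = 0.2, q_init = 0,
                       impute = c("row-mean", "none"), seed = 1,
                       stationary = FALSE, gamma = 0.9) {
  impute <- match.arg(impute)
  method <- match.arg(method)
  S <- env$n_states(); A <- env$n_actions(); T <- env$horizon
  if (stationary) {
    return(.estimate_q_stationary(env, policy, n_episodes, alpha, q_init,
                                  impute, seed, gamma))
  }
  pol <- .as_policy_array(policy, T, S, A)
  Q <- array(q_init, c(T, S, A))
  Wsum <- array(0, c(T, S, A))
  visits <- array(0L, c(T, S, A))
  set.seed(seed)
  total_costs <- numeric(n_episodes)
  for (ep in seq_len(n_episodes)) {
    s <- env$reset(seed = .derive_seed(seed, ep))
    ss <- integer(T); aa <- integer(T); cc <- numeric(T)
    for (t in seq_len(T)) {
      a <- sample.int(A, 1, prob = pol[t, s, ])
      out <- env$step(a)
      ss[t] <- s; aa[t] <- a; cc[t] <- out$cost
      s <- out$s_idx
    }
    total_costs[ep] <- sum(cc)
    if (method == "mc") {
      g <- rev(cumsum(rev(cc)))  # cost-to-go
      for (t in seq_len(T)) {
        w <- Wsum[t, ss[t], aa[t]] + 1
        Q[t, ss[t], aa[t]] <- Q[t, ss[t], aa[t]] +
          (g[t] - Q[t, ss[t], aa[t]]) / w
        Wsum[t, ss[t], aa[t]] <- w
        visits[t, ss[t], aa[t]] <- visits[t, ss[t], aa[t]] + 1L
      }
    } else {
      for (t in seq_len(T)) {
        nxt <- if (t < T) sum(pol[t + 1, ss[t + 1], ] * Q[t + 1, ss[t + 1], ]) else 0
        delta <- cc[t] + nxt - Q[t, ss[t], aa[t]]
        Q[t, ss[t], aa[t]] <- Q[t, ss[t], aa[t]] + alpha * delta
        visits[t, ss[t], aa[t]] <- visits[t, ss[t], aa[t]] + 1L
      }
    }
  }
  if (impute == "row-mean") {
    for (t in seq_len(T)) for (s in seq_len(S)) {
      vis <- visits[t, s, ] > 0
      if (any(vis) && !all(vis)) Q[t, s, !vis] <- mean(Q[t, s, vis])
    }
  }
  list(Q = Q, visits = visits, n_unvisited = sum(visits == 0),
       avg_cost = mean(total_costs))
}

# Stationary discounted Q estimation (on-policy SARSA) for the long-term
# routine-production setting: one S x A table shared across stages.
.estimate_q_stationary <- function(env, policy, n_episodes, alpha, q_init,
                                   impute, seed, gamma) {
  S <- env$n_states(); A <- env$n_actions(); T <- env$horizon
  pol <- if (is.matrix(policy)) policy else policy[1, , , drop = TRUE]
  Q <- matrix(q_init, S, A)
  visits <- matrix(0L, S, A)
  set.seed(seed)
  total_costs <- numeric(n_episodes)
  for (ep in seq_len(n_episodes)) {
    s <- env$reset(seed = .derive_seed(seed, ep))
    a <- sample.int(A, 1, prob = pol[s, ])
    tot <- 0
    for (t in seq_len(T)) {
      out <- env$step(a)
      tot <- tot + out$cost
      s2 <- out$s_idx
      a2 <- sample.int(A, 1, prob = pol[s2, ])
      nxt <- if (t < T) gamma * Q[s2, a2] else 0
      visits[s, a] <- visits[s, a] + 1L
      Q[s, a] <- Q[s, a] + alpha * (out$cost + nxt - Q[s, a]) /
        max(1, visits[s, a])^0.25
      s <- s2; a <- a2
    }
    total_costs[ep] <- tot
  }
  if (impute == "row-mean") {
    for (s in seq_len(S)) {
      vis <- visits[s, ] > 0
      if (any(vis) && !all(vis)) Q[s, !vis] <- mean(Q[s, vis])
    }
  }
  list(Q = Q, visits = visits, n_unvisited = sum(visits == 0),
       avg_cost = mean(total_costs))
}

#' Wrap a known [mdp_model()] as a sampling environment
#'
#' @param model An [mdp_model()].
#' @return Environment with the same interface as [digester_env()].
#' @export
mdp_env <- function(model) {
  stopifnot(inherits(model, "mdp_model"))
  e <- new.env(parent = emptyenv())
  list(
    reset = function(seed = NULL) {
      if (!is.null(seed)) set.seed(seed)
      e$t <- 1L
      e$s <- sample.int(model$S, 1, prob = model$mu0)
      e$s
    },
    step = function(a) {
      s2 <- sample.int(model$S, 1, prob = model$P[e$s, a, ])
      cost <- model$cost[e$t, e$s, a]
      e$s <- s2; e$t <- e$t + 1L
      list(s_idx = s2, cost = cost, y = NA_real_)
    },
    n_states = function() model$S,
    n_actions = function() model$A,
    horizon = model$horizon)
}

#' Train a policy by policy mirror descent
#'
#' Alternates Q estimation and the closed-form KL update for `K`
#' iterations, starting from the uniform policy. With `exact_model`
#' supplied, Q is computed by exact policy evaluation (deterministic
#' training, used by the oracle tests); otherwise Q is estimated from
#' on-policy rollouts of `env`.
#'
#' @param env Sampling environment (ignored when `exact_model` given).
#' @param config List: `K` iterations, `eta` step size, `tau0` initial
#'   perturbation, `tau_decay` geometric factor per iteration,
#'   `episodes_per_iter`, `method` for [estimate_q()].
#' @param seed Integer seed.
#' @param exact_model Optional [mdp_model()] for exact evaluation.
#' @return List: `policy` (`T x S x A`), `avg_cost` per-iteration trace,
#'   `config`.
#' @export
train_pmd <- function(env, config = pmd_default_config(), seed = 1,
                      exact_model = NULL) {
  if (!is.null(exact_model)) env <- mdp_env(exact_model)
  S <- env$n_states(); A <- env$n_actions(); T <- env$horizon
  stationary <- isTRUE(config$stationary) && is.null(exact_model)
  pol <- if (stationary) matrix(1 / A, S, A) else array(1 / A, c(T, S, A))
  trace <- numeric(0)
  tau <- config$tau0
  for (k in seq_len(config$K)) {
    if (!is.null(exact_model)) {
      ev <- evaluate_policy(exact_model, pol)
      Q <- ev$Q
      trace <- c(trace, ev$J)
    } else {
      qe <- estimate_q(env, pol, config$episodes_per_iter,
                       method = config$method, seed = .derive_seed(seed, k),
                       stationary = stationary, gamma = config$gamma)
      Q <- qe$Q
      trace <- c(trace, qe$avg_cost)
    }
    if (length(trace) > 5 &&
        all(utils::tail(trace, 5) > 10 * trace[1]) && trace[1] > 0) {
      stop("PMD diverged: average cost > 10x initial for 5 iterations",
           call. = FALSE)
    }
    if (stationary) {
      pol <- pmd_update(pol, Q, eta = config$eta, tau = tau)
    } else {
      for (t in seq_len(T)) {
        pol[t, , ] <- pmd_update(pol[t, , , drop = TRUE], Q[t, , , drop = TRUE],
                                 eta = config$eta, tau = tau)
      }
    }
    tau <- tau * config$tau_decay
  }
  if (stationary) {
    full <- array(NA_real_, c(T, S, A))
    for (t in seq_len(T)) full[t, , ] <- pol
    pol <- full
  }
  list(policy = pol, avg_cost = trace, config = config)
}

#' @rdname train_pmd
#' @export
pmd_default_config <- function(K = 20, eta = 1, tau0 = 0.1, tau_decay = 0.5,
                               episodes_per_iter = 20, method = "mc",
                               stationary = FALSE, gamma = 0.9) {
  list(K = K, eta = eta, tau0 = tau0, tau_decay = tau_decay,
       episodes_per_iter = episodes_per_iter, method = method,
       stationary = stationary, gamma = gamma)
}

#' Serialise a policy with its grid metadata to JSON
#'
#' @param policy `T x S x A` policy array (or DP fit list with `policy`).
#' @param path Output path.
#' @param state_grid,action_grid Grid metadata stored alongside.
#' @return `path`, invisibly.
#' @export
policy_save <- function(policy, path, state_grid = NULL, action_grid = NULL) {
  obj <- list(policy = as.vector(policy), dim = dim(policy),
              state_grid = state_grid, action_grid = action_grid)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname policy_save
#' @export
policy_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$policy <- array(unlist(obj$policy), dim = obj$dim)
  obj
}
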