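# DP, PID, KL/PMD updates, Q estimation.

test_that("backward DP equals brute-force policy enumeration on the toy MDP", {
  model <- toy_mdp_2s2a()
  fit <- backward_dp(model)
  orc <- oracle_enumerate_policies(model)
  J_dp <- sum(model$mu0 * fit$value[1, ])
  expect_equal(J_dp, orc$J, tolerance = 1e-12)
  expect_identical(unname(fit$policy), unname(orc$policy))
})

test_that("T = 1 DP is the per-state myopic argmin; ties break low", {
  P <- array(0, c(2, 2, 2)); P[, , 1] <- 0.5; P[, , 2] <- 0.5
  cost <- matrix(c(0.3, 0.9,
                   0.7, 0.1), 2, 2, byrow = TRUE)
  fit <- backward_dp(mdp_model(P, cost, horizon = 1))
  expect_identical(as.integer(fit$policy), c(1L, 2L))
  zero <- backward_dp(mdp_model(P, matrix(0, 2, 2), horizon = 3))
  expect_true(all(zero$value == 0))
  expect_true(all(zero$policy == 1L))  # lowest-index tie break
})

test_that("DP value table is stage-monotone under non-negative costs", {
  model <- toy_mdp_2s2a()
  fit <- backward_dp(model)
  # cost-to-go with fewer remaining stages can only shrink
  expect_true(all(fit$value[1, ] >= fit$value[2, ] - 1e-12))
  expect_true(all(fit$value[2, ] >= fit$value[3, ]))
})

test_that("pid_step: bias, P-only, derivative kick, clamps", {
  cfg <- list(Kp = 2, Ki = 0.5, Kd = 1, dt = 0.5, u_min = -10, u_max = 10,
              i_max = 4, bias = 3)
  st <- pid_init_state()
  r0 <- pid_step(cfg, st, 0)
  expect_equal(r0$u, 3)  # zero error -> bias only
  cfgP <- list(Kp = 2, Ki = 0, Kd = 0, dt = 1, u_min = -100, u_max = 100,
               i_max = 10, bias = 1)
  st <- pid_init_state()
  for (i in 1:3) { r <- pid_step(cfgP, st, 1.5); st <- r$state }
  expect_equal(r$u, 1 + 2 * 1.5)  # constant error, P-only
  # first-step derivative kick Kd * e / dt on a step error
  st <- pid_init_state()
  r1 <- pid_step(cfg, st, 0); st <- r1$state
  r2 <- pid_step(cfg, st, 2)
  kick <- cfg$Kd * (2 - 0) / cfg$dt
  expect_equal(r2$u_raw, cfg$bias + cfg$Kp * 2 + cfg$Ki * min(cfg$i_max, 0 + 2 * 0.5) + kick)
  # anti-windup: integral never exceeds i_max
  st <- pid_init_state()
  for (i in 1:50) { r <- pid_step(cfg, st, 100); st <- r$state }
  expect_equal(st$integral, cfg$i_max)
  expect_equal(r$u, cfg$u_max)  # output clamp
})

test_that("pid_action maps commands to the nearest grid total", {
  grid <- default_action_grid(c(0, 30, 60, 90))
  expect_equal(pid_action(0, grid), 1)
  expect_equal(pid_action(58, grid), 3)
  expect_equal(pid_action(500, grid), 4)
})

test_that("kl_divergence: identity, hand value, asymmetry, support", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2))
  p <- c(0.9, 0.1); q <- c(0.5, 0.5)
  expect_false(isTRUE(all.equal(kl_divergence(p, q), kl_divergence(q, p))))
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "support")
})

test_that("pmd_update: closed form, shift invariance, monotonicity", {
  pol <- matrix(0.5, 1, 2)
  # constant Q leaves the row unchanged
  expect_equal(pmd_update(pol, matrix(c(3, 3), 1), eta = 0.7, tau = 0.2),
               pol)
  # hand evaluation: Q = (1, 0), eta = 1, tau = 0, uniform prior
  up <- pmd_update(pol, matrix(c(1, 0), 1), eta = 1, tau = 0)
  expect_equal(as.numeric(up), c(exp(-1), 1) / (exp(-1) + 1), tolerance = 1e-12)
  expect_equal(round(as.numeric(up), 3), c(0.269, 0.731))
  # larger Q -> strictly smaller updated probability
  up2 <- pmd_update(matrix(0.25, 1, 4), matrix(c(0, 1, 2, 3), 1), eta = 0.5)
  expect_true(all(diff(as.numeric(up2)) < 0))
  # tau = 0 reduces to pi * exp(-eta Q), at machine precision
  set.seed(4)
  pol3 <- matrix(rgamma(6, 1), 2); pol3 <- pol3 / rowSums(pol3)
  Q3 <- matrix(rnorm(6), 2)
  ref <- pol3 * exp(-1.3 * Q3); ref <- ref / rowSums(ref)
  expect_equal(pmd_update(pol3, Q3, eta = 1.3, tau = 0), ref,
               tolerance = 1e-14)
  # rows remain distributions with preserved support
  up3 <- pmd_update(pol3, Q3, eta = 2, tau = 0.3)
  expect_equal(rowSums(up3), c(1, 1), tolerance = 1e-12)
  expect_true(all(up3 > 0))
  expect_error(pmd_update(pol, matrix(0, 1, 2), eta = 1,
                          policy0 = matrix(c(0.9, 0.1), 1)), "uniform")
})

test_that("estimate_q: deterministic one-step env gives exact costs", {
  P <- array(0, c(2, 2, 2)); P[, , 1] <- 1
  cost <- matrix(c(0.2, 0.8, 0.5, 0.1), 2, 2, byrow = TRUE)
  model <- mdp_model(P, cost, horizon = 1)
  env <- mdp_env(model)
  qe <- estimate_q(env, matrix(0.5, 2, 2), n_episodes = 200, seed = 3)
  vis <- qe$visits[1, , ] > 0
  expect_true(all(abs(qe$Q[1, , ][vis] - cost[vis]) < 1e-12))
})

test_that("estimate_q converges to the exact Q on the toy MDP", {
  model <- toy_mdp_2s2a()
  pol <- matrix(0.5, 2, 2)
  exact <- evaluate_policy(model, pol)$Q
  env <- mdp_env(model)
  qe <- estimate_q(env, pol, n_episodes = 4000, method = "mc", seed = 11)
  err_big <- max(abs(qe$Q - exact))
  expect_lt(err_big, 0.06)
  # doubling the budget shrinks the error (trend over seeds)
  errs <- function(n) {
    med <- sapply(1:5, function(sd) {
      q <- estimate_q(env, pol, n_episodes = n, method = "mc", seed = sd)
      sqrt(mean((q$Q - exact)^2))
    })
    median(med)
  }
  expect_lt(errs(800), errs(100))
})

test_that("TD(0) Q estimation also approaches the exact values", {
  model <- toy_mdp_2s2a()
  pol <- matrix(0.5, 2, 2)
  exact <- evaluate_policy(model, pol)$Q
  qe <- estimate_q(mdp_env(model), pol, n_episodes = 3000, method = "td",
                   alpha = 0.05, seed = 7)
  expect_lt(max(abs(qe$Q - exact)), 0.15)
})

test_that("train_pmd: K = 0 returns uniform; exact PMD reaches DP optimum", {
  model <- toy_mdp_2s2a()
  cfg0 <- pmd_default_config(K = 0)
  out0 <- train_pmd(NULL, cfg0, exact_model = model)
  expect_true(all(out0$policy == 0.5))
  cfg <- pmd_default_config(K = 40, eta = 2, tau0 = 0, tau_decay = 1)
  out <- train_pmd(NULL, cfg, exact_model = model)
  J_pmd <- evaluate_policy(model, out$policy)$J
  J_opt <- oracle_enumerate_policies(model)$J
  expect_lt((J_pmd - J_opt) / J_opt, 0.05)
  # exact-evaluation trace is monotone non-increasing
  expect_true(all(diff(out$avg_cost) < 1e-9))
})

test_that("sampled PMD improves the median cost trace on the toy MDP", {
  model <- toy_mdp_2s2a()
  first <- numeric(5); last <- numeric(5)
  for (sd in 1:5) {
    out <- train_pmd(mdp_env(model),
                     pmd_default_config(K = 8, eta = 2, tau0 = 0,
                                        episodes_per_iter = 60),
                     seed = sd)
    first[sd] <- out$avg_cost[1]
    last[sd] <- mean(utils::tail(out$avg_cost, 2))
  }
  expect_lt(median(last), median(first))
})

test_that("policy serialisation round trip", {
  pol <- array(runif(2 * 3 * 4), c(2, 3, 4))
  pol <- pol / array(rep(apply(pol, c(1, 2), sum), 4), dim(pol))
  f <- tempfile(fileext = ".json")
  policy_save(pol, f, action_grid = default_action_grid(c(0, 50)))
  back <- policy_load(f)
  expect_equal(back$policy, pol, tolerance = 1e-12)
  unlink(f)
})
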