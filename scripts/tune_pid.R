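# Coarse grid search for the PID baseline gains on a nominal
# (uncertainty-free) 20-day tracking episode, for fairness of the DP/PID
# comparison. Run from the repository root:
#   Rscript scripts/tune_pid.R
# The winning gains are frozen into pid_default_config().

library(adcontrol)

cfg <- shortterm_config()
params <- adm1_params()
comp <- list(x_sugar = 0.45, x_lipids = 0.20, x_proteins = 0.25,
             x_lignin = 0.10)
target <- cfg$target
horizon <- cfg$horizon
grid <- cfg$action_grid

episode_mae <- function(Kp, Ki, Kd, bias) {
  pc <- list(Kp = Kp, Ki = Ki, Kd = Kd, dt = 1, u_min = 0, u_max = 200,
             i_max = 2000, bias = bias)
  st <- pid_init_state()
  s <- adm1_initial_state()
  y <- biogas_rate(s, params)
  ys <- numeric(horizon)
  for (t in seq_len(horizon)) {
    res <- pid_step(pc, st, target[t] - y)
    st <- res$state
    a <- pid_action(res$u, grid)
    inf <- feed_to_adm1_influent(grid[a, ], list(comp, comp, comp), params)
    r <- adm1_step(s, inf$influent, inf$q, 1, params)
    s <- r$state
    y <- r$biogas_rate
    ys[t] <- y
  }
  mae(ys, target)
}

res <- expand.grid(Kp = c(0.005, 0.01, 0.02, 0.04),
                   Ki = c(0, 0.002, 0.005, 0.01),
                   Kd = c(0, 0.005, 0.01),
                   bias = c(60, 70))
res$mae <- mapply(episode_mae, res$Kp, res$Ki, res$Kd, res$bias)
res <- res[order(res$mae), ]
print(utils::head(res, 10))
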