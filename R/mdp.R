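# The controlled digester as a finite-horizon MDP.
#
# The reactor is only partially observed; instead of a POMDP belief state,
# the MDP state is the pair of two consecutive biogas-rate observations
# (which carries gradient information), optionally extended with a
# feed-storage holdup feature in long-term mode. Actions are triples of
# stream flow rates.

# derive a valid 32-bit RNG seed from a base seed and an index
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i)) %% 2147483629)
}

#' Build a uniform discretisation grid
#'
#' @param lo,hi Range covered.
#' @param n Number of bins.
#' @return Numeric vector of bin centers.
#' @export
make_grid <- function(lo, hi, n) {
  stopifnot(n >= 1, hi > lo)
  w <- (hi - lo) / n
  lo + w * (seq_len(n) - 0.5)
}

#' Map continuous observations to a discrete state index
#'
#' Nearest-bin lookup on each component grid, composed row-major into a
#' single index. Values beyond the grid range clamp to the boundary bin.
#'
#' @param grid List of bin-center vectors, one per observation component.
#' @param values Numeric vector, one value per component.
#' @return Integer state index in `1:prod(lengths(grid))`.
#' @export
discretize <- function(grid, values) {
  stopifnot(length(values) == length(grid))
  if (any(!is.finite(values))) stop("non-finite observation", call. = FALSE)
  idx <- mapply(function(g, v) which.min(abs(g - v)), grid, values)
  sizes <- lengths(grid)
  as.integer(1 + sum((idx - 1) * cumprod(c(1, sizes[-length(sizes)]))))
}

#' Inverse of [discretize()]: bin centers of a state index
#'
#' @param grid List of bin-center vectors.
#' @param index State index.
#' @return Numeric vector of component bin centers.
#' @export
grid_center <- function(grid, index) {
  sizes <- lengths(grid)
  stopifnot(index >= 1, index <= prod(sizes))
  rem <- index - 1
  out <- numeric(length(grid))
  for (k in seq_along(grid)) {
    i <- rem %% sizes[k]
    rem <- rem %/% sizes[k]
    out[k] <- grid[[k]][i + 1]
  }
  out
}

#' Per-step target-tracking cost
#'
#' Absolute deviation of the observed biogas rate from the target (the
#' per-step contribution to the MAE).
#'
#' @param y,y_target Non-negative rates, m3 d-1.
#' @return `|y - y_target|`.
#' @export
tracking_cost <- function(y, y_target) abs(y - y_target)

#' Long-horizon production/inventory cost
#'
#' Four terms: a mild linear (MAE-type) penalty when production exceeds the
#' demand target, a stronger quadratic (MSE-type) penalty when production
#' falls short, an operating cost proportional to total feed throughput,
#' and a penalty on feed wasted to storage overflow. A single production
#' value is routed to exactly one of the first two branches.
#'
#' @param y Biogas production rate, m3 d-1.
#' @param params List with weights `w0`, `w1`, `w2`, `w3` (>= 0) and demand
#'   target `y_star`.
#' @param F_T Total feed flow, m3 d-1.
#' @param delta_x Overflow volume this step, m3 (>= 0).
#' @return List with `total` and the per-term breakdown `terms` (length 4).
#' @export
longterm_cost <- function(y, params, F_T = 0, delta_x = 0) {
  stopifnot(all(unlist(params[c("w0", "w1", "w2", "w3")]) >= 0))
  if (delta_x < 0) stop("delta_x must be >= 0", call. = FALSE)
  ys <- params$y_star
  t1 <- if (y >= ys) params$w0 * (y - ys) else 0
  t2 <- if (y < ys) params$w1 * (ys - y)^2 else 0
  terms <- c(over = t1, under = t2, throughput = params$w2 * F_T,
             overflow = params$w3 * delta_x)
  list(total = sum(terms), terms = terms)
}

#' Default weights for the long-horizon cost
#'
#' Unit weight on the mild over-production penalty; the shortfall MSE
#' weight `100 / y_star` makes missing the demand target dominate every
#' other term (robust production is the stated purpose of this cost, and
#' the optimal hedging margin it induces is a couple of process standard
#' deviations above target); throughput and overflow weights are sized to
#' roughly 10% of a typical tracking cost at nominal operation.
#'
#' @param y_star Demand target, m3 d-1.
#' @return Parameter list for [longterm_cost()].
#' @export
longterm_cost_params <- function(y_star) {
  list(w0 = 1, w1 = 100 / y_star, w2 = 0.5, w3 = 1.5, y_star = y_star)
}

#' Construct the digester control environment
#'
#' A closure wrapping the ADM1 simulator as an episodic MDP environment.
#' Each control step lasts `step_duration` days of continuous feeding at
#' the commanded flows, with per-step feed compositions drawn from the
#' per-stream KDE models (pre-drawn at reset so that paired controller
#' comparisons share common random numbers). In `"longterm"` mode each
#' stream passes through a storage tank fed by a seasonal supply model, and
#' the cost is [longterm_cost()]; in `"tracking"` mode the cost is
#' [tracking_cost()] against `target` and tanks are unlimited.
#'
#' @param kde_models List of three `wkde` models (FW, AW, MSW order).
#' @param action_grid Matrix, one row per action, columns = flows of
#'   FW/AW/MSW in m3 d-1.
#' @param state_grid List of bin-center vectors: `dy` (observation slope
#'   `y_curr - y_prev`), `y_curr`, and optionally `holdup` (aggregate tank
#'   fill fraction) in longterm mode.
#' @param horizon Steps per episode.
#' @param target Target biogas series (length `horizon`) for tracking mode.
#' @param cost_kind `"tracking"` or `"longterm"`.
#' @param lt_params [longterm_cost_params()] list (longterm mode).
#' @param supply_model [seasonal_supply_model()] (longterm mode).
#' @param tanks List with `v_max` (length 3) and `init` holdups (longterm).
#' @param init_state Initial reactor state.
#' @param params,step_duration Simulator settings.
#' @return Environment object (list of closures): `reset(seed)` returning
#'   the initial state index, `step(a_idx)` returning
#'   `list(s_idx, cost, y, terms, flows, overflow, holdups)`, plus
#'   accessors `n_states()`, `n_actions()`, `horizon`, `draws()`,
#'   `state_grid`, `action_grid`.
#' @export
digester_env <- function(kde_models, action_grid, state_grid, horizon,
                         target = NULL, cost_kind = c("tracking", "longterm"),
                         lt_params = NULL, supply_model = NULL, tanks = NULL,
                         init_state = adm1_initial_state(),
                         params = adm1_params(), step_duration = 1) {
  cost_kind <- match.arg(cost_kind)
  action_grid <- as.matrix(action_grid)
  stopifnot(ncol(action_grid) == 3)
  if (cost_kind == "tracking") stopifnot(length(target) >= horizon)
  if (cost_kind == "longterm") {
    stopifnot(!is.null(lt_params), !is.null(supply_model), !is.null(tanks))
  }
  has_holdup_dim <- length(state_grid) >= 3

  e <- new.env(parent = emptyenv())

  # feature state: (slope, level) recoding of the two consecutive
  # observations -- same information as (y_prev, y_curr), but the slope
  # component tolerates a much coarser grid
  obs_index <- function() {
    v <- c(e$y_curr - e$y_prev, e$y_curr)
    if (has_holdup_dim) v <- c(v, sum(e$holdups) / sum(tanks$v_max))
    discretize(state_grid, v)
  }

  reset <- function(seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    e$reactor <- init_state
    e$t <- 1L
    y0 <- biogas_rate(init_state, params)
    e$y_prev <- y0
    e$y_curr <- y0
    e$holdups <- if (!is.null(tanks)) tanks$init else c(0, 0, 0)
    # pre-draw all per-step randomness (common random numbers for pairing)
    comps <- vector("list", horizon)
    for (t in seq_len(horizon)) {
      comps[[t]] <- lapply(kde_models, function(m) kde_sample(m, 1))
    }
    e$comps <- comps
    if (cost_kind == "longterm") {
      e$supply <- t(vapply(seq_len(horizon), function(t)
        seasonal_supply(t * step_duration, supply_model), numeric(3)))
    } else {
      e$supply <- NULL
    }
    obs_index()
  }

  step <- function(a_idx) {
    stopifnot(a_idx >= 1, a_idx <= nrow(action_grid))
    if (e$t > horizon) stop("episode over; call reset()", call. = FALSE)
    flows_req <- action_grid[a_idx, ]
    overflow <- c(0, 0, 0)
    if (cost_kind == "longterm") {
      flows <- numeric(3)
      for (k in 1:3) {
        upd <- tank_update(list(holdup = e$holdups[k], v_max = tanks$v_max[k]),
                           inflow = e$supply[e$t, k] * step_duration,
                           outflow = flows_req[k] * step_duration)
        flows[k] <- upd$realized_outflow / step_duration
        e$holdups[k] <- upd$tank$holdup
        overflow[k] <- upd$overflow
      }
    } else {
      flows <- flows_req
    }
    inf <- feed_to_adm1_influent(flows, e$comps[[e$t]], params)
    r <- adm1_step(e$reactor, inf$influent, inf$q, step_duration, params)
    e$reactor <- r$state
    y <- r$biogas_rate
    e$y_prev <- e$y_curr
    e$y_curr <- y
    if (cost_kind == "tracking") {
      cost <- tracking_cost(y, target[e$t])
      terms <- NULL
    } else {
      lc <- longterm_cost(y, lt_params, F_T = sum(flows),
                          delta_x = sum(overflow))
      cost <- lc$total
      terms <- lc$terms
    }
    e$t <- e$t + 1L
    list(s_idx = obs_index(), cost = cost, y = y, terms = terms,
         flows = flows, overflow = overflow, holdups = e$holdups)
  }

  list(reset = reset, step = step,
       n_states = function() prod(lengths(state_grid)),
       n_actions = function() nrow(action_grid),
       horizon = horizon,
       state_grid = state_grid, action_grid = action_grid,
       cost_kind = cost_kind,
       obs = function() c(e$y_curr - e$y_prev, e$y_curr),
       draws = function() e$comps,
       supply_draws = function() e$supply,
       t_now = function() e$t,
       reactor = function() e$reactor)
}
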