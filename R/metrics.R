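# Controller performance metrics: accuracy (MAE), precision (CoV across
# runs), lag (dynamic time warping loss).

#' Mean absolute error between a series and its target
#'
#' @param series,target Equal-length numeric vectors.
#' @return Mean of absolute differences.
#' @export
mae <- function(series, target) {
  if (length(series) != length(target)) stop("length mismatch", call. = FALSE)
  if (length(series) < 1) stop("empty series", call. = FALSE)
  mean(abs(series - target))
}

#' Per-time coefficient of variation across simulation runs
#'
#' CoV at each time step is the sample (n-1) standard deviation across runs
#' divided by the mean across runs; entries with zero mean are `NA`.
#'
#' @param runs Numeric matrix, rows = runs, columns = time steps (>= 2 runs).
#' @return List with `cov` (per-time series) and `aggregate` (time average
#'   over defined entries).
#' @export
cov_across_runs <- function(runs) {
  runs <- as.matrix(runs)
  if (nrow(runs) < 2) stop("need >= 2 runs", call. = FALSE)
  mu <- colMeans(runs)
  sdv <- apply(runs, 2, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu)
  list(cov = cv, aggregate = mean(cv, na.rm = TRUE))
}

#' Dynamic time warping loss between two series
#'
#' Classic DTW dynamic program with absolute-difference local cost and no
#' window constraint: the minimum total cost over all monotone alignments
#' matching both series end to end. Optionally normalised by the optimal
#' warping-path length.
#'
#' @param a,b Non-empty numeric vectors.
#' @param normalize If `TRUE`, divide by the optimal path length.
#' @return Non-negative alignment cost.
#' @export
dtw_loss <- function(a, b, normalize = FALSE) {
  n <- length(a); m <- length(b)
  if (n < 1 || m < 1) stop("empty series", call. = FALSE)
  D <- matrix(Inf, n + 1, m + 1)
  L <- matrix(0L, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- abs(a[i] - b[j])
      opts <- c(D[i, j], D[i, j + 1], D[i + 1, j])
      k <- which.min(opts)
      D[i + 1, j + 1] <- cost + opts[k]
      L[i + 1, j + 1] <- 1L + switch(k, L[i, j], L[i, j + 1], L[i + 1, j])
    }
  }
  if (normalize) D[n + 1, m + 1] / L[n + 1, m + 1] else D[n + 1, m + 1]
}

#' Summarise a set of controlled runs against a target
#'
#' @param runs Matrix of biogas-rate trajectories, rows = runs.
#' @param target Target series (length = columns of `runs`).
#' @param normalize_dtw Passed to [dtw_loss()].
#' @return List: per-run `mae` and `dtw` vectors, `cov` (per-time), and
#'   aggregate `mae_mean`, `cov_mean`, `dtw_mean`.
#' @export
metrics_report <- function(runs, target, normalize_dtw = FALSE) {
  runs <- as.matrix(runs)
  stopifnot(ncol(runs) == length(target))
  per_mae <- unname(apply(runs, 1, mae, target = target))
  per_dtw <- unname(apply(runs, 1, dtw_loss, b = target,
                          normalize = normalize_dtw))
  cv <- if (nrow(runs) >= 2) cov_across_runs(runs) else list(cov = NA_real_, aggregate = NA_real_)
  list(mae = per_mae, dtw = per_dtw, cov = cv$cov,
       mae_mean = mean(per_mae), cov_mean = cv$aggregate,
       dtw_mean = mean(per_dtw))
}
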