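# Weighted Gaussian kernel density models of biochemical composition.
#
# Compositions live on the 3-simplex in four variables; the KDE operates on
# the first three coordinates (sugar, lipids, proteins) with lignin implied
# as 1 - sum, which keeps the kernel covariance non-degenerate.

#' Fit a weighted Gaussian KDE to composition vectors
#'
#' Each data point contributes a Gaussian kernel centred on its reduced
#' (sugar, lipids, proteins) coordinates, weighted by its (renormalised)
#' category weight. The default bandwidth is Scott's rule applied to the
#' weighted covariance at the weighted effective sample size
#' `ess = (sum w)^2 / sum(w^2)`.
#'
#' @param compositions Matrix or data frame of composition vectors. Columns
#'   `x_sugar`, `x_lipids`, `x_proteins` are used if named, otherwise the
#'   first three columns.
#' @param weights Non-negative weights, not all zero; recycled to equal
#'   weights when `NULL`.
#' @param bandwidth `"scott"` (default) or a positive scalar multiplier `h`
#'   giving kernel covariance `h^2 * I`.
#' @param waste_type Optional label stored on the model.
#' @return Object of class `wkde`: list with `points` (n x 3), `weights`
#'   (sum 1), `H` (3 x 3 kernel covariance), `cholH`, `waste_type`.
#' @export
fit_kde <- function(compositions, weights = NULL, bandwidth = "scott",
                    waste_type = NA_character_) {
  X <- .composition_matrix(compositions)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (sum(weights) <= 0) stop("weights must not be all zero", call. = FALSE)
  w <- weights / sum(weights)
  d <- ncol(X)
  if (identical(bandwidth, "scott")) {
    if (n < 2) stop("automatic bandwidth needs >= 2 points; pass a scalar bandwidth",
                    call. = FALSE)
    ess <- 1 / sum(w^2)
    mu <- colSums(X * w)
    Xc <- sweep(X, 2, mu)
    S <- crossprod(Xc * sqrt(w), Xc * sqrt(w)) / max(1 - sum(w^2), .Machine$double.eps)
    H <- ess^(-2 / (d + 4)) * S
    if (!all(is.finite(H)) || min(eigen(H, symmetric = TRUE, only.values = TRUE)$values) <= 1e-14) {
      stop("degenerate automatic bandwidth (identical or collinear points); ",
           "pass a manual scalar bandwidth", call. = FALSE)
    }
  } else {
    stopifnot(is.numeric(bandwidth), length(bandwidth) == 1, bandwidth > 0)
    H <- diag(bandwidth^2, d)
  }
  structure(list(points = X, weights = w, H = H, cholH = chol(H),
                 waste_type = waste_type),
            class = "wkde")
}

.composition_matrix <- function(compositions) {
  X <- as.matrix(as.data.frame(compositions))
  cn <- c("x_sugar", "x_lipids", "x_proteins")
  if (all(cn %in% colnames(X))) X <- X[, cn, drop = FALSE]
  else X <- X[, seq_len(min(3, ncol(X))), drop = FALSE]
  storage.mode(X) <- "double"
  X[stats::complete.cases(X), , drop = FALSE]
}

#' Evaluate a weighted KDE density
#'
#' @param model A `wkde` model.
#' @param x Numeric vector (one point) or matrix (rows are points) in the
#'   model's reduced coordinates.
#' @return Density value(s), the exact weighted Gaussian-mixture evaluation.
#' @export
kde_density <- function(model, x) {
  stopifnot(inherits(model, "wkde"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d <- ncol(model$points)
  if (ncol(x) != d) stop("dimension mismatch: expected ", d, " coordinates", call. = FALSE)
  Hinv <- chol2inv(model$cholH)
  logdet <- 2 * sum(log(diag(model$cholH)))
  norm_const <- exp(-0.5 * (d * log(2 * pi) + logdet))
  vapply(seq_len(nrow(x)), function(i) {
    D <- sweep(model$points, 2, x[i, ])
    q <- rowSums((D %*% Hinv) * D)
    sum(model$weights * norm_const * exp(-0.5 * q))
  }, 0.0)
}

#' Sample compositions from a weighted KDE
#'
#' Draws kernel indices by weight, adds multivariate Gaussian noise with the
#' model bandwidth, and rejection-samples until the draw lies in the
#' simplex (all coordinates >= 0 and their sum <= 1); the implied lignin
#' fraction is `1 - sum`. Rejection preserves relative density within the
#' simplex; clipping (`method = "clip"`) is available but distorts it.
#'
#' @param model A `wkde` model.
#' @param n Number of samples.
#' @param seed Optional integer seed for reproducibility.
#' @param method `"reject"` (default) or `"clip"`.
#' @param max_tries Error if more than `max_tries` rounds are needed
#'   (rejection rate too high for the bandwidth).
#' @return Data frame with `x_sugar`, `x_lipids`, `x_proteins`, `x_lignin`
#'   (and the model's `waste_type` if set), plus attribute `kernel_index`.
#' @export
kde_sample <- function(model, n, seed = NULL, method = c("reject", "clip"),
                       max_tries = 1000L) {
  stopifnot(inherits(model, "wkde"), n >= 1)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(model$points)
  out <- matrix(NA_real_, n, d)
  kidx <- integer(n)
  pending <- seq_len(n)
  tries <- 0L
  while (length(pending) > 0) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("rejection rate too high; use a smaller bandwidth or method='clip'",
           call. = FALSE)
    }
    m <- length(pending)
    ki <- sample.int(nrow(model$points), m, replace = TRUE, prob = model$weights)
    Z <- matrix(stats::rnorm(m * d), m, d)
    cand <- model$points[ki, , drop = FALSE] + Z %*% model$cholH
    if (method == "clip") {
      cand[cand < 0] <- 0
      s <- rowSums(cand)
      over <- s > 1
      cand[over, ] <- cand[over, , drop = FALSE] / s[over]
      ok <- rep(TRUE, m)
    } else {
      ok <- rowSums(cand < 0) == 0 & rowSums(cand) <= 1
    }
    take <- which(ok)
    if (length(take)) {
      rows <- pending[take]
      out[rows, ] <- cand[take, , drop = FALSE]
      kidx[rows] <- ki[take]
      pending <- pending[-take]
    }
  }
  df <- data.frame(x_sugar = out[, 1], x_lipids = out[, 2], x_proteins = out[, 3])
  df$x_lignin <- pmax(0, 1 - rowSums(out))
  if (!is.na(model$waste_type)) df$waste_type <- model$waste_type
  attr(df, "kernel_index") <- kidx
  df
}

#' Pairwise Pearson correlations of composition coordinates
#'
#' @param samples Data frame or matrix of composition samples (reduced or
#'   full coordinates).
#' @return Correlation matrix; zero-variance coordinates give `NA` entries
#'   with a warning.
#' @export
pairwise_correlation <- function(samples) {
  X <- as.matrix(as.data.frame(samples)[, sapply(as.data.frame(samples), is.numeric), drop = FALSE])
  stopifnot(nrow(X) >= 3)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) warning("zero-variance coordinate(s): ",
                             paste(colnames(X)[sds == 0], collapse = ", "),
                             "; correlations undefined (NA)")
  suppressWarnings(stats::cor(X))
}

#' Serialize / deserialize a weighted KDE model as JSON
#' @param model A `wkde` model.
#' @param path File path.
#' @return `kde_save` returns `path` invisibly; `kde_load` returns a `wkde`.
#' @export
kde_save <- function(model, path) {
  stopifnot(inherits(model, "wkde"))
  obj <- list(points = model$points, weights = model$weights, H = model$H,
              waste_type = model$waste_type)
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname kde_save
#' @export
kde_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- unname(as.matrix(obj$H))
  pts <- unname(as.matrix(obj$points))
  structure(list(points = pts, weights = as.numeric(obj$weights), H = H,
                 cholH = chol(H),
                 waste_type = if (is.null(obj$waste_type)) NA_character_ else obj$waste_type),
            class = "wkde")
}
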