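# Biochemical composition from ultimate (elemental) analysis.
#
# A waste sample characterised only by its C/H/O/N mass fractions is mapped
# to mass fractions of the four ADM1-relevant biochemical components
# (carbohydrate "sugar", lipids, proteins, lignin) by solving
#   min 1/2 ||A x - b||^2   s.t.  sum(x) = 1,  x >= 0
# where the columns of A are the elemental mass fractions of reference
# compounds and b is the sample's (C,H,O,N) vector.

ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

#' Default reference formulas for the biochemical basis
#'
#' Atom counts (possibly fractional, e.g. an average amino-acid residue) for
#' the four reference compounds whose elemental make-up spans waste organics:
#' carbohydrate as anhydroglucose C6H10O5, lipid as glyceryl tripalmitate
#' C51H98O6, protein as the average residue C4.43 H7 O1.44 N1.16, lignin as a
#' softwood-type C10 H11.6 O3.9 monomer. These are conventions of the biomass
#' literature, not measurements; override any of them in
#' [build_basis_matrix()].
#'
#' @return Named list of named numeric vectors (atom counts per element).
#' @export
default_component_formulas <- function() {
  list(
    sugar    = c(C = 6,    H = 10,   O = 5,    N = 0),
    lipids   = c(C = 51,   H = 98,   O = 6,    N = 0),
    proteins = c(C = 4.43, H = 7,    O = 1.44, N = 1.16),
    lignin   = c(C = 10,   H = 11.6, O = 3.9,  N = 0)
  )
}

#' Build the elemental basis matrix from component formulas
#'
#' Converts each reference formula to a column of element mass fractions
#' (rows C, H, O, N), i.e. atom count times atomic mass divided by the
#' formula's molar mass.
#'
#' @param formulas Named list of atom-count vectors, one per component, in
#'   the order the composition vector will use. Defaults to
#'   [default_component_formulas()]. Element names must be among C, H, O, N.
#' @return Object of class `elemental_basis`: list with `A` (4 x k matrix of
#'   mass fractions, rows C/H/O/N), `formulas`, `molar_mass`.
#' @examples
#' basis <- build_basis_matrix()
#' basis$A[, "sugar"]  # ~ (0.444, 0.062, 0.494, 0)
#' @export
build_basis_matrix <- function(formulas = default_component_formulas()) {
  stopifnot(is.list(formulas), length(formulas) >= 1, !is.null(names(formulas)))
  elements <- names(ATOMIC_MASS)
  A <- matrix(0, nrow = 4, ncol = length(formulas),
              dimnames = list(elements, names(formulas)))
  mm <- numeric(length(formulas))
  for (j in seq_along(formulas)) {
    f <- formulas[[j]]
    if (is.null(names(f)) || !all(names(f) %in% elements)) {
      stop("unknown element symbol in formula '", names(formulas)[j],
           "': only C, H, O, N are supported", call. = FALSE)
    }
    if (any(f < 0) || f[["C"]] <= 0 || is.na(f["H"]) || f[["H"]] <= 0) {
      # pure-carbon pseudo-components are permitted by relaxing H when absent
      if (!(f[["C"]] > 0 && all(f[setdiff(names(f), "C")] == 0))) {
        stop("formula '", names(formulas)[j],
             "' must have positive C and H atom counts", call. = FALSE)
      }
    }
    masses <- ATOMIC_MASS[names(f)] * f
    mm[j] <- sum(masses)
    A[names(f), j] <- masses / mm[j]
  }
  structure(list(A = A, formulas = formulas,
                 molar_mass = stats::setNames(mm, names(formulas))),
            class = "elemental_basis")
}

#' @export
print.elemental_basis <- function(x, ...) {
  cat("Elemental basis matrix (mass fractions; rows C,H,O,N):\n")
  print(round(x$A, 4))
  invisible(x)
}

# Exact minimiser of 1/2||Ax-b||^2 s.t. sum(x)=1, x>=0, by support
# enumeration: the active set of the optimum is one of the 2^k - 1 nonempty
# supports; for each support solve the equality-constrained KKT system and
# keep the feasible candidate with the smallest objective. Exact for the
# small k (= 4) used here.
.simplex_lsq <- function(A, b) {
  k <- ncol(A)
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) != 0L)
    As <- A[, idx, drop = FALSE]
    m <- length(idx)
    K <- rbind(cbind(crossprod(As), rep(1, m)), c(rep(1, m), 0))
    rhs <- c(crossprod(As, b), 1)
    xs <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(xs)) next
    xi <- xs[seq_len(m)]
    if (any(xi < -1e-10)) next
    xi[xi < 0] <- 0
    xi <- xi / sum(xi)
    x <- numeric(k)
    x[idx] <- xi
    obj <- 0.5 * sum((A %*% x - b)^2)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- x
    }
  }
  if (is.null(best)) stop("simplex least-squares failed to converge", call. = FALSE)
  list(x = best, residual_norm = sqrt(2 * best_obj))
}

#' Estimate biochemical composition of one sample
#'
#' Solves the simplex-constrained least-squares problem mapping the sample's
#' elemental fractions to component mass fractions.
#'
#' @param record List or one-row data frame with numeric `C`, `H`, `O`, `N`
#'   mass fractions (dry basis, each in \[0,1\], sum <= 1; remainder is
#'   ash/other).
#' @param basis An `elemental_basis` from [build_basis_matrix()].
#' @param renormalize If `TRUE` (default) the C/H/O/N vector is rescaled to
#'   sum to 1 (ash-free basis) before solving, so that the sum-to-one
#'   constraint on the composition is consistent with ash-bearing raw data.
#'   Set `FALSE` for raw-basis fitting.
#' @return List with `x` (named composition vector on the simplex),
#'   `residual_norm` (attained `||Ax - b||_2`), and `degenerate` flag
#'   (all-zero elemental vector).
#' @export
estimate_composition <- function(record, basis, renormalize = TRUE) {
  stopifnot(inherits(basis, "elemental_basis"))
  b <- vapply(c("C", "H", "O", "N"), function(e) as.numeric(record[[e]]), 0.0)
  if (any(!is.finite(b)) || any(b < 0) || any(b > 1)) {
    stop("elemental fractions must be finite and in [0,1]", call. = FALSE)
  }
  if (sum(b) == 0) {
    k <- ncol(basis$A)
    return(list(x = stats::setNames(rep(NA_real_, k), colnames(basis$A)),
                residual_norm = NA_real_, degenerate = TRUE))
  }
  if (renormalize) b <- b / sum(b)
  fit <- .simplex_lsq(basis$A, b)
  list(x = stats::setNames(fit$x, colnames(basis$A)),
       residual_norm = fit$residual_norm, degenerate = FALSE)
}

#' Estimate compositions for a whole elemental dataset
#'
#' @param records Data frame with columns `C`, `H`, `O`, `N` (fractions or
#'   percents, auto-detected by magnitude) and optionally `waste_type`,
#'   `category`, `weight`.
#' @param basis An `elemental_basis`.
#' @param renormalize Passed to [estimate_composition()].
#' @return Data frame, one row per record in input order: the carried-over
#'   `waste_type`/`weight` columns, `x_sugar`, `x_lipids`, `x_proteins`,
#'   `x_lignin`, `residual`, and a logical `degenerate` flag. Degenerate
#'   records are flagged, never dropped.
#' @export
estimate_dataset <- function(records, basis = build_basis_matrix(),
                             renormalize = TRUE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  el <- as.matrix(records[, c("C", "H", "O", "N")])
  # percent vs fraction auto-detection: percent tables have row sums ~ 100
  if (stats::median(rowSums(el), na.rm = TRUE) > 1.5) el <- el / 100
  comp_names <- colnames(basis$A)
  out <- matrix(NA_real_, nrow(records), length(comp_names))
  resid <- rep(NA_real_, nrow(records))
  degen <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- as.list(el[i, ])
    fit <- estimate_composition(rec, basis, renormalize = renormalize)
    out[i, ] <- fit$x
    resid[i] <- fit$residual_norm
    degen[i] <- fit$degenerate
  }
  res <- data.frame(out)
  names(res) <- paste0("x_", comp_names)
  if ("waste_type" %in% names(records)) res <- cbind(waste_type = records$waste_type, res)
  if ("weight" %in% names(records)) res$weight <- records$weight
  res$residual <- resid
  res$degenerate <- degen
  res
}

#' Read an elemental-analysis CSV
#'
#' Expected header: `waste_type,category,C,H,O,N,weight`. Fractions may be
#' decimals or percents (auto-detected downstream).
#'
#' @param path CSV file path.
#' @return Data frame with validated columns.
#' @export
read_elemental_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("waste_type", "C", "H", "O", "N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"weight" %in% names(df)) df$weight <- 1
  if (any(df$weight < 0)) stop("weights must be non-negative", call. = FALSE)
  df
}
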