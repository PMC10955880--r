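# Elemental basis construction and simplex-constrained least squares.

test_that("basis matrix columns are mass fractions from atomic masses", {
  basis <- build_basis_matrix()
  # anhydroglucose C6H10O5: hand-computed from atomic masses
  # M = 6*12.011 + 10*1.008 + 5*15.999 = 162.141
  expect_equal(unname(basis$A[, "sugar"]),
               c(72.066, 10.08, 79.995, 0) / 162.141, tolerance = 1e-12)
  expect_equal(unname(round(basis$A[, "sugar"], 3)), c(0.444, 0.062, 0.493, 0))
  # proteins are the sole nitrogen carrier among the defaults
  expect_gt(basis$A["N", "proteins"], 0)
  expect_identical(unname(basis$A["N", c("sugar", "lipids", "lignin")]),
                   c(0, 0, 0))
  expect_true(all(basis$A >= 0 & basis$A <= 1))
  expect_true(all(colSums(basis$A) <= 1 + 1e-12))
})

test_that("pure-carbon pseudo-component and bad formulas", {
  b <- build_basis_matrix(list(carbon = c(C = 1)))
  expect_equal(unname(b$A[, "carbon"]), c(1, 0, 0, 0))
  expect_error(build_basis_matrix(list(x = c(C = 1, S = 2))), "element")
})

test_that("estimate_composition recovers exact and composed mixtures", {
  basis <- build_basis_matrix()
  A <- basis$A
  # b equal to one column -> unit vector, zero residual
  fit <- estimate_composition(list(C = A["C", "sugar"], H = A["H", "sugar"],
                                   O = A["O", "sugar"], N = A["N", "sugar"]),
                              basis)
  expect_equal(unname(fit$x), c(1, 0, 0, 0), tolerance = 1e-9)
  expect_lt(fit$residual_norm, 1e-9)
  # forward-composed mixture is inverted exactly
  x0 <- c(sugar = 0.5, lipids = 0.2, proteins = 0.3, lignin = 0)
  b <- as.numeric(A %*% x0)
  fit2 <- estimate_composition(list(C = b[1], H = b[2], O = b[3], N = b[4]),
                               basis)
  expect_equal(unname(fit2$x), unname(x0), tolerance = 1e-6)
})

test_that("solver matches the simplex grid-search oracle off the column span", {
  basis <- build_basis_matrix()
  set.seed(41)
  b <- as.numeric(basis$A %*% c(0.4, 0.2, 0.3, 0.1)) +
    c(0.03, -0.02, 0.01, 0.02)
  b <- pmax(b, 0); b <- b / sum(b)
  fit <- estimate_composition(list(C = b[1], H = b[2], O = b[3], N = b[4]),
                              basis, renormalize = FALSE)
  orc <- oracle_simplex_grid(basis$A, b)
  expect_gt(fit$residual_norm, 0)
  # solver objective can only be at or below the grid optimum
  expect_lte(0.5 * fit$residual_norm^2, orc$obj + 1e-12)
  expect_equal(0.5 * fit$residual_norm^2, orc$obj, tolerance = 1e-3)
})

test_that("forward-inverse idempotence on random simplex points", {
  basis <- build_basis_matrix()
  set.seed(7)
  for (i in 1:20) {
    x0 <- rgamma(4, 1); x0 <- x0 / sum(x0)
    b <- as.numeric(basis$A %*% x0)
    fit <- estimate_composition(list(C = b[1], H = b[2], O = b[3], N = b[4]),
                                basis)
    expect_lt(max(abs(fit$x - x0)), 1e-6)
  }
})

test_that("estimate_dataset preserves order, flags degenerates, parses percents", {
  basis <- build_basis_matrix()
  df <- data.frame(waste_type = c("FW", "AW", "MSW"),
                   C = c(0.45, 0, 0.40), H = c(0.06, 0, 0.06),
                   O = c(0.40, 0, 0.44), N = c(0.02, 0, 0.01),
                   weight = c(1, 1, 2))
  res <- estimate_dataset(df, basis)
  expect_equal(nrow(res), 3)
  expect_identical(res$degenerate, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(res[2, c("x_sugar", "x_lignin")])))
  rs <- rowSums(res[!res$degenerate, c("x_sugar", "x_lipids",
                                       "x_proteins", "x_lignin")])
  expect_equal(unname(rs), c(1, 1), tolerance = 1e-9)
  # percent-scale inputs give the same composition as fractions
  dfp <- df[c(1, 3), ]; dfp[, c("C", "H", "O", "N")] <- dfp[, c("C", "H", "O", "N")] * 100
  resp <- estimate_dataset(dfp, basis)
  expect_equal(resp$x_sugar, res$x_sugar[c(1, 3)], tolerance = 1e-12)
})

test_that("every returned composition satisfies the simplex constraints", {
  basis <- build_basis_matrix()
  set.seed(13)
  for (i in 1:25) {
    b <- runif(4); b <- b / sum(b) * runif(1, 0.7, 1)
    fit <- estimate_composition(list(C = b[1], H = b[2], O = b[3], N = b[4]),
                                basis)
    expect_true(all(fit$x >= 0))
    expect_equal(sum(fit$x), 1, tolerance = 1e-6)
  }
})
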