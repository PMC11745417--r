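test_that("flat complex indices map to enzyme/template pairs and back", {
  expect_equal(index_to_pair(1, 3), list(i = 1L, j = 1L))
  expect_equal(index_to_pair(3, 3), list(i = 1L, j = 3L))
  expect_equal(index_to_pair(4, 3), list(i = 2L, j = 1L))
  for (n in 1:5) {
    l <- seq_len(n * n)
    p <- index_to_pair(l, n)
    expect_identical(pair_to_index(p$i, p$j, n), l)
  }
  expect_error(index_to_pair(10, 3), "out of range")
  expect_error(pair_to_index(4, 1, 3), "out of range")
})

test_that("free concentrations account for both binding slots", {
  expect_equal(free_concentrations(c(1, 2), rep(0, 4)), c(1, 2))
  expect_equal(free_concentrations(2, 1), 1)  # self-complex consumes two, counted once
  x <- rep(0, 4); x[pair_to_index(1, 2, 2)] <- 0.2
  expect_equal(free_concentrations(c(1, 1), x), c(0.8, 0.8))
  expect_error(free_concentrations(c(1, 1), rep(0, 3)), "expected 4")
})

test_that("residual measures departure from the quasi-steady-state balance", {
  totals <- c(1, 2)
  km <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  p <- index_to_pair(1:4, 2)
  expect_equal(qssa_residual(totals, rep(0, 4), km),
               -totals[p$i] * totals[p$j])
  # one species: (2 - 1)^2 = 1 * 1, an exact root
  expect_equal(qssa_residual(2, 1, matrix(1)), 0)
  # a converged solution annihilates the residual
  sol <- newton_solve(totals, km)
  expect_lt(max(abs(qssa_residual(totals, sol$solution, km))), 1e-12)
})

test_that("analytic Jacobian matches closed forms and finite differences", {
  # one species: d/dc [KM c - (R - c)^2] = KM + 2 (R - c)
  expect_equal(qssa_jacobian(3, 0.5, matrix(2))[1, 1], 2 + 2 * (3 - 0.5))
  # zero state with zero totals: only the KM diagonal survives
  km <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  expect_equal(qssa_jacobian(c(0, 0), rep(0, 4), km), diag(as.numeric(t(km))))
  # randomized states against central finite differences
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(2:4, 1)
    inst <- random_instance(n)
    x <- runif(n * n, 0, 0.3)
    J <- qssa_jacobian(inst$totals, x, inst$km)
    Jfd <- fd_jacobian(inst$totals, x, inst$km)
    expect_lt(max(abs(J - Jfd)) / max(1, max(abs(J))), 1e-6)
  }
})

test_that("the tight-binding closed form behaves across regimes", {
  expect_equal(morrison_complex(0, 3, 1), 0)
  expect_equal(morrison_complex(1, 1, 1), (3 - sqrt(5)) / 2)
  # weak binding limit: c -> E S / KM
  expect_lt(abs(morrison_complex(1, 1, 1e4) - 1 / 1e4) / (1 / 1e4), 0.01)
  # the complex never exceeds either total
  set.seed(7)
  for (rep in 1:50) {
    e <- runif(1, 0, 5); s <- runif(1, 0, 5); km <- runif(1, 0.01, 10)
    c0 <- morrison_complex(e, s, km)
    expect_gte(c0, 0)
    expect_lte(c0, min(e, s) + 1e-12)
  }
  expect_error(morrison_complex(-1, 1, 1), "nonnegative")
  expect_error(morrison_complex(1, 1, 0), "strictly positive")
})

test_that("Newton solves the scalar quadratic exactly and the trivial system instantly", {
  sol <- newton_solve(2, matrix(1))
  expect_true(sol$converged)
  # roots of (2 - c)^2 = c are 1 and 4; only c = 1 keeps the free mass nonnegative
  expect_equal(sol$solution, 1, tolerance = 1e-12)

  sol0 <- newton_solve(c(0, 0, 0), matrix(1, 3, 3))
  expect_true(sol0$converged)
  expect_equal(sol0$solution, rep(0, 9))
  expect_lte(sol0$iterations, 1L)
})

test_that("converged solutions are feasible and respect mass bounds", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(1:4, 1)
    inst <- random_instance(n)
    sol <- newton_solve(inst$totals, inst$km)
    expect_true(sol$converged)
    expect_true(all(sol$solution >= 0))
    free <- free_concentrations(inst$totals, sol$solution)
    expect_true(all(free >= -1e-12))
    p <- index_to_pair(seq_len(n * n), n)
    expect_true(all(sol$solution <=
                      pmin(inst$totals[p$i], inst$totals[p$j]) + 1e-9))
  }
})

test_that("warm and cold starts converge to the same solution", {
  set.seed(5)
  inst <- random_instance(3)
  cold <- newton_solve(inst$totals, inst$km)
  warm <- newton_solve(inst$totals, inst$km,
                       warm_start = cold$solution * 0.9 + 0.01)
  expect_true(warm$converged)
  expect_equal(warm$solution, cold$solution, tolerance = 1e-9)
})

test_that("relabeling species permutes the solution accordingly", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    inst <- random_instance(n)
    perm <- sample(n)
    sol <- newton_solve(inst$totals, inst$km)
    sol_p <- newton_solve(inst$totals[perm], inst$km[perm, perm])
    C <- matrix(sol$solution, n, n, byrow = TRUE)
    C_p <- matrix(sol_p$solution, n, n, byrow = TRUE)
    expect_equal(C_p, C[perm, perm], tolerance = 1e-9)
  }
})

test_that("a failed solve is reported, never passed off as converged", {
  inst <- list(totals = c(4, 4), km = matrix(0.2, 2, 2))
  sol <- newton_solve(inst$totals, inst$km, max_iter = 1)
  expect_false(sol$converged)
  expect_gt(sol$residual_norm, sol$tol_effective)
  expect_match(sol$message, "iterations")
})

test_that("the fixed-point oracle agrees with Newton and the closed form", {
  expect_equal(fixed_point_oracle(c(0, 0), matrix(1, 2, 2)), rep(0, 4))
  km <- morrison_instance(1.0)
  fp <- fixed_point_oracle(c(1, 1), km)
  expect_equal(fp[pair_to_index(1, 2, 2)], morrison_complex(1, 1, 1),
               tolerance = 1e-6)
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    inst <- random_instance(n)
    nt <- newton_solve(inst$totals, inst$km)
    fp <- fixed_point_oracle(inst$totals, inst$km)
    expect_lt(max(abs(fp - nt$solution)), 1e-6)
  }
})
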