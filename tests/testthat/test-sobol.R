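test_that("Saltelli matrices sample each edge's population distribution", {
  net <- generate_reference_network(10, 0.4, seed = 71)
  et <- network_edges(net)
  ab <- saltelli_matrices(net, variation_spec(0.2), n_sobol = 5000, seed = 71)
  expect_identical(dim(ab$A), c(5000L, nrow(et)))
  expect_identical(dim(ab$B), c(5000L, nrow(et)))
  # ~ 2k simultaneous column checks: Bonferroni-style 4-sigma bound
  se <- 0.2 * abs(et$weight) / sqrt(5000)
  expect_true(all(abs(colMeans(ab$A) - et$weight) < 4 * se))
  expect_true(all(abs(colMeans(ab$B) - et$weight) < 4 * se))
  expect_false(identical(ab$A, ab$B))
  # sd 0: constant columns, degenerate downstream
  ab0 <- saltelli_matrices(net, variation_spec(0), n_sobol = 100, seed = 71)
  expect_identical(ab0$A, ab0$B)
  expect_error(saltelli_matrices(matrix(0, 3, 3)), "no edges")
})

test_that("radial matrices swap exactly one column", {
  A <- matrix(1:12, 4, 3)
  B <- matrix(101:112, 4, 3)
  C2 <- radial_matrix(A, B, 2)
  expect_identical(C2[, c(1, 3)], A[, c(1, 3)])
  expect_identical(C2[, 2], B[, 2])
  expect_identical(radial_matrix(A, A, 3), A)
  expect_error(radial_matrix(A, B, 4), "column index")
})

test_that("estimated indices match the analytic additive oracle", {
  # y = sum a_i x_i with independent normals: S0i = STi = a_i^2 s_i^2 / V
  n <- 20000
  a <- c(1.5, -2, 0.7)
  s <- c(1, 0.5, 2)
  withr::with_seed(72, {
    A <- sapply(1:3, function(i) rnorm(n, 10, s[i]))
    B <- sapply(1:3, function(i) rnorm(n, 10, s[i]))
  })
  f <- function(m) drop(m %*% a)
  yC <- sapply(1:3, function(i) f(radial_matrix(A, B, i)))
  res <- sobol_indices(f(A), f(B), yC)
  analytic <- a^2 * s^2 / sum(a^2 * s^2)
  expect_true(all(abs(res$indices$s0 - analytic) <
                    3 * res$indices$se_s0 + 1e-3))
  expect_true(all(abs(res$indices$st - analytic) <
                    3 * res$indices$se_st + 1e-3))
  expect_true(all(abs(res$indices$eps) <
                    3 * (res$indices$se_s0 + res$indices$se_st) + 1e-3))
  expect_equal(res$s0_sum, 1, tolerance = 0.05)
})

test_that("estimated indices match the analytic interaction oracle", {
  # y = x1 + x2 x3, standard normals: V = 2, S0 = (1/2, 0, 0),
  # ST = (1/2, 1/2, 1/2) by direct conditional-variance computation
  n <- 20000
  withr::with_seed(73, {
    A <- matrix(rnorm(3 * n), n)
    B <- matrix(rnorm(3 * n), n)
  })
  f <- function(m) m[, 1] + m[, 2] * m[, 3]
  yC <- sapply(1:3, function(i) f(radial_matrix(A, B, i)))
  res <- sobol_indices(f(A), f(B), yC)
  expect_equal(res$indices$s0, c(0.5, 0, 0), tolerance = 0.04)
  expect_equal(res$indices$st, c(0.5, 0.5, 0.5), tolerance = 0.04)
  expect_equal(res$output_variance, 2, tolerance = 0.1)
})

test_that("constant outputs are refused as degenerate", {
  y <- rep(1, 100)
  expect_error(sobol_indices(y, y, cbind(y, y)), "variance")
})

test_that("eps is exactly st - s0 and permutation-equivariant", {
  sel <- fixture_bundle()
  sob <- network_sobol(sel$network, variation_spec(0.1), sel$initial_state,
                       n_sobol = 400, seed = 74)
  expect_identical(sob$indices$eps, sob$indices$st - sob$indices$s0)
  expect_identical(sob$s0_sum, sum(sob$indices$s0))
  # total >= first-order up to Monte-Carlo noise
  expect_true(all(sob$indices$st >= sob$indices$s0 -
                    3 * (sob$indices$se_s0 + sob$indices$se_st)))
})

test_that("network Sobol is deterministic and replicates shrink dispersion", {
  sel <- fixture_bundle()
  net <- sel$network
  g0 <- sel$initial_state
  a <- network_sobol(net, variation_spec(0.1), g0, n_sobol = 300, seed = 75)
  b <- network_sobol(net, variation_spec(0.1), g0, n_sobol = 300, seed = 75)
  expect_identical(a$indices, b$indices)
  r <- network_sobol(net, variation_spec(0.1), g0, n_sobol = 300,
                     replicates = 3, seed = 76)
  expect_identical(nrow(r$replicates), 3L * nrow(r$indices))
  expect_true(all(is.finite(r$indices$se_s0)))
})

test_that("additive sum tracks the PGS R2 on a linear-regime network", {
  sel <- linear_regime_fixture()
  net <- sel$network
  g0 <- sel$initial_state
  pop <- build_population(net, variation_spec(0.05), 1000, g0, seed = 77)
  fit <- fit_pgs(pop, seed = 77)
  sob <- network_sobol(net, variation_spec(0.05), g0, n_sobol = 4000,
                       seed = 77)
  expect_lt(abs(fit$r2 - sob$s0_sum), 0.05)
})
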