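test_that("sigmoid matches its closed form and is odd, bounded, increasing", {
  expect_identical(sigmoid(0, 10), 0)
  expect_equal(sigmoid(0.1, 10), 2 / (1 + exp(-1)) - 1, tolerance = 1e-12)
  x <- seq(-2, 2, by = 0.17)
  expect_equal(sigmoid(x, 10), -sigmoid(-x, 10))
  expect_true(all(abs(sigmoid(x, 10)) < 1))
  expect_true(all(diff(sigmoid(x, 10)) > 0))
  # saturation rounds to the closed bounds but never beyond
  expect_true(all(abs(sigmoid(seq(-50, 50, by = 1), 10)) <= 1))
  # numerically safe far into saturation
  expect_identical(sigmoid(1e6, 10), 1)
  expect_identical(sigmoid(-1e6, 10), -1)
  expect_error(sigmoid(0, -1), "positive")
})

test_that("sigmoid_deriv is the derivative of sigmoid", {
  x <- seq(-2, 2, by = 0.23)
  h <- 1e-6
  fd <- (sigmoid(x + h, 10) - sigmoid(x - h, 10)) / (2 * h)
  expect_equal(sigmoid_deriv(x, 10), fd, tolerance = 1e-7)
  expect_identical(sigmoid_deriv(0, 10), 5)
})

test_that("zero-weight dynamics collapse to the origin within 2 iterations", {
  tr <- iterate_dynamics(matrix(0, 4, 4), c(1, -1, 1, 1))
  expect_true(tr$converged)
  expect_lte(tr$path_length, 2)
  expect_identical(tr$equilibrium, rep(0, 4))
  expect_identical(tr$phenotype, 0)
})

test_that("two-gene chain follows the hand-iterated trajectory", {
  # gene 1 unregulated: decays 1 -> f(0) = 0; gene 2 driven by w = 5
  w <- edge_matrix(2, list(c(1, 2, 5)))
  g <- c(1, 1)
  expected <- list(g)
  for (t in 1:6) {
    g <- c(tanh(5 * 0 / 1), tanh(10 * 5 * g[1] / 2))  # f(0), f(5 g1)
    expected[[t + 1]] <- g
  }
  tr <- iterate_dynamics(w, c(1, 1))
  rows <- min(nrow(tr$states), 7)
  expect_equal(tr$states[seq_len(rows), ],
               do.call(rbind, expected)[seq_len(rows), ], tolerance = 1e-12)
  expect_true(tr$converged)
  expect_equal(tr$equilibrium, c(0, 0), tolerance = 1e-3)
})

test_that("states stay inside the sigmoid range after the first update", {
  # mathematically the open interval (-1, 1); saturated inputs round to the
  # closed bounds in double precision, which is the representable supremum
  for (s in 1:10) {
    net <- generate_reference_network(10, 0.5, seed = s)
    tr <- iterate_dynamics(net, sample_initial_state(10, seed = s))
    expect_true(all(abs(tr$states[-1, ]) <= 1))
  }
})

test_that("converged trajectories satisfy the fixed-point residual bound", {
  p <- sigmoid_params()
  for (s in 1:20) {
    sel <- select_converging_network(10, 0.3, p, seed = s)
    w <- unclass(sel$network)
    g <- sel$trajectory$equilibrium
    expect_lte(max(abs(g - sigmoid(w %*% g, p$steepness))), p$conv_tol)
  }
})

test_that("the map agrees with its linearisation in the linear regime", {
  # small weights => |W g| <= 0.01 along the trajectory; f(x) ~ (a/2) x
  withr::with_seed(31, {
    w <- matrix(rnorm(100, sd = 5e-4), 10, 10); diag(w) <- 0
  })
  g <- rep(c(1, -1), 5)
  for (t in 1:5) {
    h <- drop(w %*% g)
    expect_true(all(abs(h) <= 0.01))
    nonlinear <- sigmoid(h, 10)
    linear <- 5 * h
    expect_lt(max(abs(nonlinear - linear)[linear != 0] /
                    abs(linear)[linear != 0]), 0.05)
    g <- nonlinear
  }
})

test_that("psi score is zero iff the window is constant", {
  const <- matrix(0.3, 5, 4)
  expect_identical(psi_score(const), 0)
  alt <- rbind(rep(1, 4), rep(-1, 4), rep(1, 4))
  expect_gt(psi_score(alt), 1)
  # single entry differing by delta: psi = delta / ((rows-1) * genes)
  delta <- 1e-3
  win <- matrix(0.5, 3, 4)
  win[3, 2] <- 0.5 + delta
  expect_equal(psi_score(win), delta / (2 * 4), tolerance = 1e-15)
  expect_error(psi_score(const[1, , drop = FALSE]), "at least 2")
})

test_that("trajectories are bit-identical under a fixed seed", {
  a <- select_converging_network(10, 0.3, seed = 17)
  b <- select_converging_network(10, 0.3, seed = 17)
  expect_identical(a$network, b$network)
  expect_identical(a$trajectory$states, b$trajectory$states)
  expect_identical(a$trajectory$path_length, b$trajectory$path_length)
})

test_that("select_converging_network always returns a converged triple", {
  sel <- select_converging_network(10, 0.3, seed = 23)
  expect_true(sel$trajectory$converged)
  expect_gte(sel$n_rejected, 0L)
  # with an empty network (c = 0) acceptance is immediate
  sel0 <- select_converging_network(10, 0, seed = 23)
  expect_identical(sel0$n_rejected, 0L)
  expect_identical(sel0$trajectory$phenotype, 0)
})

test_that("the psi criterion is available and reports convergence", {
  p <- sigmoid_params(criterion = "psi")
  sel <- fixture_bundle()
  tr <- iterate_dynamics(sel$network, sel$initial_state, p)
  expect_true(tr$converged)
  expect_lte(tr$psi, p$conv_tol)
})

test_that("trajectory TSV export has one row per iteration", {
  tr <- fixture_bundle()$trajectory
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  df <- read.delim(path)
  expect_identical(nrow(df), nrow(tr$states))
  expect_identical(df$t, seq_len(nrow(df)) - 1L)
})

test_that("compiled batch evaluator agrees exactly with iterate_dynamics", {
  sel <- fixture_bundle()
  et <- network_edges(sel$network)
  withr::with_seed(41, {
    geno <- matrix(rnorm(50 * nrow(et), rep(et$weight, each = 50),
                         rep(0.3 * abs(et$weight), each = 50)), nrow = 50)
  })
  res <- pgsnet:::evaluate_genotypes(geno, et, 10, sel$initial_state,
                                     sigmoid_params())
  for (i in seq_len(nrow(geno))) {
    w <- matrix(0, 10, 10)
    w[cbind(et$target, et$regulator)] <- geno[i, ]
    tr <- iterate_dynamics(w, sel$initial_state)
    # agreement to rounding (summation order differs between BLAS and the
    # compiled edge loop); convergence decisions must coincide exactly
    expect_equal(res$phenotype[i], tr$phenotype, tolerance = 1e-12)
    expect_identical(res$converged[i], tr$converged)
    expect_identical(res$path_length[i], tr$path_length)
  }
})
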