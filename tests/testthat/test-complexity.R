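test_that("positive two-cycle counting matches exhaustive enumeration", {
  expect_identical(count_positive_two_cycles(
    edge_matrix(2, list(c(1, 2, 0.5), c(2, 1, 0.2)))), 1L)
  expect_identical(count_positive_two_cycles(
    edge_matrix(2, list(c(1, 2, 0.5), c(2, 1, -0.2)))), 0L)
  # two repressions also form a positive loop
  expect_identical(count_positive_two_cycles(
    edge_matrix(2, list(c(1, 2, -0.5), c(2, 1, -0.2)))), 1L)
  for (s in 1:50) {
    net <- generate_reference_network(10, 0.5, seed = s)
    expect_identical(count_positive_two_cycles(net),
                     brute_force_pos_cycles(unclass(net)))
  }
})

test_that("feedback count is invariant under gene relabelling", {
  net <- generate_reference_network(10, 0.4, seed = 81)
  withr::with_seed(81, perm <- sample(10))
  relabelled <- unclass(net)[perm, perm]
  expect_identical(count_positive_two_cycles(relabelled),
                   count_positive_two_cycles(net))
})

test_that("ensemble mean feedback count matches the Erdos-Renyi expectation", {
  # pair {i,j} mutual with prob c^2, positive product with prob 1/2:
  # E[count] = 45 c^2 / 2 at N = 10
  n_nets <- 600
  withr::with_seed(82, {
    counts <- vapply(seq_len(n_nets), function(i) {
      count_positive_two_cycles(generate_reference_network(10, 0.3))
    }, integer(1))
  })
  expected <- 45 * 0.3^2 * 0.5
  p <- 0.3^2 * 0.5
  se <- sqrt(45 * p * (1 - p) / n_nets)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("density and clustering follow their definitions", {
  full <- generate_reference_network(6, 1, seed = 83)
  prof <- complexity_profile(full)
  expect_identical(prof$density, 1)
  expect_identical(prof$clustering, 1)

  empty <- as_reference_network(matrix(0, 6, 6))
  expect_identical(complexity_profile(empty)$density, 0)

  # star graph: hub + 4 leaves, no triangles anywhere
  star <- edge_matrix(5, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1),
                              c(1, 5, 1)))
  expect_identical(complexity_profile(star)$clustering, 0)
  expect_identical(complexity_profile(star, clustering_type = "global")$clustering, 0)

  # triangle plus pendant, mean local coefficient by hand:
  # genes 1,2,3 mutually linked (coeff 1 each except gene 1 which also
  # touches gene 4): c1 = 1/3, c2 = c3 = 1, c4 = 0 -> mean 7/12
  tri <- edge_matrix(4, list(c(1, 2, 1), c(2, 3, 1), c(3, 1, 1),
                             c(1, 4, 1)))
  expect_equal(complexity_profile(tri)$clustering, (1/3 + 1 + 1 + 0) / 4)
})

test_that("profiles carry path length and normalised feedback count", {
  sel <- fixture_bundle()
  prof <- complexity_profile(sel$network, sel$trajectory, ensemble_median = 2)
  expect_identical(prof$path_length, sel$trajectory$path_length)
  expect_identical(prof$n_pos_two_cycles_norm, prof$n_pos_two_cycles / 2)
  expect_error(complexity_profile(sel$network, ensemble_median = 0),
               "normalise")
})

test_that("permutation test hits its resolution floor on extreme groups", {
  # the ten largest of forty distinct values: no permuted group can reach the
  # observed mean (redrawing the identical set has probability 1/C(40,10))
  values <- c(101:110, 1:30)
  mask <- values > 100
  res <- enrichment_permutation_test(values, mask, n_perm = 999, seed = 84)
  expect_identical(res$p_value, 1 / 1000)
  expect_gt(res$observed_mean, res$expected_mean)
})

test_that("permutation test is calibrated on exchangeable data", {
  values <- rep(1, 10)
  res <- enrichment_permutation_test(values, c(rep(TRUE, 3), rep(FALSE, 7)),
                                     n_perm = 200, seed = 85)
  expect_identical(res$p_value, 1)
  withr::with_seed(86, vals <- rnorm(40))
  res2 <- enrichment_permutation_test(vals, seq_along(vals) <= 10,
                                      n_perm = 5000, seed = 86)
  expect_equal(res2$expected_mean, mean(vals), tolerance = 0.1)
  expect_error(enrichment_permutation_test(vals, rep(FALSE, 40), 100),
               "subset")
})
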