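#' Transfer R^2 of a polygenic score on another population
#'
#' Scores the fitted PGS on a test population's genotypes and returns the
#' R^2 against the test phenotypes. Negative values mean the transferred
#' score predicts worse than the test-population mean.
#'
#' @param fit A `pgs_fit`.
#' @param test_population A `population` over the same edge set.
#' @return Single number (unbounded below).
#' @export
cross_population_r2 <- function(fit, test_population) {
  if (!identical(test_population$edge_index$edge, names(fit$betas))) {
    abort("Test population and fit cover different edge sets.")
  }
  r_squared(test_population$phenotypes,
            predict_pgs(fit, test_population$genotypes))
}

#' Mutate a single regulatory connection
#'
#' Picks one existing edge uniformly at random and replaces its weight by a
#' fresh standard-normal draw, leaving every other entry (and the support)
#' untouched.
#'
#' @param reference A `reference_network` with at least one edge.
#' @param seed Optional seed.
#' @return List: `network` (the mutant `reference_network`), `edge` (label),
#'   `regulator`, `target`, `old_weight`, `new_weight`.
#' @export
mutate_network <- function(reference, seed = NULL) {
  reference <- as_reference_network(reference)
  et <- network_edges(reference)
  if (nrow(et) == 0) abort("Reference network has no edges to mutate.")
  local_seed(seed)
  e <- sample.int(nrow(et), 1)
  new_w <- rnorm(1)
  w <- unclass(reference)
  w[et$target[e], et$regulator[e]] <- new_w
  list(network = new_reference_network(w),
       edge = et$edge[e], regulator = et$regulator[e],
       target = et$target[e],
       old_weight = et$weight[e], new_weight = new_w)
}

#' Spectral distance between two networks
#'
#' Condenses each weight matrix into its eigenvalue spectrum and compares
#' the absolute moduli sorted in decreasing order:
#' `d(G1, G2) = sum_i (|lambda_i(G1)| - |lambda_i(G2)|)^2`. Symmetric,
#' non-negative, zero on isospectral pairs (in particular under gene
#' relabelling); not a metric, since moduli discard sign and phase.
#'
#' @param net1,net2 `reference_network`s or arbitrary square weight matrices
#'   of equal size (the comparison is meaningful for any weighted digraph).
#' @param rooted Take the square root (conventional Euclidean form)?
#'   Default FALSE, the plain sum of squared differences; the two are
#'   monotonically related, so group comparisons are unaffected.
#' @return Single non-negative number.
#' @export
spectral_distance <- function(net1, net2, rooted = FALSE) {
  w1 <- as.matrix(net1)
  w2 <- as.matrix(net2)
  if (nrow(w1) != ncol(w1) || !all(is.finite(w1), is.finite(w2))) {
    abort("Networks must be finite square matrices.")
  }
  if (!identical(dim(w1), dim(w2))) abort("Networks must have equal size.")
  m1 <- sort(Mod(eigen(w1, only.values = TRUE)$values), decreasing = TRUE)
  m2 <- sort(Mod(eigen(w2, only.values = TRUE)$values), decreasing = TRUE)
  d <- sum((m1 - m2)^2)
  if (rooted) sqrt(d) else d
}

#' Single-edge mutant screen of polygenic-score transferability
#'
#' Repeatedly mutates one regulatory connection of the base network
#' ([mutate_network()]), builds a fresh population around each mutant at the
#' training variation regime (same shared initial state), and scores the
#' base network's PGS on it. Each mutant is annotated with its spectral
#' distance to the base network and, when a base `sobol_result` is given,
#' the total Sobol index of the mutated edge in the base network.
#'
#' @param reference The base `reference_network`.
#' @param fit The PGS fitted on the base network's population.
#' @param variation Training [variation_spec()].
#' @param initial_state Shared initial expression state of the populations.
#' @param params A [sigmoid_params()] list.
#' @param n_mutants Number of mutants (default 200).
#' @param pop_size Test-population size per mutant (default 1000).
#' @param sobol Optional base-network `sobol_result` supplying `st` per edge.
#' @param seed Optional seed.
#' @return Tibble: `mutant_id`, `edge`, `old_weight`, `new_weight`,
#'   `spectral_dist`, `transfer_r2`, `mutated_edge_st`, `transferable`
#'   (`transfer_r2 > 0`).
#' @export
mutant_screen <- function(reference, fit, variation, initial_state,
                          params = sigmoid_params(), n_mutants = 200,
                          pop_size = 1000, sobol = NULL, seed = NULL) {
  reference <- as_reference_network(reference)
  local_seed(seed)
  st_lookup <- if (is.null(sobol)) NULL else
    stats::setNames(sobol$indices$st, sobol$indices$edge)
  rows <- lapply(seq_len(n_mutants), function(m) {
    mut <- mutate_network(reference)
    pop <- build_population(mut$network, variation, pop_size, initial_state,
                            params)
    tibble::tibble(
      mutant_id = m,
      edge = mut$edge,
      old_weight = mut$old_weight,
      new_weight = mut$new_weight,
      spectral_dist = spectral_distance(reference, mut$network),
      transfer_r2 = cross_population_r2(fit, pop),
      mutated_edge_st = if (is.null(st_lookup)) NA_real_ else
        unname(st_lookup[mut$edge])
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(transferable = .data$transfer_r2 > 0)
}

#' Compare transferable and non-transferable mutants
#'
#' Splits a mutant screen at `transfer_r2 <= r2_cut` (non-transferable,
#' ties included) versus `> r2_cut` (transferable) and tests whether
#' non-transferable mutants are structurally farther from the base network:
#' one-sided Wilcoxon rank-sum on the spectral distances (alternative:
#' non-transferable greater). Per-group means of the spectral distance and
#' of the mutated edge's total Sobol index are reported alongside.
#'
#' @param mutants Tibble from [mutant_screen()].
#' @param r2_cut Transferability cutoff on `transfer_r2` (default 0).
#' @return List: `groups` (tibble with one row per group: `n`,
#'   `mean_spectral_dist`, `mean_mutated_edge_st`), `rank_sum_p` (NA with a
#'   warning when a group is empty).
#' @export
transfer_group_comparison <- function(mutants, r2_cut = 0) {
  mutants <- dplyr::mutate(mutants,
                           group = ifelse(.data$transfer_r2 <= r2_cut,
                                          "non_transferable", "transferable"))
  groups <- mutants |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_spectral_dist = mean(.data$spectral_dist),
      mean_mutated_edge_st = mean(.data$mutated_edge_st),
      .by = "group")
  if (dplyr::n_distinct(mutants$group) < 2) {
    warning("One transferability group is empty; no rank-sum p-value.",
            call. = FALSE)
    return(list(groups = groups, rank_sum_p = NA_real_))
  }
  p <- wilcox.test(
    mutants$spectral_dist[mutants$group == "non_transferable"],
    mutants$spectral_dist[mutants$group == "transferable"],
    alternative = "greater", exact = FALSE)$p.value
  list(groups = groups, rank_sum_p = p)
}
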