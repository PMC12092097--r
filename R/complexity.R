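#' Count two-component positive feedback loops
#'
#' An unordered gene pair {i, j} forms a two-component positive feedback
#' when both regulations exist and the product of the two weights is
#' positive — two activations or two repressions, either of which acts as a
#' bistable switch motif.
#'
#' @param network `reference_network` or weight matrix.
#' @return Integer count (at most N(N-1)/2).
#' @export
count_positive_two_cycles <- function(network) {
  w <- unclass(as_reference_network(network))
  p <- w * t(w)                       # p[i,j] = w_ij * w_ji
  sum(p[upper.tri(p)] > 0)
}

#' Structural complexity profile of a network
#'
#' Density is the ratio of realised to possible directed regulations,
#' I / (N(N-1)). The clustering coefficient is computed on the undirected,
#' unweighted projection of the support: by default the mean local
#' clustering coefficient (isolated and degree-1 genes contribute 0), with
#' global transitivity available as an alternative. Path length is the
#' trajectory's iterations-to-equilibrium. The feedback count is optionally
#' normalised by an ensemble median.
#'
#' @param network `reference_network` or weight matrix.
#' @param trajectory Optional `trajectory_result` providing the path length.
#' @param ensemble_median Optional positive median feedback count of a
#'   reference ensemble, for the normalised count.
#' @param clustering_type `"localaverage"` (default) or `"global"`.
#' @return One-row tibble: `n_pos_two_cycles`, `n_pos_two_cycles_norm`,
#'   `density`, `clustering`, `path_length`.
#' @export
complexity_profile <- function(network, trajectory = NULL,
                               ensemble_median = NA_real_,
                               clustering_type = c("localaverage", "global")) {
  clustering_type <- match.arg(clustering_type)
  w <- unclass(as_reference_network(network))
  n <- nrow(w)
  n_edges <- sum(w != 0)
  cyc <- count_positive_two_cycles(w)
  if (!is.na(ensemble_median) && ensemble_median == 0) {
    abort("`ensemble_median` of 0 cannot normalise the feedback count.")
  }
  support <- (w != 0) | (t(w) != 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  cl <- if (clustering_type == "localaverage") {
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  } else {
    igraph::transitivity(g, type = "global")
  }
  if (is.nan(cl)) cl <- 0
  tibble::tibble(
    n_pos_two_cycles = cyc,
    n_pos_two_cycles_norm = if (is.na(ensemble_median)) NA_real_ else
      cyc / ensemble_median,
    density = n_edges / (n * (n - 1)),
    clustering = cl,
    path_length = if (is.null(trajectory)) NA_integer_ else
      trajectory$path_length
  )
}

#' Permutation enrichment test for a network group
#'
#' Tests whether a designated group of networks (e.g. those with
#' non-additive share above the ensemble's 80th percentile) carries a higher
#' mean of some structural measure than random groups of the same size. The
#' one-sided p-value uses the add-one correction
#' `p = (1 + #\{permuted mean >= observed\}) / (n_perm + 1)`, so its
#' resolution is bounded below by `1 / (n_perm + 1)`.
#'
#' @param values Numeric vector (one value per network).
#' @param group_mask Logical vector marking the group; must be non-empty and
#'   not everything.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return One-row tibble: `observed_mean`, `expected_mean` (mean of
#'   permuted group means), `p_value`, `n_perm`.
#' @export
enrichment_permutation_test <- function(values, group_mask, n_perm = 10000,
                                        seed = NULL) {
  if (length(values) != length(group_mask)) abort("Length mismatch.")
  n_in <- sum(group_mask)
  if (n_in == 0 || n_in == length(values)) {
    abort("`group_mask` must select a non-empty strict subset.")
  }
  if (!is_scalar_num(n_perm) || n_perm < 1) abort("`n_perm` must be >= 1.")
  local_seed(seed)
  observed <- mean(values[group_mask])
  perm_means <- vapply(seq_len(n_perm), function(i) {
    mean(values[sample.int(length(values), n_in)])
  }, numeric(1))
  tibble::tibble(
    observed_mean = observed,
    expected_mean = mean(perm_means),
    p_value = (1 + sum(perm_means >= observed)) / (n_perm + 1),
    n_perm = as.integer(n_perm)
  )
}
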