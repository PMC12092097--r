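#' Specify population-level genetic variation
#'
#' Individual networks in a population share the reference topology but carry
#' perturbed weights: each non-zero reference weight w is replaced by a draw
#' from `N(w, sd)`. In `"relative"` mode (the default) `sd = sd_fraction *
#' |w|`, i.e. the spread scales with the wild-type weight; in `"absolute"`
#' mode `sd = sd_fraction` for every edge.
#'
#' @param sd_fraction Non-negative spread parameter; typical regimes range
#'   from 0.05 (5% variation) to 0.5. Default 0.1.
#' @param mode `"relative"` or `"absolute"`.
#' @return A `variation_spec` list.
#' @export
variation_spec <- function(sd_fraction = 0.1, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (!is_scalar_num(sd_fraction) || sd_fraction < 0) {
    abort("`sd_fraction` must be a single non-negative number.")
  }
  structure(list(sd_fraction = sd_fraction, mode = mode),
            class = "variation_spec")
}

#' Draw a random initial expression state
#'
#' Each gene starts fully on (+1) or fully off (-1) with probability 1/2,
#' independently.
#'
#' @param n_genes Number of genes.
#' @param seed Optional seed.
#' @return Numeric vector of +1/-1 of length `n_genes`.
#' @export
sample_initial_state <- function(n_genes, seed = NULL) {
  if (!is_scalar_num(n_genes) || n_genes < 1) abort("`n_genes` must be >= 1.")
  local_seed(seed)
  sample(c(-1, 1), n_genes, replace = TRUE)
}

#' Sample one individual's weight matrix around a reference network
#'
#' Every non-zero reference weight is resampled from a normal centred on it,
#' with the spread given by the [variation_spec()]; zero entries (absent
#' regulations) and the diagonal stay exactly zero, so the topology is shared
#' by the whole population.
#'
#' @param reference A `reference_network`.
#' @param variation A [variation_spec()].
#' @param seed Optional seed.
#' @return Plain weight matrix of the same dimension as the reference.
#' @export
sample_individual_weights <- function(reference, variation = variation_spec(),
                                      seed = NULL) {
  local_seed(seed)
  w <- bare_weights(reference)
  et <- network_edges(w)
  sds <- edge_sds(et$weight, variation)
  w[cbind(et$target, et$regulator)] <- rnorm(nrow(et), et$weight, sds)
  w
}

edge_sds <- function(ref_weights, variation) {
  if (variation$mode == "relative") {
    variation$sd_fraction * abs(ref_weights)
  } else {
    rep(variation$sd_fraction, length(ref_weights))
  }
}

#' Build a variational population of networks and their phenotypes
#'
#' Samples `pop_size` individual weight matrices around the reference,
#' iterates each to its fixed point from the shared `initial_state`, and
#' records the phenotype (mean equilibrium expression). Individuals that do
#' not converge within the iteration cap keep the state at the cap as their
#' phenotype and remain in the population (dropping them would distort the
#' genotype distribution); `n_converged` reports how many converged.
#'
#' @param reference A `reference_network` with at least one edge.
#' @param variation A [variation_spec()].
#' @param pop_size Number of individuals P (default 10000).
#' @param initial_state Shared initial expression state; drawn once with
#'   [sample_initial_state()] if omitted.
#' @param params A [sigmoid_params()] list (the `"delta"` criterion is used
#'   for population evaluation).
#' @param seed Optional seed.
#' @return A `population` object: list with `genotypes` (P x I matrix, one
#'   column per reference edge in [network_edges()] order), `phenotypes`
#'   (length P), `edge_index` (the edge tibble), `initial_state`,
#'   `variation`, `n_converged`, `path_lengths`.
#' @examples
#' net <- generate_reference_network(10, 0.3, seed = 4)
#' pop <- build_population(net, variation_spec(0.1), pop_size = 200, seed = 4)
#' var(pop$phenotypes)
#' @export
build_population <- function(reference, variation = variation_spec(),
                             pop_size = 10000, initial_state = NULL,
                             params = sigmoid_params(), seed = NULL) {
  reference <- as_reference_network(reference)
  if (!is_scalar_num(pop_size) || pop_size < 2) abort("`pop_size` must be >= 2.")
  et <- network_edges(reference)
  if (nrow(et) == 0) abort("Reference network has no edges: no predictors.")
  local_seed(seed)
  if (is.null(initial_state)) {
    initial_state <- sample_initial_state(nrow(reference))
  }
  sds <- edge_sds(et$weight, variation)
  genotypes <- matrix(rnorm(pop_size * nrow(et),
                            mean = rep(et$weight, each = pop_size),
                            sd = rep(sds, each = pop_size)),
                      nrow = pop_size)
  colnames(genotypes) <- et$edge
  res <- evaluate_genotypes(genotypes, et, nrow(reference), initial_state,
                            params)
  structure(list(
    genotypes = genotypes,
    phenotypes = res$phenotype,
    edge_index = et,
    initial_state = initial_state,
    variation = variation,
    n_converged = sum(res$converged),
    path_lengths = res$path_length
  ), class = "population")
}

# Phenotype map for a batch of individuals (rows of `genotypes` are edge
# weight vectors in edge_index order). Uses the compiled core for the default
# "delta" criterion; falls back to per-individual R iteration otherwise.
evaluate_genotypes <- function(genotypes, edge_index, n_genes, initial_state,
                               params) {
  if (params$criterion == "delta") {
    batch_phenotypes_cpp(genotypes, edge_index$target, edge_index$regulator,
                         n_genes, initial_state, params$steepness,
                         params$max_iter, params$conv_tol)
  } else {
    trs <- lapply(seq_len(nrow(genotypes)), function(i) {
      w <- matrix(0, n_genes, n_genes)
      w[cbind(edge_index$target, edge_index$regulator)] <- genotypes[i, ]
      iterate_dynamics(w, initial_state, params)
    })
    list(phenotype = vapply(trs, `[[`, numeric(1), "phenotype"),
         converged = vapply(trs, `[[`, logical(1), "converged"),
         path_length = vapply(trs, `[[`, integer(1), "path_length"),
         equilibrium = do.call(rbind, lapply(trs, `[[`, "equilibrium")))
  }
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf(
    "<population> %d individuals x %d edges; %.1f%% converged; phenotype sd %.4g\n",
    nrow(x$genotypes), ncol(x$genotypes),
    100 * x$n_converged / nrow(x$genotypes), sd(x$phenotypes)))
  invisible(x)
}

#' @describeIn build_population Tidy one-row-per-individual view: `phenotype`
#'   plus one column per edge weight.
#' @param x A `population`.
#' @param ... Unused.
#' @export
tidy.population <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(phenotype = x$phenotypes),
                   tibble::as_tibble(x$genotypes))
}

#' Read / write populations as TSV
#'
#' One row per individual; columns are `phenotype` followed by one column per
#' edge, labelled `w(regulator->target)`.
#'
#' @param population A `population`.
#' @param path File path.
#' @name population_io
#' @export
write_population_tsv <- function(population, path) {
  df <- tidy.population(population)
  header <- paste(names(df), collapse = "\t")
  rows <- do.call(paste, c(lapply(df, fmt_num), sep = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname population_io
#' @return A tibble (`read_population_tsv`); the path, invisibly
#'   (`write_population_tsv`).
#' @export
read_population_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}
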