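#' Experiment configuration
#'
#' Bundles every knob of the simulation study with its default: 10-gene
#' networks at connectivity 0.3, sigmoid steepness 10, 100-iteration cap,
#' populations of 10^4 individuals at 10% relative weight variation, Sobol
#' base sample 5x10^4, 100-network ensembles, 200-mutant screens, 10^4
#' permutations. The `"test"` profile scales the expensive counts down
#' (populations 10^3, Sobol 2x10^3, 20 networks, 50 mutants) for quick runs.
#'
#' A master `seed` is expanded into independent named per-stage streams
#' (network, population, folds, sobol, mutants, permutations) so changing
#' one stage's settings does not shift another stage's draws.
#'
#' @param n_genes,connect_prob Network size and connectivity.
#' @param steepness,max_iter Dynamics parameters (see [sigmoid_params()]).
#' @param pop_size Population size P.
#' @param sd_fraction Variation used for single-network runs.
#' @param sd_fractions Sweep grid for [run_variation_sweep()].
#' @param variation_mode `"relative"` or `"absolute"` (see
#'   [variation_spec()]).
#' @param n_sobol Sobol base sample size.
#' @param n_networks Ensemble size.
#' @param n_mutants Mutant-screen size.
#' @param n_perm Permutations for enrichment tests.
#' @param seed Master seed.
#' @param profile `"full"` (study scale) or `"test"` (scaled down); applied
#'   before any explicit argument.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_genes = 10, connect_prob = 0.3,
                              steepness = 10, max_iter = 100,
                              pop_size = 10000, sd_fraction = 0.1,
                              sd_fractions = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                              variation_mode = "relative",
                              n_sobol = 50000, n_networks = 100,
                              n_mutants = 200, n_perm = 10000, seed = 1,
                              profile = c("full", "test")) {
  profile <- match.arg(profile)
  cfg <- list(n_genes = n_genes, connect_prob = connect_prob,
              steepness = steepness, max_iter = max_iter,
              pop_size = pop_size, sd_fraction = sd_fraction,
              sd_fractions = sd_fractions, variation_mode = variation_mode,
              n_sobol = n_sobol, n_networks = n_networks,
              n_mutants = n_mutants, n_perm = n_perm, seed = seed,
              profile = profile)
  if (profile == "test") {
    scaled <- list(pop_size = 1000, n_sobol = 2000, n_networks = 20,
                   n_mutants = 50, n_perm = 1000)
    defaults <- formals(experiment_config)
    for (nm in names(scaled)) {
      if (identical(cfg[[nm]], eval(defaults[[nm]]))) cfg[[nm]] <- scaled[[nm]]
    }
  }
  if (any(vapply(cfg[c("n_genes", "pop_size", "n_sobol", "n_networks",
                       "n_mutants", "n_perm", "max_iter")],
                 function(v) !is_scalar_num(v) || v < 1, logical(1)))) {
    abort("All configuration counts must be positive.")
  }
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path YAML file path; the config round-trips losslessly.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

config_params <- function(config) {
  sigmoid_params(steepness = config$steepness, max_iter = config$max_iter)
}

config_variation <- function(config, sd = config$sd_fraction) {
  variation_spec(sd, config$variation_mode)
}

#' Single-network deep dive
#'
#' The full per-network pipeline: rejection-sample a converging network,
#' build its variational population, fit the polygenic score, run the
#' local-stability analysis at the equilibrium and the Sobol global
#' sensitivity analysis. When `out_dir` is given every result is persisted
#' as a plain-text artifact (TSV/JSON) plus a manifest listing files and
#' per-stage seeds; outputs are byte-identical across reruns with the same
#' config.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return (Invisibly when writing) list with `network`, `initial_state`,
#'   `trajectory`, `population`, `fit`, `stability`, `sobol`,
#'   `classification`, `seeds`.
#' @export
run_single_network <- function(config = experiment_config(), out_dir = NULL) {
  seeds <- derive_seeds(config$seed, c("network", "population", "folds",
                                       "sobol", "mutants", "permutations"))
  params <- config_params(config)
  sel <- select_converging_network(config$n_genes, config$connect_prob,
                                   params, seed = seeds$network)
  variation <- config_variation(config)
  pop <- build_population(sel$network, variation, config$pop_size,
                          sel$initial_state, params, seed = seeds$population)
  fit <- fit_pgs(pop, cv_folds = 5, seed = seeds$folds)
  stab <- local_stability(sel$network, sel$trajectory$equilibrium,
                          config$steepness)
  sob <- network_sobol(sel$network, variation, sel$initial_state, params,
                       n_sobol = config$n_sobol, seed = seeds$sobol)
  cls <- classify_edges(sob)
  bundle <- list(network = sel$network, initial_state = sel$initial_state,
                 trajectory = sel$trajectory, population = pop, fit = fit,
                 stability = stab, sobol = sob, classification = cls,
                 seeds = seeds)
  if (is.null(out_dir)) return(bundle)
  write_bundle(bundle, config, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_network_tsv(bundle$network, p("network.tsv"))
  write_edge_list_tsv(bundle$network, p("edges.tsv"))
  write_trajectory_tsv(bundle$trajectory, p("trajectory.tsv"))
  write_population_tsv(bundle$population, p("population.tsv"))
  write_tibble_tsv(tidy(bundle$fit)[, c("edge", "beta")], p("pgs.tsv"))
  jsonlite::write_json(
    list(intercept = bundle$fit$intercept, shrinkage = bundle$fit$shrinkage,
         r2 = bundle$fit$r2, r2_insample = bundle$fit$r2_insample,
         cv_folds = bundle$fit$cv_folds, seed = bundle$seeds$folds),
    p("pgs.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(eigenvalues = lapply(bundle$stability$eigenvalues,
                              function(z) c(Re(z), Im(z))),
         n_zero_eigen = bundle$stability$n_zero_eigen,
         max_modulus = bundle$stability$max_modulus),
    p("stability.json"), auto_unbox = TRUE, digits = NA)
  write_matrix_tsv(bundle$stability$edge_scores, p("edge_scores.tsv"))
  write_tibble_tsv(tidy(bundle$sobol), p("sobol.tsv"))
  jsonlite::write_json(
    list(s0_sum = bundle$sobol$s0_sum, eps_sum = bundle$sobol$eps_sum,
         output_mean = bundle$sobol$output_mean,
         output_variance = bundle$sobol$output_variance,
         n_sobol = bundle$sobol$n, seed = bundle$seeds$sobol,
         n_nonconverged = bundle$sobol$n_nonconverged),
    p("sobol.json"), auto_unbox = TRUE, digits = NA)
  write_tibble_tsv(bundle$classification, p("classification.tsv"))
  files <- c("network.tsv", "edges.tsv", "trajectory.tsv", "population.tsv",
             "pgs.tsv", "pgs.json", "stability.json", "edge_scores.tsv",
             "sobol.tsv", "sobol.json", "classification.tsv")
  yaml::write_yaml(list(files = files, seeds = bundle$seeds,
                        config = unclass(config),
                        pgsnet_version =
                          as.character(utils::packageVersion("pgsnet"))),
                   p("manifest.yaml"))
  invisible(out_dir)
}

write_tibble_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path) {
  writeLines(c(
    paste(sprintf("g%d", seq_len(ncol(m))), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(fmt_num(m[i, ]), collapse = "\t")
    }, character(1))), path)
  invisible(path)
}

#' Ensemble study across random networks
#'
#' Repeats the per-network pipeline over `n_networks` converging networks
#' and assembles the additive-space table — one row per network with its
#' Sobol sums, PGS R^2, complexity profile, stability diagnostics and
#' connection-class ratios — plus the permutation enrichment tests of the
#' complexity measures in the high-non-additivity group (networks with
#' `eps_sum` above the ensemble's 80th percentile) and the rolling-window
#' class-ratio summaries ordered by R^2.
#'
#' @param config An [experiment_config()].
#' @param .progress Print one line per network.
#' @return List: `table` (tibble, one row per network), `enrichment`
#'   (tibble, one row per complexity measure), `rolling` (tibble of window
#'   means by class), `eps80` (the 80th-percentile cutoff).
#' @export
run_ensemble <- function(config = experiment_config(), .progress = FALSE) {
  seeds <- derive_seeds(config$seed, c("networks", "permutations"))
  params <- config_params(config)
  variation <- config_variation(config)
  net_seeds <- withr::with_seed(seeds$networks,
                                sample.int(.Machine$integer.max - 1L,
                                           3L * config$n_networks))
  rows <- vector("list", config$n_networks)
  classes <- vector("list", config$n_networks)
  for (i in seq_len(config$n_networks)) {
    s <- net_seeds[(3L * (i - 1L) + 1L):(3L * i)]
    sel <- select_converging_network(config$n_genes, config$connect_prob,
                                     params, seed = s[1])
    pop <- build_population(sel$network, variation, config$pop_size,
                            sel$initial_state, params, seed = s[2])
    fit <- fit_pgs(pop, cv_folds = 5, seed = s[3])
    sob <- network_sobol(sel$network, variation, sel$initial_state, params,
                         n_sobol = config$n_sobol, seed = s[3])
    stab <- stability_summary(
      jacobian_at_equilibrium(sel$network, sel$trajectory$equilibrium,
                              config$steepness))
    cls <- classify_edges(sob)
    classes[[i]] <- cls
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(network_id = i, r2 = fit$r2, s0_sum = sob$s0_sum,
                     eps_sum = sob$eps_sum,
                     n_zero_eigen = stab$n_zero_eigen,
                     max_modulus = stab$max_modulus),
      complexity_profile(sel$network, sel$trajectory),
      class_ratios(cls))
    if (.progress) {
      cat(sprintf("network %d/%d: R2 %.3f S0 %.3f epsT %.3f\n", i,
                  config$n_networks, fit$r2, sob$s0_sum, sob$eps_sum))
    }
  }
  tbl <- dplyr::bind_rows(rows)
  med <- stats::median(tbl$n_pos_two_cycles)
  tbl$n_pos_two_cycles_norm <- if (med > 0) tbl$n_pos_two_cycles / med else
    NA_real_
  eps80 <- quantile(tbl$eps_sum, 0.8, names = FALSE)
  mask <- tbl$eps_sum > eps80
  perm_seeds <- withr::with_seed(seeds$permutations,
                                 sample.int(.Machine$integer.max - 1L, 4L))
  measures <- c("n_pos_two_cycles", "path_length", "density", "clustering")
  enrich <- dplyr::bind_rows(lapply(seq_along(measures), function(j) {
    dplyr::mutate(
      enrichment_permutation_test(tbl[[measures[j]]], mask,
                                  n_perm = config$n_perm,
                                  seed = perm_seeds[j]),
      measure = measures[j], .before = 1)
  }))
  window <- min(5L, config$n_networks)
  rolling <- tibble::tibble(
    window_index = seq_len(config$n_networks - window + 1L),
    r2 = rolling_window_summary(tbl$r2, tbl$r2, window),
    core_ratio = rolling_window_summary(tbl$core_ratio, tbl$r2, window),
    peripheral_ratio = rolling_window_summary(tbl$peripheral_ratio, tbl$r2,
                                              window),
    remote_ratio = rolling_window_summary(tbl$remote_ratio, tbl$r2, window)
  )
  list(table = tbl, enrichment = enrich, rolling = rolling, eps80 = eps80,
       classifications = classes)
}

#' Variation-regime sweep and cross-condition transfer matrix
#'
#' For one converging network, fits a PGS at every variation level in
#' `config$sd_fractions` and scores each fit on fresh test populations at
#' every level, giving the train-by-test transfer matrix of R^2. Each row
#' is also reported normalised by the training condition's R^2 on its own
#' fresh test population, so the diagonal normalises to 1. Per-level Sobol
#' sums and the cross-regime correlations of the per-edge indices are
#' returned alongside.
#'
#' @param config An [experiment_config()] (needs >= 2 `sd_fractions`).
#' @return List: `per_sd` (tibble: sd, r2, s0_sum, eps_sum), `transfer`
#'   (tibble: train_sd, test_sd, r2, r2_normalized), `sobol_cor_s0`,
#'   `sobol_cor_st` (correlation matrices across regimes), `network`,
#'   `initial_state`.
#' @export
run_variation_sweep <- function(config = experiment_config()) {
  sds <- config$sd_fractions
  if (length(sds) < 2) abort("Need at least 2 `sd_fractions`.")
  seeds <- derive_seeds(config$seed, c("network", "population", "folds",
                                       "sobol", "test_population"))
  params <- config_params(config)
  sel <- select_converging_network(config$n_genes, config$connect_prob,
                                   params, seed = seeds$network)
  pop_seeds <- withr::with_seed(seeds$population,
                                sample.int(.Machine$integer.max - 1L,
                                           length(sds)))
  test_seeds <- withr::with_seed(seeds$test_population,
                                 sample.int(.Machine$integer.max - 1L,
                                            length(sds)))
  sobol_seeds <- withr::with_seed(seeds$sobol,
                                  sample.int(.Machine$integer.max - 1L,
                                             length(sds)))
  fits <- vector("list", length(sds))
  test_pops <- vector("list", length(sds))
  per_sd <- vector("list", length(sds))
  for (j in seq_along(sds)) {
    variation <- config_variation(config, sds[j])
    train_pop <- build_population(sel$network, variation, config$pop_size,
                                  sel$initial_state, params,
                                  seed = pop_seeds[j])
    fits[[j]] <- fit_pgs(train_pop, cv_folds = 5, seed = seeds$folds)
    test_pops[[j]] <- build_population(sel$network, variation,
                                       config$pop_size, sel$initial_state,
                                       params, seed = test_seeds[j])
    sob <- network_sobol(sel$network, variation, sel$initial_state, params,
                         n_sobol = config$n_sobol, seed = sobol_seeds[j])
    per_sd[[j]] <- tibble::tibble(sd = sds[j], r2 = fits[[j]]$r2,
                                  s0_sum = sob$s0_sum,
                                  eps_sum = sob$eps_sum)
    attr(per_sd[[j]], "sobol") <- sob
  }
  sobols <- lapply(per_sd, attr, "sobol")
  transfer <- tidyr::expand_grid(train = seq_along(sds),
                                 test = seq_along(sds)) |>
    dplyr::mutate(
      train_sd = sds[.data$train], test_sd = sds[.data$test],
      r2 = purrr::map2_dbl(.data$train, .data$test, function(a, b) {
        cross_population_r2(fits[[a]], test_pops[[b]])
      })) |>
    dplyr::mutate(
      r2_normalized = .data$r2 /
        .data$r2[.data$train == .data$test][.data$train],
      .by = NULL) |>
    dplyr::select("train_sd", "test_sd", "r2", "r2_normalized")
  cor_of <- function(col) {
    m <- vapply(sobols, function(s) s$indices[[col]],
                numeric(nrow(sobols[[1]]$indices)))
    colnames(m) <- sprintf("sd_%g", sds)
    stats::cor(m, method = "spearman")
  }
  list(per_sd = dplyr::bind_rows(lapply(per_sd, function(x) {
         attr(x, "sobol") <- NULL; x
       })),
       transfer = transfer,
       sobol_cor_s0 = cor_of("s0"), sobol_cor_st = cor_of("st"),
       network = sel$network, initial_state = sel$initial_state)
}
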