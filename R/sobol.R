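#' Saltelli sample matrices over a network's weight space
#'
#' Draws two independent n x k matrices A and B whose column e holds draws
#' of edge e's weight from its population distribution (normal around the
#' reference weight, spread per the [variation_spec()]). Together with the
#' radial matrices C_i they support the Monte-Carlo estimation of Sobol
#' indices. Sampling is plain pseudo-random normal.
#'
#' @param reference A `reference_network` with k >= 1 edges.
#' @param variation A [variation_spec()].
#' @param n_sobol Base sample size n (rows of each matrix; default 50000).
#' @param seed Optional seed.
#' @return List with matrices `A` and `B` (columns named by edge) and the
#'   `edge_index` tibble.
#' @export
saltelli_matrices <- function(reference, variation = variation_spec(),
                              n_sobol = 50000, seed = NULL) {
  reference <- as_reference_network(reference)
  et <- network_edges(reference)
  if (nrow(et) == 0) abort("Reference network has no edges.")
  if (!is_scalar_num(n_sobol) || n_sobol < 100) abort("`n_sobol` must be >= 100.")
  local_seed(seed)
  sds <- edge_sds(et$weight, variation)
  draw <- function() {
    m <- matrix(rnorm(n_sobol * nrow(et),
                      mean = rep(et$weight, each = n_sobol),
                      sd = rep(sds, each = n_sobol)),
                nrow = n_sobol)
    colnames(m) <- et$edge
    m
  }
  list(A = draw(), B = draw(), edge_index = et)
}

#' Radial matrix C_i of the Saltelli scheme
#'
#' All columns of A except column `i`, which is taken from B: rows of C_i
#' differ from rows of A in input `i` only, and share only input `i` with B.
#'
#' @param A,B Conformable sample matrices.
#' @param i Column (edge) index.
#' @return Matrix of the same shape as A.
#' @export
radial_matrix <- function(A, B, i) {
  if (!identical(dim(A), dim(B))) abort("`A` and `B` must have equal shape.")
  if (!is_scalar_num(i) || i < 1 || i > ncol(A)) {
    abort("`i` must be a column index of `A`.")
  }
  C <- A
  C[, i] <- B[, i]
  C
}

#' Sobol indices from model outputs on the A/B/C_i design
#'
#' Estimates, for each input i, the first-order index `S0_i` (the additive
#' share of output variance explained by input i alone) and the total index
#' `ST_i` (variance involving input i in any combination); their difference
#' `eps_i = ST_i - S0_i` is input i's non-additive (epistatic) share.
#'
#' With the C_i convention used here (C_i = A except column i from B) the
#' estimators are `S0_i = mean(y_B * (y_Ci - y_A)) / V` and the Jansen form
#' `ST_i = mean((y_A - y_Ci)^2) / (2 V)`, with the output mean f0 and
#' variance V taken from the pooled y_A, y_B. Negative Monte-Carlo
#' estimates are reported raw, never clipped (clipping biases the sums);
#' per-index standard errors from the sample spread of the estimator terms
#' accompany each index.
#'
#' @param y_A,y_B Model outputs on the rows of A and B (length n).
#' @param y_C n x k matrix, column i = outputs on the rows of C_i.
#' @return A `sobol_result`: tibble-backed list with per-edge `s0`, `st`,
#'   `eps` and standard errors, sums `s0_sum` and `eps_sum`, `output_mean`
#'   (f0), `output_variance` (V), `n`.
#' @export
sobol_indices <- function(y_A, y_B, y_C) {
  y_A <- as.numeric(y_A); y_B <- as.numeric(y_B); y_C <- as.matrix(y_C)
  n <- length(y_A)
  if (length(y_B) != n || nrow(y_C) != n) abort("Output lengths must agree.")
  if (!all(is.finite(y_A), is.finite(y_B), is.finite(y_C))) {
    abort("Model outputs must be finite.")
  }
  pooled <- c(y_A, y_B)
  f0 <- mean(pooled)
  v <- mean(pooled^2) - f0^2
  if (v <= 0) abort("Zero output variance (degenerate input).")
  k <- ncol(y_C)
  # centring by f0 leaves the estimators' expectations unchanged but removes
  # the f0-amplified Monte-Carlo noise when |f0| >> sd(y)
  y_A <- y_A - f0; y_B <- y_B - f0; y_C <- y_C - f0
  first_terms <- y_B * (y_C - y_A)          # n x k
  total_terms <- (y_A - y_C)^2              # n x k
  s0 <- colMeans(first_terms) / v
  st <- colMeans(total_terms) / (2 * v)
  se_s0 <- apply(first_terms, 2, sd) / (v * sqrt(n))
  se_st <- apply(total_terms, 2, sd) / (2 * v * sqrt(n))
  new_sobol_result(
    tibble::tibble(
      edge = colnames(y_C) %||% sprintf("x%d", seq_len(k)),
      s0 = unname(s0), st = unname(st), eps = unname(st - s0),
      se_s0 = unname(se_s0), se_st = unname(se_st)
    ),
    n = n, f0 = f0, v = v
  )
}

new_sobol_result <- function(indices, n, f0, v, replicates = NULL,
                             n_nonconverged = NA_integer_) {
  structure(list(
    indices = indices,
    s0_sum = sum(indices$s0),
    eps_sum = sum(indices$eps),
    output_mean = f0,
    output_variance = v,
    n = n,
    replicates = replicates,
    n_nonconverged = n_nonconverged
  ), class = "sobol_result")
}

#' Global sensitivity analysis of a network's phenotype map
#'
#' Runs the full Saltelli scheme on the phenotype map (edge weights ->
#' fixed-point mean expression from the shared initial state): n rows of A,
#' n of B and n of each C_i are iterated to equilibrium — n(k+2) model
#' evaluations — and [sobol_indices()] is applied. Individuals that fail to
#' converge within the iteration cap contribute their capped state (same
#' policy as [build_population()]) and are counted. With `replicates > 1`
#' the whole scheme is repeated with fresh draws and per-index means and
#' standard deviations across replicates are reported.
#'
#' @inheritParams saltelli_matrices
#' @param initial_state Shared initial expression state.
#' @param params A [sigmoid_params()] list.
#' @param replicates Number of independent repetitions (default 1).
#' @return A `sobol_result` (means across replicates when `replicates > 1`,
#'   with the per-replicate table in `$replicates`).
#' @examples
#' net <- generate_reference_network(6, 0.4, seed = 11)
#' sob <- network_sobol(net, variation_spec(0.1), sample_initial_state(6, seed = 11),
#'                      n_sobol = 500, seed = 11)
#' sob$s0_sum; sob$eps_sum
#' @export
network_sobol <- function(reference, variation = variation_spec(),
                          initial_state, params = sigmoid_params(),
                          n_sobol = 50000, replicates = 1, seed = NULL) {
  reference <- as_reference_network(reference)
  local_seed(seed)
  one_replicate <- function() {
    ab <- saltelli_matrices(reference, variation, n_sobol)
    et <- ab$edge_index
    k <- nrow(et)
    n <- n_sobol
    eval_batch <- function(m) {
      evaluate_genotypes(m, et, nrow(reference), initial_state, params)
    }
    res_A <- eval_batch(ab$A)
    res_B <- eval_batch(ab$B)
    nonconv <- sum(!res_A$converged) + sum(!res_B$converged)
    y_C <- matrix(NA_real_, n, k, dimnames = list(NULL, et$edge))
    for (i in seq_len(k)) {
      res_C <- eval_batch(radial_matrix(ab$A, ab$B, i))
      y_C[, i] <- res_C$phenotype
      nonconv <- nonconv + sum(!res_C$converged)
    }
    out <- sobol_indices(res_A$phenotype, res_B$phenotype, y_C)
    out$n_nonconverged <- nonconv
    out
  }
  if (replicates == 1) return(one_replicate())
  reps <- lapply(seq_len(replicates), function(r) one_replicate())
  rep_tbl <- dplyr::bind_rows(
    lapply(seq_along(reps), function(r) {
      dplyr::mutate(reps[[r]]$indices, replicate = r)
    })
  )
  mean_idx <- rep_tbl |>
    dplyr::summarise(
      se_s0 = sd(.data$s0) / sqrt(replicates),
      se_st = sd(.data$st) / sqrt(replicates),
      s0 = mean(.data$s0), st = mean(.data$st), eps = mean(.data$eps),
      .by = "edge") |>
    dplyr::select("edge", "s0", "st", "eps", "se_s0", "se_st")
  new_sobol_result(
    mean_idx,
    n = n_sobol,
    f0 = mean(vapply(reps, `[[`, numeric(1), "output_mean")),
    v = mean(vapply(reps, `[[`, numeric(1), "output_variance")),
    replicates = rep_tbl,
    n_nonconverged = sum(vapply(reps, `[[`, integer(1), "n_nonconverged"))
  )
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf(
    "<sobol_result> %d inputs, n = %d; additive sum S0 = %.3f; non-additive sum epsT = %.3f\n",
    nrow(x$indices), x$n, x$s0_sum, x$eps_sum))
  invisible(x)
}

#' @describeIn sobol_indices Per-edge index table (`edge`, `s0`, `st`,
#'   `eps`, standard errors).
#' @param x A `sobol_result`.
#' @param ... Unused.
#' @export
tidy.sobol_result <- function(x, ...) x$indices

#' @describeIn sobol_indices One-row summary: `s0_sum`, `eps_sum`,
#'   `output_mean`, `output_variance`, `n`, `n_nonconverged`.
#' @export
glance.sobol_result <- function(x, ...) {
  tibble::tibble(s0_sum = x$s0_sum, eps_sum = x$eps_sum,
                 output_mean = x$output_mean,
                 output_variance = x$output_variance,
                 n = x$n, n_nonconverged = x$n_nonconverged)
}
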