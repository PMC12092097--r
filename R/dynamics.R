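#' Sigmoidal gene-activation function
#'
#' The squashing function of the Wagner-model dynamics,
#' `f(x) = 2 / (1 + exp(-a x)) - 1`, mapping summed regulatory input to an
#' expression level in (-1, 1): -1 is the fully off state, +1 fully on.
#' Computed as `tanh(a x / 2)`, which is the same function and numerically
#' stable for large `|a x|`.
#'
#' @param x Numeric vector of regulatory inputs.
#' @param steepness Sigmoid steepness a > 0; the larger, the closer to a step
#'   function. Default 10.
#' @return Values in (-1, 1); odd and strictly increasing in `x`.
#' @examples
#' sigmoid(0.1, 10)  # 2/(1 + exp(-1)) - 1
#' @export
sigmoid <- function(x, steepness = 10) {
  if (!is_scalar_num(steepness) || steepness <= 0) {
    abort("`steepness` must be a single positive number.")
  }
  tanh(steepness * x / 2)
}

#' @rdname sigmoid
#' @details `sigmoid_deriv()` is the derivative
#'   `f'(x) = (a/2) (1 - f(x)^2)`, used by the Jacobian of the linearised
#'   dynamics; `f'(0) = a/2`.
#' @export
sigmoid_deriv <- function(x, steepness = 10) {
  (steepness / 2) * (1 - sigmoid(x, steepness)^2)
}

#' Dynamics control parameters
#'
#' @param steepness Sigmoid steepness a (default 10).
#' @param max_iter Iteration cap for equilibrium search (default 100).
#' @param conv_tol Convergence tolerance (default 1e-4): with the default
#'   criterion, equilibrium is declared once the sup-norm one-step change
#'   falls to `conv_tol` or below, which bounds the fixed-point residual
#'   `max |g* - f(W g*)|` by `conv_tol` exactly.
#' @param conv_window Trailing window (number of recent steps) over which the
#'   psi convergence score is computed/reported (default 10).
#' @param criterion `"delta"` (default; per-step sup-norm change) or `"psi"`
#'   (trailing-window mean absolute change, the score of [psi_score()]).
#' @return A `sigmoid_params` list.
#' @export
sigmoid_params <- function(steepness = 10, max_iter = 100, conv_tol = 1e-4,
                           conv_window = 10, criterion = c("delta", "psi")) {
  criterion <- match.arg(criterion)
  stopifnot(is_scalar_num(steepness), steepness > 0,
            is_scalar_num(max_iter), max_iter >= 1,
            is_scalar_num(conv_tol), conv_tol > 0,
            is_scalar_num(conv_window), conv_window >= 2)
  structure(list(steepness = steepness, max_iter = as.integer(max_iter),
                 conv_tol = conv_tol, conv_window = as.integer(conv_window),
                 criterion = criterion),
            class = "sigmoid_params")
}

#' Convergence score of a window of expression states
#'
#' Mean absolute componentwise change between consecutive states in the
#' window: zero iff all states in the window coincide. Used as the reported
#' convergence score of a trajectory and, with `criterion = "psi"`, as the
#' equilibrium-detection statistic.
#'
#' @param states Matrix with one row per time point (>= 2 rows), one column
#'   per gene; or a list of state vectors.
#' @return Single non-negative number.
#' @export
psi_score <- function(states) {
  if (is.list(states)) states <- do.call(rbind, states)
  states <- as.matrix(states)
  if (nrow(states) < 2) abort("`states` must contain at least 2 states.")
  mean(abs(diff(states)))
}

#' Iterate the network dynamics to a fixed-point equilibrium
#'
#' Synchronous discrete-time update `g(t+1) = f(W g(t))` with the sigmoid
#' `f`, starting from `initial_state`, until the convergence criterion fires
#' or `max_iter` updates have been performed.
#'
#' With the default `"delta"` criterion, convergence fires at the first
#' update t with `max |g(t) - g(t-1)| <= conv_tol`; the equilibrium is then
#' `g(t-1)`, whose fixed-point residual `max |g* - f(W g*)|` equals that
#' change and is therefore `<= conv_tol` by construction. The path length is
#' t, the iteration at which the criterion fires. If the cap is reached the
#' trajectory is flagged `converged = FALSE` and the final state is reported.
#'
#' @param network `reference_network` or square weight matrix (row = target).
#' @param initial_state Numeric vector of length N with entries in \[-1, 1\].
#' @param params A [sigmoid_params()] list.
#' @return A `trajectory_result`: list with `states` (matrix, one row per
#'   time point including t = 0), `converged`, `path_length`, `equilibrium`,
#'   `psi`, `phenotype` (mean of the equilibrium expression).
#' @examples
#' net <- generate_reference_network(10, 0.3, seed = 4)
#' tr <- iterate_dynamics(net, sample_initial_state(10, seed = 4))
#' tr$converged; tr$path_length; tr$phenotype
#' @export
iterate_dynamics <- function(network, initial_state,
                             params = sigmoid_params()) {
  w <- unclass(as_reference_network(network))
  n <- nrow(w)
  g <- as.numeric(initial_state)
  if (length(g) != n) abort("`initial_state` length must match the network.")
  if (!all(is.finite(g)) || any(abs(g) > 1)) {
    abort("`initial_state` entries must be finite and in [-1, 1].")
  }
  states <- matrix(NA_real_, params$max_iter + 1L, n)
  states[1L, ] <- g
  converged <- FALSE
  path_length <- params$max_iter
  equilibrium <- NULL
  for (t in seq_len(params$max_iter)) {
    g_new <- sigmoid(drop(w %*% g), params$steepness)
    states[t + 1L, ] <- g_new
    hit <- if (params$criterion == "delta") {
      max(abs(g_new - g)) <= params$conv_tol
    } else {
      first <- max(1L, t + 1L - params$conv_window)
      psi_score(states[first:(t + 1L), , drop = FALSE]) <= params$conv_tol
    }
    if (hit) {
      converged <- TRUE
      path_length <- t
      equilibrium <- if (params$criterion == "delta") g else g_new
      states <- states[seq_len(t + 1L), , drop = FALSE]
      break
    }
    g <- g_new
  }
  if (!converged) equilibrium <- states[params$max_iter + 1L, ]
  first <- max(1L, nrow(states) - params$conv_window)
  structure(list(
    states = states,
    converged = converged,
    path_length = path_length,
    equilibrium = equilibrium,
    psi = psi_score(states[first:nrow(states), , drop = FALSE]),
    phenotype = mean(equilibrium)
  ), class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf(
    "<trajectory_result> %s after %d iterations; phenotype %.4f; psi %.2e\n",
    if (x$converged) "converged" else "NOT converged (cap reached)",
    x$path_length, x$phenotype, x$psi))
  invisible(x)
}

#' Export a trajectory as TSV
#'
#' One row per iteration (including the initial state at t = 0), one column
#' per gene.
#'
#' @param trajectory A `trajectory_result`.
#' @param path Output file.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  st <- trajectory$states
  lines <- c(
    paste(c("t", sprintf("g%d", seq_len(ncol(st)))), collapse = "\t"),
    vapply(seq_len(nrow(st)), function(i) {
      paste(c(i - 1L, fmt_num(st[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Rejection-sample a network that reaches a fixed-point equilibrium
#'
#' Draws (network, initial state) pairs until the dynamics converges within
#' `max_iter` iterations, mirroring the selection of fixed-point-attractor
#' networks for the analysis ensembles.
#'
#' @inheritParams generate_reference_network
#' @param params A [sigmoid_params()] list.
#' @param max_attempts Cap on rejection-sampling attempts.
#' @param seed Optional seed.
#' @return List with `network`, `initial_state`, `trajectory` (converged),
#'   and `n_rejected`.
#' @export
select_converging_network <- function(n_genes = 10, connect_prob = 0.3,
                                      params = sigmoid_params(),
                                      max_attempts = 1000, seed = NULL) {
  local_seed(seed)
  for (attempt in seq_len(max_attempts)) {
    net <- generate_reference_network(n_genes, connect_prob)
    g0 <- sample_initial_state(n_genes)
    tr <- iterate_dynamics(net, g0, params)
    if (tr$converged) {
      return(list(network = net, initial_state = g0, trajectory = tr,
                  n_rejected = attempt - 1L))
    }
  }
  abort(sprintf("No converging network found in %d attempts.", max_attempts))
}
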