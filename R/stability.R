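#' Jacobian of the dynamics at an equilibrium
#'
#' Linearises one update step `g -> f(W g)` at the state `g*`:
#' `J[i, j] = f'(h*_i) w[i, j]` with `h*_i = sum_j w[i, j] g*_j` and
#' `f'(x) = (a/2)(1 - f(x)^2)`. At the all-off/neutral state `g* = 0` this
#' reduces to `J = (a/2) W`. Saturated genes (`|h*_i|` large) contribute
#' near-zero rows: perturbations there die immediately.
#'
#' @param network `reference_network` or weight matrix.
#' @param equilibrium State vector `g*` with entries in \[-1, 1\].
#' @param steepness Sigmoid steepness a (default 10).
#' @return N x N Jacobian matrix.
#' @export
jacobian_at_equilibrium <- function(network, equilibrium, steepness = 10) {
  w <- bare_weights(network)
  g <- as.numeric(equilibrium)
  if (length(g) != nrow(w)) abort("`equilibrium` length must match the network.")
  h <- drop(w %*% g)
  sigmoid_deriv(h, steepness) * w
}

#' Eigenvalue diagnostics of a Jacobian
#'
#' Converged Wagner networks typically show a mix of (near-)zero eigenvalues
#' — neutral directions, from saturated genes whose rows vanish — and
#' eigenvalues of modulus below 1 — stable, decaying directions. The count
#' of zeros and the spectral radius summarise where on this spectrum a
#' network sits.
#'
#' @param jacobian Square matrix.
#' @param zero_tol Modulus below which an eigenvalue counts as zero
#'   (default 1e-6).
#' @return List with `eigenvalues` (complex), `n_zero_eigen`, `max_modulus`.
#' @export
stability_summary <- function(jacobian, zero_tol = 1e-6) {
  ev <- eigen(jacobian, only.values = TRUE)$values
  list(eigenvalues = ev,
       n_zero_eigen = sum(Mod(ev) <= zero_tol),
       max_modulus = max(Mod(ev)))
}

#' Local effect score of each regulatory connection
#'
#' The one-step linear response of a target gene to its incoming weight,
#' `s[i, j] = d g_i(t+1) / d w[i, j] = f'(h*_i) g*_j`, evaluated at the
#' equilibrium and masked to the network support. Large `|s|` marks the
#' edges whose perturbation moves expression the most locally — these
#' predict the top polygenic-score effect sizes in near-linear networks.
#'
#' @inheritParams jacobian_at_equilibrium
#' @return List with `edge_scores` (N x N matrix, zero off-support) and
#'   `jg` (the matrix-vector product `J g*`, the per-gene aggregate
#'   response, exposed as the alternative reading of the construct).
#' @export
local_effect_scores <- function(network, equilibrium, steepness = 10) {
  w <- bare_weights(network)
  g <- as.numeric(equilibrium)
  h <- drop(w %*% g)
  s <- outer(sigmoid_deriv(h, steepness), g)
  s[w == 0] <- 0
  list(edge_scores = s,
       jg = drop(jacobian_at_equilibrium(w, g, steepness) %*% g))
}

#' Full local-stability report for a network at its equilibrium
#'
#' @inheritParams jacobian_at_equilibrium
#' @param zero_tol Passed to [stability_summary()].
#' @return A `stability_report`: `jacobian`, `eigenvalues`, `n_zero_eigen`,
#'   `max_modulus`, `edge_scores`. A spectral radius >= 1 at a converged
#'   fixed point triggers a warning (convergence within the iteration cap
#'   does not strictly guarantee linear stability).
#' @export
local_stability <- function(network, equilibrium, steepness = 10,
                            zero_tol = 1e-6) {
  j <- jacobian_at_equilibrium(network, equilibrium, steepness)
  s <- stability_summary(j, zero_tol)
  if (s$max_modulus >= 1) {
    warning("Spectral radius >= 1 at the supplied equilibrium.",
            call. = FALSE)
  }
  structure(c(list(jacobian = j), s,
              local_effect_scores(network, equilibrium, steepness)["edge_scores"]),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> spectral radius %.4f; %d zero eigenvalue(s) of %d\n",
    x$max_modulus, x$n_zero_eigen, length(x$eigenvalues)))
  invisible(x)
}
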