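#' Generate a reference gene regulation network
#'
#' Draws a signed, weighted, directed Erdős–Rényi network on `n_genes` genes:
#' each ordered off-diagonal pair (i, j) carries a regulatory edge
#' independently with probability `connect_prob`, and edge weights are i.i.d.
#' standard normal. Self-loops are excluded, so the diagonal is exactly zero.
#'
#' The weight matrix is stored in "incoming" orientation: row `i` holds the
#' regulations received by gene `i`, so one update step of the dynamics is
#' `g(t+1) = f(W %*% g(t))`. An edge "regulator r -> target t" therefore
#' lives at entry `W[t, r]`.
#'
#' @param n_genes Number of genes N (>= 2). Default 10.
#' @param connect_prob Connection probability c in \[0, 1\]. Each of the
#'   N(N-1) possible directed regulations exists independently with this
#'   probability.
#' @param seed Optional integer seed for reproducibility (RNG state is
#'   restored afterwards).
#' @return A `reference_network` object: the N x N weight matrix with
#'   attributes `n_genes`, `connect_prob`, `seed`.
#' @examples
#' net <- generate_reference_network(10, 0.3, seed = 1)
#' sum(unclass(net) != 0)   # realised number of regulatory connections
#' @export
generate_reference_network <- function(n_genes = 10, connect_prob = 0.3,
                                       seed = NULL) {
  if (!is_scalar_num(n_genes) || n_genes < 2 || n_genes != round(n_genes)) {
    abort("`n_genes` must be a single integer >= 2.")
  }
  stop_if_not_scalar_prob(connect_prob, "connect_prob")
  local_seed(seed)
  n <- as.integer(n_genes)
  w <- matrix(0, n, n)
  off <- which(row(w) != col(w))
  present <- rbinom(length(off), 1L, connect_prob) == 1L
  w[off[present]] <- rnorm(sum(present))
  new_reference_network(w, connect_prob = connect_prob, seed = seed)
}

new_reference_network <- function(weights, connect_prob = NA_real_,
                                  seed = NULL) {
  structure(weights,
            n_genes = nrow(weights),
            connect_prob = connect_prob,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
            class = c("reference_network", "matrix", "array"))
}

#' Coerce a square weight matrix to a reference network
#'
#' Validates shape, finiteness and the zero diagonal, and attaches the
#' `reference_network` class. Use this to analyse externally supplied
#' weight matrices with the rest of the package.
#'
#' @param weights Square numeric matrix with zero diagonal; row i holds the
#'   incoming regulations of gene i.
#' @return A `reference_network`.
#' @export
as_reference_network <- function(weights) {
  if (inherits(weights, "reference_network")) return(weights)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights) || nrow(weights) < 2) {
    abort("`weights` must be a square matrix with at least 2 genes.")
  }
  if (!all(is.finite(weights))) abort("`weights` must be finite.")
  if (any(diag(weights) != 0)) {
    abort("`weights` must have a zero diagonal (no self-loops).")
  }
  new_reference_network(weights)
}

#' @export
print.reference_network <- function(x, ...) {
  cat(sprintf("<reference_network> %d genes, %d regulatory connections\n",
              nrow(x), sum(unclass(x) != 0)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Tabulate the non-zero edges of a network
#'
#' The edge table fixes the column order of every genotype matrix, effect-
#' size vector and Sobol index vector in the package: edges are listed
#' row-major over (target, regulator) of the reference support.
#'
#' @param network A `reference_network` or square weight matrix.
#' @return A tibble with columns `edge` (label "regulator->target"),
#'   `regulator`, `target`, `weight`, in canonical order.
#' @export
network_edges <- function(network) {
  w <- unclass(as_reference_network(network))
  idx <- which(t(w) != 0)  # t(w) column-major == w row-major over (target, regulator)
  n <- nrow(w)
  regulator <- (idx - 1L) %% n + 1L
  target <- (idx - 1L) %/% n + 1L
  tibble::tibble(
    edge = sprintf("w(%d->%d)", regulator, target),
    regulator = regulator,
    target = target,
    weight = w[cbind(target, regulator)]
  )
}

n_edges <- function(network) nrow(network_edges(network))

# Replace the weights at the canonical edge positions of `network` with the
# rows of `edge_weights` (a length-k vector), returning a plain matrix.
matrix_from_edges <- function(network, edge_weights, edge_table = NULL) {
  w <- unclass(as_reference_network(network))
  et <- edge_table %||% network_edges(w)
  if (length(edge_weights) != nrow(et)) abort("edge weight length mismatch.")
  w[cbind(et$target, et$regulator)] <- edge_weights
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write networks as plain-text files
#'
#' Two interchange formats are supported. The dense format is a TSV with a
#' header row and first column of gene labels; the edge-list format has
#' columns `regulator`, `target`, `weight`. Both carry a comment header
#' documenting the orientation convention. Weights round-trip exactly to 17
#' significant digits.
#'
#' @param network A `reference_network` or weight matrix.
#' @param path File path.
#' @return `read_*` return a `reference_network`; `write_*` return `path`
#'   invisibly.
#' @name network_io
NULL

#' @rdname network_io
#' @export
write_network_tsv <- function(network, path) {
  w <- unclass(as_reference_network(network))
  genes <- sprintf("g%d", seq_len(nrow(w)))
  lines <- c(
    "# dense weight matrix; entry (row=target, col=regulator); g(t+1)=f(W g(t))",
    paste(c("gene", genes), collapse = "\t"),
    vapply(seq_len(nrow(w)), function(i) {
      paste(c(genes[i], fmt_num(w[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname network_io
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  dimnames(w) <- NULL
  as_reference_network(w)
}

#' @rdname network_io
#' @export
write_edge_list_tsv <- function(network, path) {
  et <- network_edges(network)
  lines <- c(
    "# edge list; weight acts on the target: g_target(t+1)=f(... + weight*g_regulator(t))",
    "regulator\ttarget\tweight",
    sprintf("%d\t%d\t%s", et$regulator, et$target, fmt_num(et$weight))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname network_io
#' @param n_genes Number of genes (needed for the edge-list format, whose
#'   isolated genes carry no rows).
#' @export
read_edge_list_tsv <- function(path, n_genes) {
  df <- utils::read.delim(path, comment.char = "#")
  w <- matrix(0, n_genes, n_genes)
  w[cbind(df$target, df$regulator)] <- df$weight
  as_reference_network(w)
}
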