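# Internal helpers shared across modules.

# Scoped seeding: set the RNG seed for the caller's frame and restore the
# previous RNG state on exit. seed = NULL leaves the ambient RNG untouched.
local_seed <- function(seed, .env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  withr::local_seed(as.integer(seed), .local_envir = .env)
  invisible(NULL)
}

# Derive named per-stage seeds from one master seed so that changing one
# stage's settings does not shift another stage's draws.
derive_seeds <- function(master_seed, stages) {
  withr::with_seed(as.integer(master_seed), {
    s <- sample.int(.Machine$integer.max - 1L, length(stages))
  })
  stats::setNames(as.list(s), stages)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Validated plain weight matrix: reference_network semantics, no attributes
# beyond dim, so arithmetic on it yields clean matrices.
bare_weights <- function(network) {
  w <- unclass(as_reference_network(network))
  attributes(w) <- list(dim = dim(w))
  w
}

# Format numbers for TSV artifacts: full double precision, round-trip exact.
fmt_num <- function(x) formatC(x, digits = 17, format = "g")
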