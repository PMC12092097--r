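#' Classify regulatory connections as core, peripheral or remote
#'
#' Applies the omnigenic-style rule on the Sobol indices of each edge:
#' *core* edges contribute more than `threshold` of phenotypic variance in
#' total (`st > threshold`) with the additive part dominating
#' (`s0 >= eps`); *peripheral* edges pass the same total-contribution bar
#' but are dominated by non-additive effects (`s0 < eps`); *remote* edges
#' have `st <= threshold`. Ties `s0 == eps` go to core. Negative
#' Monte-Carlo estimates enter the comparisons as-is unless `clamp_eps`
#' floors `eps` at 0.
#'
#' @param sobol A `sobol_result` (or a tibble with columns `edge`, `s0`,
#'   `st`, `eps`).
#' @param threshold Total-index cutoff separating remote edges
#'   (default 0.01, i.e. 1% of phenotypic variance).
#' @param clamp_eps Floor negative `eps` estimates at 0 before comparing
#'   (default FALSE).
#' @return Tibble: `edge`, `s0`, `st`, `eps`, `class` (factor
#'   core/peripheral/remote).
#' @export
classify_edges <- function(sobol, threshold = 0.01, clamp_eps = FALSE) {
  idx <- if (inherits(sobol, "sobol_result")) sobol$indices else
    tibble::as_tibble(sobol)
  eps_cmp <- if (clamp_eps) pmax(idx$eps, 0) else idx$eps
  cls <- dplyr::case_when(
    idx$st <= threshold ~ "remote",
    idx$s0 >= eps_cmp ~ "core",
    .default = "peripheral"
  )
  dplyr::mutate(
    idx[, intersect(c("edge", "s0", "st", "eps"), names(idx))],
    class = factor(cls, levels = c("core", "peripheral", "remote"))
  )
}

#' Share of each connection class
#'
#' @param classification Output of [classify_edges()].
#' @return One-row tibble `core_ratio`, `peripheral_ratio`, `remote_ratio`
#'   summing to 1.
#' @export
class_ratios <- function(classification) {
  tab <- table(classification$class) / nrow(classification)
  tibble::tibble(core_ratio = as.numeric(tab[["core"]]),
                 peripheral_ratio = as.numeric(tab[["peripheral"]]),
                 remote_ratio = as.numeric(tab[["remote"]]))
}

#' Rolling-window means of a per-network measure ordered by prediction
#'
#' Sorts networks by `sort_key` (ascending, typically the PGS R^2) and
#' returns means of `metric` over each contiguous window, the smoothing used
#' to display class ratios and effect sizes as a function of prediction
#' accuracy.
#'
#' @param metric Numeric vector, one value per network.
#' @param sort_key Numeric vector of the same length (sorted ascending).
#' @param window Window size (default 5).
#' @return Numeric vector of length `length(metric) - window + 1`.
#' @export
rolling_window_summary <- function(metric, sort_key, window = 5) {
  n <- length(metric)
  if (length(sort_key) != n) abort("Length mismatch.")
  if (!is_scalar_num(window) || window < 1 || window > n) {
    abort("`window` must be between 1 and the number of networks.")
  }
  m <- metric[order(sort_key)]
  vapply(seq_len(n - window + 1), function(i) mean(m[i:(i + window - 1)]),
         numeric(1))
}

#' Mean absolute PGS effect size per connection class
#'
#' @param classification Output of [classify_edges()].
#' @param fit A `pgs_fit` over the same edge set (matched by edge label).
#' @return Tibble `class`, `n`, `mean_abs_beta` (NA for absent classes, one
#'   row per class always).
#' @export
class_mean_beta <- function(classification, fit) {
  if (!setequal(classification$edge, names(fit$betas))) {
    abort("Classification and fit cover different edge sets.")
  }
  df <- dplyr::mutate(classification,
                      abs_beta = abs(fit$betas[.data$edge]))
  out <- df |>
    dplyr::summarise(n = dplyr::n(),
                     mean_abs_beta = mean(.data$abs_beta),
                     .by = "class")
  all_cls <- tibble::tibble(class = factor(c("core", "peripheral", "remote"),
                                           levels = levels(df$class)))
  dplyr::left_join(all_cls, out, by = "class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}
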