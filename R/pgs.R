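#' Fit an additive polygenic score by LASSO
#'
#' Regresses phenotype on the individual edge weights, `y = G beta + eps`,
#' with L1 shrinkage. The penalty is chosen by k-fold cross-validation over
#' glmnet's logarithmic grid (100 values, smallest = 1e-4 times the
#' null-model penalty) at the plain CV minimum; the final coefficients are
#' refit on all data at that penalty. Predictors are standardised internally
#' for penalty comparability; coefficients are reported on the original
#' weight scale.
#'
#' The reported `r2` is the out-of-fold (cross-validated) R^2 by default —
#' an honest measure of prediction; `r2_insample` is also stored. Fold
#' assignment is seeded and kept in the fit.
#'
#' @param population A `population` (or any list with `genotypes`,
#'   `phenotypes`, `edge_index`).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Optional seed controlling fold assignment.
#' @return A `pgs_fit`: list with `betas` (named, one per edge), `intercept`,
#'   `shrinkage` (selected lambda), `r2` (cross-validated), `r2_insample`,
#'   `edge_index`, `cv_folds`, `foldid`, `fitted` (in-sample predictions).
#' @examples
#' net <- generate_reference_network(10, 0.3, seed = 4)
#' pop <- build_population(net, variation_spec(0.1), pop_size = 500, seed = 4)
#' fit <- fit_pgs(pop, seed = 4)
#' glance(fit)
#' @export
fit_pgs <- function(population, cv_folds = 5, seed = NULL) {
  g <- population$genotypes
  y <- population$phenotypes
  if (nrow(g) <= cv_folds) abort("Population smaller than the fold count.")
  if (var(y) == 0) {
    abort("Phenotype variance is zero: nothing to fit (degenerate input).")
  }
  local_seed(seed)
  foldid <- sample(rep_len(seq_len(cv_folds), nrow(g)))
  cv <- glmnet::cv.glmnet(g, y, alpha = 1, nfolds = cv_folds,
                          foldid = foldid, standardize = TRUE,
                          lambda.min.ratio = 1e-4, nlambda = 100,
                          keep = TRUE)
  lam <- cv$lambda.min
  i_lam <- which(cv$lambda == lam)
  co <- coef(cv$glmnet.fit, s = lam)
  betas <- as.numeric(co)[-1]
  names(betas) <- population$edge_index$edge
  # out-of-fold predictions at the selected penalty (prevalidated array)
  y_oof <- cv$fit.preval[, i_lam]
  fitted <- as.numeric(co)[1] + drop(g %*% betas)
  structure(list(
    betas = betas,
    intercept = as.numeric(co)[1],
    shrinkage = lam,
    r2 = r_squared(y, y_oof),
    r2_insample = r_squared(y, fitted),
    edge_index = population$edge_index,
    cv_folds = cv_folds,
    foldid = foldid,
    fitted = fitted,
    lambda_path = cv$glmnet.fit$lambda,
    nzero_path = cv$nzero
  ), class = "pgs_fit")
}

#' @export
print.pgs_fit <- function(x, ...) {
  cat(sprintf(
    "<pgs_fit> %d edges (%d non-zero beta); lambda %.3g; CV R2 %.3f (in-sample %.3f)\n",
    length(x$betas), sum(x$betas != 0), x$shrinkage, x$r2, x$r2_insample))
  invisible(x)
}

#' @describeIn fit_pgs One row per edge: `edge`, `regulator`, `target`,
#'   `weight` (reference), `beta`, `abs_beta`.
#' @param x A `pgs_fit`.
#' @param ... Unused.
#' @export
tidy.pgs_fit <- function(x, ...) {
  dplyr::mutate(x$edge_index, beta = unname(x$betas),
                abs_beta = abs(unname(x$betas)))
}

#' @describeIn fit_pgs One-row model summary: `r2`, `r2_insample`,
#'   `shrinkage`, `n_nonzero`, `cv_folds`.
#' @export
glance.pgs_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, r2_insample = x$r2_insample,
                 shrinkage = x$shrinkage, n_nonzero = sum(x$betas != 0),
                 cv_folds = x$cv_folds)
}

#' Evaluate a polygenic score on a genotype matrix
#'
#' Linear score: `intercept + G beta`.
#'
#' @param fit A `pgs_fit`.
#' @param genotypes Matrix (individuals x edges) whose columns match the
#'   fit's edge set (checked by name when column names are present).
#' @return Numeric vector of predicted phenotypes.
#' @export
predict_pgs <- function(fit, genotypes) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(fit$betas)) {
    abort("Genotype columns do not match the fitted edge set.")
  }
  if (!is.null(colnames(genotypes)) &&
      !identical(colnames(genotypes), names(fit$betas))) {
    abort("Genotype column names do not match the fitted edge set.")
  }
  fit$intercept + drop(genotypes %*% fit$betas)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the mean of `observed`.
#' Unbounded below: out-of-sample (transfer) predictions can score negative,
#' meaning worse than predicting the observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return Single number, at most 1.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    abort("`observed` and `predicted` must be equal-length, length >= 2.")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) abort("Zero variance in `observed` (degenerate input).")
  1 - sum((observed - predicted)^2) / ss_tot
}
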