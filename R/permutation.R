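# Permutation null construction. Each permutation shuffles the
# subject-to-FSIQ assignment (runs keep their subject's permuted value) and
# reruns the full screen -> select -> fit -> predict pipeline, so screening
# is re-done under every permutation. p-values use the add-one formula
# (1 + #{null >= observed}) / (1 + n_perm): never zero, unbiased.

permute_target <- function(dataset, target = "fsiq") {
  ds <- dataset
  ds$phenotypes[[target]] <- sample(ds$phenotypes[[target]])
  ds
}

new_permutation_null <- function(null_r, observed_r, scheme, seed) {
  # a permuted model that predicts a constant has no association with the
  # target; its null entry counts as r = 0
  degenerate <- !is.finite(null_r)
  null_r[degenerate] <- 0
  p <- (1 + sum(null_r >= observed_r)) / (1 + length(null_r))
  structure(list(null_r = null_r, observed_r = observed_r, p = p,
                 scheme = scheme, seed = seed),
            class = "permutation_null")
}

#' @method print permutation_null
#' @export
print.permutation_null <- function(x, ...) {
  cat("permutation_null (", x$scheme, "): observed r =",
      signif(x$observed_r, 4), ", p =", signif(x$p, 4),
      "over", length(x$null_r), "permutations\n")
  invisible(x)
}

#' Permutation test of cross-validated predictability
#'
#' Repeats the entire nested-CV pipeline with FSIQ labels permuted across
#' subjects (one-sided: large r = better prediction). The observed
#' statistic is the mean CV r of the unpermuted run.
#'
#' @param dataset A [connectome_dataset()].
#' @param n_perm Number of permutations (the study-scale default is 1000;
#'   tests use 99-199).
#' @param seed RNG seed; permutation `i` reruns the pipeline with a seed
#'   derived from it.
#' @param target Phenotype column (default `"fsiq"`).
#' @param ... Passed to [nested_cv()] (rounds, outer_folds, ...).
#' @return A `permutation_null`: `null_r`, `observed_r`, `p`
#'   (add-one formula), `scheme = "cv"`, `seed`.
#' @export
cv_permutation_null <- function(dataset, n_perm = 1000, seed = 1L,
                                target = "fsiq", ...) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  observed <- nested_cv(dataset, seed = seed, target = target, ...)
  null_r <- vapply(seq_len(n_perm), function(i) {
    sub_seed <- (seed + 7919L * i) %% 2147483647L
    set.seed(sub_seed)
    perm_ds <- permute_target(dataset, target)
    cv <- nested_cv(perm_ds, seed = sub_seed, target = target, ...)
    cv$summary$r_mean
  }, numeric(1))
  new_permutation_null(null_r, observed$summary$r_mean, "cv", seed)
}

#' Unified models trained on permuted labels
#'
#' Builds `n_perm` unified models, each by the same CV + averaging
#' procedure on a label-permuted copy of the dataset — the null-model
#' ensemble applied to external cohorts by [external_permutation_test()].
#'
#' @inheritParams cv_permutation_null
#' @return List of `unified_model` objects (empty list for `n_perm = 0`).
#' @export
unified_permutation_models <- function(dataset, n_perm = 1000, seed = 1L,
                                       target = "fsiq", ...) {
  if (n_perm < 0) stop("n_perm must be >= 0")
  lapply(seq_len(n_perm), function(i) {
    sub_seed <- (seed + 7919L * i) %% 2147483647L
    set.seed(sub_seed)
    perm_ds <- permute_target(dataset, target)
    unify(nested_cv(perm_ds, seed = sub_seed, target = target, ...))
  })
}

#' Transfer-significance test on an external cohort
#'
#' Applies each permuted unified model and the real model to an external
#' cohort; the null is the distribution of permuted-model transfer r.
#'
#' @param perm_models List of `unified_model` (from
#'   [unified_permutation_models()]).
#' @param real_model The unified model under test.
#' @param external A [connectome_dataset()] (dimension-compatible).
#' @param target Phenotype column (default `"fsiq"`).
#' @return A `permutation_null` with `scheme = "external"`.
#' @export
external_permutation_test <- function(perm_models, real_model, external,
                                      target = "fsiq") {
  y <- stats::setNames(external$phenotypes[[target]],
                       external$phenotypes$subject_id)
  transfer_r <- function(m) {
    pred <- predict(m, external)
    evaluate(pred, y[names(pred)])$r
  }
  null_r <- vapply(perm_models, transfer_r, numeric(1))
  new_permutation_null(null_r, transfer_r(real_model), "external", NA_integer_)
}
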