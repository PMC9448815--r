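#' Nested run-grouped cross-validation for connectome-based prediction
#'
#' The "standard model" procedure: for each of `rounds` rounds, subjects are
#' partitioned into `outer_folds` folds (both scan runs of a subject travel
#' together). Within each training fold, edges are screened by Pearson
#' correlation with the target across training subjects (run-averaged FC,
#' p < `p_threshold`), the LASSO penalty is chosen by subject-grouped inner
#' cross-validation, and a LASSO model is fitted on the screened edges
#' using the run-level training rows. Held-out runs are predicted and averaged
#' per subject; performance (Pearson r, coefficient of determination R^2)
#' is computed on the pooled per-subject out-of-fold predictions of each
#' round and summarized as mean and SD across rounds.
#'
#' A single seed deterministically drives fold partitions and inner-fold
#' assignments; reruns with the same seed are bit-identical. Folds whose
#' screening retains no edge predict the training mean (with a warning).
#'
#' @param dataset A [connectome_dataset()].
#' @param rounds Number of CV rounds (default 10).
#' @param outer_folds Folds per round (default 5).
#' @param p_threshold Screening threshold (default 0.05).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param target Phenotype column to predict (default `"fsiq"`).
#' @param inner_folds Inner-CV folds for penalty selection (default 5).
#' @param n_lambda,lambda_min_ratio Penalty-grid shape (see [lambda_grid()]).
#' @return A `cv_result`: `fold_models` (rounds x outer_folds models),
#'   `predictions` (rounds x subjects out-of-fold matrix), `pred_mean`
#'   (per-subject mean across rounds), `per_round` (r, R^2, p per round),
#'   `summary` (mean/SD of r and R^2), `assignments` (rounds x subjects
#'   fold ids), plus scheme metadata.
#' @export
nested_cv <- function(dataset, rounds = 10, outer_folds = 5,
                      p_threshold = 0.05, seed = 1L, target = "fsiq",
                      inner_folds = 5, n_lambda = 50,
                      lambda_min_ratio = 1e-3) {
  stopifnot(inherits(dataset, "connectome_dataset"))
  ids <- dataset$phenotypes$subject_id
  y <- dataset$phenotypes[[target]]
  if (is.null(y)) stop("unknown target column: ", target)
  if (any(!is.finite(y))) stop("missing values in target '", target,
                               "'; exclude those subjects first")
  ns <- length(ids)
  if (ns < outer_folds) stop("fewer subjects than outer folds")
  row_sub <- match(dataset$subject_id, ids)
  y_row <- y[row_sub]
  ne <- ncol(dataset$fc)

  set.seed(seed)
  predictions <- matrix(NA_real_, nrow = rounds, ncol = ns,
                        dimnames = list(NULL, ids))
  assignments <- matrix(NA_integer_, nrow = rounds, ncol = ns,
                        dimnames = list(NULL, ids))
  fold_models <- vector("list", rounds * outer_folds)

  for (rd in seq_len(rounds)) {
    perm <- sample(ns)
    fold_of <- integer(ns)
    fold_of[perm] <- rep(seq_len(outer_folds), length.out = ns)
    assignments[rd, ] <- fold_of
    for (f in seq_len(outer_folds)) {
      test_sub <- which(fold_of == f)
      train_rows <- which(!(row_sub %in% test_sub))
      test_rows <- which(row_sub %in% test_sub)
      train_sub_ids <- ids[setdiff(seq_len(ns), test_sub)]
      # inner fold assignment drawn before screening so the RNG stream does
      # not depend on data values
      inner_assign <- sample(rep(seq_len(inner_folds),
                                 length.out = length(train_sub_ids)))
      names(inner_assign) <- train_sub_ids

      # screening is across subjects: run-averaged FC vs per-subject target
      tr_sub <- row_sub[train_rows]
      sfc_tr <- rowsum(dataset$fc[train_rows, , drop = FALSE], group = tr_sub,
                       reorder = TRUE)
      sub_idx <- as.integer(rownames(sfc_tr))
      sfc_tr <- sfc_tr / tabulate(tr_sub, nbins = ns)[sub_idx]
      rownames(sfc_tr) <- ids[sub_idx]
      y_tr_sub <- stats::setNames(y[sub_idx], ids[sub_idx])
      scr <- screen_edges(sfc_tr, y_tr_sub, p_threshold)
      k <- sum(scr$mask)
      w_full <- numeric(ne)
      if (k == 0) {
        warning("round ", rd, " fold ", f,
                ": screening retained no edges; predicting training mean")
        intercept <- mean(y_row[train_rows])
        lambda <- NA_real_
      } else {
        xtr <- dataset$fc[train_rows, scr$mask, drop = FALSE]
        ytr <- y_row[train_rows]
        grid <- lambda_grid(xtr, ytr, n_lambda = n_lambda,
                            min_ratio = lambda_min_ratio)
        sel <- select_lambda(dataset$fc[train_rows, , drop = FALSE], ytr,
                             groups = dataset$subject_id[train_rows],
                             grid = grid, inner_folds = inner_folds,
                             foldid = inner_assign,
                             rescreen = list(fc_subjects = sfc_tr,
                                             y_subjects = y_tr_sub,
                                             p_threshold = p_threshold))
        fit <- fit_lasso(xtr, ytr, sel$lambda)
        w_full[scr$mask] <- fit$weights
        intercept <- fit$intercept
        lambda <- sel$lambda
      }
      pred_rows <- intercept +
        as.numeric(dataset$fc[test_rows, , drop = FALSE] %*% w_full)
      pred_sub <- tapply(pred_rows, row_sub[test_rows], mean)
      predictions[rd, as.integer(names(pred_sub))] <- pred_sub
      fold_models[[(rd - 1) * outer_folds + f]] <-
        list(round = rd, fold = f, mask = scr$mask, weights = w_full,
             intercept = intercept, lambda = lambda)
    }
  }

  per_round <- do.call(rbind, lapply(seq_len(rounds), function(rd) {
    ev <- evaluate(predictions[rd, ], y)
    data.frame(round = rd, r = ev$r, R2 = ev$R2, p = ev$p)
  }))
  structure(
    list(fold_models = fold_models,
         predictions = predictions,
         pred_mean = colMeans(predictions),
         assignments = assignments,
         per_round = per_round,
         summary = list(r_mean = mean(per_round$r), r_sd = stats::sd(per_round$r),
                        R2_mean = mean(per_round$R2), R2_sd = stats::sd(per_round$R2)),
         subjects = ids, y = stats::setNames(y, ids),
         rounds = rounds, outer_folds = outer_folds,
         p_threshold = p_threshold, seed = seed, target = target,
         n_roi = dataset$n_roi),
    class = "cv_result")
}

#' @method print cv_result
#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", x$rounds, "x", x$outer_folds, "CV on",
      length(x$subjects), "subjects; mean r =",
      signif(x$summary$r_mean, 4), "( SD", signif(x$summary$r_sd, 4), ")\n")
  invisible(x)
}

new_unified_model <- function(weights, intercept, selection_frequency,
                              n_roi, provenance = NULL) {
  structure(list(weights = weights, intercept = intercept,
                 selection_frequency = selection_frequency,
                 n_roi = n_roi, provenance = provenance),
            class = "unified_model")
}

#' Build the unified model from a cross-validation result
#'
#' Averages each edge's feature weight across all fold models, counting an
#' edge as zero in folds where the LASSO did not select it, and averages
#' the intercepts. `selection_frequency` records the fraction of fold
#' models in which each edge had a nonzero weight.
#'
#' @param cv A `cv_result`.
#' @return A `unified_model` with `weights`, `intercept`,
#'   `selection_frequency`, `n_roi`, `provenance`.
#' @export
unify <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  models <- cv$fold_models
  if (length(models) < 1) stop("no fold models")
  ne <- length(models[[1]]$weights)
  for (m in models) {
    if (length(m$weights) != ne) stop("inconsistent n_edges across folds")
  }
  wmat <- vapply(models, function(m) m$weights, numeric(ne))
  new_unified_model(
    weights = rowMeans(wmat),
    intercept = mean(vapply(models, function(m) m$intercept, numeric(1))),
    selection_frequency = rowMeans(wmat != 0),
    n_roi = cv$n_roi,
    provenance = list(rounds = cv$rounds, outer_folds = cv$outer_folds,
                      p_threshold = cv$p_threshold, seed = cv$seed,
                      target = cv$target))
}

#' Predict per-subject scores with a unified model
#'
#' Per-run prediction is `intercept + weights . fc_row`; a subject's
#' prediction is the mean over their available runs.
#'
#' @param object A `unified_model`.
#' @param dataset A [connectome_dataset()] with matching edge count.
#' @param ... Unused.
#' @return Named numeric vector of per-subject predictions, aligned with
#'   `dataset$phenotypes`.
#' @export
predict.unified_model <- function(object, dataset, ...) {
  if (ncol(dataset$fc) != length(object$weights)) {
    stop("edge-count mismatch: model has ", length(object$weights),
         ", dataset has ", ncol(dataset$fc))
  }
  per_run <- object$intercept + as.numeric(dataset$fc %*% object$weights)
  ids <- dataset$phenotypes$subject_id
  idx <- match(dataset$subject_id, ids)
  out <- tapply(per_run, idx, mean)
  stats::setNames(as.numeric(out[as.character(seq_along(ids))]), ids)
}

#' Evaluate predictions against observed scores
#'
#' Pearson correlation (two-sided t-based p) and the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` on raw predictions. Constant
#' predictions leave `r` undefined (`NA`) with `status =
#' "constant_predictions"`; `R^2` is still reported.
#'
#' @param pred Per-subject predictions.
#' @param actual Per-subject observed scores.
#' @return List with `r`, `R2`, `p`, `n`, `status`.
#' @export
evaluate <- function(pred, actual) {
  ok <- is.finite(pred) & is.finite(actual)
  pred <- pred[ok]; actual <- actual[ok]
  n <- length(pred)
  if (n < 3) stop("need at least 3 prediction pairs")
  if (stats::sd(actual) == 0) stop("actual scores are constant")
  R2 <- 1 - sum((actual - pred)^2) / sum((actual - mean(actual))^2)
  if (stats::sd(pred) == 0) {
    return(list(r = NA_real_, R2 = R2, p = NA_real_, n = n,
                status = "constant_predictions"))
  }
  r <- stats::cor(pred, actual)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, R2 = R2, p = p, n = n, status = "ok")
}

#' Age-band grouping used for subgroup evaluation
#'
#' Bands: `<9`, `9-12`, `>12` years.
#'
#' @param age Numeric ages in years.
#' @return Factor with levels `"<9"`, `"9-12"`, `">12"`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 9, 12, Inf), labels = c("<9", "9-12", ">12"),
      right = FALSE)
}

#' Evaluate out-of-fold predictions within phenotype subgroups
#'
#' Restricts [evaluate()] to each level of a phenotype column (or to age
#' bands when `grouping = "age_band"`), using the per-subject predictions
#' averaged across CV rounds.
#'
#' @param cv A `cv_result`.
#' @param dataset The dataset the CV was run on.
#' @param grouping Phenotype column name, or `"age_band"`.
#' @param min_n Minimum subjects per group (smaller groups are skipped with
#'   a warning; default 3).
#' @return Data frame with columns `group`, `r`, `R2`, `p`, `n`.
#' @export
evaluate_subgroups <- function(cv, dataset, grouping, min_n = 3) {
  phen <- dataset$phenotypes
  g <- if (grouping == "age_band") age_band(phen$age) else phen[[grouping]]
  if (is.null(g)) stop("unknown grouping column: ", grouping)
  g <- as.character(g)
  stopifnot(identical(phen$subject_id, cv$subjects))
  out <- lapply(unique(g), function(lv) {
    sel <- g == lv
    if (sum(sel) < min_n) {
      warning("group '", lv, "' has fewer than ", min_n, " subjects; skipped")
      return(NULL)
    }
    ev <- evaluate(cv$pred_mean[sel], cv$y[sel])
    data.frame(group = lv, r = ev$r, R2 = ev$R2, p = ev$p, n = ev$n)
  })
  do.call(rbind, out)
}

#' Subset a dataset to a set of subjects
#' @param dataset A [connectome_dataset()].
#' @param subject_ids Subjects to keep.
#' @return A [connectome_dataset()].
#' @export
subset_dataset <- function(dataset, subject_ids) {
  keep_rows <- dataset$subject_id %in% subject_ids
  if (!any(keep_rows)) stop("no rows left after subsetting")
  connectome_dataset(
    dataset$fc[keep_rows, , drop = FALSE],
    dataset$subject_id[keep_rows],
    dataset$run_id[keep_rows],
    dataset$phenotypes[dataset$phenotypes$subject_id %in% subject_ids, ,
                       drop = FALSE],
    n_roi = dataset$n_roi)
}

#' Leave-one-group-out fit and holdout evaluation
#'
#' Runs the full nested CV and unified-model construction on all subjects
#' outside the held-out group (e.g. a study site), then applies the unified
#' model to the held-out subjects — the leave-study-site-out
#' generalizability analysis.
#'
#' @param dataset A [connectome_dataset()].
#' @param grouping Phenotype column (e.g. `"site"`).
#' @param held_out Level of `grouping` to hold out.
#' @param ... Passed to [nested_cv()].
#' @return List with `model` (unified), `cv` (training `cv_result`),
#'   `holdout_pred`, `holdout_eval`.
#' @export
leave_group_out_fit <- function(dataset, grouping, held_out, ...) {
  phen <- dataset$phenotypes
  g <- if (grouping == "age_band") as.character(age_band(phen$age)) else phen[[grouping]]
  if (is.null(g)) stop("unknown grouping column: ", grouping)
  if (!held_out %in% g) stop("held-out value '", held_out, "' not present")
  train_ids <- phen$subject_id[g != held_out]
  test_ids <- phen$subject_id[g == held_out]
  cv <- nested_cv(subset_dataset(dataset, train_ids), ...)
  model <- unify(cv)
  test_ds <- subset_dataset(dataset, test_ids)
  pred <- predict(model, test_ds)
  ev <- evaluate(pred, stats::setNames(test_ds$phenotypes$fsiq,
                                       test_ds$phenotypes$subject_id)[names(pred)])
  list(model = model, cv = cv, holdout_pred = pred, holdout_eval = ev)
}

#' Restrict a unified model to an edge subset
#'
#' Zeroes weights outside the subset and recenters the intercept so the
#' mean in-sample prediction on a reference dataset is unchanged.
#'
#' @param model A `unified_model`.
#' @param edge_subset 0-based edge ids to keep.
#' @param reference A [connectome_dataset()] used for recentering.
#' @return A `unified_model`.
#' @export
restrict_model <- function(model, edge_subset, reference) {
  ne <- length(model$weights)
  if (length(edge_subset) && (min(edge_subset) < 0 || max(edge_subset) >= ne)) {
    stop("edge subset out of range")
  }
  if (!length(edge_subset)) {
    warning("empty edge subset: model becomes constant")
  }
  w <- numeric(ne)
  w[edge_subset + 1L] <- model$weights[edge_subset + 1L]
  sfc <- subject_fc(reference)
  removed_mean <- mean(sfc %*% (model$weights - w))
  new_unified_model(
    weights = w,
    intercept = model$intercept + removed_mean,
    selection_frequency = model$selection_frequency,
    n_roi = model$n_roi,
    provenance = c(model$provenance, list(restricted_to = length(edge_subset))))
}
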