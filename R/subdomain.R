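#' Partition edges into IQ-correlated and IQ-uncorrelated sets
#'
#' Ranks edges by absolute unified weight (descending; ties broken by edge
#' id ascending) and takes the top `k` as the "IQ-correlated" set; the rest
#' form the uncorrelated complement used by the controlled permutation.
#'
#' @param model A `unified_model`.
#' @param k Size of the correlated set (default 500).
#' @return An `edge_set_partition`: list with 0-based `correlated` and
#'   `uncorrelated` edge ids and `k`.
#' @export
top_k_edges <- function(model, k = 500) {
  ne <- length(model$weights)
  if (k <= 0) stop("k must be positive")
  if (k > ne) stop("k exceeds the number of edges (", ne, ")")
  ord <- order(-abs(model$weights), seq_len(ne))
  correlated <- sort(ord[seq_len(k)]) - 1L
  structure(list(correlated = correlated,
                 uncorrelated = setdiff(seq_len(ne) - 1L, correlated),
                 k = as.integer(k)),
            class = "edge_set_partition")
}

# least squares with min-norm fallback for rank-deficient designs
ls_solve <- function(x, y) {
  qrx <- qr(x)
  rank_def <- qrx$rank < ncol(x)
  if (!rank_def) {
    list(coef = qr.coef(qrx, y), rank_deficient = FALSE)
  } else {
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * 1e-12
    coef <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], y) / sv$d[pos])
    list(coef = as.numeric(coef), rank_deficient = TRUE)
  }
}

#' Multiple linear regression of a cognitive score on an edge set
#'
#' In-sample least squares of the target on the given per-subject features
#' (with intercept), reporting the true-fitted Pearson correlation. A
#' rank-deficient design falls back to the minimum-norm solution with a
#' flag.
#'
#' @param features Subjects x k numeric matrix (e.g. run-averaged FC for an
#'   edge subset, or ROI scores).
#' @param target Per-subject score.
#' @param label Optional label for the target.
#' @return A `subdomain_fit`: `weights` (k), `intercept`, `fitted`, `r`
#'   (true-fitted Pearson), `R2`, `rank_deficient`, `label`.
#' @export
mlr_fit <- function(features, target, label = NULL) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 2) stop("need more than 1 subject")
  if (stats::sd(target) == 0) stop("constant target")
  sol <- ls_solve(cbind(`(Intercept)` = 1, x), target)
  if (sol$rank_deficient) {
    message("rank-deficient MLR design; minimum-norm solution used")
  }
  coef <- sol$coef
  fitted <- as.numeric(cbind(1, x) %*% coef)
  R2 <- 1 - sum((target - fitted)^2) / sum((target - mean(target))^2)
  r <- if (stats::sd(fitted) == 0) NA_real_ else stats::cor(target, fitted)
  structure(list(weights = coef[-1], intercept = coef[1], fitted = fitted,
                 r = r, R2 = R2, rank_deficient = sol$rank_deficient,
                 label = label),
            class = "subdomain_fit")
}

#' Subdomain regressions on the IQ-correlated edge set
#'
#' Fits [mlr_fit()] for FSIQ and the five subdomain indices on the
#' correlated edges of a partition (per-subject FC = mean over runs).
#'
#' @param dataset A [connectome_dataset()].
#' @param partition An `edge_set_partition`.
#' @param targets Phenotype columns (default FSIQ + five subdomains).
#' @return Named list of `subdomain_fit` objects.
#' @export
subdomain_fits <- function(dataset, partition,
                           targets = c("fsiq", "wmi", "fri", "vci", "vsi", "psi")) {
  sfc <- subject_fc(dataset)[, partition$correlated + 1L, drop = FALSE]
  stats::setNames(lapply(targets, function(tg) {
    mlr_fit(sfc, dataset$phenotypes[[tg]], label = tg)
  }), targets)
}

#' Controlled permutation test against random uncorrelated edge sets
#'
#' Each trial draws `k` edges (without replacement) from the uncorrelated
#' complement, fits the same MLR, and records the true-fitted r; the
#' observed statistic is the correlated-set r. p uses the add-one formula.
#'
#' @param dataset A [connectome_dataset()].
#' @param partition An `edge_set_partition`.
#' @param target Phenotype column.
#' @param n_trials Number of random draws (study-scale default 1000).
#' @param seed RNG seed.
#' @return List with `observed_r`, `null_r` (length `n_trials`), `p`.
#' @export
controlled_permutation <- function(dataset, partition, target,
                                   n_trials = 1000, seed = 1L) {
  k <- partition$k
  if (length(partition$uncorrelated) < k) {
    stop("uncorrelated pool smaller than k")
  }
  sfc <- subject_fc(dataset)
  y <- dataset$phenotypes[[target]]
  observed <- mlr_fit(sfc[, partition$correlated + 1L, drop = FALSE], y)$r
  set.seed(seed)
  null_r <- vapply(seq_len(n_trials), function(i) {
    pick <- sample(partition$uncorrelated, k)
    mlr_fit(sfc[, pick + 1L, drop = FALSE], y)$r
  }, numeric(1))
  list(observed_r = observed, null_r = null_r,
       p = (1 + sum(null_r >= observed)) / (1 + n_trials))
}

#' Pattern similarity between subdomain weight vectors
#'
#' Scales each fit's weight vector to unit Euclidean length and returns the
#' matrix of inner products (diagonal 1).
#'
#' @param fits List of `subdomain_fit` sharing one edge set.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
pattern_similarity <- function(fits) {
  k <- length(fits[[1]]$weights)
  w <- vapply(fits, function(f) {
    if (length(f$weights) != k) stop("fits use different edge sets")
    nrm <- sqrt(sum(f$weights^2))
    if (nrm == 0) stop("zero weight vector")
    f$weights / nrm
  }, numeric(k))
  s <- crossprod(w)
  diag(s) <- 1
  dimnames(s) <- list(names(fits), names(fits))
  s
}

#' Per-subject ROI scores from a unified model
#'
#' ROI score of subject i at ROI R = sum over scope edges incident to R of
#' (unified weight x subject's FC value). This subject-varying construction
#' is what makes an across-subject "ROI importance" regression possible.
#'
#' @param dataset A [connectome_dataset()].
#' @param model A `unified_model`.
#' @param scope_edges 0-based edge ids to include.
#' @return Subjects x n_roi numeric matrix.
#' @export
roi_scores <- function(dataset, model, scope_edges) {
  n_roi <- dataset$n_roi
  sfc <- subject_fc(dataset)
  ids <- as.integer(scope_edges) + 1L
  ep <- edge_endpoints(n_roi)[ids, , drop = FALSE]
  w <- model$weights[ids]
  scores <- matrix(0, nrow = nrow(sfc), ncol = n_roi)
  contrib <- sweep(sfc[, ids, drop = FALSE], 2, w, "*")
  for (side in 1:2) {
    agg <- rowsum(t(contrib), group = ep[, side], reorder = TRUE)
    roi_idx <- as.integer(rownames(agg)) + 1L
    scores[, roi_idx] <- scores[, roi_idx] + t(agg)
  }
  rownames(scores) <- rownames(sfc)
  scores
}

#' ROI-level regression of a cognitive score
#'
#' Regresses the target on per-subject ROI scores ([roi_scores()]) built
#' from either the IQ-correlated edge set or the full connectome, so the
#' correlated-vs-full contrast can be tested with [fisher_z_compare()].
#' Constant (all-zero) ROI columns are dropped before fitting.
#'
#' @param dataset A [connectome_dataset()].
#' @param model A `unified_model`.
#' @param partition An `edge_set_partition`.
#' @param scope `"correlated"` or `"full"`.
#' @param target Phenotype column.
#' @return A `subdomain_fit` over ROI regressors (attribute `scope`).
#' @export
roi_level_regression <- function(dataset, model, partition,
                                 scope = c("correlated", "full"), target) {
  scope <- match.arg(scope)
  edges <- if (scope == "correlated") partition$correlated else {
    seq_len(length(model$weights)) - 1L
  }
  scores <- roi_scores(dataset, model, edges)
  keep <- apply(scores, 2, stats::sd) > 0
  if (!any(keep)) stop("all ROI scores are constant; nothing to regress")
  fit <- mlr_fit(scores[, keep, drop = FALSE], dataset$phenotypes[[target]],
                 label = target)
  attr(fit, "scope") <- scope
  attr(fit, "rois_used") <- which(keep) - 1L
  fit
}
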