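#' Edge-wise importance of the prediction model
#'
#' The signed mean of each edge's feature weight across all fold models
#' (edges unselected in a fold count as zero) — identical to the unified
#' model's weight vector.
#'
#' @param cv A `cv_result`.
#' @return Numeric vector over edges.
#' @export
edge_importance <- function(cv) {
  unify(cv)$weights
}

#' ROI-level importance
#'
#' Aggregates absolute feature weights over the edges incident to each ROI,
#' optionally restricted to an edge subset. Both aggregations used for
#' importance displays are exposed: the mean (`mean_abs`) and the sum
#' (`sum_abs`) of `|w|` over incident edges.
#'
#' @param weights Length-n_edges weight vector.
#' @param n_roi Number of ROIs.
#' @param edge_subset Optional 0-based edge ids to restrict to (default:
#'   all edges).
#' @param aggregation `"mean_abs"` or `"sum_abs"`.
#' @return Numeric vector of length `n_roi`; ROIs with no incident edge in
#'   the subset get 0 (with attribute `no_edges` listing them).
#' @export
roi_importance <- function(weights, n_roi, edge_subset = NULL,
                           aggregation = c("mean_abs", "sum_abs")) {
  aggregation <- match.arg(aggregation)
  ne <- n_edges_for(n_roi)
  stopifnot(length(weights) == ne)
  ids <- if (is.null(edge_subset)) seq_len(ne) else as.integer(edge_subset) + 1L
  ep <- edge_endpoints(n_roi)[ids, , drop = FALSE]
  aw <- abs(weights[ids])
  inc <- c(ep[, 1], ep[, 2]) + 1L
  sums <- unname(vapply(split(rep(aw, 2), factor(inc, levels = seq_len(n_roi))),
                        sum, numeric(1)))
  counts <- tabulate(inc, nbins = n_roi)
  out <- if (aggregation == "sum_abs") sums else sums / pmax(counts, 1)
  empty <- which(counts == 0) - 1L
  if (length(empty)) attr(out, "no_edges") <- empty
  out
}

#' Network-by-network importance matrix
#'
#' Entry (A, B) is the mean absolute feature weight over edges with one
#' endpoint in network A and the other in network B (diagonal: edges within
#' the network). Symmetric by construction.
#'
#' @param weights Length-n_edges weight vector.
#' @param networks A [network_map()].
#' @return 7 x 7 symmetric matrix (dimnames = network labels); blocks with
#'   no edges (a network with < 2 ROIs on the diagonal) are `NA` and listed
#'   in attribute `undefined`.
#' @export
network_importance <- function(weights, networks) {
  n_roi <- length(networks)
  ne <- n_edges_for(n_roi)
  stopifnot(length(weights) == ne)
  ep <- edge_endpoints(n_roi)
  la <- unclass(networks)[ep[, 1] + 1L]
  lb <- unclass(networks)[ep[, 2] + 1L]
  # unordered block label
  blk_a <- pmin(match(la, NETWORK_LABELS), match(lb, NETWORK_LABELS))
  blk_b <- pmax(match(la, NETWORK_LABELS), match(lb, NETWORK_LABELS))
  key <- (blk_a - 1L) * 7L + blk_b
  aw <- abs(weights)
  m <- matrix(NA_real_, 7, 7, dimnames = list(NETWORK_LABELS, NETWORK_LABELS))
  sums <- tapply(aw, key, sum)
  cnts <- tapply(aw, key, length)
  for (k in names(sums)) {
    kk <- as.integer(k)
    i <- (kk - 1L) %/% 7L + 1L
    j <- (kk - 1L) %% 7L + 1L
    m[i, j] <- m[j, i] <- sums[[k]] / cnts[[k]]
  }
  und <- which(is.na(m), arr.ind = TRUE)
  if (nrow(und)) attr(m, "undefined") <- und
  m
}

#' Leave-one-network-out predictability drop
#'
#' In every fold model, zeroes all weights on edges incident to any ROI of
#' the given network, regenerates the out-of-fold per-subject predictions,
#' and evaluates overall and per group. The drop is `delta_r = r_standard -
#' r_removed`, with `r_standard` recomputed on exactly the same per-subject
#' prediction set (paired design).
#'
#' @param cv A `cv_result`.
#' @param dataset The dataset the CV was run on.
#' @param network Network label to remove.
#' @param networks A [network_map()].
#' @param grouping Optional phenotype column (or `"age_band"`) for
#'   per-group rows; overall row always included as group `"all"`.
#' @return Data frame with columns `network`, `group`, `n`, `r_standard`,
#'   `r_removed`, `delta_r`.
#' @export
leave_network_out <- function(cv, dataset, network, networks,
                              grouping = NULL) {
  if (!network %in% NETWORK_LABELS) stop("unknown network: ", network)
  rois <- network_rois(networks, network)
  drop_edges <- edges_incident(rois, length(networks)) + 1L
  pred_removed <- regenerate_predictions(cv, dataset, zero_edges = drop_edges)
  pred_standard <- cv$pred_mean
  y <- cv$y
  groups <- list(all = rep(TRUE, length(y)))
  if (!is.null(grouping)) {
    phen <- dataset$phenotypes
    gv <- if (grouping == "age_band") as.character(age_band(phen$age)) else phen[[grouping]]
    for (lv in unique(gv)) groups[[lv]] <- gv == lv
  }
  out <- lapply(names(groups), function(gn) {
    sel <- groups[[gn]]
    if (sum(sel) < 4) return(NULL)  # Fisher z needs n > 3 downstream
    ev_std <- evaluate(pred_standard[sel], y[sel])
    ev_rm <- evaluate(pred_removed[sel], y[sel])
    data.frame(network = network, group = gn, n = sum(sel),
               r_standard = ev_std$r, r_removed = ev_rm$r,
               delta_r = ev_std$r - ev_rm$r)
  })
  do.call(rbind, out)
}

# Recompute per-subject out-of-fold predictions from stored fold models,
# optionally zeroing a set of edge columns (1-based) in every model.
regenerate_predictions <- function(cv, dataset, zero_edges = integer(0)) {
  ids <- cv$subjects
  stopifnot(identical(dataset$phenotypes$subject_id, ids))
  row_sub <- match(dataset$subject_id, ids)
  preds <- matrix(NA_real_, nrow = cv$rounds, ncol = length(ids),
                  dimnames = list(NULL, ids))
  for (m in cv$fold_models) {
    test_sub <- which(cv$assignments[m$round, ] == m$fold)
    test_rows <- which(row_sub %in% test_sub)
    w <- m$weights
    if (length(zero_edges)) w[zero_edges] <- 0
    pr <- m$intercept + as.numeric(dataset$fc[test_rows, , drop = FALSE] %*% w)
    ps <- tapply(pr, row_sub[test_rows], mean)
    preds[m$round, as.integer(names(ps))] <- ps
  }
  colMeans(preds)
}

#' Full leave-one-network-out report with Fisher z tests and FDR control
#'
#' Runs [leave_network_out()] for all seven networks, tests each
#' standard-vs-removed correlation pair with [fisher_z_compare()] and
#' adjusts p-values across the seven networks within each group by
#' Benjamini-Hochberg.
#'
#' @inheritParams leave_network_out
#' @return Data frame with columns of [leave_network_out()] plus
#'   `fisher_z`, `p`, `p_fdr`.
#' @export
leave_network_out_report <- function(cv, dataset, networks, grouping = NULL) {
  tab <- do.call(rbind, lapply(NETWORK_LABELS, function(nw) {
    leave_network_out(cv, dataset, nw, networks, grouping)
  }))
  tab$fisher_z <- NA_real_
  tab$p <- NA_real_
  for (i in seq_len(nrow(tab))) {
    if (!is.finite(tab$r_standard[i]) || !is.finite(tab$r_removed[i]) ||
        max(abs(c(tab$r_standard[i], tab$r_removed[i]))) >= 1 ||
        tab$n[i] <= 3) next
    fz <- fisher_z_compare(tab$r_standard[i], tab$n[i],
                           tab$r_removed[i], tab$n[i])
    tab$fisher_z[i] <- fz$z
    tab$p[i] <- fz$p
  }
  tab$p_fdr <- NA_real_
  for (gn in unique(tab$group)) {
    sel <- tab$group == gn & is.finite(tab$p)
    if (any(sel)) tab$p_fdr[sel] <- bh_fdr(tab$p[sel])
  }
  tab
}

#' Fisher r-to-z comparison of two correlations
#'
#' Independent-samples form: `z = (atanh(r1) - atanh(r2)) /
#' sqrt(1/(n1-3) + 1/(n2-3))`, two-sided normal p. Note the compared CV
#' correlations share subjects; the dependent-correlation (Steiger) variant
#' is not implemented — this is the plain two-sample form.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, each > 3.
#' @return List with `z` and two-sided `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) stop("|r| must be < 1")
  if (any(c(n1, n2) <= 3)) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, <= 1).
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
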