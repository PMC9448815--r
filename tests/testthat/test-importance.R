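test_that("roi_importance handles uniform, incident and hand-worked cases", {
  n_roi <- 6
  ne <- n_edges_for(n_roi)
  w <- rep(-0.3, ne)
  expect_equal(roi_importance(w, n_roi, aggregation = "mean_abs"),
               rep(0.3, n_roi))
  expect_equal(roi_importance(w, n_roi, aggregation = "sum_abs"),
               rep((n_roi - 1) * 0.3, n_roi))
  # single nonzero edge touches exactly its two endpoints
  w2 <- numeric(ne)
  w2[edge_id(1, 4, n_roi) + 1L] <- 0.7
  ri <- roi_importance(w2, n_roi, aggregation = "sum_abs")
  expect_equal(ri, c(0, 0.7, 0, 0, 0.7, 0))
})

test_that("a 4-ROI toy matches hand-summed per-ROI importances", {
  # edges in order: (0,1) (0,2) (0,3) (1,2) (1,3) (2,3)
  w <- c(0.1, -0.2, 0.3, 0.4, -0.5, 0.6)
  ri <- roi_importance(w, 4, aggregation = "sum_abs")
  expect_equal(ri, c(0.1 + 0.2 + 0.3,
                     0.1 + 0.4 + 0.5,
                     0.2 + 0.4 + 0.6,
                     0.3 + 0.5 + 0.6))
  # subsetting to two edges leaves the others out
  sub <- c(edge_id(0, 1, 4), edge_id(2, 3, 4))
  ri_sub <- roi_importance(w, 4, edge_subset = sub, aggregation = "sum_abs")
  expect_equal(as.numeric(ri_sub), c(0.1, 0.1, 0.6, 0.6))
})

test_that("summed ROI importance double-counts each edge exactly once per end", {
  set.seed(51)
  n_roi <- 9
  w <- rnorm(n_edges_for(n_roi))
  expect_equal(sum(roi_importance(w, n_roi, aggregation = "sum_abs")),
               2 * sum(abs(w)))
})

test_that("network importance partitions edges into blocks correctly", {
  labels <- rep(c("Visual", "Motor", "DAN"), each = 2)
  nm <- network_map(labels)
  ne <- n_edges_for(6)
  # uniform |w| gives a constant matrix on defined blocks
  m_unif <- network_importance(rep(0.2, ne), nm)
  expect_equal(unique(as.vector(m_unif[1:3, 1:3])), 0.2)
  expect_true(all(is.na(m_unif["DMN", ])))
  # hand enumeration: within-Visual edge (0,1); Visual-Motor edges
  # (0,2) (0,3) (1,2) (1,3)
  w <- numeric(ne)
  w[edge_id(0, 1, 6) + 1L] <- 0.5
  w[edge_id(0, 2, 6) + 1L] <- 0.1
  w[edge_id(1, 3, 6) + 1L] <- 0.3
  m <- network_importance(w, nm)
  expect_equal(m["Visual", "Visual"], 0.5)
  expect_equal(m["Visual", "Motor"], (0.1 + 0.3 + 0 + 0) / 4)
  expect_equal(m["Motor", "Visual"], m["Visual", "Motor"])
  expect_equal(m["DAN", "DAN"], 0)
})

test_that("block means recombine to the global mean absolute weight", {
  set.seed(52)
  labels <- rep(c("Visual", "Motor", "DAN", "DMN"), times = c(3, 2, 2, 3))
  nm <- network_map(labels)
  ne <- n_edges_for(10)
  w <- rnorm(ne)
  m <- network_importance(w, nm)
  ep <- cpmiq:::edge_endpoints(10)
  la <- labels[ep[, 1] + 1L]; lb <- labels[ep[, 2] + 1L]
  total <- 0
  for (a in unique(labels)) for (b in unique(labels)) {
    if (match(a, unique(labels)) > match(b, unique(labels))) next
    cnt <- sum((la == a & lb == b) | (la == b & lb == a))
    if (cnt > 0) total <- total + m[a, b] * cnt
  }
  expect_equal(total / ne, mean(abs(w)))
})

test_that("removing a zero-weight network leaves predictability unchanged", {
  sim <- simulate_cohort(tiny_config(n_subjects = 40,
                                     true_edge_network = "DMN",
                                     n_true_edges = 3,
                                     effect_scale = 0.25), seed = 53)
  cv <- nested_cv(sim$dataset, rounds = 1, outer_folds = 5, seed = 14)
  # zero every weight incident to the Limbic network by hand, then ask for
  # its removal: delta r must be exactly 0
  limbic_edges <- cpmiq:::edges_incident(network_rois(sim$networks, "Limbic"),
                                         20) + 1L
  cv0 <- cv
  cv0$fold_models <- lapply(cv$fold_models, function(fm) {
    fm$weights[limbic_edges] <- 0
    fm
  })
  cv0$pred_mean <- cpmiq:::regenerate_predictions(cv0, sim$dataset)
  tab <- leave_network_out(cv0, sim$dataset, "Limbic", sim$networks)
  expect_equal(tab$delta_r[tab$group == "all"], 0, tolerance = 1e-14)
  expect_error(leave_network_out(cv, sim$dataset, "Cortex", sim$networks),
               "unknown network")
})

test_that("every edge is removed by at least one network removal", {
  labels <- rep(NETWORK_LABELS, times = c(3, 3, 3, 3, 2, 3, 3))
  covered <- logical(n_edges_for(20))
  for (nw in NETWORK_LABELS) {
    rois <- which(labels == nw) - 1L
    covered[cpmiq:::edges_incident(rois, 20) + 1L] <- TRUE
  }
  expect_true(all(covered))
})

test_that("fisher_z_compare matches the textbook formula", {
  # worked example: r1 = 0.63 (n = 45) vs r2 = 0.70 (n = 35)
  z_hand <- (atanh(0.63) - atanh(0.70)) / sqrt(1 / 42 + 1 / 32)
  fz <- fisher_z_compare(0.63, 45, 0.70, 35)
  expect_equal(fz$z, z_hand, tolerance = 1e-6)
  expect_equal(fz$p, 2 * pnorm(abs(z_hand), lower.tail = FALSE),
               tolerance = 1e-6)
  # equality gives z = 0, p = 1; swapping negates z, keeps p
  eq <- fisher_z_compare(0.4, 50, 0.4, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  ab <- fisher_z_compare(0.8, 30, 0.2, 40)
  ba <- fisher_z_compare(0.2, 40, 0.8, 30)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_error(fisher_z_compare(1, 30, 0.5, 30), "< 1")
  expect_error(fisher_z_compare(0.5, 3, 0.5, 30), "exceed 3")
})

test_that("the one-vs-two-run comparison inputs evaluate under the formula", {
  # independent-samples form at the study's sample size
  fz <- fisher_z_compare(0.5573, 1721, 0.4847, 1721)
  z_hand <- (atanh(0.5573) - atanh(0.4847)) / sqrt(2 / (1721 - 3))
  expect_equal(fz$z, z_hand, tolerance = 1e-10)
})

test_that("bh_fdr reproduces the step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  # hand-applied step-up: min over j >= i of p_(j) * m / j
  m <- length(p)
  hand <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(bh_fdr(p), pmin(hand, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
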