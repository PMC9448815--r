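test_that("top_k_edges partitions the edge set with deterministic ties", {
  ne <- n_edges_for(10)
  w <- numeric(ne)
  w[c(5, 20, 31)] <- c(0.4, -0.9, 0.4)
  model <- cpmiq:::new_unified_model(w, 100, numeric(ne), 10)
  part <- top_k_edges(model, k = 3)
  expect_setequal(part$correlated, c(4L, 19L, 30L))
  expect_identical(length(intersect(part$correlated, part$uncorrelated)), 0L)
  expect_setequal(c(part$correlated, part$uncorrelated), seq_len(ne) - 1L)
  # ties broken by ascending edge id
  w2 <- rep(1, ne)
  model2 <- cpmiq:::new_unified_model(w2, 100, numeric(ne), 10)
  expect_identical(top_k_edges(model2, k = 4)$correlated, 0:3)
  # k = n_edges empties the complement
  expect_identical(top_k_edges(model, k = ne)$uncorrelated, integer(0))
  expect_error(top_k_edges(model, k = 0), "positive")
  expect_error(top_k_edges(model, k = ne + 1), "exceeds")
})

test_that("mlr_fit solves the normal equations and reports true-fitted r", {
  # 3 subjects, 2 edges + intercept: exact interpolation
  x <- rbind(c(1, 0), c(0, 1), c(1, 1))
  y <- c(3, 5, 7)
  fit <- mlr_fit(x, y)
  hand <- solve(cbind(1, x), y)
  expect_equal(unname(c(fit$intercept, fit$weights)), unname(hand),
               tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  # single proportional edge
  x1 <- matrix(c(1, 2, 3, 4), 4, 1)
  fit1 <- mlr_fit(x1, 10 + 2 * x1[, 1])
  expect_equal(fit1$r, 1, tolerance = 1e-12)
  expect_error(mlr_fit(x1, rep(5, 4)), "constant target")
})

test_that("true-fitted r equals the square root of in-sample R^2", {
  set.seed(61)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 6), 40, 6)
    y <- rnorm(40, 100, 15)
    fit <- mlr_fit(x, y)
    expect_equal(fit$r, sqrt(fit$R2), tolerance = 1e-10)
  }
})

test_that("null-model in-sample R^2 inflates like k/(n-1)", {
  set.seed(62)
  k <- 5; n <- 40
  R2s <- replicate(40, mlr_fit(matrix(rnorm(n * k), n, k), rnorm(n))$R2)
  expect_lt(abs(mean(R2s) - k / (n - 1)), 0.05)
})

test_that("rank-deficient designs fall back to minimum norm with a flag", {
  x <- cbind(1:5, (1:5) * 2)  # collinear
  expect_message(fit <- mlr_fit(x, rnorm(5)), "rank-deficient")
  expect_true(fit$rank_deficient)
  expect_true(all(is.finite(fit$weights)))
})

test_that("controlled permutation separates planted signal from random sets", {
  cfg <- tiny_config(n_subjects = 60, effect_scale = 0.25)
  sim <- simulate_cohort(cfg, seed = 63)
  cv <- nested_cv(sim$dataset, rounds = 1, outer_folds = 5, seed = 15)
  model <- unify(cv)
  part <- top_k_edges(model, k = 30)
  ctrl <- controlled_permutation(sim$dataset, part, "fsiq",
                                 n_trials = 19, seed = 16)
  expect_equal(ctrl$p, 1 / 20)
  expect_gt(ctrl$observed_r, max(ctrl$null_r))
  one <- controlled_permutation(sim$dataset, part, "fsiq",
                                n_trials = 1, seed = 17)
  expect_true(one$p %in% c(1 / 2, 1))
  # k larger than the uncorrelated pool is impossible
  big <- top_k_edges(model, k = n_edges_for(20) - 5)
  expect_error(controlled_permutation(sim$dataset, big, "fsiq",
                                      n_trials = 2, seed = 1),
               "pool smaller")
})

test_that("pattern similarity is a unit-diagonal inner-product matrix", {
  fits <- list(
    a = structure(list(weights = c(1, 0, 0)), class = "subdomain_fit"),
    b = structure(list(weights = c(0, 2, 0)), class = "subdomain_fit"),
    c = structure(list(weights = c(3, 3, 0)), class = "subdomain_fit"))
  s <- pattern_similarity(fits)
  expect_equal(diag(s), c(a = 1, b = 1, c = 1))
  expect_equal(s["a", "b"], 0)
  expect_equal(s["a", "c"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(s, t(s))
  expect_true(all(s >= -1 & s <= 1))
  fits$z <- structure(list(weights = c(0, 0, 0)), class = "subdomain_fit")
  expect_error(pattern_similarity(fits), "zero weight")
})

test_that("subdomain weight similarity tracks shared latent loadings", {
  # seed-averaged off-diagonal similarities should rank like the products
  # of the latent loadings a_j * a_k
  cfg <- tiny_config(n_subjects = 150, effect_scale = 0.3,
                     subdomain_loadings = c(wmi = 0.95, fri = 0.85, vci = 0.6,
                                            vsi = 0.4, psi = 0.15))
  sm_acc <- matrix(0, 5, 5)
  for (s in 1:5) {
    sim <- simulate_cohort(cfg, seed = 70 + s)
    cv <- nested_cv(sim$dataset, rounds = 1, outer_folds = 5, seed = s)
    part <- top_k_edges(unify(cv), k = 15)
    fits <- subdomain_fits(sim$dataset, part,
                           targets = c("wmi", "fri", "vci", "vsi", "psi"))
    sm_acc <- sm_acc + pattern_similarity(fits)
  }
  load <- cfg$subdomain_loadings
  prods <- outer(load, load)[upper.tri(diag(5))]
  rho <- cor((sm_acc / 5)[upper.tri(sm_acc)], prods, method = "spearman")
  expect_gt(rho, 0.6)
})

test_that("ROI scores respect incidence and hand computation", {
  ne <- n_edges_for(4)
  w <- numeric(ne)
  e13 <- edge_id(1, 3, 4)
  w[e13 + 1L] <- 2
  model <- cpmiq:::new_unified_model(w, 0, numeric(ne), 4)
  fc <- matrix(seq_len(3 * ne), 3, ne)
  ds <- toy_dataset(fc, fsiq = c(95, 100, 105), n_roi = 4)
  sc <- roi_scores(ds, model, seq_len(ne) - 1L)
  expect_equal(unname(sc[, c(1, 3)]), matrix(0, 3, 2))
  expect_equal(unname(sc[, 2]), 2 * fc[, e13 + 1L])
  expect_equal(unname(sc[, 4]), 2 * fc[, e13 + 1L])
  # hand-worked multi-edge case
  w2 <- c(0.5, 0, -1, 0, 0, 0.25)  # edges (0,1), (0,3), (2,3)
  model2 <- cpmiq:::new_unified_model(w2, 0, numeric(ne), 4)
  sc2 <- roi_scores(ds, model2, seq_len(ne) - 1L)
  expect_equal(unname(sc2[, 1]), 0.5 * fc[, 1] - 1 * fc[, 3])
  expect_equal(unname(sc2[, 2]), 0.5 * fc[, 1])
  expect_equal(unname(sc2[, 3]), 0.25 * fc[, 6])
  expect_equal(unname(sc2[, 4]), -1 * fc[, 3] + 0.25 * fc[, 6])
})

test_that("ROI-level regressions expose both scopes for the contrast", {
  sim <- simulate_cohort(tiny_config(n_subjects = 70, effect_scale = 0.25),
                         seed = 81)
  cv <- nested_cv(sim$dataset, rounds = 2, outer_folds = 5, seed = 1)
  model <- unify(cv)
  part <- top_k_edges(model, k = 10)
  rc <- suppressMessages(
    roi_level_regression(sim$dataset, model, part, "correlated", "fsiq"))
  rf <- suppressMessages(
    roi_level_regression(sim$dataset, model, part, "full", "fsiq"))
  expect_identical(attr(rc, "scope"), "correlated")
  expect_identical(attr(rf, "scope"), "full")
  # planted signal shows up through the ROI scores in both scopes
  expect_gt(rc$r, 0.5)
  expect_gt(rf$r, 0.5)
  # scopes genuinely differ when the support is wider than the top-k set
  expect_gt(sum(model$weights != 0), part$k)
  expect_false(isTRUE(all.equal(rc$r, rf$r)))
  # the two fits feed a Fisher r-to-z comparison of the paired scopes
  fz <- fisher_z_compare(rc$r, length(rc$fitted), rf$r, length(rf$fitted))
  expect_true(is.finite(fz$z) && is.finite(fz$p))
})
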