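test_that("duplicating a single run as a second identical run changes nothing", {
  cfg <- clean_config(n_subjects = 25, runs_per_subject = 1)
  sim <- simulate_cohort(cfg, seed = 31)
  ds1 <- sim$dataset
  # duplicate every row as a second, identical run
  idx <- rep(seq_len(nrow(ds1$fc)), each = 2)
  ds2 <- connectome_dataset(ds1$fc[idx, ], ds1$subject_id[idx],
                            rep(c("run1", "run2"), nrow(ds1$fc)),
                            ds1$phenotypes, n_roi = ds1$n_roi)
  cv1 <- nested_cv(ds1, rounds = 2, outer_folds = 5, seed = 7)
  cv2 <- nested_cv(ds2, rounds = 2, outer_folds = 5, seed = 7)
  expect_equal(cv2$predictions, cv1$predictions, tolerance = 1e-6)
  expect_equal(cv2$per_round$r, cv1$per_round$r, tolerance = 1e-6)
})

test_that("held-out subjects cannot influence their own predictions", {
  sim <- simulate_cohort(tiny_config(n_subjects = 30), seed = 32)
  cv <- nested_cv(sim$dataset, rounds = 2, outer_folds = 5, seed = 8)
  for (victim in c(3, 17)) {
    poisoned <- sim$dataset
    poisoned$phenotypes$fsiq[victim] <- poisoned$phenotypes$fsiq[victim] + 40
    cv_p <- nested_cv(poisoned, rounds = 2, outer_folds = 5, seed = 8)
    expect_identical(cv_p$predictions[, victim], cv$predictions[, victim])
  }
})

test_that("unify averages fold weights with zeros for unselected edges", {
  sim <- simulate_cohort(tiny_config(n_subjects = 25), seed = 33)
  cv <- nested_cv(sim$dataset, rounds = 1, outer_folds = 5, seed = 9)
  m <- unify(cv)
  wmat <- vapply(cv$fold_models, function(fm) fm$weights,
                 numeric(ncol(sim$dataset$fc)))
  expect_equal(m$weights, rowMeans(wmat))
  expect_equal(m$intercept,
               mean(vapply(cv$fold_models, function(fm) fm$intercept, 1)))
  expect_true(all(m$selection_frequency >= 0 & m$selection_frequency <= 1))
  # an edge selected in exactly s of the 5 folds with weight w each time
  # averages to s*w/5: check against a hand-built cv_result
  fake <- cv
  fake$fold_models <- lapply(1:5, function(i) {
    w <- numeric(ncol(sim$dataset$fc))
    if (i <= 2) w[10] <- 1.0
    list(round = 1, fold = i, mask = w != 0, weights = w,
         intercept = 100, lambda = 0.1)
  })
  mf <- unify(fake)
  expect_equal(mf$weights[10], 2 * 1.0 / 5)
  expect_equal(mf$selection_frequency[10], 0.4)
})

test_that("a single fold model unifies to itself", {
  sim <- simulate_cohort(tiny_config(n_subjects = 20), seed = 34)
  cv <- suppressWarnings(nested_cv(sim$dataset, rounds = 1, outer_folds = 5,
                                   seed = 10))
  solo <- cv
  solo$fold_models <- cv$fold_models[1]
  m <- unify(solo)
  expect_equal(m$weights, cv$fold_models[[1]]$weights)
  expect_equal(m$intercept, cv$fold_models[[1]]$intercept)
})

test_that("zero-weight models predict their intercept everywhere", {
  sim <- simulate_cohort(tiny_config(n_subjects = 10), seed = 35)
  m <- cpmiq:::new_unified_model(numeric(190), 101.5, numeric(190), 20)
  pred <- predict(m, sim$dataset)
  expect_true(all(pred == 101.5))
  expect_error(predict(m, simulate_cohort(sim_config(
    n_subjects = 5, n_roi = 10,
    network_sizes = c(Visual = 2, Motor = 2, DAN = 1, VAN = 1, Limbic = 1,
                      FPCN = 1, DMN = 2), n_true_edges = 2), seed = 1)$dataset),
    "mismatch")
})

test_that("evaluate matches hand-computed r and R^2", {
  pred <- c(96, 104, 99, 107, 94)
  act <- c(95, 105, 100, 110, 90)
  ev <- evaluate(pred, act)
  mp <- mean(pred); ma <- mean(act)
  r_hand <- sum((pred - mp) * (act - ma)) /
    sqrt(sum((pred - mp)^2) * sum((act - ma)^2))
  R2_hand <- 1 - sum((act - pred)^2) / sum((act - ma)^2)
  expect_equal(ev$r, r_hand, tolerance = 1e-12)
  expect_equal(ev$R2, R2_hand, tolerance = 1e-12)
  ev_id <- evaluate(act, act)
  expect_equal(ev_id$r, 1)
  expect_equal(ev_id$R2, 1)
  # null predictor: R^2 = 0, r undefined but flagged
  ev0 <- evaluate(rep(ma, 5), act)
  expect_equal(ev0$R2, 0)
  expect_identical(ev0$status, "constant_predictions")
  expect_true(is.na(ev0$r))
})

test_that("subgroup evaluation restricted to everyone matches the overall fit", {
  sim <- simulate_cohort(tiny_config(n_subjects = 30), seed = 36)
  sim$dataset$phenotypes$diagnosis <- "HC"
  cv <- nested_cv(sim$dataset, rounds = 1, outer_folds = 5, seed = 11)
  tab <- evaluate_subgroups(cv, sim$dataset, "diagnosis")
  overall <- evaluate(cv$pred_mean, cv$y)
  expect_equal(tab$r, overall$r)
  expect_equal(tab$R2, overall$R2)
  expect_identical(tab$n, overall$n)
  expect_error(evaluate_subgroups(cv, sim$dataset, "nope"), "unknown grouping")
})

test_that("restrict_model keeps predictions on the full support and
           collapses to the reference mean on the empty set", {
  sim <- simulate_cohort(tiny_config(n_subjects = 30), seed = 37)
  cv <- nested_cv(sim$dataset, rounds = 1, outer_folds = 5, seed = 12)
  m <- unify(cv)
  support <- which(m$weights != 0) - 1L
  r_full <- restrict_model(m, support, sim$dataset)
  expect_equal(predict(r_full, sim$dataset), predict(m, sim$dataset),
               tolerance = 1e-12)
  expect_warning(r_none <- restrict_model(m, integer(0), sim$dataset),
                 "empty edge subset")
  pred0 <- predict(r_none, sim$dataset)
  expect_equal(unname(pred0), rep(mean(predict(m, sim$dataset)),
                                  length(pred0)), tolerance = 1e-10)
})

test_that("leave-group-out fits partition the cohort and evaluate holdouts", {
  sim <- simulate_cohort(tiny_config(n_subjects = 40), seed = 38)
  sim$dataset$phenotypes$site <- rep(paste0("site", 1:4), each = 10)
  sites <- unique(sim$dataset$phenotypes$site)
  held <- unlist(lapply(sites, function(s) {
    fit <- leave_group_out_fit(sim$dataset, "site", s,
                               rounds = 1, outer_folds = 4, seed = 13)
    expect_true(is.finite(fit$holdout_eval$R2))
    names(fit$holdout_pred)
  }))
  expect_setequal(held, sim$dataset$phenotypes$subject_id)
  expect_error(leave_group_out_fit(sim$dataset, "site", "siteX", rounds = 1,
                                   outer_folds = 4, seed = 13),
               "not present")
})
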