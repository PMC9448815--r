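#' Run the full analysis pipeline end to end
#'
#' Composes every stage on one dataset: simulate (or load) -> nested CV ->
#' unified model -> permutation inference (optional) -> importance and
#' leave-one-network-out -> subdomain analysis -> individual
#' differentiability -> external-cohort application (simulated cohorts
#' only). One JSON report per stage plus a combined summary is written to
#' `out_dir`; any stage error aborts with the failing stage named, keeping
#' the reports already written.
#'
#' @param out_dir Output directory for stage reports.
#' @param config A [sim_config()] (used when `data_dir` is `NULL`).
#' @param data_dir Directory with `fc.tsv`, `phenotypes.csv`,
#'   `networks.tsv` to load instead of simulating.
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param rounds,outer_folds,p_threshold Nested-CV scheme.
#' @param k IQ-correlated edge-set size (default 500, capped at the edge
#'   count).
#' @param n_perm CV permutations (0 = skip permutation inference).
#' @param n_trials Controlled-permutation trials for the subdomain stage.
#' @param grouping Phenotype column for subgroup tables (default
#'   `"diagnosis"`).
#' @param external Simulate and evaluate an external cohort (needs ground
#'   truth, i.e. simulated data).
#' @return Invisibly, a list with all stage results.
#' @export
run_full_analysis <- function(out_dir, config = NULL, data_dir = NULL,
                              seed = 1L, rounds = 10, outer_folds = 5,
                              p_threshold = 0.05, k = 500, n_perm = 0,
                              n_trials = 199, grouping = "diagnosis",
                              external = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }

  truth <- NULL
  dat <- stage("data", {
    if (!is.null(data_dir)) {
      load_dataset(file.path(data_dir, "fc.tsv"),
                   file.path(data_dir, "phenotypes.csv"),
                   file.path(data_dir, "networks.tsv"))
    } else {
      if (is.null(config)) config <- sim_config(seed = seed)
      sim <- simulate_cohort(config, seed = seed)
      truth <- sim$truth
      write_ground_truth(truth, file.path(out_dir, "truth.json"))
      sim
    }
  })
  dataset <- dat$dataset
  networks <- dat$networks
  if (is.null(truth) && !is.null(dat$truth)) truth <- dat$truth
  k <- min(k, ncol(dataset$fc))

  cv <- stage("cv", nested_cv(dataset, rounds = rounds,
                              outer_folds = outer_folds,
                              p_threshold = p_threshold, seed = seed))
  subgroups <- stage("cv", evaluate_subgroups(cv, dataset, grouping))
  wj(list(per_round = cv$per_round, summary = cv$summary,
          predictions = as.list(round(cv$pred_mean, 6)),
          subgroups = subgroups,
          scheme = list(rounds = rounds, outer_folds = outer_folds,
                        p_threshold = p_threshold, seed = seed)),
     "cv.json")

  model <- stage("unify", unify(cv))
  write_unified_model(model, file.path(out_dir, "model.json"))
  insample <- stage("unify", {
    evaluate(predict(model, dataset),
             stats::setNames(dataset$phenotypes$fsiq,
                             dataset$phenotypes$subject_id))
  })

  perm <- NULL
  if (n_perm > 0) {
    perm <- stage("permutation", {
      cv_permutation_null(dataset, n_perm = n_perm, seed = seed,
                          rounds = rounds, outer_folds = outer_folds,
                          p_threshold = p_threshold)
    })
    wj(list(scheme = "cv", n_perm = n_perm, observed_r = perm$observed_r,
            p = perm$p, null_r = perm$null_r), "permutation.json")
  } else {
    wj(list(status = "skipped", n_perm = 0), "permutation.json")
  }

  imp <- stage("importance", {
    lno <- leave_network_out_report(cv, dataset, networks, grouping)
    list(lno = lno,
         roi_mean_abs = roi_importance(model$weights, dataset$n_roi,
                                       aggregation = "mean_abs"),
         network_matrix = network_importance(model$weights, networks))
  })
  wj(list(lno = imp$lno, roi_mean_abs = imp$roi_mean_abs,
          network_matrix = as.data.frame(imp$network_matrix)),
     "importance.json")

  subdom <- stage("subdomains", {
    part <- top_k_edges(model, k = k)
    fits <- subdomain_fits(dataset, part)
    ctrl <- controlled_permutation(dataset, part, "fsiq",
                                   n_trials = n_trials, seed = seed)
    sim_mat <- pattern_similarity(fits)
    roi_corr <- roi_level_regression(dataset, model, part, "correlated", "fsiq")
    roi_full <- roi_level_regression(dataset, model, part, "full", "fsiq")
    list(partition = part, fits = fits, controlled = ctrl,
         similarity = sim_mat, roi_correlated = roi_corr,
         roi_full = roi_full)
  })
  wj(list(k = k,
          correlated_edges = subdom$partition$correlated,
          subdomain_r = lapply(subdom$fits, function(f) f$r),
          controlled_p_fsiq = subdom$controlled$p,
          similarity = as.data.frame(subdom$similarity),
          roi_r_correlated = subdom$roi_correlated$r,
          roi_r_full = subdom$roi_full$r),
     "subdomains.json")

  idres <- stage("differentiability",
                 individual_differentiability(dataset, grouping = "age_band"))
  wj(list(group_summaries = idres$group_summaries,
          id_mean = mean(idres$id_values), id_sd = stats::sd(idres$id_values)),
     "differentiability.json")

  ext <- NULL
  if (external && !is.null(truth)) {
    ext <- stage("external", {
      ext_ds <- simulate_external_cohort(truth, fsiq_mean = 95, fsiq_sd = 14,
                                         edge_offset = 0.02,
                                         seed = (seed + 101L) %% 2147483647L)
      pred <- predict(model, ext_ds)
      evaluate(pred, stats::setNames(ext_ds$phenotypes$fsiq,
                                     ext_ds$phenotypes$subject_id))
    })
    wj(list(transfer_r = ext$r, transfer_R2 = ext$R2, n = ext$n),
       "external.json")
  }

  wj(list(cv_r_mean = cv$summary$r_mean, cv_r_sd = cv$summary$r_sd,
          cv_R2_mean = cv$summary$R2_mean,
          unified_insample_r = insample$r,
          permutation_p = if (!is.null(perm)) perm$p else NULL,
          subdomain_r = lapply(subdom$fits, function(f) f$r),
          transfer_r = if (!is.null(ext)) ext$r else NULL,
          k = k, seed = seed),
     "summary.json")

  invisible(list(dataset = dataset, networks = networks, truth = truth,
                 cv = cv, model = model, insample = insample, perm = perm,
                 importance = imp, subdomains = subdom, id = idres,
                 external = ext))
}
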