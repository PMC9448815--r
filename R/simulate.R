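#' Configuration for the synthetic-cohort generator
#'
#' The generator plants a sparse set of edges linearly coupled to a single
#' latent ability trait `g`, and scales FSIQ so that the oracle linear
#' predictor built from the planted edges attains a chosen population R^2.
#' Attenuation from edge and run noise is compensated exactly: with
#' \eqn{\kappa = \gamma^2 m / (\gamma^2 m + \sigma_e^2 + \sigma_r^2/runs)}
#' (m = number of true edges), the latent-FSIQ coupling used internally is
#' `h / kappa`, so the FC-linear oracle achieves population R^2 = `h`.
#'
#' @param n_subjects Cohort size.
#' @param n_roi Number of ROIs.
#' @param network_sizes Named integer vector over the seven canonical
#'   networks, summing to `n_roi`.
#' @param n_true_edges Number of planted signal edges.
#' @param true_edge_network Optional network label; when given, planted
#'   edges are drawn only from edges with both endpoints in that network.
#' @param effect_scale Edge-trait coupling gamma (Fisher-z FC units per
#'   latent SD).
#' @param edge_noise_sd Subject-level edge noise SD (z units).
#' @param run_noise_sd Additional per-run edge noise SD (z units).
#' @param runs_per_subject 1 or 2 scan runs per subject.
#' @param h Target population R^2 of the oracle FC predictor for FSIQ,
#'   in `[0, 1)`; `h = 0` gives a null cohort (FSIQ independent of FC).
#' @param subdomain_loadings Length-5 vector in (0,1): loadings of
#'   WMI/FRI/VCI/VSI/PSI on the latent trait.
#' @param diagnosis_mix List with `labels`, `proportions` (sum 1),
#'   `fsiq_shift` (points per group) and optionally `fc_shift` (z units per
#'   group) applied to edges of `fc_shift_network` (all edges when `NULL`).
#' @param site_offsets List with `labels`, `proportions`, `edge_shift`
#'   (z units added to every edge) and `fsiq_shift` (points).
#' @param within_mean,between_mean Mean FC (z units) for within- and
#'   between-network edges of the group-mean connectome.
#' @param mean_jitter_sd SD of per-edge jitter around those means.
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 600,
                       n_roi = 100,
                       network_sizes = c(Visual = 15, Motor = 15, DAN = 13,
                                         VAN = 12, Limbic = 10, FPCN = 15,
                                         DMN = 20),
                       n_true_edges = 50,
                       true_edge_network = NULL,
                       effect_scale = 0.1,
                       edge_noise_sd = 0.1,
                       run_noise_sd = 0.1,
                       runs_per_subject = 2,
                       h = 0.35,
                       subdomain_loadings = c(wmi = 0.75, fri = 0.80,
                                              vci = 0.70, vsi = 0.65,
                                              psi = 0.55),
                       diagnosis_mix = list(
                         labels = c("HC", "ADHD", "ASD", "MDD", "Anxiety", "Other"),
                         proportions = c(0.35, 0.25, 0.15, 0.10, 0.10, 0.05),
                         fsiq_shift = c(0, -2, -3, -1, 0, -2),
                         fc_shift = c(0, 0, 0, 0, 0, 0),
                         fc_shift_network = NULL),
                       site_offsets = list(
                         labels = paste0("site", 1:4),
                         proportions = c(0.40, 0.05, 0.45, 0.10),
                         edge_shift = c(0, 0.02, -0.02, 0.01),
                         fsiq_shift = c(0, 0, 0, 0)),
                       within_mean = 0.35,
                       between_mean = 0.10,
                       mean_jitter_sd = 0.02,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_roi >= 2, runs_per_subject %in% c(1L, 2L))
  if (length(network_sizes) != 7L || is.null(names(network_sizes)) ||
      !setequal(names(network_sizes), NETWORK_LABELS)) {
    stop("network_sizes must be named over the seven canonical networks")
  }
  network_sizes <- network_sizes[NETWORK_LABELS]
  if (sum(network_sizes) != n_roi) {
    stop("network_sizes must sum to n_roi (", n_roi, "), got ", sum(network_sizes))
  }
  if (n_true_edges > n_edges_for(n_roi)) stop("n_true_edges exceeds edge count")
  if (h < 0 || h >= 1) stop("h must lie in [0, 1)")
  if (any(subdomain_loadings <= 0 | subdomain_loadings >= 1)) {
    stop("subdomain_loadings must lie in (0, 1)")
  }
  if (abs(sum(diagnosis_mix$proportions) - 1) > 1e-8) {
    stop("diagnosis proportions must sum to 1")
  }
  if (abs(sum(site_offsets$proportions) - 1) > 1e-8) {
    stop("site proportions must sum to 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

# oracle-predictor attenuation factor for a config (1 when noise-free)
signal_attenuation <- function(config) {
  m <- config$n_true_edges
  gsq <- config$effect_scale^2 * m
  noise <- config$edge_noise_sd^2 + config$run_noise_sd^2 / config$runs_per_subject
  if (gsq + noise == 0) return(1)
  gsq / (gsq + noise)
}

#' Simulate a transdiagnostic connectome cohort
#'
#' Executes the generative model of [sim_config()]: a group-mean connectome
#' with elevated within-network FC, a standard-normal latent trait `g` per
#' subject, planted signal edges `M_j + gamma * sign_j * g_i`, diagnosis and
#' site shifts, subject- and run-level Gaussian edge noise, FSIQ scaled to
#' mean 100 / SD 15 with latent coupling calibrated to the target oracle
#' R^2, and five correlated subdomain scores.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`. Identical seed + config
#'   gives bit-identical output.
#' @return List with `dataset` (a [connectome_dataset()]), `networks`
#'   (a [network_map()]) and `truth` (a `ground_truth`: planted `beta`,
#'   latent `g`, `true_edge_ids` (0-based), `signs`, mean connectome `M`).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_subjects
  n_roi <- config$n_roi
  ne <- n_edges_for(n_roi)
  labels <- rep(NETWORK_LABELS, times = config$network_sizes[NETWORK_LABELS])
  networks <- network_map(labels)

  ep <- edge_endpoints(n_roi)
  lab_a <- labels[ep[, 1] + 1L]
  lab_b <- labels[ep[, 2] + 1L]
  within <- lab_a == lab_b
  M <- ifelse(within, config$within_mean, config$between_mean) +
    stats::rnorm(ne, 0, config$mean_jitter_sd)

  pool <- if (is.null(config$true_edge_network)) {
    seq_len(ne)
  } else {
    which(within & lab_a == config$true_edge_network)
  }
  if (config$n_true_edges > length(pool)) {
    stop("n_true_edges = ", config$n_true_edges, " exceeds the ",
         length(pool), " edges available in the target network")
  }
  true_idx <- sort(sample(pool, config$n_true_edges))
  signs <- sample(c(-1, 1), config$n_true_edges, replace = TRUE)
  beta <- numeric(ne)
  beta[true_idx] <- config$effect_scale * signs

  g <- stats::rnorm(n)
  dmix <- config$diagnosis_mix
  diagnosis <- sample(dmix$labels, n, replace = TRUE, prob = dmix$proportions)
  soff <- config$site_offsets
  site <- sample(soff$labels, n, replace = TRUE, prob = soff$proportions)

  # subject-level FC
  subj_fc <- matrix(M, nrow = n, ncol = ne, byrow = TRUE) + outer(g, beta)
  subj_fc <- subj_fc + soff$edge_shift[match(site, soff$labels)]
  dshift <- dmix$fc_shift[match(diagnosis, dmix$labels)]
  if (any(dshift != 0)) {
    cols <- if (is.null(dmix$fc_shift_network)) seq_len(ne) else {
      which(within & lab_a == dmix$fc_shift_network)
    }
    subj_fc[, cols] <- subj_fc[, cols] + dshift
  }
  if (config$edge_noise_sd > 0) {
    subj_fc <- subj_fc + matrix(stats::rnorm(n * ne, 0, config$edge_noise_sd), n, ne)
  }

  # FSIQ with latent coupling compensated for noise attenuation
  kappa <- signal_attenuation(config)
  h_lat <- if (config$h == 0) 0 else config$h / kappa
  if (h_lat >= 1) {
    stop("target oracle R^2 = ", config$h, " is unattainable: attenuation ",
         "kappa = ", signif(kappa, 4), " < h; increase effect_scale or ",
         "reduce noise")
  }
  eps <- stats::rnorm(n)
  core <- sqrt(h_lat) * g + sqrt(1 - h_lat) * eps
  fsiq <- 100 + 15 * core +
    dmix$fsiq_shift[match(diagnosis, dmix$labels)] +
    soff$fsiq_shift[match(site, soff$labels)]

  a <- config$subdomain_loadings
  sub_scores <- vapply(a, function(ak) {
    100 + 15 * (ak * g + sqrt(1 - ak^2) * stats::rnorm(n))
  }, numeric(n))
  colnames(sub_scores) <- names(a)

  ids <- sprintf("sub%04d", seq_len(n))
  phen <- data.frame(subject_id = ids, fsiq = fsiq,
                     wmi = sub_scores[, "wmi"], fri = sub_scores[, "fri"],
                     vci = sub_scores[, "vci"], vsi = sub_scores[, "vsi"],
                     psi = sub_scores[, "psi"],
                     age = round(stats::runif(n, 6, 17), 1),
                     gender = sample(c("F", "M"), n, replace = TRUE),
                     diagnosis = diagnosis, site = site,
                     stringsAsFactors = FALSE)

  runs <- config$runs_per_subject
  fc <- matrix(0, nrow = n * runs, ncol = ne)
  row_sub <- rep(ids, each = runs)
  row_run <- rep(paste0("run", seq_len(runs)), times = n)
  for (r in seq_len(runs)) {
    noise <- if (config$run_noise_sd > 0) {
      matrix(stats::rnorm(n * ne, 0, config$run_noise_sd), n, ne)
    } else 0
    fc[seq(r, n * runs, by = runs), ] <- subj_fc + noise
  }

  dataset <- connectome_dataset(fc, row_sub, row_run, phen, n_roi = n_roi)
  truth <- structure(
    list(beta = beta, g = g, true_edge_ids = true_idx - 1L, signs = signs,
         M = M, h_latent = h_lat, networks = networks, config = config),
    class = "ground_truth")
  list(dataset = dataset, networks = networks, truth = truth)
}

#' Simulate an external validation cohort from the same ground truth
#'
#' Draws new subjects under the same planted edge-trait mechanism and mean
#' connectome, with an optionally shifted FSIQ distribution and a uniform
#' site offset on every edge — the generalization setting in which a unified
#' model trained on the source cohort is applied to an independent cohort.
#'
#' @param truth A `ground_truth` from [simulate_cohort()].
#' @param n_subjects External cohort size (default: source size).
#' @param fsiq_mean,fsiq_sd FSIQ location/scale of the external cohort.
#' @param edge_offset Constant added to every edge (site shift, z units).
#' @param runs_per_subject Overrides the source value when given.
#' @param seed RNG seed.
#' @return A [connectome_dataset()].
#' @export
simulate_external_cohort <- function(truth, n_subjects = NULL,
                                     fsiq_mean = 100, fsiq_sd = 15,
                                     edge_offset = 0,
                                     runs_per_subject = NULL,
                                     seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  config <- truth$config
  n <- if (is.null(n_subjects)) config$n_subjects else n_subjects
  runs <- if (is.null(runs_per_subject)) config$runs_per_subject else runs_per_subject
  ne <- length(truth$beta)
  set.seed(seed)

  g <- stats::rnorm(n)
  subj_fc <- matrix(truth$M, nrow = n, ncol = ne, byrow = TRUE) +
    outer(g, truth$beta) + edge_offset
  if (config$edge_noise_sd > 0) {
    subj_fc <- subj_fc + matrix(stats::rnorm(n * ne, 0, config$edge_noise_sd), n, ne)
  }
  h_lat <- truth$h_latent
  core <- sqrt(h_lat) * g + sqrt(1 - h_lat) * stats::rnorm(n)
  fsiq <- fsiq_mean + fsiq_sd * core
  a <- config$subdomain_loadings
  sub_scores <- vapply(a, function(ak) {
    100 + 15 * (ak * g + sqrt(1 - ak^2) * stats::rnorm(n))
  }, numeric(n))
  colnames(sub_scores) <- names(a)

  ids <- sprintf("ext%04d", seq_len(n))
  phen <- data.frame(subject_id = ids, fsiq = fsiq,
                     wmi = sub_scores[, "wmi"], fri = sub_scores[, "fri"],
                     vci = sub_scores[, "vci"], vsi = sub_scores[, "vsi"],
                     psi = sub_scores[, "psi"],
                     age = round(stats::runif(n, 6, 17), 1),
                     gender = sample(c("F", "M"), n, replace = TRUE),
                     diagnosis = "HC", site = "ext",
                     stringsAsFactors = FALSE)

  fc <- matrix(0, nrow = n * runs, ncol = ne)
  row_sub <- rep(ids, each = runs)
  row_run <- rep(paste0("run", seq_len(runs)), times = n)
  for (r in seq_len(runs)) {
    noise <- if (config$run_noise_sd > 0) {
      matrix(stats::rnorm(n * ne, 0, config$run_noise_sd), n, ne)
    } else 0
    fc[seq(r, n * runs, by = runs), ] <- subj_fc + noise
  }
  connectome_dataset(fc, row_sub, row_run, phen, n_roi = config$n_roi)
}

#' Write ground truth to JSON
#' @param truth A `ground_truth`.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(true_edge_ids = truth$true_edge_ids, beta = truth$beta,
         signs = truth$signs, g = truth$g, h_latent = truth$h_latent),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
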