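# Shared fixtures: small simulation configs and hand-built toy datasets.

# 20-ROI config used by most pipeline-level tests (190 edges)
tiny_sizes <- c(Visual = 3, Motor = 3, DAN = 3, VAN = 3, Limbic = 2,
                FPCN = 3, DMN = 3)

tiny_config <- function(n_subjects = 60, n_true_edges = 10, ...) {
  sim_config(n_subjects = n_subjects, n_roi = 20, network_sizes = tiny_sizes,
             n_true_edges = n_true_edges, ...)
}

# a clean config: one diagnosis, one site, no shifts — for invariance checks
clean_config <- function(n_subjects = 60, ...) {
  tiny_config(
    n_subjects = n_subjects,
    diagnosis_mix = list(labels = "HC", proportions = 1, fsiq_shift = 0,
                         fc_shift = 0, fc_shift_network = NULL),
    site_offsets = list(labels = "site1", proportions = 1, edge_shift = 0,
                        fsiq_shift = 0),
    ...)
}

# hand-buildable dataset: n_roi ROIs, one run per subject, given FC rows
toy_dataset <- function(fc, fsiq = NULL, n_roi = NULL, phen_extra = list()) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  ids <- sprintf("s%02d", seq_len(n))
  if (is.null(fsiq)) fsiq <- seq(90, 110, length.out = n)
  phen <- data.frame(subject_id = ids, fsiq = fsiq,
                     wmi = fsiq, fri = fsiq, vci = fsiq, vsi = fsiq,
                     psi = fsiq,
                     age = seq(7, 15, length.out = n),
                     gender = rep(c("F", "M"), length.out = n),
                     diagnosis = "HC", site = "site1",
                     stringsAsFactors = FALSE)
  for (nm in names(phen_extra)) phen[[nm]] <- phen_extra[[nm]]
  connectome_dataset(fc, ids, rep("run1", n), phen, n_roi = n_roi)
}

# independent KKT check on the package's standardization convention
kkt_violation <- function(x, y, fit, lambda) {
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))
  xs <- sweep(sweep(x, 2, m), 2, s, "/")
  yc <- y - mean(y)
  b <- fit$weights * s
  g <- as.numeric(crossprod(xs, yc - xs %*% b)) / nrow(x)
  on <- b != 0
  max(c(abs(g[on] - lambda * sign(b[on])), pmax(abs(g[!on]) - lambda, 0), 0))
}
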