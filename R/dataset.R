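#' The seven canonical cortical networks
#'
#' Fixed label set (Yeo-style seven-network partition): Visual, Motor
#' (somatomotor), DAN (dorsal attention), VAN (ventral attention), Limbic,
#' FPCN (frontoparietal control), DMN (default mode).
#'
#' @export
NETWORK_LABELS <- c("Visual", "Motor", "DAN", "VAN", "Limbic", "FPCN", "DMN")

PHENOTYPE_COLS <- c("subject_id", "fsiq", "wmi", "fri", "vci", "vsi", "psi",
                    "age", "gender", "diagnosis", "site")

#' Construct a connectome dataset
#'
#' Bundles a runs-by-edges Fisher-z FC matrix (one row per scan run) with
#' per-row subject and run identifiers and a per-subject phenotype table.
#'
#' @param fc Numeric matrix, rows are scan runs, `n_roi*(n_roi-1)/2` columns
#'   in canonical edge order.
#' @param subject_id Character vector, one per FC row.
#' @param run_id Character vector, one per FC row.
#' @param phenotypes Data frame with columns `subject_id, fsiq, wmi, fri,
#'   vci, vsi, psi, age, gender, diagnosis, site` (one row per subject).
#' @param n_roi Number of ROIs; inferred from `ncol(fc)` when `NULL`.
#' @return An object of class `connectome_dataset`.
#' @export
connectome_dataset <- function(fc, subject_id, run_id, phenotypes, n_roi = NULL) {
  fc <- as.matrix(fc)
  if (is.null(n_roi)) {
    n_roi <- (1 + sqrt(1 + 8 * ncol(fc))) / 2
    if (n_roi != floor(n_roi)) {
      stop("ncol(fc) = ", ncol(fc), " is not a valid edge count n*(n-1)/2")
    }
    n_roi <- as.integer(n_roi)
  }
  if (ncol(fc) != n_edges_for(n_roi)) {
    stop("fc has ", ncol(fc), " columns but n_roi = ", n_roi,
         " implies ", n_edges_for(n_roi), " edges")
  }
  subject_id <- as.character(subject_id)
  run_id <- as.character(run_id)
  stopifnot(length(subject_id) == nrow(fc), length(run_id) == nrow(fc))
  phenotypes <- as.data.frame(phenotypes)
  missing_cols <- setdiff(PHENOTYPE_COLS, names(phenotypes))
  if (length(missing_cols)) {
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  phenotypes$subject_id <- as.character(phenotypes$subject_id)
  if (anyDuplicated(phenotypes$subject_id)) {
    stop("duplicated subject_id in phenotype table")
  }
  orphan <- setdiff(subject_id, phenotypes$subject_id)
  if (length(orphan)) {
    stop("FC rows reference subjects absent from phenotypes: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  # keep only subjects that actually have runs, in first-appearance order
  phenotypes <- phenotypes[match(unique(subject_id), phenotypes$subject_id), ,
                           drop = FALSE]
  rownames(phenotypes) <- NULL
  colnames(fc) <- edge_names(n_roi)
  structure(
    list(fc = fc, subject_id = subject_id, run_id = run_id,
         phenotypes = phenotypes, n_roi = as.integer(n_roi)),
    class = "connectome_dataset"
  )
}

#' @method print connectome_dataset
#' @export
print.connectome_dataset <- function(x, ...) {
  cat("connectome_dataset:", nrow(x$fc), "runs,",
      nrow(x$phenotypes), "subjects,", x$n_roi, "ROIs (",
      ncol(x$fc), "edges )\n")
  invisible(x)
}

#' Number of subjects in a dataset
#' @param dataset A `connectome_dataset`.
#' @return Integer subject count.
#' @export
n_subjects <- function(dataset) nrow(dataset$phenotypes)

#' Per-subject run-averaged FC matrix
#'
#' Averages each subject's scan runs into a single connectome row. Rows are
#' aligned with `dataset$phenotypes`.
#'
#' @param dataset A `connectome_dataset`.
#' @return A subjects x edges numeric matrix with subject ids as rownames.
#' @export
subject_fc <- function(dataset) {
  ids <- dataset$phenotypes$subject_id
  idx <- match(dataset$subject_id, ids)
  out <- matrix(0, nrow = length(ids), ncol = ncol(dataset$fc),
                dimnames = list(ids, colnames(dataset$fc)))
  counts <- tabulate(idx, nbins = length(ids))
  sums <- rowsum(dataset$fc, group = idx, reorder = TRUE)
  g <- as.integer(rownames(sums))
  out[g, ] <- sums / counts[g]
  out
}

#' Construct an ROI-to-network map
#'
#' @param labels Character vector of length `n_roi`; each entry one of the
#'   seven canonical labels in [NETWORK_LABELS].
#' @return An object of class `network_map` (character vector with attr).
#' @export
network_map <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), NETWORK_LABELS)
  if (length(bad)) {
    stop("unknown network label(s): ", paste(bad, collapse = ", "))
  }
  structure(labels, class = "network_map")
}

#' ROIs (0-based) belonging to a network
#' @param networks A `network_map`.
#' @param label One of [NETWORK_LABELS].
#' @return Integer vector of 0-based ROI indices.
#' @export
network_rois <- function(networks, label) {
  if (!label %in% NETWORK_LABELS) stop("unknown network: ", label)
  which(unclass(networks) == label) - 1L
}

## ---------------------------------------------------------------- file IO

#' Write / read the FC table
#'
#' Dialect: TSV or CSV (by extension), columns `subject_id`, `run_id`, then
#' `e0000` ... `e{n_edges-1}`.
#'
#' @param dataset A `connectome_dataset`.
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly (writer); the reader returns a list with
#'   elements `fc`, `subject_id`, `run_id`.
#' @export
write_fc_table <- function(dataset, path) {
  dt <- data.table::data.table(subject_id = dataset$subject_id,
                               run_id = dataset$run_id)
  # %.17g guarantees the doubles parse back bit-identically
  num <- data.table::as.data.table(
    matrix(sprintf("%.17g", dataset$fc), nrow = nrow(dataset$fc),
           dimnames = dimnames(dataset$fc)))
  dt <- cbind(dt, num)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(dt, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' @rdname write_fc_table
#' @export
read_fc_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = c("subject_id", "run_id")))
  ecols <- grep("^e[0-9]+$", names(dt), value = TRUE)
  list(fc = as.matrix(dt[, ecols, with = FALSE]),
       subject_id = dt$subject_id, run_id = dt$run_id)
}

#' Write / read the phenotype table (CSV)
#' @param phenotypes Per-subject phenotype data frame.
#' @param path CSV path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  ph <- phenotypes[, PHENOTYPE_COLS]
  for (cl in names(ph)) {
    if (is.double(ph[[cl]])) ph[[cl]] <- sprintf("%.17g", ph[[cl]])
  }
  data.table::fwrite(ph, path, sep = ",", quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = list(character = "subject_id")))
}

#' Write / read the ROI-to-network map (TSV: roi_index, network)
#' @param networks A `network_map`.
#' @param path TSV path.
#' @export
write_network_map <- function(networks, path) {
  data.table::fwrite(
    data.table::data.table(roi_index = seq_along(networks) - 1L,
                           network = unclass(networks)),
    path, sep = "\t")
  invisible(path)
}

#' @rdname write_network_map
#' @export
read_network_map <- function(path) {
  dt <- data.table::fread(path)
  stopifnot(all(c("roi_index", "network") %in% names(dt)))
  dt <- dt[order(dt$roi_index), ]
  if (!identical(as.integer(dt$roi_index), seq_len(nrow(dt)) - 1L)) {
    stop("roi_index must cover 0 .. n_roi-1 exactly once")
  }
  network_map(dt$network)
}

#' Load a dataset from its three table files
#'
#' Reads the FC table, phenotype table and network map, validates their
#' consistency, and drops subjects with missing FSIQ (listwise deletion for
#' the modeling target, with a logged count).
#'
#' @param fc_path,phenotype_path,network_path File paths (see the writers
#'   for dialects).
#' @return List with elements `dataset` (a `connectome_dataset`) and
#'   `networks` (a `network_map`).
#' @export
load_dataset <- function(fc_path, phenotype_path, network_path) {
  fct <- read_fc_table(fc_path)
  phen <- read_phenotypes(phenotype_path)
  networks <- read_network_map(network_path)
  n_roi <- length(networks)
  if (ncol(fct$fc) != n_edges_for(n_roi)) {
    stop("FC table has ", ncol(fct$fc), " edge columns; network map declares n_roi = ",
         n_roi, " (", n_edges_for(n_roi), " edges)")
  }
  drop <- phen$subject_id[!is.finite(phen$fsiq)]
  if (length(drop)) {
    message("dropping ", length(drop), " subject(s) with missing FSIQ")
    keep <- !(fct$subject_id %in% drop)
    fct$fc <- fct$fc[keep, , drop = FALSE]
    fct$subject_id <- fct$subject_id[keep]
    fct$run_id <- fct$run_id[keep]
    phen <- phen[!(phen$subject_id %in% drop), , drop = FALSE]
  }
  ds <- connectome_dataset(fct$fc, fct$subject_id, fct$run_id, phen, n_roi = n_roi)
  list(dataset = ds, networks = networks)
}

#' Write a dataset (and network map) to a directory
#'
#' Emits `fc.tsv`, `phenotypes.csv` and `networks.tsv` in the documented
#' dialects.
#'
#' @param dataset A `connectome_dataset`.
#' @param networks A `network_map`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, networks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fc_table(dataset, file.path(dir, "fc.tsv"))
  write_phenotypes(dataset$phenotypes, file.path(dir, "phenotypes.csv"))
  write_network_map(networks, file.path(dir, "networks.tsv"))
  invisible(dir)
}

## ------------------------------------------------------- unified model IO

#' Write / read a unified model (JSON)
#'
#' @param model A `unified_model` (see [unify()]).
#' @param path JSON path.
#' @export
write_unified_model <- function(model, path) {
  jsonlite::write_json(
    list(n_roi = model$n_roi,
         weights = model$weights,
         intercept = model$intercept,
         selection_frequency = model$selection_frequency,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_unified_model
#' @export
read_unified_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_unified_model(
    weights = as.numeric(obj$weights),
    intercept = as.numeric(obj$intercept),
    selection_frequency = as.numeric(obj$selection_frequency),
    n_roi = as.integer(obj$n_roi),
    provenance = obj$provenance)
}
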