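#' Cohort mean connectome
#'
#' Per-edge mean over all subjects (each subject's runs averaged first),
#' computed over the entire cohort regardless of diagnosis.
#'
#' @param dataset A [connectome_dataset()].
#' @return Numeric vector over edges.
#' @export
mean_connectome <- function(dataset) {
  if (n_subjects(dataset) < 1) stop("empty dataset")
  colMeans(subject_fc(dataset))
}

#' Individual differentiability
#'
#' Per-subject L1 distance between the subject's (run-averaged) connectome
#' and the cohort mean connectome:
#' \deqn{ID_i = \sum_j |FC_{ij} - \bar{FC}_j|}
#' summed over all edges, unnormalized. A subject identical to the mean
#' connectome has ID 0; adding a constant to every connectome leaves IDs
#' unchanged, and scaling all FC by s > 0 scales every ID by s.
#'
#' @param dataset A [connectome_dataset()].
#' @param grouping Optional phenotype column (or `"age_band"`) for group
#'   summaries.
#' @return An `id_result`: `mean_connectome`, `id_values` (named per
#'   subject), and `group_summaries` (mean/SD/median/IQR per group) when a
#'   grouping is given.
#' @export
individual_differentiability <- function(dataset, grouping = NULL) {
  sfc <- subject_fc(dataset)
  m <- colMeans(sfc)
  id_values <- rowSums(abs(sweep(sfc, 2, m, "-")))
  group_summaries <- NULL
  if (!is.null(grouping)) {
    phen <- dataset$phenotypes
    g <- if (grouping == "age_band") as.character(age_band(phen$age)) else phen[[grouping]]
    if (is.null(g)) stop("unknown grouping column: ", grouping)
    group_summaries <- do.call(rbind, lapply(unique(g), function(lv) {
      v <- id_values[g == lv]
      data.frame(group = lv, n = length(v), mean = mean(v), sd = stats::sd(v),
                 median = stats::median(v), iqr = stats::IQR(v))
    }))
  }
  structure(list(mean_connectome = m, id_values = id_values,
                 group_summaries = group_summaries),
            class = "id_result")
}
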