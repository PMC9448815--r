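#' Compute a functional-connectivity vector from ROI time series
#'
#' Pairwise Pearson correlations between ROI time series, Fisher
#' z-transformed (`atanh`), flattened to the canonical edge ordering of
#' [edge_id()]. FC values are stored on the z-scale throughout the package:
#' the unbounded support suits linear modeling and the L1 sums of the
#' individual-differentiability statistic.
#'
#' @param timeseries A T x n_roi numeric matrix (T time points, one column
#'   per ROI); T must be at least 3 and every column must vary.
#' @return Numeric vector of length `n_roi*(n_roi-1)/2`, Fisher-z FC values.
#' @export
compute_fc <- function(timeseries) {
  ts <- as.matrix(timeseries)
  if (!is.numeric(ts)) stop("timeseries must be numeric")
  if (nrow(ts) < 3) stop("need at least 3 time points")
  n_roi <- ncol(ts)
  if (n_roi < 2) stop("need at least 2 ROIs")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series for ROI(s): ",
         paste(which(sds == 0) - 1L, collapse = ", "))
  }
  r <- stats::cor(ts)
  ut <- upper.tri(r)
  # row-major upper triangle: transpose before extracting (R is column-major)
  vals <- t(r)[t(ut)]
  if (any(abs(vals) >= 1 - 1e-12)) {
    bad <- which(abs(vals) >= 1 - 1e-12)[1]
    pr <- edge_pair(bad - 1L, n_roi)
    stop("|r| = 1 between ROIs ", pr[1, 1], " and ", pr[1, 2],
         "; Fisher z-transform diverges")
  }
  atanh(vals)
}
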