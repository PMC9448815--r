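#' Edge screening by Pearson correlation
#'
#' Correlates every edge with the target across training rows and retains
#' edges whose two-sided p-value (t-distribution, `rows - 2` df) falls below
#' the threshold — the CPM feature-selection step, applied inside each
#' training fold only.
#'
#' @param fc_train Rows x edges FC matrix (training rows only).
#' @param y_train Per-row target values.
#' @param p_threshold Retention threshold on the two-sided p-value
#'   (default 0.05).
#' @return A `screening_result`: list with `r`, `p`, `mask` (p <
#'   p_threshold), `n`, `p_threshold`. Constant edges get `r = 0` (hence
#'   p = 1, excluded) with a warning.
#' @export
screen_edges <- function(fc_train, y_train, p_threshold = 0.05) {
  fc_train <- as.matrix(fc_train)
  n <- nrow(fc_train)
  if (n < 4) stop("need at least 4 training rows for screening")
  if (length(y_train) != n) stop("y_train length must match rows of fc_train")
  if (stats::sd(y_train) == 0) stop("target is constant; screening undefined")
  r <- suppressWarnings(as.vector(stats::cor(fc_train, y_train)))
  const <- !is.finite(r)
  if (any(const)) {
    warning(sum(const), " constant edge(s) excluded from screening")
    r[const] <- 0
  }
  # guard |r| = 1 (t = Inf -> p = 0, retained)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[const] <- 1
  structure(list(r = r, p = p, mask = p < p_threshold, n = n,
                 p_threshold = p_threshold),
            class = "screening_result")
}
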