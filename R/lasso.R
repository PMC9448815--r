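# Internal standardization convention: columns are centered and scaled by
# the population SD (divisor n, not n-1), the target is centered, and the
# penalized objective is
#     (1/(2n)) * sum((y - b - x w)^2) + lambda * sum(|w|).
# On this scale lambda_max = max_j |<x_j, y>| / n zeroes every weight.
# Weights are always reported back in original feature units so that
# cross-fold averaging (unify) is on a common scale.

standardize_cols <- function(x) {
  m <- colMeans(x)
  xc <- sweep(x, 2, m, "-")
  s <- sqrt(colMeans(xc^2))
  ok <- s > 0
  xs <- xc
  xs[, ok] <- sweep(xc[, ok, drop = FALSE], 2, s[ok], "/")
  list(x = xs, center = m, scale = s, ok = ok)
}

#' Largest useful LASSO penalty for a design
#'
#' `lambda_max = max_j |<x_std_j, y - mean(y)>| / n` on the standardized
#' scale; every penalty at or above it shrinks all weights to zero.
#'
#' @param x Rows x features matrix.
#' @param y Target vector.
#' @return Scalar `lambda_max`.
#' @export
lambda_max <- function(x, y) {
  std <- standardize_cols(as.matrix(x))
  yc <- y - mean(y)
  max(abs(crossprod(std$x[, std$ok, drop = FALSE], yc)) / length(y))
}

#' Log-spaced penalty grid
#'
#' @param x,y Design and target used to anchor `lambda_max`.
#' @param n_lambda Grid size (default 50).
#' @param min_ratio Smallest grid value as a fraction of `lambda_max`
#'   (default 1e-3).
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(x, y, n_lambda = 50, min_ratio = 1e-3) {
  lmax <- lambda_max(x, y)
  if (lmax == 0) lmax <- .Machine$double.eps
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Fit a LASSO regression at a fixed penalty
#'
#' Minimizes `(1/(2n)) RSS + lambda * L1` after internal standardization
#' (population-SD scaling, centered target); the solver is coordinate
#' descent via \pkg{glmnet} (tight convergence threshold), with exact
#' closed forms for the single-feature and `lambda >= lambda_max` cases and
#' a minimum-norm least-squares solution at `lambda = 0`. Weights are
#' returned in original feature units.
#'
#' @param x Rows x features numeric matrix (k >= 1 columns).
#' @param y Target vector.
#' @param lambda Penalty, >= 0.
#' @return List with `weights` (length k, original units), `intercept`,
#'   `lambda`.
#' @export
fit_lasso <- function(x, y, lambda) {
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite inputs")
  if (length(lambda) != 1 || lambda < 0) stop("lambda must be a single value >= 0")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2) stop("need at least 2 rows")
  if (k < 1) stop("need at least 1 feature")
  std <- standardize_cols(x)
  my <- mean(y)
  yc <- y - my
  beta_std <- numeric(k)
  xs <- std$x[, std$ok, drop = FALSE]
  k_ok <- ncol(xs)

  if (k_ok > 0) {
    if (lambda == 0) {
      # unpenalized limit: (minimum-norm) least squares on standardized x
      fit <- tryCatch(qr.coef(qr(xs), yc), error = function(e) NULL)
      if (is.null(fit) || anyNA(fit)) {
        sv <- svd(xs)
        pos <- sv$d > max(sv$d) * 1e-12
        fit <- sv$v[, pos, drop = FALSE] %*%
          ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos])
      }
      beta_std[std$ok] <- as.numeric(fit)
    } else {
      cj <- as.numeric(crossprod(xs, yc)) / n
      lmax <- max(abs(cj))
      if (lambda >= lmax) {
        # full shrinkage: all weights zero
      } else if (k_ok == 1) {
        # univariate soft-threshold; standardized column has <x,x>/n = 1
        beta_std[std$ok] <- sign(cj) * max(abs(cj) - lambda, 0)
      } else {
        path <- exp(seq(log(lmax), log(lambda), length.out = 8))
        fit <- glmnet::glmnet(xs, yc, family = "gaussian", alpha = 1,
                              lambda = path, standardize = FALSE,
                              intercept = FALSE, thresh = 1e-14,
                              maxit = 1e7)
        beta_std[std$ok] <- as.numeric(fit$beta[, length(path)])
      }
    }
  }
  w <- numeric(k)
  w[std$ok] <- beta_std[std$ok] / std$scale[std$ok]
  intercept <- my - sum(w * std$center)
  list(weights = w, intercept = intercept, lambda = lambda)
}

#' Select the LASSO penalty by subject-grouped inner cross-validation
#'
#' Splits training subjects (not rows) into `inner_folds` groups, fits the
#' penalty path on each inner-training set and picks the penalty with the
#' lowest mean validation squared error; ties go to the largest penalty
#' (sparsest model).
#'
#' When `rescreen` is supplied, edge screening is repeated inside every
#' inner fold on the inner-training subjects only, so the validation error
#' is not biased by features selected with the validation subjects' data —
#' without this the inner loop is optimistic and systematically
#' under-penalizes. In that mode `x` must carry all candidate columns.
#'
#' @param x Rows x features matrix (screened training rows; all edges when
#'   `rescreen` is used).
#' @param y Per-row target.
#' @param groups Per-row subject identifiers (runs of a subject always land
#'   in the same inner fold).
#' @param grid Decreasing penalty vector; default [lambda_grid()] on (x, y).
#' @param inner_folds Number of inner folds (default 5).
#' @param foldid Optional per-subject fold assignment (named integer vector
#'   over unique subjects); drawn at random when `NULL`.
#' @param rescreen Optional list with `fc_subjects` (subjects x all-edges
#'   run-averaged FC, rownames = subject ids), `y_subjects` (named), and
#'   `p_threshold`: enables per-inner-fold screening.
#' @param thresh Convergence threshold for the inner path fits.
#' @return List with `lambda` (selected), `grid`, `cv_mse` (mean validation
#'   MSE per grid point).
#' @export
select_lambda <- function(x, y, groups, grid = NULL, inner_folds = 5,
                          foldid = NULL, rescreen = NULL, thresh = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n, length(groups) == n)
  subjects <- unique(groups)
  if (length(subjects) < inner_folds) {
    stop("fewer subjects (", length(subjects), ") than inner folds (",
         inner_folds, ")")
  }
  if (is.null(grid)) grid <- lambda_grid(x, y)
  grid <- sort(grid, decreasing = TRUE)
  if (is.null(foldid)) {
    foldid <- sample(rep(seq_len(inner_folds), length.out = length(subjects)))
    names(foldid) <- subjects
  }
  row_fold <- foldid[match(groups, names(foldid))]

  sq_err <- matrix(NA_real_, nrow = inner_folds, ncol = length(grid))
  counts <- integer(inner_folds)
  for (f in seq_len(inner_folds)) {
    tr <- row_fold != f
    va <- !tr
    if (!any(va) || sum(tr) < 2) next
    cols <- seq_len(ncol(x))
    if (!is.null(rescreen)) {
      tr_subjects <- names(foldid)[foldid != f]
      scr <- screen_edges(
        rescreen$fc_subjects[tr_subjects, , drop = FALSE],
        rescreen$y_subjects[tr_subjects],
        rescreen$p_threshold)
      cols <- which(scr$mask)
      if (!length(cols)) {
        sq_err[f, ] <- mean((y[va] - mean(y[tr]))^2)
        counts[f] <- sum(va)
        next
      }
    }
    xtr <- x[tr, cols, drop = FALSE]
    ytr <- y[tr]
    std <- standardize_cols(xtr)
    yc <- ytr - mean(ytr)
    xs <- std$x[, std$ok, drop = FALSE]
    xva <- x[va, cols, drop = FALSE]
    xva_s <- sweep(xva[, std$ok, drop = FALSE], 2, std$center[std$ok], "-")
    xva_s <- sweep(xva_s, 2, std$scale[std$ok], "/")
    if (ncol(xs) == 0) {
      pred <- matrix(mean(ytr), nrow = sum(va), ncol = length(grid))
    } else if (ncol(xs) == 1) {
      cj <- sum(xs * yc) / sum(tr)
      betas <- sign(cj) * pmax(abs(cj) - grid, 0)
      pred <- mean(ytr) + outer(as.numeric(xva_s), betas)
    } else {
      fit <- glmnet::glmnet(xs, yc, family = "gaussian", alpha = 1,
                            lambda = grid, standardize = FALSE,
                            intercept = FALSE, thresh = thresh, maxit = 1e7)
      beta <- as.matrix(fit$beta)
      # glmnet can stop early on a supplied path; recycle the last solution
      if (ncol(beta) < length(grid)) {
        beta <- cbind(beta, beta[, rep(ncol(beta), length(grid) - ncol(beta)),
                                 drop = FALSE])
      }
      pred <- mean(ytr) + xva_s %*% beta
    }
    sq_err[f, ] <- colMeans((y[va] - pred)^2)
    counts[f] <- sum(va)
  }
  used <- which(is.finite(sq_err[, 1]))
  cv_mse <- colSums(sq_err[used, , drop = FALSE] * counts[used]) / sum(counts[used])
  best <- min(cv_mse)
  idx <- min(which(cv_mse <= best + 1e-12))  # grid decreasing: first = largest
  list(lambda = grid[idx], grid = grid, cv_mse = cv_mse)
}
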