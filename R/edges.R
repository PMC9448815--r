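#' Number of edges for a given parcellation size
#'
#' An undirected connectome over `n_roi` regions has `n_roi*(n_roi-1)/2`
#' unique edges (upper triangle of the FC matrix).
#'
#' @param n_roi Number of regions of interest (positive integer).
#' @return Integer edge count.
#' @export
n_edges_for <- function(n_roi) {
  stopifnot(is.numeric(n_roi), length(n_roi) == 1L, n_roi >= 1, n_roi == floor(n_roi))
  as.integer(n_roi * (n_roi - 1) / 2)
}

#' Map an ROI pair to its edge id
#'
#' Edge ids are 0-based and enumerate the strict upper triangle of the
#' ROI-by-ROI matrix in row-major order: (0,1), (0,2), ..., (0,n-1),
#' (1,2), ... ROI indices are 0-based; the pair is unordered.
#'
#' @param a,b 0-based ROI indices (vectors recycle).
#' @param n_roi Number of ROIs.
#' @return Integer vector of 0-based edge ids in `[0, n_roi*(n_roi-1)/2)`.
#' @seealso [edge_pair()] for the inverse.
#' @export
edge_id <- function(a, b, n_roi) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(a == b)) stop("self-pairs (a == b) are not edges")
  if (any(a < 0 | a >= n_roi | b < 0 | b >= n_roi)) {
    stop("ROI indices must lie in [0, n_roi)")
  }
  i <- pmin(a, b)
  j <- pmax(a, b)
  as.integer(i * n_roi - i * (i + 1) / 2 + (j - i - 1))
}

#' Map an edge id back to its ROI pair
#'
#' Inverse of [edge_id()] under the fixed upper-triangle row-major
#' convention.
#'
#' @param id 0-based edge id (vector allowed).
#' @param n_roi Number of ROIs.
#' @return A two-column integer matrix with columns `a`, `b` (a < b, 0-based).
#' @export
edge_pair <- function(id, n_roi) {
  ne <- n_edges_for(n_roi)
  if (any(id < 0 | id >= ne)) stop("edge id out of range [0, ", ne, ")")
  id <- as.numeric(id)
  # row i owns ids [offset_i, offset_i + n_roi - i - 1); solve for i
  # offset_i = i*n_roi - i*(i+1)/2
  i <- floor(((2 * n_roi - 1) - sqrt((2 * n_roi - 1)^2 - 8 * id)) / 2)
  # guard against floating-point edge cases at row boundaries
  off <- i * n_roi - i * (i + 1) / 2
  too_far <- off > id
  i[too_far] <- i[too_far] - 1
  off <- i * n_roi - i * (i + 1) / 2
  j <- id - off + i + 1
  cbind(a = as.integer(i), b = as.integer(j))
}

#' Canonical FC column names
#'
#' Column names `e0000`, `e0001`, ... used by the FC table dialect; ids are
#' zero-padded to at least four digits.
#'
#' @param n_roi Number of ROIs.
#' @return Character vector of length `n_edges_for(n_roi)`.
#' @export
edge_names <- function(n_roi) {
  ne <- n_edges_for(n_roi)
  width <- max(4L, nchar(ne - 1L))
  sprintf(paste0("e%0", width, "d"), seq_len(ne) - 1L)
}

# 0-based incidence: list over edges of their two 0-based ROI endpoints,
# as an n_edges x 2 matrix (cached per n_roi within a call site).
edge_endpoints <- function(n_roi) {
  edge_pair(seq_len(n_edges_for(n_roi)) - 1L, n_roi)
}

# Edge ids (0-based) incident to any ROI in `rois` (0-based vector)
edges_incident <- function(rois, n_roi) {
  ep <- edge_endpoints(n_roi)
  which(ep[, 1] %in% rois | ep[, 2] %in% rois) - 1L
}
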