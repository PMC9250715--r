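#' Dynamic time warping distance
#'
#' Distance between two univariate sequences under unconstrained monotone
#' time warping: the square root of the minimal accumulated cost over all
#' warping paths, with squared-difference local cost and the recurrence
#' `D(i,j) = (x_i - y_j)^2 + min(D(i-1,j), D(i,j-1), D(i-1,j-1))`. No band
#' constraint is applied; SOFA trajectories are length 12, so the full
#' alignment is cheap. For equal-length sequences the result never exceeds
#' the Euclidean distance. DTW is not a metric: the triangle inequality can
#' fail, but symmetry, non-negativity and `dtw_distance(x, x) == 0` hold.
#'
#' @param x,y Non-empty numeric sequences.
#' @return Non-negative scalar distance.
#' @examples
#' dtw_distance(c(0, 0, 0), c(1, 1, 1)) # sqrt(3)
#' dtw_distance(c(1, 2, 3), c(1, 3))    # 1
#' @export
dtw_distance <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("sequences must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("sequences must not contain NA")
  dtw_distance_cpp(x, y)
}

#' Pairwise DTW distance matrix
#'
#' Computes the symmetric matrix of DTW distances between all patient
#' trajectories; each unordered pair is evaluated once.
#'
#' @param traj A `sofa_trajectories` object or an n x K numeric matrix
#'   (patients in rows), n >= 2.
#' @return Symmetric n x n matrix with zero diagonal and patient ids as
#'   dimnames.
#' @export
pairwise_dtw <- function(traj) {
  m <- trajectory_matrix(traj)
  if (nrow(m) < 2) stop("need at least two trajectories")
  if (anyNA(m)) stop("trajectory matrix must not contain missing values")
  D <- pairwise_dtw_cpp(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  dimnames(D) <- list(ids, ids)
  D
}

.validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-9)) stop("distance matrix must have zero diagonal")
  d
}
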