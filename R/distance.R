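#' Euclidean distance between two records
#'
#' The distance used by the plain hierarchical clustering stage (HC):
#' `sqrt(sum((p - q)^2))`.
#'
#' @param p,q Numeric vectors of equal length.
#' @return Nonnegative distance.
#' @export
#' @examples
#' euclidean_distance(c(3, 4), c(0, 0))  # 5
euclidean_distance <- function(p, q) {
  if (length(p) != length(q)) {
    stop_ehc("dimension mismatch: |p|=%d, |q|=%d", length(p), length(q))
  }
  if (length(p) < 1) stop_ehc("vectors must have length >= 1")
  sqrt(sum((p - q)^2))
}

#' Variance weight of a record
#'
#' The weight used by the enhanced (variance-weighted) distance: the sample
#' variance of a single record's attribute values,
#' `sum((p - mean(p))^2) / (n - 1)`.
#'
#' @param p Numeric vector of length >= 2.
#' @return Nonnegative sample variance.
#' @export
variance_weight <- function(p) {
  n <- length(p)
  if (n < 2) stop_ehc("variance weight needs >= 2 components (got %d)", n)
  sum((p - mean(p))^2) / (n - 1)
}

#' Variance-weighted distance between two records
#'
#' The enhanced clustering distance: the Euclidean distance scaled by the
#' reciprocal of a variance weight.  In `"as_printed"` mode the weight is the
#' first record's own variance `v(p)`, which is asymmetric in (p, q); the
#' default `"mean_variance"` mode uses the mean of `v(p)` and `v(q)` so that
#' the proximity matrix is symmetric, as agglomerative clustering requires.
#' When the applicable variance is zero the function falls back to the plain
#' Euclidean distance with a warning (constant records must not crash
#' clustering).
#'
#' @param p,q Numeric vectors of equal length >= 2.
#' @param symmetrization `"mean_variance"` (default) or `"as_printed"`.
#' @return Nonnegative distance.
#' @export
weighted_distance <- function(p, q,
                              symmetrization = c("mean_variance", "as_printed")) {
  symmetrization <- match.arg(symmetrization)
  if (length(p) != length(q)) {
    stop_ehc("dimension mismatch: |p|=%d, |q|=%d", length(p), length(q))
  }
  eu <- euclidean_distance(p, q)
  v <- if (symmetrization == "as_printed") {
    variance_weight(p)
  } else {
    (variance_weight(p) + variance_weight(q)) / 2
  }
  if (v == 0) {
    warning("zero variance weight; falling back to Euclidean distance",
            call. = FALSE)
    return(eu)
  }
  eu / v
}

#' Pairwise proximity matrix of a dataset
#'
#' Computes the full M x M matrix of pairwise distances between records, the
#' input to agglomerative clustering.
#'
#' @param d An `hb_dataset` (or numeric matrix) with continuous attributes
#'   only; >= 2 records.
#' @param distance_kind `"euclidean"` (HC) or `"weighted"` (EHC).
#' @param symmetrization For the weighted distance: `"mean_variance"`
#'   (default, symmetric) or `"as_printed"` (asymmetric single-record
#'   variance).
#' @return An `hb_proximity` object: `entries` (M x M), `distance_kind`,
#'   `symmetrization`.
#' @export
proximity_matrix <- function(d,
                             distance_kind = c("euclidean", "weighted"),
                             symmetrization = c("mean_variance", "as_printed")) {
  distance_kind <- match.arg(distance_kind)
  symmetrization <- match.arg(symmetrization)
  X <- if (inherits(d, "hb_dataset")) as_matrix(d) else as.matrix(d)
  n <- nrow(X)
  if (n < 2) stop_ehc("proximity matrix needs >= 2 records")
  E <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    di <- sqrt(colSums((t(X[js, , drop = FALSE]) - X[i, ])^2))
    E[i, js] <- di
    E[js, i] <- di
  }
  if (distance_kind == "weighted") {
    v <- apply(X, 1, variance_weight)
    if (symmetrization == "mean_variance") {
      W <- (outer(v, v, "+")) / 2
    } else {
      W <- matrix(v, n, n)  # row i scaled by v(p_i)
    }
    zero <- W == 0
    if (any(zero & row(W) != col(W))) {
      warning("zero variance weight; falling back to Euclidean distance",
              call. = FALSE)
    }
    D <- E
    D[!zero] <- E[!zero] / W[!zero]
    E <- D
  }
  structure(list(entries = E, distance_kind = distance_kind,
                 symmetrization = symmetrization),
            class = "hb_proximity")
}

#' Write a proximity matrix as square CSV
#' @param pm An `hb_proximity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proximity <- function(pm, path) {
  m <- as.data.frame(pm$entries)
  names(m) <- seq_len(ncol(m))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
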