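#' Agglomerative hierarchical clustering over a proximity matrix
#'
#' Bottom-up clustering: every record starts as its own cluster; at each step
#' the globally closest pair under the linkage rule is merged, until a single
#' cluster remains.  Inter-cluster distances are maintained by the
#' Lance-Williams updates (single = min, complete = max, average =
#' size-weighted mean, which equals the mean over all cross pairs).
#'
#' Cluster ids: leaves are `1..n`; each merge creates id `n+1, n+2, ...` in
#' merge order.  If several pairs tie at the minimal distance, the pair with
#' the lexicographically smallest `(left_id, right_id)` is merged, which makes
#' the procedure fully deterministic.
#'
#' @param pm An `hb_proximity` (or plain symmetric matrix with zero
#'   diagonal), n >= 2.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return An `hb_dendrogram`: `merges` data frame (`left`, `right`,
#'   `height`, `new_id`), `leaf_count`, `linkage`.
#' @export
agglomerate <- function(pm, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  D <- if (inherits(pm, "hb_proximity")) pm$entries else as.matrix(pm)
  n <- nrow(D)
  if (n < 2) stop_ehc("need >= 2 records to cluster")
  if (ncol(D) != n || max(abs(D - t(D))) > 1e-8) {
    stop_ehc("proximity matrix must be symmetric (use symmetrization = 'mean_variance')")
  }
  if (any(diag(D) != 0)) stop_ehc("proximity matrix must have a zero diagonal")
  if (any(D < 0) || any(!is.finite(D))) {
    stop_ehc("proximity entries must be finite and nonnegative")
  }

  ids <- seq_len(n)       # current cluster id at each active position
  sizes <- rep(1L, n)
  W <- D
  diag(W) <- Inf
  merges <- data.frame(left = integer(n - 1), right = integer(n - 1),
                       height = numeric(n - 1), new_id = integer(n - 1))
  for (step in seq_len(n - 1)) {
    m <- min(W)
    cand <- which(W == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie rule: smallest (left_id, right_id) lexicographically
    lid <- pmin(ids[cand[, 1]], ids[cand[, 2]])
    rid <- pmax(ids[cand[, 1]], ids[cand[, 2]])
    pick <- order(lid, rid)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- min(ids[i], ids[j]); ri <- max(ids[i], ids[j])
    merges$left[step] <- li
    merges$right[step] <- ri
    merges$height[step] <- m
    merges$new_id[step] <- n + step

    if (length(ids) > 2) {
      others <- setdiff(seq_along(ids), c(i, j))
      dnew <- switch(linkage,
        single   = pmin(W[i, others], W[j, others]),
        complete = pmax(W[i, others], W[j, others]),
        average  = (sizes[i] * W[i, others] + sizes[j] * W[j, others]) /
                   (sizes[i] + sizes[j]))
      W[i, others] <- dnew
      W[others, i] <- dnew
    }
    ids[i] <- n + step
    sizes[i] <- sizes[i] + sizes[j]
    keep <- setdiff(seq_along(ids), j)
    ids <- ids[keep]; sizes <- sizes[keep]
    W <- W[keep, keep, drop = FALSE]
  }
  structure(list(merges = merges, leaf_count = n, linkage = linkage),
            class = "hb_dendrogram")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges, leaving exactly `k` nonempty clusters.
#' Cluster labels are renumbered `1..k` in order of each cluster's smallest
#' leaf index.
#'
#' @param dg An `hb_dendrogram`.
#' @param k Number of clusters, `1 <= k <= leaf_count`.
#' @return Integer vector of per-record cluster labels in `1..k`.
#' @export
cut_dendrogram <- function(dg, k) {
  n <- dg$leaf_count
  if (k < 1 || k > n) stop_ehc("k must be in [1, %d]", n)
  ids <- seq_len(n)
  nm <- n - k
  for (t in seq_len(nm)) {
    hit <- ids == dg$merges$left[t] | ids == dg$merges$right[t]
    ids[hit] <- dg$merges$new_id[t]
  }
  # renumber by smallest member leaf index
  first <- vapply(unique(ids), function(g) min(which(ids == g)), 0L)
  ord <- unique(ids)[order(first)]
  match(ids, ord)
}

#' Fit a cluster model on training data
#'
#' Runs the full clustering stage: proximity matrix under the chosen distance
#' (Euclidean for HC, variance-weighted for EHC), agglomeration, cut at `k`,
#' and per-cluster centroid representatives (exact means of member records).
#'
#' @param train An `hb_dataset` with continuous attributes.
#' @param distance_kind `"euclidean"` or `"weighted"`.
#' @param linkage Linkage rule (default `"average"`).
#' @param k Number of clusters (default: number of classes).
#' @param symmetrization Weighted-distance symmetrization mode.
#' @return An `hb_cluster_model`: `k`, `labels`, `representatives` (k x p
#'   matrix), `distance_kind`, `symmetrization`, `linkage`, `attr_names`.
#' @export
fit_cluster_model <- function(train,
                              distance_kind = c("euclidean", "weighted"),
                              linkage = c("average", "single", "complete"),
                              k = length(train$class_names),
                              symmetrization = c("mean_variance", "as_printed")) {
  distance_kind <- match.arg(distance_kind)
  linkage <- match.arg(linkage)
  symmetrization <- match.arg(symmetrization)
  X <- as_matrix(train)
  if (k > nrow(X)) stop_ehc("k (%d) exceeds training size (%d)", k, nrow(X))
  labels <- if (k == nrow(X)) {
    seq_len(nrow(X))
  } else {
    pm <- proximity_matrix(train, distance_kind, symmetrization)
    cut_dendrogram(agglomerate(pm, linkage), k)
  }
  reps <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(X[labels == g, , drop = FALSE])
  }))
  rownames(reps) <- paste0("c", seq_len(k))
  structure(list(k = k, labels = labels, representatives = reps,
                 distance_kind = distance_kind,
                 symmetrization = symmetrization, linkage = linkage,
                 attr_names = colnames(X)),
            class = "hb_cluster_model")
}

#' Assign a record to its nearest cluster representative
#'
#' Test-time counterpart of [fit_cluster_model()]: returns the index of the
#' representative minimizing the model's configured distance; ties break to
#' the lowest cluster index.
#'
#' @param cm An `hb_cluster_model`.
#' @param x Numeric vector with one value per clustered attribute.
#' @return Cluster index in `1..k`.
#' @export
assign_cluster <- function(cm, x) {
  if (length(x) != ncol(cm$representatives)) {
    stop_ehc("dimension mismatch: record has %d values, model expects %d",
             length(x), ncol(cm$representatives))
  }
  d <- vapply(seq_len(cm$k), function(g) {
    r <- cm$representatives[g, ]
    if (cm$distance_kind == "euclidean") {
      euclidean_distance(x, r)
    } else {
      suppressWarnings(weighted_distance(x, r, cm$symmetrization))
    }
  }, 0)
  which.min(d)
}

#' Assign every record of a dataset to a cluster
#' @param cm An `hb_cluster_model`.
#' @param d An `hb_dataset` (only the model's attributes are used).
#' @return Integer vector of cluster indices.
#' @export
assign_clusters <- function(cm, d) {
  X <- if (inherits(d, "hb_dataset")) {
    as.matrix(d$x[, cm$attr_names, drop = FALSE])
  } else {
    as.matrix(d)
  }
  vapply(seq_len(nrow(X)), function(i) assign_cluster(cm, X[i, ]), 0L)
}

#' Append the cluster assignment as a nominal feature
#'
#' The bridge between the clustering and forest stages: adds one nominal
#' attribute holding each record's cluster, making the hierarchy structure
#' available to the forest.  Training data should be augmented with the
#' fitted labels (`labels = cm$labels`); held-out data is assigned by nearest
#' representative.
#'
#' @param d An `hb_dataset`.
#' @param cm An `hb_cluster_model`.
#' @param labels Optional precomputed integer labels (e.g. the model's fitted
#'   training labels); computed via [assign_clusters()] when omitted.
#' @param name Name for the appended attribute (default `"cluster"`); if the
#'   name is taken, a uniquified name is used with a warning.
#' @return The dataset with one extra nominal attribute.
#' @export
augment <- function(d, cm, labels = NULL, name = "cluster") {
  if (is.null(labels)) labels <- assign_clusters(cm, d)
  stopifnot(length(labels) == n_records(d))
  if (name %in% names(d$x)) {
    new <- make.unique(c(names(d$x), name))[ncol(d$x) + 1]
    warning(sprintf("attribute '%s' already present; appending '%s'",
                    name, new), call. = FALSE)
    name <- new
  }
  out <- d
  out$x[[name]] <- factor(paste0("c", labels), levels = paste0("c", seq_len(cm$k)))
  out$schema <- rbind(out$schema, data.frame(
    name = name, description = "hierarchical cluster assignment",
    unit = "", kind = "nominal", stringsAsFactors = FALSE))
  out
}

#' Export a dendrogram's merge table as CSV
#' @param dg An `hb_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dg, path) {
  utils::write.csv(dg$merges, path, row.names = FALSE)
  invisible(path)
}

#' Render a dendrogram as Newick-style nested text
#' @param dg An `hb_dendrogram`.
#' @return A single Newick string (leaf labels are record indices, branch
#'   annotations are merge heights).
#' @export
dendrogram_newick <- function(dg) {
  n <- dg$leaf_count
  txt <- as.character(seq_len(n))
  for (t in seq_len(n - 1)) {
    l <- dg$merges$left[t]; r <- dg$merges$right[t]
    txt[dg$merges$new_id[t]] <- sprintf("(%s,%s):%g", txt[l], txt[r],
                                        dg$merges$height[t])
  }
  paste0(txt[2 * n - 1], ";")
}
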