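#' Bootstrap resample of the training set
#'
#' Draws M records with replacement from an M-record training set (forest-RI
#' step: the training set for each tree is picked M times with substitution);
#' the records never drawn form the out-of-bag (OOB) set used for internal
#' error estimation.
#'
#' @param train An `hb_dataset` (or a single integer M).
#' @param seed Integer seed.
#' @return List with `sample` (M drawn indices, in draw order) and `oob`
#'   (sorted indices never drawn).
#' @export
bootstrap_sample <- function(train, seed) {
  M <- if (inherits(train, "hb_dataset")) n_records(train) else as.integer(train)
  if (M < 1) stop_ehc("need at least one training record")
  idx <- with_seed(seed, sample.int(M, M, replace = TRUE))
  list(sample = idx, oob = setdiff(seq_len(M), idx))
}

#' Gini impurity of a class-count vector
#'
#' `1 - sum((c_i / sum(c))^2)`; the node splitting criterion for the CART
#' learner.
#'
#' @param counts Nonnegative counts with positive sum.
#' @return Impurity in `[0, 1 - 1/K]`.
#' @export
gini_impurity <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) stop_ehc("gini impurity undefined for zero total count")
  1 - sum((counts / tot)^2)
}

# ---- internal column representation -----------------------------------------
# each attribute becomes list(kind, values) where nominal values are integer
# level codes (NA = unseen level at prediction time)
prep_columns <- function(x, template = NULL) {
  cols <- vector("list", ncol(x))
  names(cols) <- names(x)
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]])) {
      cols[[j]] <- list(kind = "continuous", values = as.numeric(x[[j]]))
    } else {
      lv <- if (!is.null(template)) template[[j]]$levels else levels(factor(x[[j]]))
      cols[[j]] <- list(kind = "nominal",
                        values = match(as.character(x[[j]]), lv),
                        levels = lv)
    }
  }
  cols
}

# weighted Gini of a left/right count split; rows of `left` are candidate
# splits, `total` the node counts
split_impurity <- function(left, total) {
  right <- sweep(left, 2, total, function(a, b) b - a)
  nl <- rowSums(left); nr <- rowSums(right)
  gl <- 1 - rowSums((left / pmax(nl, 1))^2)
  gr <- 1 - rowSums((right / pmax(nr, 1))^2)
  (nl * gl + nr * gr) / (nl + nr)
}

# best CART split of one attribute within a node; returns NULL if the
# attribute cannot split the node
best_split_cart <- function(col, idx, yk, K) {
  if (col$kind == "continuous") {
    xv <- col$values[idx]
    o <- order(xv)
    xs <- xv[o]; ys <- yk[o]
    m <- length(xs)
    bnd <- which(xs[-m] < xs[-1])
    if (!length(bnd)) return(NULL)
    cum <- apply(vapply(seq_len(K), function(k) as.numeric(ys == k),
                        numeric(m)), 2, cumsum)
    left <- cum[bnd, , drop = FALSE]
    imp <- split_impurity(left, cum[m, ])
    b <- which.min(imp)  # first minimum = lowest threshold
    list(kind = "continuous", threshold = (xs[bnd[b]] + xs[bnd[b] + 1]) / 2,
         impurity = imp[b])
  } else {
    cv <- col$values[idx]
    present <- sort(unique(cv))
    if (length(present) < 2) return(NULL)
    total <- vapply(seq_len(K), function(k) sum(yk == k), 0)
    left <- do.call(rbind, lapply(present, function(v) {
      vapply(seq_len(K), function(k) sum(yk == k & cv == v), 0)
    }))
    imp <- split_impurity(left, total)
    b <- which.min(imp)  # first minimum = lowest level code
    list(kind = "nominal", left_levels = present[b], impurity = imp[b])
  }
}

# randomized-tree candidate: one uniform-random threshold (or random level)
# per attribute; draws from the current RNG stream
best_split_random <- function(col, idx, yk, K) {
  if (col$kind == "continuous") {
    xv <- col$values[idx]
    rng <- range(xv)
    if (rng[1] >= rng[2]) return(NULL)
    thr <- stats::runif(1, rng[1], rng[2])
    left_mask <- xv <= thr
    if (!any(left_mask) || all(left_mask)) return(NULL)
    left <- matrix(vapply(seq_len(K), function(k) sum(yk == k & left_mask), 0), 1)
    total <- vapply(seq_len(K), function(k) sum(yk == k), 0)
    list(kind = "continuous", threshold = thr,
         impurity = split_impurity(left, total)[1])
  } else {
    cv <- col$values[idx]
    present <- sort(unique(cv))
    if (length(present) < 2) return(NULL)
    v <- present[sample.int(length(present), 1)]
    left_mask <- cv == v
    left <- matrix(vapply(seq_len(K), function(k) sum(yk == k & left_mask), 0), 1)
    total <- vapply(seq_len(K), function(k) sum(yk == k), 0)
    list(kind = "nominal", left_levels = v,
         impurity = split_impurity(left, total)[1])
  }
}

grow_node <- function(cols, y, idx, mtry, variant, K, depth, max_depth) {
  counts <- tabulate(y[idx], K)
  if (sum(counts > 0) <= 1 || depth >= max_depth) {
    return(list(leaf = TRUE, counts = counts))
  }
  N <- length(cols)
  yk <- y[idx]
  find_best <- function(attrs) {
    best <- NULL
    for (a in attrs) {   # ascending attribute index: ties keep the lowest
      s <- if (variant == "cart") {
        best_split_cart(cols[[a]], idx, yk, K)
      } else {
        best_split_random(cols[[a]], idx, yk, K)
      }
      if (!is.null(s) && (is.null(best) || s$impurity < best$impurity)) {
        best <- c(s, list(attr = a))
      }
    }
    best
  }
  cand <- sort(sample.int(N, mtry))
  best <- find_best(cand)
  if (is.null(best)) {
    # the sampled attributes cannot separate this impure node; fall back to
    # scanning the remaining attributes so a full-depth tree stays pure
    best <- find_best(setdiff(seq_len(N), cand))
  }
  if (is.null(best)) return(list(leaf = TRUE, counts = counts))

  col <- cols[[best$attr]]
  left_mask <- if (best$kind == "continuous") {
    col$values[idx] <= best$threshold
  } else {
    col$values[idx] %in% best$left_levels
  }
  list(leaf = FALSE, attr = best$attr, kind = best$kind,
       threshold = if (best$kind == "continuous") best$threshold else NULL,
       left_levels = if (best$kind == "nominal") best$left_levels else NULL,
       n_left = sum(left_mask), n_right = sum(!left_mask),
       left = grow_node(cols, y, idx[left_mask], mtry, variant, K,
                        depth + 1, max_depth),
       right = grow_node(cols, y, idx[!left_mask], mtry, variant, K,
                         depth + 1, max_depth))
}

#' Grow a single decision tree
#'
#' Implements the per-tree step of forest-RI: at every node, `mtry` of the N
#' input attributes are drawn at random (`mtry < N`); the CART learner
#' (`variant = "cart"`) takes the Gini-minimizing exhaustive split among
#' them, while the randomized learner (`variant = "random"`) evaluates one
#' uniform-random threshold per candidate attribute and keeps the best.
#' Trees are grown to the maximum extent with no pruning (a node stops only
#' when pure, at `max_depth`, or unsplittable).  Leaves store class counts.
#'
#' @param sample An `hb_dataset` (typically a bootstrap sample).
#' @param mtry Number of candidate attributes per node, `1 <= mtry < N`.
#' @param variant `"cart"` or `"random"`.
#' @param seed Integer seed for attribute sampling and random thresholds.
#' @param max_depth Optional depth cap (default unlimited).
#' @return An `hb_tree` (nested node list plus metadata).
#' @export
grow_tree <- function(sample, mtry, variant = c("cart", "random"), seed = 1,
                      max_depth = Inf) {
  variant <- match.arg(variant)
  N <- ncol(sample$x)
  if (mtry < 1 || mtry >= N) {
    stop_ehc("mtry must satisfy 1 <= mtry < N (got mtry=%d, N=%d)", mtry, N)
  }
  if (n_records(sample) < 1) stop_ehc("empty training sample")
  cols <- prep_columns(sample$x)
  y <- as.integer(sample$y)
  K <- length(sample$class_names)
  root <- with_seed(seed, grow_node(cols, y, seq_along(y), mtry, variant, K,
                                    0, max_depth))
  structure(list(root = root, class_names = sample$class_names,
                 attr_names = names(sample$x),
                 columns = lapply(cols, function(cl) cl[setdiff(names(cl), "values")]),
                 variant = variant, mtry = mtry, seed = seed),
            class = "hb_tree")
}

# vectorized routing of records through one tree; returns n x K probabilities
predict_node <- function(node, cols, idx, out) {
  if (node$leaf) {
    out[idx, ] <- matrix(node$counts / sum(node$counts), length(idx),
                         length(node$counts), byrow = TRUE)
    return(out)
  }
  v <- cols[[node$attr]]$values[idx]
  left_mask <- if (node$kind == "continuous") {
    v <= node$threshold
  } else {
    !is.na(v) & v %in% node$left_levels
  }
  # unseen nominal level (NA code): route to the child that held the
  # majority of this node's training mass (ties to the left)
  if (node$kind == "nominal" && anyNA(v)) {
    left_mask[is.na(v)] <- node$n_left >= node$n_right
  }
  if (any(left_mask)) out <- predict_node(node$left, cols, idx[left_mask], out)
  if (any(!left_mask)) out <- predict_node(node$right, cols, idx[!left_mask], out)
  out
}

#' Class-probability prediction of a single tree
#'
#' Routes each record from the root down to a terminal node and returns that
#' leaf's class counts normalized to probabilities.
#'
#' @param tree An `hb_tree`.
#' @param newdata An `hb_dataset`, data frame, or a single numeric vector.
#' @return Matrix of class probabilities (records x classes).
#' @export
tree_predict <- function(tree, newdata) {
  x <- tree_input_frame(tree$attr_names, newdata)
  cols <- prep_columns(x, template = tree$columns)
  K <- length(tree$class_names)
  out <- matrix(0, nrow(x), K, dimnames = list(NULL, tree$class_names))
  predict_node(tree$root, cols, seq_len(nrow(x)), out)
}

tree_input_frame <- function(attr_names, newdata) {
  if (inherits(newdata, "hb_dataset")) {
    newdata <- newdata$x
  } else if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- as.data.frame(as.list(stats::setNames(newdata, attr_names)))
  }
  missing <- setdiff(attr_names, names(newdata))
  if (length(missing)) {
    stop_ehc("missing attribute(s): %s", paste(missing, collapse = ", "))
  }
  as.data.frame(newdata)[, attr_names, drop = FALSE]
}

#' Fit a random decision forest
#'
#' Grows `n_trees` trees, each on its own bootstrap sample of the training
#' set, with `mtry` random candidate attributes per node.  `variant = "cart"`
#' is the plain random forest (RF); `variant = "random"` is the improved
#' forest (ERF) whose learner uses random split thresholds.  All per-tree
#' randomness derives deterministically from `seed`.
#'
#' @param train An `hb_dataset` with >= 2 classes present.
#' @param n_trees Forest size F (default 100).
#' @param mtry Candidate attributes per node (default `floor(sqrt(N))`).
#' @param variant `"cart"` or `"random"`.
#' @param seed Integer master seed.
#' @param max_depth Optional depth cap (default unlimited; the reference
#'   procedure grows trees to the maximum extent with no pruning).
#' @return An `hb_forest`: `trees`, `bootstrap_indices`, config fields,
#'   `class_names`.
#' @export
fit_forest <- function(train, n_trees = 100, mtry = NULL,
                       variant = c("cart", "random"), seed = 1,
                       max_depth = Inf) {
  variant <- match.arg(variant)
  if (n_trees < 1) stop_ehc("n_trees must be >= 1")
  if (length(unique(as.character(train$y))) < 2) {
    stop_ehc("training data must contain >= 2 classes")
  }
  N <- ncol(train$x)
  if (is.null(mtry)) mtry <- max(1L, min(N - 1L, floor(sqrt(N))))
  trees <- vector("list", n_trees)
  bsi <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    bs <- bootstrap_sample(train, derive_seed(seed, "bootstrap", t))
    bsi[[t]] <- bs$sample
    trees[[t]] <- grow_tree(dataset_subset(train, bs$sample), mtry, variant,
                            seed = derive_seed(seed, "tree", t),
                            max_depth = max_depth)
  }
  structure(list(trees = trees, bootstrap_indices = bsi, n_trees = n_trees,
                 mtry = mtry, variant = variant, seed = seed,
                 max_depth = max_depth, class_names = train$class_names,
                 attr_names = names(train$x)),
            class = "hb_forest")
}

# majority-vote label with the documented tie-breaks: most per-tree hard
# votes; ties -> larger averaged probability; then lexicographic class order
vote_labels <- function(votes, avg_prob, class_names) {
  n <- nrow(votes)
  lab <- integer(n)
  lex <- order(class_names)
  for (i in seq_len(n)) {
    tied <- which(votes[i, ] == max(votes[i, ]))
    if (length(tied) > 1) {
      tied <- tied[avg_prob[i, tied] == max(avg_prob[i, tied])]
      if (length(tied) > 1) tied <- tied[order(match(tied, lex))][1]
    }
    lab[i] <- tied[1]
  }
  factor(class_names[lab], levels = class_names)
}

#' Forest prediction: averaged probabilities and majority-vote labels
#'
#' The finite-forest estimate is the arithmetic mean of the individual trees'
#' probability vectors; the predicted label is the class with the most
#' per-tree hard votes (each tree votes for its own argmax), the multi-class
#' generalization of the binary majority-vote rule.  Vote ties break to the
#' larger averaged probability, then to lexicographic class order.
#'
#' @param forest An `hb_forest`.
#' @param newdata An `hb_dataset` or data frame.
#' @return List: `labels` (factor) and `prob` (records x classes matrix).
#' @export
forest_predict <- function(forest, newdata) {
  x <- tree_input_frame(forest$attr_names, newdata)
  K <- length(forest$class_names)
  n <- nrow(x)
  prob_sum <- matrix(0, n, K)
  votes <- matrix(0L, n, K)
  for (tr in forest$trees) {
    p <- tree_predict(tr, x)
    prob_sum <- prob_sum + p
    hard <- max.col(p, ties.method = "first")
    votes[cbind(seq_len(n), hard)] <- votes[cbind(seq_len(n), hard)] + 1L
  }
  avg <- prob_sum / forest$n_trees
  colnames(avg) <- forest$class_names
  list(labels = vote_labels(votes, avg, forest$class_names), prob = avg)
}

#' Out-of-bag error of a forest
#'
#' For each training record, aggregates votes only from trees whose bootstrap
#' sample excluded it; the OOB error is the misclassified fraction among
#' records with at least one such vote.  This is the internal, unbiased
#' generalization-error estimate of forest-RI.
#'
#' @param forest An `hb_forest`.
#' @param train The training `hb_dataset` the forest was fitted on.
#' @return OOB error in `[0, 1]`, or `NA` (with a warning) when no record
#'   has OOB coverage.
#' @export
oob_error <- function(forest, train) {
  x <- tree_input_frame(forest$attr_names, train)
  M <- nrow(x)
  K <- length(forest$class_names)
  votes <- matrix(0L, M, K)
  prob_sum <- matrix(0, M, K)
  n_oob <- integer(M)
  for (t in seq_along(forest$trees)) {
    oob <- setdiff(seq_len(M), forest$bootstrap_indices[[t]])
    if (!length(oob)) next
    p <- tree_predict(forest$trees[[t]], x[oob, , drop = FALSE])
    hard <- max.col(p, ties.method = "first")
    votes[cbind(oob, hard)] <- votes[cbind(oob, hard)] + 1L
    prob_sum[oob, ] <- prob_sum[oob, ] + p
    n_oob[oob] <- n_oob[oob] + 1L
  }
  covered <- n_oob > 0
  if (!any(covered)) {
    warning("no record has out-of-bag coverage; OOB error undefined",
            call. = FALSE)
    return(NA_real_)
  }
  avg <- prob_sum[covered, , drop = FALSE] / n_oob[covered]
  lab <- vote_labels(votes[covered, , drop = FALSE], avg, forest$class_names)
  mean(as.character(lab) != as.character(train$y[covered]))
}
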