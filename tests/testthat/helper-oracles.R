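# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

# term-by-term Euclidean accumulation
oracle_euclidean <- function(p, q) {
  acc <- 0
  for (j in seq_along(p)) acc <- acc + (p[j] - q[j])^2
  sqrt(acc)
}

oracle_variance <- function(p) {
  m <- 0
  for (v in p) m <- m + v
  m <- m / length(p)
  acc <- 0
  for (v in p) acc <- acc + (v - m)^2
  acc / (length(p) - 1)
}

oracle_weighted <- function(p, q, mode) {
  v <- if (mode == "as_printed") {
    oracle_variance(p)
  } else {
    (oracle_variance(p) + oracle_variance(q)) / 2
  }
  if (v == 0) oracle_euclidean(p, q) else oracle_euclidean(p, q) / v
}

# O(n^3) agglomeration: keeps explicit membership lists and recomputes every
# inter-cluster distance from the point-level matrix at each step
oracle_agglomerate <- function(D, linkage) {
  n <- nrow(D)
  members <- as.list(seq_len(n))   # position -> leaf members
  ids <- seq_len(n)
  merges <- NULL
  cluster_dist <- function(a, b) {
    vals <- as.vector(D[members[[a]], members[[b]], drop = FALSE])
    switch(linkage, single = min(vals), complete = max(vals),
           average = mean(vals))
  }
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (a in seq_len(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        dd <- cluster_dist(a, b)
        li <- min(ids[a], ids[b]); ri <- max(ids[a], ids[b])
        better <- is.null(best) || dd < best$d ||
          (dd == best$d && (li < best$l || (li == best$l && ri < best$r)))
        if (better) best <- list(a = a, b = b, d = dd, l = li, r = ri)
      }
    }
    merges <- rbind(merges, data.frame(left = best$l, right = best$r,
                                       height = best$d, new_id = n + step))
    members[[best$a]] <- c(members[[best$a]], members[[best$b]])
    ids[best$a] <- n + step
    members[[best$b]] <- NULL
    ids <- ids[-best$b]
  }
  merges
}

# per-record OOB recount from first principles
oracle_oob <- function(forest, train) {
  M <- n_records(train)
  K <- length(forest$class_names)
  wrong <- 0; covered <- 0
  for (i in seq_len(M)) {
    votes <- rep(0, K); psum <- rep(0, K); nt <- 0
    for (t in seq_along(forest$trees)) {
      if (i %in% forest$bootstrap_indices[[t]]) next
      p <- as.numeric(tree_predict(forest$trees[[t]],
                                   dataset_subset(train, i)))
      votes[which.max(p)] <- votes[which.max(p)] + 1
      psum <- psum + p
      nt <- nt + 1
    }
    if (nt == 0) next
    covered <- covered + 1
    mx <- which(votes == max(votes))
    if (length(mx) > 1) {
      avg <- psum[mx] / nt
      mx <- mx[avg == max(avg)]
      if (length(mx) > 1) mx <- mx[order(forest$class_names[mx])][1]
    }
    if (forest$class_names[mx[1]] != as.character(train$y[i])) wrong <- wrong + 1
  }
  wrong / covered
}
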