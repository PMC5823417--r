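#' Configuration of one model variant
#'
#' The five variants differ in the learner and in the clustering stage:
#' \describe{
#'   \item{RF}{random forest with the CART learner, no clustering}
#'   \item{ERF}{improved forest with the randomized-tree learner, no clustering}
#'   \item{HC-RF}{Euclidean hierarchical clustering feeding RF}
#'   \item{HC-ERF}{Euclidean hierarchical clustering feeding ERF}
#'   \item{EHC-ERF}{variance-weighted (enhanced) clustering feeding ERF}
#' }
#' The clustering distance is implied by the variant and cannot be
#' overridden; passing clustering parameters for a plain RF/ERF variant is a
#' validation error.
#'
#' @param variant One of `"RF"`, `"ERF"`, `"HC-RF"`, `"HC-ERF"`, `"EHC-ERF"`.
#' @param n_trees Forest size F (default 100).
#' @param mtry Candidate attributes per node (default `floor(sqrt(N))`).
#' @param seed Integer seed for forest randomness.
#' @param k Number of clusters (clustered variants only; default: number of
#'   classes).
#' @param linkage Linkage rule (clustered variants only; default
#'   `"average"`).
#' @param symmetrization Weighted-distance symmetrization (EHC only).
#' @param max_depth Optional tree depth cap (default unlimited).
#' @param discretize_bins Optional equal-frequency bin count: when set, the
#'   continuous attributes are discretized for the forest stage only
#'   (clustering always uses the original continuous values).
#' @return An `hb_variant_config`.
#' @export
variant_config <- function(variant = c("RF", "ERF", "HC-RF", "HC-ERF", "EHC-ERF"),
                           n_trees = 100, mtry = NULL, seed = 1,
                           k = NULL, linkage = NULL, symmetrization = NULL,
                           max_depth = Inf, discretize_bins = NULL) {
  variant <- match.arg(variant)
  clustered <- variant %in% c("HC-RF", "HC-ERF", "EHC-ERF")
  if (!clustered && (!is.null(k) || !is.null(linkage) || !is.null(symmetrization))) {
    stop_ehc("clustering parameters are not valid for variant %s", variant)
  }
  if (clustered) {
    linkage <- linkage %||% "average"
    symmetrization <- symmetrization %||% "mean_variance"
  }
  structure(list(
    variant = variant,
    n_trees = as.integer(n_trees),
    mtry = mtry,
    seed = as.integer(seed),
    k = k,
    linkage = linkage,
    symmetrization = symmetrization,
    max_depth = max_depth,
    discretize_bins = discretize_bins,
    clustered = clustered,
    distance_kind = if (!clustered) NULL
                    else if (variant == "EHC-ERF") "weighted" else "euclidean",
    forest_variant = if (variant %in% c("RF", "HC-RF")) "cart" else "random"
  ), class = "hb_variant_config")
}

#' Fit one model variant on training data
#'
#' For clustered variants the training data is clustered (on its continuous
#' attributes), the fitted cluster labels are appended as a nominal feature,
#' and the forest is grown on the augmented table.  Plain variants grow the
#' forest directly.  Test records never enter this function, so cluster
#' representatives are computed from training data only.
#'
#' @param train Training `hb_dataset` (>= 2 classes).
#' @param cfg An `hb_variant_config`.
#' @return An `hb_fitted`: `cfg`, `cluster_model` (or `NULL`), `forest`,
#'   `disc_edges` (or `NULL`), `attr_names`.
#' @export
fit_model <- function(train, cfg) {
  stopifnot(inherits(cfg, "hb_variant_config"))
  if (length(unique(as.character(train$y))) < 2) {
    stop_ehc("training data must contain >= 2 classes")
  }
  cm <- NULL
  train2 <- train
  if (cfg$clustered) {
    k <- cfg$k %||% length(train$class_names)
    cm <- fit_cluster_model(train, distance_kind = cfg$distance_kind,
                            linkage = cfg$linkage, k = k,
                            symmetrization = cfg$symmetrization)
    train2 <- augment(train, cm, labels = cm$labels)
  }
  edges <- NULL
  if (!is.null(cfg$discretize_bins)) {
    train2 <- discretize(train2, cfg$discretize_bins)
    edges <- train2$provenance$discretization
  }
  forest <- fit_forest(train2, n_trees = cfg$n_trees, mtry = cfg$mtry,
                       variant = cfg$forest_variant, seed = cfg$seed,
                       max_depth = cfg$max_depth)
  structure(list(cfg = cfg, cluster_model = cm, forest = forest,
                 disc_edges = edges, attr_names = names(train$x)),
            class = "hb_fitted")
}

#' Evaluate a fitted model on held-out data
#'
#' Clustered variants first assign each test record to its nearest training
#' cluster representative; stored discretization edges (if any) are then
#' applied, and the forest's majority-vote labels and averaged probabilities
#' are scored with the seven-metric report.
#'
#' @param fitted An `hb_fitted`.
#' @param test An `hb_dataset` with the training schema (pre-augmentation).
#' @return An `hb_metrics` report.
#' @export
evaluate_model <- function(fitted, test) {
  if (!all(fitted$attr_names %in% names(test$x))) {
    stop_ehc("test schema does not match training schema")
  }
  test2 <- test
  if (!is.null(fitted$cluster_model)) {
    test2 <- augment(test, fitted$cluster_model)
  }
  if (!is.null(fitted$disc_edges)) {
    test2 <- apply_discretization(test2, fitted$disc_edges)
  }
  pred <- forest_predict(fitted$forest, test2)
  metrics_report(test$y, pred$labels, pred$prob, test$class_names,
                 model_tag = fitted$cfg$variant, seed = fitted$cfg$seed)
}

#' Train and evaluate several variants on one shared split
#'
#' All variants see the identical train/test split; each variant's forest
#' seed derives deterministically from the shared seed and the variant name,
#' so the comparison is reproducible end to end.
#'
#' @param d Full `hb_dataset`.
#' @param cfgs List of `hb_variant_config`s (default: all five variants with
#'   default settings).
#' @param split_seed Master seed for the split and the per-variant streams.
#' @param fraction Train fraction (default 0.7).
#' @param stratified Stratify the split by class (default `TRUE`)?
#' @return An `hb_comparison`: `table` (metrics x variants data frame),
#'   `reports`, `split_seed`.
#' @export
compare_variants <- function(d, cfgs = default_variant_configs(),
                             split_seed = 1, fraction = 0.7,
                             stratified = TRUE) {
  if (!length(cfgs)) stop_ehc("need at least one variant configuration")
  sp <- split_dataset(d, fraction = fraction, seed = split_seed,
                      stratified = stratified)
  reports <- list()
  for (cfg in cfgs) {
    cfg$seed <- derive_seed(split_seed, "forest", cfg$variant)
    fit <- fit_model(sp$train, cfg)
    reports[[length(reports) + 1]] <- evaluate_model(fit, sp$test)
  }
  tags <- vapply(reports, function(r) r$model_tag, "")
  cols <- lapply(reports, function(r) {
    unname(vapply(metric_names(), function(m) r[[m]], 0))
  })
  tab <- data.frame(metric = metric_names(), stringsAsFactors = FALSE)
  tab <- cbind(tab, stats::setNames(as.data.frame(cols, check.names = FALSE,
                                                  optional = TRUE), tags))
  structure(list(table = tab, reports = reports, split_seed = split_seed,
                 fraction = fraction, stratified = stratified),
            class = "hb_comparison")
}

#' Default configurations of all five variants
#' @param n_trees Forest size shared by all variants.
#' @param max_depth Optional shared depth cap.
#' @return List of five `hb_variant_config`s.
#' @export
default_variant_configs <- function(n_trees = 100, max_depth = Inf) {
  lapply(c("RF", "ERF", "HC-RF", "HC-ERF", "EHC-ERF"), function(v) {
    variant_config(v, n_trees = n_trees, max_depth = max_depth)
  })
}

#' @export
print.hb_comparison <- function(x, ...) {
  cat(sprintf("<hb_comparison> split seed %d, fraction %.2f\n",
              x$split_seed, x$fraction))
  tab <- x$table
  for (j in seq(2, ncol(tab))) tab[[j]] <- sprintf("%.2f%%", 100 * tab[[j]])
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a comparison table as CSV (metrics in rows, variants in columns)
#' @param cmp An `hb_comparison` (or a compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_comparison <- function(cmp, path) {
  tab <- if (inherits(cmp, "hb_comparison")) cmp$table else cmp
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Repeated comparison across replicate seeds
#'
#' Regenerates data and re-splits under a sequence of seeds, producing the
#' seed-level metric spread of every variant.  Single 70/30 splits on a few
#' hundred records are high-variance, so means over replicates are the
#' honest summary.
#'
#' @param gen_cfg A `generator_config` template (its seed is re-derived per
#'   replicate).
#' @param cfgs List of variant configurations.
#' @param seeds Integer vector of replicate seeds.
#' @param metrics Which metrics to collect (default all seven).
#' @return List: `results` (long data frame seed x variant x metric values)
#'   and `summary` (mean and sd per variant and metric).
#' @export
variant_study <- function(gen_cfg, cfgs = default_variant_configs(),
                          seeds = 1:10, metrics = metric_names()) {
  rows <- list()
  for (s in seeds) {
    g <- gen_cfg
    g$seed <- derive_seed(s, "data")
    d <- generate_dataset(g)
    cmpr <- compare_variants(d, cfgs, split_seed = derive_seed(s, "split"))
    for (r in cmpr$reports) {
      vals <- stats::setNames(lapply(metrics, function(m) r[[m]]), metrics)
      rows[[length(rows) + 1]] <- data.frame(seed = s, variant = r$model_tag,
                                             vals, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(results, results$variant), function(g) {
    st <- unlist(lapply(metrics, function(m) c(mean(g[[m]]), stats::sd(g[[m]]))))
    data.frame(variant = g$variant[1], t(st))
  }))
  names(agg) <- c("variant", unlist(lapply(metrics, function(m) {
    paste0(m, c("_mean", "_sd"))
  })))
  rownames(agg) <- NULL
  list(results = results, summary = agg)
}
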