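# JSON persistence for fitted models.  Doubles are written with 17
# significant digits so a save/load cycle is bit-exact, and all output is
# deterministic: identical seeds and configuration give byte-identical files.

encode_node <- function(node) {
  if (node$leaf) return(list(leaf = TRUE, counts = as.integer(node$counts)))
  list(leaf = FALSE, attr = node$attr, kind = node$kind,
       threshold = node$threshold, left_levels = node$left_levels,
       n_left = node$n_left, n_right = node$n_right,
       left = encode_node(node$left), right = encode_node(node$right))
}

decode_node <- function(obj) {
  if (isTRUE(obj$leaf)) {
    return(list(leaf = TRUE, counts = as.integer(unlist(obj$counts))))
  }
  list(leaf = FALSE, attr = as.integer(obj$attr), kind = obj$kind,
       threshold = if (is.null(obj$threshold)) NULL else as.numeric(obj$threshold),
       left_levels = if (is.null(obj$left_levels)) NULL
                     else as.integer(unlist(obj$left_levels)),
       n_left = as.integer(obj$n_left), n_right = as.integer(obj$n_right),
       left = decode_node(obj$left), right = decode_node(obj$right))
}

encode_forest <- function(f) {
  list(n_trees = f$n_trees, mtry = f$mtry, variant = f$variant,
       seed = f$seed,
       max_depth = if (is.finite(f$max_depth)) f$max_depth else -1,
       class_names = f$class_names, attr_names = f$attr_names,
       bootstrap_indices = f$bootstrap_indices,
       trees = lapply(f$trees, function(tr) {
         list(root = encode_node(tr$root), seed = tr$seed,
              columns = tr$columns)
       }))
}

decode_forest <- function(obj) {
  class_names <- unlist(obj$class_names)
  attr_names <- unlist(obj$attr_names)
  columns_tpl <- function(cols) {
    lapply(cols, function(cl) {
      out <- list(kind = cl$kind)
      if (!is.null(cl$levels)) out$levels <- unlist(cl$levels)
      out
    })
  }
  trees <- lapply(obj$trees, function(tr) {
    structure(list(root = decode_node(tr$root), class_names = class_names,
                   attr_names = attr_names,
                   columns = stats::setNames(columns_tpl(tr$columns), attr_names),
                   variant = obj$variant, mtry = as.integer(obj$mtry),
                   seed = as.integer(tr$seed)),
              class = "hb_tree")
  })
  structure(list(trees = trees,
                 bootstrap_indices = lapply(obj$bootstrap_indices,
                                            function(i) as.integer(unlist(i))),
                 n_trees = as.integer(obj$n_trees),
                 mtry = as.integer(obj$mtry), variant = obj$variant,
                 seed = as.integer(obj$seed),
                 max_depth = if (obj$max_depth < 0) Inf else as.numeric(obj$max_depth),
                 class_names = class_names, attr_names = attr_names),
            class = "hb_forest")
}

encode_cluster_model <- function(cm) {
  if (is.null(cm)) return(NULL)
  list(k = cm$k, labels = cm$labels,
       representatives = apply(cm$representatives, 1, as.numeric,
                               simplify = FALSE),
       distance_kind = cm$distance_kind, symmetrization = cm$symmetrization,
       linkage = cm$linkage, attr_names = cm$attr_names)
}

decode_cluster_model <- function(obj) {
  if (is.null(obj)) return(NULL)
  reps <- do.call(rbind, lapply(obj$representatives, function(r) {
    as.numeric(unlist(r))
  }))
  colnames(reps) <- unlist(obj$attr_names)
  rownames(reps) <- paste0("c", seq_len(obj$k))
  structure(list(k = as.integer(obj$k),
                 labels = as.integer(unlist(obj$labels)),
                 representatives = reps, distance_kind = obj$distance_kind,
                 symmetrization = obj$symmetrization, linkage = obj$linkage,
                 attr_names = unlist(obj$attr_names)),
            class = "hb_cluster_model")
}

#' Save a fitted model (or a bare forest) as a JSON model file
#'
#' The file carries the full forest (trees and bootstrap indices), the
#' cluster model, the variant configuration and all seeds; reloading with
#' [load_model()] is bit-exact, and re-running the same fit produces a
#' byte-identical file.
#'
#' @param model An `hb_fitted` or `hb_forest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- if (inherits(model, "hb_forest")) {
    list(type = "forest", forest = encode_forest(model))
  } else {
    cfg <- model$cfg
    cfg$max_depth <- if (is.finite(cfg$max_depth)) cfg$max_depth else -1
    list(type = "fitted", cfg = unclass(cfg),
         cluster_model = encode_cluster_model(model$cluster_model),
         disc_edges = model$disc_edges,
         attr_names = model$attr_names,
         forest = encode_forest(model$forest))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a model file written by [save_model()]
#' @param path JSON model path.
#' @return An `hb_fitted` or `hb_forest`, bit-identical to the saved object.
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(obj$type, "forest")) return(decode_forest(obj$forest))
  cfg <- obj$cfg
  cfg$max_depth <- if (cfg$max_depth < 0) Inf else as.numeric(cfg$max_depth)
  cfg$n_trees <- as.integer(cfg$n_trees)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$k)) cfg$k <- as.integer(cfg$k)
  if (!is.null(cfg$mtry)) cfg$mtry <- as.integer(cfg$mtry)
  if (!is.null(cfg$discretize_bins)) {
    cfg$discretize_bins <- as.integer(cfg$discretize_bins)
  }
  class(cfg) <- "hb_variant_config"
  edges <- if (is.null(obj$disc_edges)) NULL else {
    lapply(obj$disc_edges, function(e) as.numeric(unlist(e)))
  }
  structure(list(cfg = cfg,
                 cluster_model = decode_cluster_model(obj$cluster_model),
                 forest = decode_forest(obj$forest),
                 disc_edges = edges,
                 attr_names = unlist(obj$attr_names)),
            class = "hb_fitted")
}
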