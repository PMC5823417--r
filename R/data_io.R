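#' The nine hepatobiliary laboratory attributes
#'
#' Returns the default attribute schema: nine continuous biomedical test
#' measurements routinely used to assess hepatobiliary disorders.
#'
#' @return A data frame with columns `name`, `description`, `unit`, `kind`.
#' @export
default_schema <- function() {
  data.frame(
    name = c("GOT", "GPT", "LDH", "GGT", "BUN", "MCV", "MCH", "TBIL", "CRTNN"),
    description = c(
      "Glutamic oxaloacetic transaminase",
      "Glutamic pyruvic transaminase",
      "Lactate dehydrogenase",
      "Gamma glutamyl transpeptidase",
      "Blood urea nitrogen",
      "Mean corpuscular volume of red blood cells",
      "Mean corpuscular hemoglobin",
      "Total bilirubin",
      "Creatinine"
    ),
    unit = c("Karmen unit", "Karmen unit", "iu/l", "mu/ml", "mg/dl",
             "fl", "pg", "mg/dl", "mg/dl"),
    kind = "continuous",
    stringsAsFactors = FALSE
  )
}

#' Default hepatobiliary disorder class labels
#' @return Character vector of the four diagnostic classes.
#' @export
default_classes <- function() {
  c("alcoholic_liver_damage", "primary_hepatoma",
    "liver_cirrhosis", "cholelithiasis")
}

#' Construct a tabular clinical dataset
#'
#' The basic container of the package: a table of attribute values (continuous
#' measurements, optionally nominal features such as cluster assignments or
#' discretized bins) together with a class label per record.
#'
#' @param x Data frame of attribute columns; numeric columns are treated as
#'   continuous, factor/character columns as nominal.
#' @param y Class labels, one per row of `x` (factor or character).
#' @param schema Optional attribute schema (`name`, `description`, `unit`,
#'   `kind`); built from `x` when omitted.
#' @param class_names Ordered class label set; defaults to the levels of `y`.
#' @param provenance Free-form list recording where the data came from.
#' @return An object of class `hb_dataset` with elements `x`, `y`, `schema`,
#'   `class_names`, `provenance`.
#' @export
hb_dataset <- function(x, y, schema = NULL, class_names = NULL,
                       provenance = list()) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (j in seq_along(x)) {
    if (is.character(x[[j]])) x[[j]] <- factor(x[[j]])
  }
  if (is.null(class_names)) {
    class_names <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  }
  y <- factor(as.character(y), levels = class_names)
  if (anyNA(y)) stop_ehc("class labels outside class_names")
  if (is.null(schema)) {
    schema <- data.frame(
      name = names(x),
      description = names(x),
      unit = "",
      kind = ifelse(vapply(x, is.numeric, TRUE), "continuous", "nominal"),
      stringsAsFactors = FALSE
    )
  }
  d <- structure(list(x = x, y = y, schema = schema,
                      class_names = class_names, provenance = provenance),
                 class = "hb_dataset")
  validate_dataset(d)
  d
}

validate_dataset <- function(d) {
  stopifnot(inherits(d, "hb_dataset"))
  if (ncol(d$x) != nrow(d$schema)) stop_ehc("schema/column count mismatch")
  if (!identical(names(d$x), d$schema$name)) stop_ehc("schema names mismatch")
  if (anyDuplicated(d$schema$name)) stop_ehc("duplicate attribute names")
  if (any(!nzchar(d$schema$name))) stop_ehc("empty attribute name")
  if (length(d$y) != nrow(d$x)) stop_ehc("label/record count mismatch")
  num <- vapply(d$x, is.numeric, TRUE)
  for (j in which(num)) {
    if (any(!is.finite(d$x[[j]]))) {
      stop_ehc("non-finite value in attribute '%s'", names(d$x)[j])
    }
  }
  invisible(d)
}

#' @export
print.hb_dataset <- function(x, ...) {
  cat(sprintf("<hb_dataset> %d records, %d attributes, %d classes\n",
              nrow(x$x), ncol(x$x), length(x$class_names)))
  cat("  attributes:", paste(x$schema$name, collapse = ", "), "\n")
  cat("  classes:   ", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of records in a dataset
#' @param d An `hb_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(d) nrow(d$x)

#' Subset a dataset by record index
#' @param d An `hb_dataset`.
#' @param idx Integer indices of the records to keep.
#' @return An `hb_dataset` with the selected records, same schema and classes.
#' @export
dataset_subset <- function(d, idx) {
  out <- d
  out$x <- d$x[idx, , drop = FALSE]
  rownames(out$x) <- NULL
  out$y <- d$y[idx]
  out
}

#' Attribute values as a numeric matrix
#'
#' Extracts the continuous attributes of a dataset as a numeric matrix, as
#' required by the distance and clustering stages.
#'
#' @param d An `hb_dataset`.
#' @param require_all_continuous Error if any nominal attribute is present
#'   (the distance functions are undefined on nominal codes).
#' @return Numeric matrix, records in rows.
#' @export
as_matrix <- function(d, require_all_continuous = TRUE) {
  num <- vapply(d$x, is.numeric, TRUE)
  if (require_all_continuous && !all(num)) {
    stop_ehc(paste0(
      "nominal attribute(s) present (%s): clustering distances are defined ",
      "on continuous values only; cluster before discretizing"),
      paste(names(d$x)[!num], collapse = ", "))
  }
  as.matrix(d$x[, num, drop = FALSE])
}

#' Read a dataset from CSV
#'
#' Reads a comma-separated file with a header row; every non-class column is
#' parsed as a continuous real-valued attribute.  If a JSON sidecar written by
#' [write_dataset()] sits next to the file it is used to restore the schema
#' (including nominal attribute kinds), class order and provenance.
#'
#' @param path CSV file path.
#' @param class_column Name of the class label column (default `"class"`).
#' @return An `hb_dataset`.
#' @export
read_dataset <- function(path, class_column = "class") {
  if (!file.exists(path)) stop_ehc("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) == 0) stop_ehc("empty input file: %s", path)
  if (!class_column %in% names(raw)) {
    stop_ehc("class column '%s' not found (columns: %s)",
             class_column, paste(names(raw), collapse = ", "))
  }
  y <- raw[[class_column]]
  x <- raw[, setdiff(names(raw), class_column), drop = FALSE]
  if (ncol(x) == 0) stop_ehc("no attribute columns in %s", path)

  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  } else NULL
  kinds <- if (!is.null(meta) && !is.null(meta$schema)) {
    meta$schema$kind[match(names(x), meta$schema$name)]
  } else rep("continuous", ncol(x))
  kinds[is.na(kinds)] <- "continuous"

  for (j in seq_along(x)) {
    if (kinds[j] == "continuous") {
      v <- x[[j]]
      blank <- !nzchar(trimws(v))
      num <- suppressWarnings(as.numeric(v))
      bad <- which(blank | is.na(num))
      if (length(bad)) {
        stop_ehc("cannot parse value '%s' as a number (row %d, column '%s')",
                 v[bad[1]], bad[1], names(x)[j])
      }
      x[[j]] <- num
    } else {
      x[[j]] <- factor(x[[j]])
    }
  }
  schema <- if (!is.null(meta) && !is.null(meta$schema)) {
    s <- as.data.frame(meta$schema, stringsAsFactors = FALSE)
    s[match(names(x), s$name), c("name", "description", "unit", "kind")]
  } else NULL
  class_names <- if (!is.null(meta)) meta$class_names else NULL
  prov <- if (!is.null(meta) && !is.null(meta$provenance)) {
    meta$provenance
  } else list(source = path)
  hb_dataset(x, y, schema = schema, class_names = class_names,
             provenance = prov)
}

#' Write a dataset to CSV (plus JSON sidecar)
#'
#' @param d An `hb_dataset`.
#' @param path Output CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @param class_column Name for the class column.
#' @param sidecar Write the JSON metadata sidecar (schema, class order,
#'   provenance, discretization edges if any)?
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, class_column = "class", sidecar = TRUE) {
  validate_dataset(d)
  tab <- d$x
  for (j in seq_along(tab)) {
    if (is.factor(tab[[j]])) tab[[j]] <- as.character(tab[[j]])
  }
  tab[[class_column]] <- as.character(d$y)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(schema = d$schema, class_names = d$class_names,
                 provenance = d$provenance)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(path)
}

#' Shuffle record order reproducibly
#'
#' @param d An `hb_dataset`.
#' @param seed Integer seed; the same seed always yields the same order.
#' @return The dataset with records in a seed-determined permutation.
#' @export
randomize <- function(d, seed) {
  perm <- with_seed(seed, sample.int(n_records(d)))
  dataset_subset(d, perm)
}

# equal-frequency cut points for one continuous column: boundaries fall at
# midpoints between adjacent observed values so that re-applying the stored
# edges reproduces the fitted labels exactly
equal_frequency_edges <- function(x, bins) {
  ux <- sort(unique(x))
  if (length(ux) <= bins) {
    if (length(ux) < bins) {
      warning(sprintf("fewer distinct values (%d) than bins (%d); using %d bins",
                      length(ux), bins, length(ux)), call. = FALSE)
    }
    if (length(ux) == 1) return(numeric(0))
    return((ux[-length(ux)] + ux[-1]) / 2)
  }
  counts <- tabulate(match(x, ux))
  cum <- cumsum(counts)
  n <- length(x)
  pos <- integer(bins - 1)
  prev <- 0L
  for (b in seq_len(bins - 1)) {
    target <- b * n / bins
    cand <- which.min(abs(cum - target))
    cand <- max(cand, prev + 1L)
    cand <- min(cand, length(ux) - (bins - b))
    pos[b] <- cand
    prev <- cand
  }
  (ux[pos] + ux[pos + 1]) / 2
}

#' Convert continuous attributes to nominal equal-frequency bins
#'
#' Optional preprocessing for the forest stage: each continuous attribute is
#' replaced by a nominal attribute of equal-frequency bin labels.  The bin
#' edges are recorded in the returned dataset's provenance so that
#' [apply_discretization()] can map held-out data onto the same bins.
#' Clustering always runs on the original continuous values, never on bins.
#'
#' @param d An `hb_dataset`.
#' @param bins Number of bins (>= 2); attributes with fewer distinct values
#'   collapse to distinct-value bins with a warning.
#' @return A dataset whose continuous attributes are nominal bin factors, with
#'   `provenance$discretization` holding the per-attribute edges.
#' @export
discretize <- function(d, bins = 10) {
  if (bins < 2) stop_ehc("bins must be >= 2")
  edges <- list()
  for (nm in names(d$x)) {
    if (is.numeric(d$x[[nm]])) edges[[nm]] <- equal_frequency_edges(d$x[[nm]], bins)
  }
  out <- apply_discretization(d, edges)
  out$provenance$discretization <- edges
  out
}

#' Apply stored discretization edges to a dataset
#'
#' @param d An `hb_dataset` with continuous attributes.
#' @param edges Named list of numeric edge vectors, as stored by
#'   [discretize()] in `provenance$discretization`.
#' @return Dataset with the listed attributes replaced by bin factors.
#' @export
apply_discretization <- function(d, edges) {
  out <- d
  for (nm in names(edges)) {
    e <- edges[[nm]]
    lab <- findInterval(out$x[[nm]], e) + 1L
    nb <- length(e) + 1L
    out$x[[nm]] <- factor(paste0("bin", lab), levels = paste0("bin", seq_len(nb)))
    out$schema$kind[out$schema$name == nm] <- "nominal"
  }
  out
}

#' Random 70/30-style train/test split
#'
#' Splits a dataset into disjoint train and test sets.  The train size is
#' `round(fraction * M)` (half-up).  The stratified variant allocates
#' per-class train counts by largest remainder, keeping every class's train
#' proportion within one record of `fraction`.
#'
#' @param d An `hb_dataset`.
#' @param fraction Train fraction in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`)?
#' @return An `hb_split` list: `train`, `test`, `fraction`, `seed`,
#'   `stratified`.
#' @export
split_dataset <- function(d, fraction = 0.7, seed = 1, stratified = TRUE) {
  if (!(fraction > 0 && fraction < 1)) stop_ehc("fraction must be in (0,1)")
  M <- n_records(d)
  ntrain <- round_half_up(fraction * M)
  if (ntrain <= 0 || ntrain >= M) {
    stop_ehc("fraction %.3f yields an empty train or test set (M=%d)",
             fraction, M)
  }
  if (stratified) {
    counts <- table(d$y)[d$class_names]
    if (any(counts < 2)) {
      stop_ehc("stratified split needs >= 2 records per class")
    }
    raw <- fraction * as.numeric(counts)
    take <- floor(raw)
    rem <- ntrain - sum(take)
    if (rem > 0) {
      ord <- order(-(raw - take), seq_along(take))
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
    } else if (rem < 0) {
      ord <- order(raw - take, seq_along(take))
      pick <- ord[take[ord] > 0][seq_len(-rem)]
      take[pick] <- take[pick] - 1L
    }
    train_idx <- with_seed(seed, {
      unlist(lapply(seq_along(d$class_names), function(k) {
        ids <- which(d$y == d$class_names[k])
        if (take[k] == 0) integer(0) else ids[sample.int(length(ids), take[k])]
      }))
    })
  } else {
    train_idx <- with_seed(seed, sample.int(M, ntrain))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(M), train_idx)
  structure(list(train = dataset_subset(d, train_idx),
                 test = dataset_subset(d, test_idx),
                 train_idx = train_idx, test_idx = test_idx,
                 fraction = fraction, seed = seed, stratified = stratified),
            class = "hb_split")
}
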