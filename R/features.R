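#' Feature-by-sample abundance matrix
#'
#' The shared container for every omics layer in the package: a numeric
#' matrix with features in rows and samples in columns, both carrying
#' unique identifiers. Missing measurements are stored as `NA`.
#'
#' @param values numeric matrix, features x samples.
#' @param feature_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return an `omics_matrix`: a numeric matrix with class attribute and
#'   row/column names set.
#' @export
omics_matrix <- function(values, feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature_ids and sample_ids are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("ID lengths do not match matrix dimensions")
  dup_f <- feature_ids[duplicated(feature_ids)]
  if (length(dup_f))
    stop("duplicated feature ID(s): ", paste(unique(dup_f), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s))
    stop("duplicated sample ID(s): ", paste(unique(dup_s), collapse = ", "))
  dimnames(values) <- list(feature_ids, sample_ids)
  class(values) <- c("omics_matrix", "matrix", "array")
  values
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

is_omics_matrix <- function(x) inherits(x, "omics_matrix")

#' Read / write a feature-by-sample matrix as TSV
#'
#' On disk the first column holds feature IDs, the header row holds sample
#' IDs and the token `NA` marks missing cells. Values round-trip losslessly
#' to at least 15 significant digits.
#'
#' @param path file path.
#' @return `read_matrix_tsv` returns an [omics_matrix()].
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = 1), fill = FALSE,
                          data.table = TRUE)
  if (ncol(dt) < 2L) stop("no sample columns found in ", path)
  ids <- dt[[1L]]
  vals <- as.matrix(dt[, -1L, with = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[, -1L, with = FALSE], is.numeric, logical(1)))
    stop("non-numeric values in column(s): ",
         paste(names(bad), collapse = ", "))
  }
  omics_matrix(vals, feature_ids = ids, sample_ids = colnames(vals))
}

#' @rdname read_matrix_tsv
#' @param matrix an [omics_matrix()].
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(is_omics_matrix(matrix))
  dt <- data.table::as.data.table(unclass(matrix), keep.rownames = "feature_id")
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Bundle of aligned omics layers plus sample metadata
#'
#' @param mrna,premrna,utr [omics_matrix()] layers (gene-level mRNA
#'   abundance, pre-mRNA abundance, normalized 3'UTR length).
#' @param protein optional [omics_matrix()] of protein abundance (training
#'   targets); may contain missing values.
#' @param metadata data.frame with a `sample_id` column plus per-sample
#'   phenotypes (diagnosis, pathology, cognition slope, age, sex, education).
#' @return a `multi_omics_dataset` list.
#' @export
multi_omics_dataset <- function(mrna, premrna = NULL, utr = NULL,
                                protein = NULL, metadata = NULL) {
  parts <- list(mrna = mrna, premrna = premrna, utr = utr, protein = protein)
  for (nm in names(parts))
    if (!is.null(parts[[nm]]) && !is_omics_matrix(parts[[nm]]))
      stop(nm, " must be an omics_matrix")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata))
      stop("metadata must contain a sample_id column")
  }
  structure(list(mrna = mrna, premrna = premrna, utr = utr,
                 protein = protein, metadata = metadata),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  for (nm in c("mrna", "premrna", "utr", "protein"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-8s %d features x %d samples\n", nm,
                  nrow(x[[nm]]), ncol(x[[nm]])))
  if (!is.null(x$metadata))
    cat(sprintf("  metadata %d samples x %d columns\n",
                nrow(x$metadata), ncol(x$metadata)))
  invisible(x)
}

dataset_parts <- function(dataset)
  Filter(Negate(is.null), dataset[c("mrna", "premrna", "utr", "protein")])

#' Restrict all layers of a dataset to their common samples
#'
#' All present omics layers and the metadata are subset to the intersection
#' of their sample IDs, in the sample order of the first layer. The number
#' of dropped samples is reported via `message()`.
#'
#' @param dataset a [multi_omics_dataset()].
#' @return the aligned dataset.
#' @export
align_samples <- function(dataset) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  parts <- dataset_parts(dataset)
  if (!length(parts)) stop("dataset has no omics layers")
  ids <- lapply(parts, colnames)
  if (!is.null(dataset$metadata)) ids <- c(ids, list(dataset$metadata$sample_id))
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("no common samples across dataset parts")
  keep <- colnames(parts[[1L]])[colnames(parts[[1L]]) %in% common]
  dropped <- length(unique(unlist(ids))) - length(keep)
  if (dropped > 0L) message("align_samples: dropped ", dropped, " sample(s)")
  for (nm in names(parts))
    dataset[[nm]] <- omics_matrix(parts[[nm]][, keep, drop = FALSE])
  if (!is.null(dataset$metadata)) {
    md <- dataset$metadata
    dataset$metadata <- md[match(keep, md$sample_id), , drop = FALSE]
    rownames(dataset$metadata) <- NULL
  }
  dataset
}

row_stats <- function(values) {
  n_obs <- rowSums(!is.na(values))
  mu <- rowMeans(values, na.rm = TRUE)
  mu[n_obs == 0L] <- 0
  centered <- values - mu
  ss <- rowSums(centered^2, na.rm = TRUE)
  v <- ifelse(n_obs >= 2L, ss / (n_obs - 1L), 0)
  list(mean = mu, var = v, sd = sqrt(v), n_obs = n_obs)
}

#' Fit an encoder input space on a designated set of samples
#'
#' Constructs either the set of most-variable features (`kind = "hvg"`,
#' default size 5000) or a principal-component projection (`kind = "pc"`,
#' default size 100) using only the values of `fit_sample_ids`. The
#' returned object is a pure function of those samples, so held-out
#' samples can never leak into the input representation.
#'
#' @param matrix an [omics_matrix()].
#' @param kind `"hvg"` or `"pc"`.
#' @param size number of features / components to keep.
#' @param fit_sample_ids samples used for fitting; defaults to all samples.
#' @return a `feature_space` object usable with [transform_features()].
#' @details For `hvg`, variance is the unbiased sample variance ignoring
#'   missing cells; ties are broken by lexicographic feature ID and
#'   zero-variance features are never eligible. For `pc`, missing cells are
#'   imputed to the fitting-sample feature mean before centering, and the
#'   loadings are the orthonormal right singular vectors of the centered
#'   fitting data.
#' @export
fit_feature_space <- function(matrix, kind = c("hvg", "pc"),
                              size = if (kind == "hvg") 5000L else 100L,
                              fit_sample_ids = colnames(matrix)) {
  kind <- match.arg(kind)
  stopifnot(is_omics_matrix(matrix), size >= 1L)
  missing_fit <- setdiff(fit_sample_ids, colnames(matrix))
  if (length(missing_fit))
    stop("fit_sample_ids not in matrix: ", paste(missing_fit, collapse = ", "))
  x <- unclass(matrix)[, fit_sample_ids, drop = FALSE]
  st <- row_stats(x)
  if (kind == "hvg") {
    eligible <- which(st$var > 0)
    if (size > length(eligible))
      stop("size (", size, ") exceeds number of variable features (",
           length(eligible), ")")
    ord <- eligible[order(-st$var[eligible], rownames(x)[eligible])]
    sel <- rownames(x)[ord[seq_len(size)]]
    space <- list(kind = "hvg", size = as.integer(size),
                  selected_ids = sel,
                  center = st$mean[sel], scale = st$sd[sel],
                  fit_sample_ids = fit_sample_ids)
  } else {
    if (size > min(nrow(x), length(fit_sample_ids)))
      stop("size (", size, ") exceeds min(#features, #fit samples)")
    center <- st$mean
    xc <- t(x)
    for (j in seq_len(ncol(xc))) {
      miss <- is.na(xc[, j])
      if (any(miss)) xc[miss, j] <- center[j]
    }
    xc <- sweep(xc, 2L, center, "-")
    sv <- svd(xc, nu = 0, nv = size)
    eig <- (sv$d[seq_len(size)]^2) / max(1L, nrow(xc) - 1L)
    loadings <- sv$v
    rownames(loadings) <- rownames(x)
    colnames(loadings) <- paste0("PC", seq_len(size))
    space <- list(kind = "pc", size = as.integer(size),
                  feature_ids = rownames(x), center = center,
                  loadings = loadings, eigenvalues = eig,
                  fit_sample_ids = fit_sample_ids)
  }
  structure(space, class = "feature_space")
}

#' Project a matrix into a fitted feature space
#'
#' Deterministic transform using only statistics stored at fitting time:
#' `hvg` spaces subset to the selected features and z-score each with its
#' fitting-sample mean and standard deviation; `pc` spaces impute missing
#' cells to the fitting mean, center, and project onto the loadings.
#'
#' @param space a `feature_space` from [fit_feature_space()].
#' @param matrix an [omics_matrix()] containing every feature the space
#'   requires.
#' @return numeric matrix, samples x size.
#' @export
transform_features <- function(space, matrix) {
  stopifnot(inherits(space, "feature_space"), is_omics_matrix(matrix))
  need <- if (space$kind == "hvg") space$selected_ids else space$feature_ids
  missing_f <- setdiff(need, rownames(matrix))
  if (length(missing_f))
    stop("required feature(s) absent: ",
         paste(utils::head(missing_f, 5L), collapse = ", "),
         if (length(missing_f) > 5L) ", ...")
  x <- t(unclass(matrix)[need, , drop = FALSE])  # samples x features
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- space$center[need[j]]
  }
  if (space$kind == "hvg") {
    sc <- space$scale
    sc[sc == 0] <- 1
    out <- sweep(sweep(x, 2L, space$center, "-"), 2L, sc, "/")
  } else {
    out <- sweep(x, 2L, space$center, "-") %*% space$loadings
  }
  rownames(out) <- colnames(matrix)
  out
}

#' Serialize / restore a feature space as JSON
#' @param space a `feature_space`.
#' @param path JSON file path.
#' @export
write_feature_space <- function(space, path) {
  obj <- unclass(space)
  if (!is.null(obj$loadings)) {
    obj$loadings_values <- as.vector(obj$loadings)
    obj$loadings_dim <- dim(obj$loadings)
    obj$loadings_rownames <- rownames(obj$loadings)
    obj$loadings <- NULL
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_space
#' @export
read_feature_space <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$loadings_values)) {
    obj$loadings <- matrix(obj$loadings_values, nrow = obj$loadings_dim[1])
    rownames(obj$loadings) <- obj$loadings_rownames
    colnames(obj$loadings) <- paste0("PC", seq_len(ncol(obj$loadings)))
    obj$loadings_values <- obj$loadings_dim <- obj$loadings_rownames <- NULL
  }
  for (nm in c("center", "scale")) {
    if (!is.null(obj[[nm]])) {
      ids <- if (obj$kind == "hvg") obj$selected_ids else obj$feature_ids
      obj[[nm]] <- stats::setNames(as.numeric(obj[[nm]]), ids)
    }
  }
  structure(obj, class = "feature_space")
}
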