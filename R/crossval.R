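#' Stratified fold assignment
#'
#' Samples are crossed over the (binned) stratification columns; within
#' each stratum they are shuffled by the seed and dealt round-robin across
#' folds, so fold sizes differ by at most one within every stratum.
#' Continuous columns are binned into tertiles before crossing.
#'
#' @param metadata data.frame with a `sample_id` column.
#' @param n_folds number of folds (default 10).
#' @param strat_columns character vector of metadata columns to balance
#'   (e.g. diagnosis and a pathology score); `NULL` for plain folds.
#' @param seed shuffle seed.
#' @return a `fold_assignment` data.frame with columns `sample_id`, `fold`.
#' @export
stratified_folds <- function(metadata, n_folds = 10L, strat_columns = NULL,
                             seed = 1L) {
  stopifnot("sample_id" %in% names(metadata))
  n <- nrow(metadata)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_folds > n) stop("n_folds (", n_folds, ") exceeds sample count (",
                        n, ")")
  missing_c <- setdiff(strat_columns, names(metadata))
  if (length(missing_c))
    stop("stratification column(s) absent: ",
         paste(missing_c, collapse = ", "))
  bins <- lapply(strat_columns, function(cl) {
    v <- metadata[[cl]]
    if (is.numeric(v) && length(unique(v)) > 3L) {
      q <- stats::quantile(v, c(1, 2) / 3, na.rm = TRUE)
      cut(v, breaks = c(-Inf, q, Inf), labels = FALSE)
    } else as.character(v)
  })
  stratum <- if (length(bins)) do.call(paste, c(bins, sep = "|"))
             else rep("all", n)
  set.seed(substream_seed(seed, "folds"))
  fold <- integer(n)
  offset <- 0L
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    offset <- (offset + length(idx)) %% n_folds
  }
  structure(data.frame(sample_id = metadata$sample_id, fold = fold,
                       stringsAsFactors = FALSE),
            strat_columns = strat_columns, seed = seed,
            n_folds = as.integer(n_folds),
            class = c("fold_assignment", "data.frame"))
}

subset_dataset <- function(dataset, sample_ids) {
  for (nm in c("mrna", "premrna", "utr", "protein"))
    if (!is.null(dataset[[nm]]))
      dataset[[nm]] <- omics_matrix(
        unclass(dataset[[nm]])[, sample_ids, drop = FALSE])
  if (!is.null(dataset$metadata)) {
    md <- dataset$metadata
    dataset$metadata <- md[match(sample_ids, md$sample_id), , drop = FALSE]
    rownames(dataset$metadata) <- NULL
  }
  dataset
}

#' Out-of-fold ensemble prediction
#'
#' For each fold, every submodel in the grid is trained on the remaining
#' folds with its encoder feature space fitted on those training samples
#' only, then ensemble-predicted on the holdout. Each protein's holdout
#' predictions are z-scored within the fold and concatenated back into the
#' original sample order. Out-of-fold purity is asserted: a model's
#' recorded training samples must never intersect its holdout.
#'
#' @param dataset an aligned [multi_omics_dataset()] with protein targets.
#' @param grid list of [submodel_config()]s.
#' @param folds a [stratified_folds()] assignment covering all samples.
#' @param keep_models keep the per-fold trained members (default `FALSE`
#'   to save memory).
#' @param verbose report per-fold progress.
#' @return list with `ensemble` (the out-of-fold consensus prediction,
#'   proteins x samples), `members` (per-submodel out-of-fold predictions,
#'   same scaling), `fold_of` (named fold index per sample), and
#'   optionally `models`.
#' @export
out_of_fold_predict <- function(dataset, grid, folds, keep_models = FALSE,
                                verbose = FALSE) {
  samples <- colnames(dataset$mrna)
  if (!setequal(folds$sample_id, samples))
    stop("fold assignment does not cover the dataset samples")
  fold_of <- stats::setNames(folds$fold, folds$sample_id)[samples]
  n_prot <- nrow(dataset$protein)
  prot_ids <- rownames(dataset$protein)
  oof <- matrix(NA_real_, n_prot, length(samples),
                dimnames = list(prot_ids, samples))
  member_oof <- lapply(seq_along(grid), function(i) oof)
  names(member_oof) <- names(grid)
  models <- list()
  for (k in sort(unique(fold_of))) {
    hold <- samples[fold_of == k]
    train <- setdiff(samples, hold)
    if (verbose) message("fold ", k, ": training on ", length(train),
                         ", predicting ", length(hold))
    train_ds <- subset_dataset(dataset, train)
    hold_ds <- subset_dataset(dataset, hold)
    members <- lapply(grid, function(cf)
      train_submodel(train_ds, cf, feature_fit_sample_ids = train))
    for (m in members)
      stopifnot(length(intersect(m$train_sample_ids, hold)) == 0L)
    preds <- lapply(members, function(m)
      zscore_rows(unclass(predict(m, hold_ds))))
    cons <- Reduce(`+`, preds) / length(preds)
    oof[, hold] <- zscore_rows(cons)
    for (i in seq_along(preds))
      member_oof[[i]][, hold] <- zscore_rows(preds[[i]])
    if (keep_models) models[[paste0("fold", k)]] <- members
  }
  res <- list(ensemble = omics_matrix(oof),
              members = lapply(member_oof, omics_matrix),
              fold_of = fold_of)
  if (keep_models) res$models <- models
  res
}

#' Per-feature Pearson correlation with a one-sided test
#'
#' Pairwise-complete Pearson correlation per shared feature plus a
#' one-sided p-value for positive correlation from the t transform with
#' `n - 2` degrees of freedom. Features with fewer than 3 paired samples
#' or zero variance are reported as missing.
#'
#' @param pred,actual [omics_matrix()] objects sharing feature and sample
#'   IDs (intersection used).
#' @return data.frame with columns `feature_id`, `n`, `r`, `p_one_sided`.
#' @export
per_feature_correlation <- function(pred, actual) {
  feats <- intersect(rownames(pred), rownames(actual))
  smp <- intersect(colnames(pred), colnames(actual))
  if (!length(feats)) stop("no shared features")
  if (length(smp) < 3L) stop("fewer than 3 shared samples")
  P <- unclass(pred)[feats, smp, drop = FALSE]
  A <- unclass(actual)[feats, smp, drop = FALSE]
  out <- data.frame(feature_id = feats, n = NA_integer_, r = NA_real_,
                    p_one_sided = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(feats)) {
    ok <- !is.na(P[i, ]) & !is.na(A[i, ])
    n <- sum(ok)
    out$n[i] <- n
    if (n < 3L) next
    x <- P[i, ok]; y <- A[i, ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y)
    out$r[i] <- r
    tt <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
    out$p_one_sided[i] <- stats::pt(tt, df = n - 2, lower.tail = FALSE)
  }
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values numeric vector in `[0, 1]` (NA allowed, propagated).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- p_values
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Bonferroni-adjusted p-values
#' @param p_values numeric vector in `[0, 1]`.
#' @param m number of tests (default `length(p_values)`).
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  pmin(p_values * m, 1)
}

#' Compare out-of-fold predictions against the raw-mRNA baseline
#'
#' For each protein, correlates both the predicted abundance and the
#' gene's own mRNA with the actual protein abundance, counts features
#' positively correlated at FDR 5%, and reports the per-protein
#' improvement.
#'
#' @param oof_pred predicted protein abundance (proteins x samples).
#' @param actual_protein measured protein abundance.
#' @param mrna mRNA matrix containing the protein genes.
#' @param fdr significance level on BH-adjusted one-sided p-values.
#' @return list with `table` (per-protein r/q for prediction and mRNA and
#'   `delta_r`) and `summary` (mean r and significant counts for both).
#' @export
evaluate_against_baseline <- function(oof_pred, actual_protein, mrna,
                                      fdr = 0.05) {
  shared <- intersect(rownames(oof_pred), rownames(actual_protein))
  shared <- intersect(shared, rownames(mrna))
  if (!length(shared)) stop("no shared feature IDs")
  pr <- per_feature_correlation(oof_pred[shared, , drop = FALSE],
                                actual_protein[shared, , drop = FALSE])
  mr <- per_feature_correlation(mrna[shared, , drop = FALSE],
                                actual_protein[shared, , drop = FALSE])
  tab <- data.frame(feature_id = shared,
                    r_pred = pr$r, q_pred = bh_fdr(pr$p_one_sided),
                    r_mrna = mr$r, q_mrna = bh_fdr(mr$p_one_sided),
                    stringsAsFactors = FALSE)
  tab$delta_r <- tab$r_pred - tab$r_mrna
  summary <- data.frame(
    input = c("estimated_protein", "mrna"),
    mean_r = c(mean(tab$r_pred, na.rm = TRUE),
               mean(tab$r_mrna, na.rm = TRUE)),
    n_significant = c(sum(tab$q_pred < fdr & tab$r_pred > 0, na.rm = TRUE),
                      sum(tab$q_mrna < fdr & tab$r_mrna > 0, na.rm = TRUE)),
    n_features = length(shared))
  list(table = tab, summary = summary)
}
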