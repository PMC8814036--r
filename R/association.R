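#' Covariate-adjusted linear trait association, feature by feature
#'
#' Fits, for every feature, the ordinary least squares model
#' `feature ~ trait + covariates` and reports the trait coefficient, its
#' t-statistic and two-sided p-value. Categorical covariates (and a
#' categorical trait) enter as standard indicator contrasts; samples with
#' missing values are dropped per feature and the used count reported.
#'
#' @param matrix an [omics_matrix()] (features x samples).
#' @param metadata data.frame with `sample_id` and the trait/covariate
#'   columns; matched to the matrix samples by ID.
#' @param trait name of the trait column (binary factors are tested via
#'   their indicator).
#' @param covariates character vector of covariate column names (default
#'   `c("age", "sex", "education")` when present, else none).
#' @param adjust `"bonferroni"` (default, mirrors conservative
#'   proteome-wide testing) or `"bh"`.
#' @return data.frame with `feature_id`, `estimate`, `t_statistic`,
#'   `p_value`, `adjusted_p`, `n_used`.
#' @export
linear_association <- function(matrix, metadata, trait,
                               covariates = intersect(
                                 c("age", "sex", "education"),
                                 names(metadata)),
                               adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(is_omics_matrix(matrix), "sample_id" %in% names(metadata))
  md <- metadata[match(colnames(matrix), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata lacks some matrix samples")
  if (!trait %in% names(md)) stop("trait column absent: ", trait)
  absent <- setdiff(covariates, names(md))
  if (length(absent))
    stop("covariate column(s) absent: ", paste(absent, collapse = ", "))

  to_num <- function(v, nm) {
    if (is.numeric(v)) return(cbind(stats::setNames(data.frame(v), nm)))
    f <- factor(v)
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(nm, levels(f)[-1L])
    # model.matrix drops NA rows; rebuild with NAs preserved
    out <- matrix(NA_real_, length(v), ncol(mm), dimnames = list(NULL,
                  colnames(mm)))
    out[!is.na(v), ] <- mm
    as.data.frame(out)
  }
  tr_cols <- to_num(md[[trait]], trait)
  if (ncol(tr_cols) != 1L)
    stop("trait must be numeric or two-level categorical")
  parts <- list(data.frame(intercept = rep(1, nrow(md))), tr_cols)
  if (length(covariates))
    parts <- c(parts, lapply(covariates, function(cl) to_num(md[[cl]], cl)))
  design <- as.matrix(do.call(cbind, parts))
  cc <- stats::complete.cases(design)
  qrd <- qr(design[cc, , drop = FALSE])
  if (qrd$rank < ncol(design)) {
    coln <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(coln, collapse = ", "))
  }

  vals <- unclass(matrix)
  p_feat <- nrow(vals)
  k <- ncol(design)
  min_n <- k + 2L
  out <- data.frame(feature_id = rownames(vals), estimate = NA_real_,
                    t_statistic = NA_real_, p_value = NA_real_,
                    adjusted_p = NA_real_, n_used = NA_integer_,
                    stringsAsFactors = FALSE)
  fit_one <- function(y, X) {
    fit <- stats::lm.fit(X, y)
    df <- length(y) - ncol(X)
    s2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(qr.R(fit$qr))
    # trait column is column 2 of the design
    j <- 2L
    se <- sqrt(s2 * XtXinv[j, j])
    est <- fit$coefficients[j]
    tt <- est / se
    c(est, tt, 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
  }
  complete_design <- cc
  all_complete <- all(complete_design)
  for (i in seq_len(p_feat)) {
    y <- vals[i, ]
    ok <- complete_design & !is.na(y)
    n <- sum(ok)
    out$n_used[i] <- n
    if (n < min_n) next
    r <- fit_one(y[ok], design[ok, , drop = FALSE])
    out$estimate[i] <- r[1]
    out$t_statistic[i] <- r[2]
    out$p_value[i] <- r[3]
  }
  out$adjusted_p <- if (adjust == "bonferroni") bonferroni(out$p_value)
                    else bh_fdr(out$p_value)
  out
}

#' Concordance of association statistics between two analyses
#'
#' Pearson correlation of the per-feature t-statistics over the features
#' shared by two association tables — the standard check of whether
#' disease signals found in one data modality replicate in another.
#'
#' @param table_a,table_b outputs of [linear_association()] (any
#'   data.frames with `feature_id` and `t_statistic`).
#' @return list with `r` and `n_shared`.
#' @export
statistic_concordance <- function(table_a, table_b) {
  m <- merge(table_a[, c("feature_id", "t_statistic")],
             table_b[, c("feature_id", "t_statistic")],
             by = "feature_id", suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 shared features with statistics")
  list(r = stats::cor(m$t_statistic_a, m$t_statistic_b), n_shared = nrow(m))
}

#' Top-N candidate validation experiment
#'
#' Emulates the standard discovery workflow: take the `n` features with
#' the smallest discovery p-values, and count how many replicate in the
#' validation analysis by effect direction, and by direction plus nominal
#' validation significance (p < 0.05). The chance baseline is the
#' fraction of all shared features expected to pass by random selection
#' (probability 1/2 of a direction match times the overall validation
#' p < 0.05 fraction).
#'
#' @param discovery,validation association tables with `feature_id`,
#'   `t_statistic`, `p_value`.
#' @param n number of top candidates (ties at the n-th p-value broken by
#'   larger `|t|`, then feature ID).
#' @param p_threshold nominal validation significance (default 0.05).
#' @return list with counts `direction_match`, `direction_and_p05`, the
#'   selected IDs, and `random_baseline_rate`.
#' @export
top_n_validation <- function(discovery, validation, n, p_threshold = 0.05) {
  shared <- intersect(discovery$feature_id, validation$feature_id)
  if (n > length(shared)) stop("n exceeds number of shared features")
  d <- discovery[match(shared, discovery$feature_id), , drop = FALSE]
  v <- validation[match(shared, validation$feature_id), , drop = FALSE]
  ord <- order(d$p_value, -abs(d$t_statistic), d$feature_id)
  top <- ord[seq_len(n)]
  same_dir <- sign(d$t_statistic[top]) == sign(v$t_statistic[top])
  sig <- v$p_value[top] < p_threshold
  p05_frac <- mean(v$p_value < p_threshold, na.rm = TRUE)
  list(direction_match = sum(same_dir, na.rm = TRUE),
       direction_and_p05 = sum(same_dir & sig, na.rm = TRUE),
       selected_ids = d$feature_id[top],
       random_baseline_rate = 0.5 * p05_frac)
}

#' One-sided Fisher enrichment of two feature sets
#'
#' Exact hypergeometric upper-tail probability `P(X >= overlap)` of the
#' observed overlap given the universe, with the sample odds ratio
#' (Haldane 0.5 correction when a margin cell is zero).
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible features.
#' @return list with `overlap`, `odds_ratio`, `p_one_sided`, and the
#'   2x2 table counts.
#' @export
fisher_enrichment <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  set_a <- unique(intersect(set_a, universe))
  set_b <- unique(intersect(set_b, universe))
  k <- length(intersect(set_a, set_b))
  m <- length(set_a); n2 <- length(set_b); U <- length(universe)
  p <- stats::phyper(k - 1L, m, U - m, n2, lower.tail = FALSE)
  a <- k
  b <- m - k
  cc <- n2 - k
  d <- U - m - n2 + k
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  list(overlap = k, odds_ratio = (a * d) / (b * cc), p_one_sided = p,
       table = c(both = k, a_only = m - k, b_only = n2 - k,
                 neither = U - m - n2 + k))
}

#' Module summary scores
#'
#' Each feature is z-scored across samples (subtract the mean, divide by
#' the standard deviation) and features of a module are averaged with
#' equal weight, giving one summary trajectory-ready score per module and
#' sample. Zero-variance features are excluded with a warning.
#'
#' @param matrix an [omics_matrix()].
#' @param module_assignments named character/factor vector mapping
#'   feature IDs to module labels (features absent from the matrix are
#'   ignored).
#' @return modules x samples numeric matrix.
#' @export
module_summary <- function(matrix, module_assignments) {
  stopifnot(is_omics_matrix(matrix))
  feats <- intersect(names(module_assignments), rownames(matrix))
  if (!length(feats)) stop("no assigned features present in the matrix")
  vals <- unclass(matrix)[feats, , drop = FALSE]
  st <- row_stats(vals)
  keep <- st$sd > 0
  if (any(!keep))
    warning("excluding ", sum(!keep), " zero-variance feature(s)")
  if (!any(keep)) stop("all features have zero variance")
  vals <- vals[keep, , drop = FALSE]
  z <- (vals - st$mean[keep]) / st$sd[keep]
  mods <- as.character(module_assignments[feats])[keep]
  rowsum(z, group = mods, na.rm = TRUE) /
    rowsum((!is.na(z)) * 1, group = mods)
}
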