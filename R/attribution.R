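#' Expected-gradient input attribution
#'
#' Computes each input's contribution to the model output for every
#' (sample, target) pair as the average, over background samples, of the
#' path integral of the model gradient along the straight line from
#' background to input, times the input-minus-background difference. The
#' contributions satisfy local accuracy: they sum to the prediction minus
#' the mean background prediction.
#'
#' Two integrators are available. `method = "exact"` (default) uses the
#' fact that a ReLU network is piecewise linear along any straight path:
#' the path is segmented at every hidden-unit sign change (located by
#' exact linear interpolation, layer by layer) and the gradient is
#' constant within each segment, so the integral — and therefore local
#' accuracy — is exact to floating-point precision. `method = "sampled"`
#' is the conventional estimator: it cycles through every background
#' sample with `n_draws` stratified interpolation coefficients, is exact
#' for linear maps at any number of draws, and converges to local
#' accuracy as draws grow.
#'
#' Encoder inputs (typically principal components, whose independence
#' favours accurate attribution) are handled by backpropagating each
#' target's gradient to the encoder input; merge inputs have constant
#' per-protein gradients, so their contributions are computed in closed
#' form.
#'
#' @param model a `trained_submodel`, or any list with `params` from
#'   [submodel_params()].
#' @param encoder_input samples x features matrix of the inputs to explain.
#' @param background list with `encoder_input` (>= 2 rows) and optionally
#'   `merge_features` matching `merge_features`.
#' @param merge_features optional named list of samples x proteins merge
#'   input matrices (z-scored scale), as used by [lr_merge()].
#' @param targets protein indices or IDs to attribute (default: all).
#' @param n_draws gradient evaluations per sample for
#'   `method = "sampled"` (default 200; ignored by the exact integrator).
#' @param seed seed for subsampling a large background.
#' @param max_background cap on background rows (default 100, seeded
#'   subsample beyond that).
#' @param method `"exact"` or `"sampled"` (see Details).
#' @return an `attribution_result` with `contributions`
#'   (samples x inputs x targets), `prediction`, `baseline_prediction`,
#'   and ID vectors.
#' @export
expected_gradient_attribution <- function(model, encoder_input, background,
                                          merge_features = NULL,
                                          targets = NULL, n_draws = 200L,
                                          seed = 1L, max_background = 100L,
                                          method = c("exact", "sampled")) {
  method <- match.arg(method)
  params <- model$params %||% model
  X <- as.matrix(encoder_input)
  BGX <- as.matrix(background$encoder_input)
  if (nrow(BGX) < 2L) stop("background needs at least 2 samples")
  bg_merge <- background$merge_features
  if (nrow(BGX) > max_background) {
    set.seed(substream_seed(seed, "background"))
    keep <- sort(sample.int(nrow(BGX), max_background))
    BGX <- BGX[keep, , drop = FALSE]
    if (!is.null(bg_merge))
      bg_merge <- lapply(bg_merge, function(m) m[keep, , drop = FALSE])
  }
  n_prot <- length(params$merge$a)
  prot_ids <- model$protein_ids %||% as.character(seq_len(n_prot))
  if (is.null(targets)) targets <- seq_len(n_prot)
  if (is.character(targets)) targets <- match(targets, prot_ids)
  if (anyNA(targets)) stop("unknown target protein ID(s)")
  tids <- prot_ids[targets]

  B <- nrow(BGX)
  S <- nrow(X)
  P <- ncol(X)
  input_ids <- c(colnames(X) %||% paste0("in", seq_len(P)),
                 if (length(merge_features))
                   paste0("merge:", names(merge_features)))
  contrib <- array(0, dim = c(S, length(input_ids), length(targets)),
                   dimnames = list(rownames(X), input_ids, tids))
  a <- params$merge$a
  if (method == "sampled") {
    n_alpha <- max(1L, ceiling(n_draws / B))
    alphas <- (seq_len(n_alpha) - 0.5) / n_alpha
    w <- 1 / (B * n_alpha)
    for (bi in seq_len(B)) {
      bg_row <- BGX[bi, ]
      Dx <- sweep(X, 2L, bg_row, "-")  # x - b, fixed for this background
      for (al in alphas) {
        pts <- sweep(Dx * al, 2L, bg_row, "+")
        cache <- nn_forward(params, pts, mode = "infer")
        for (ti in seq_along(targets)) {
          G <- nn_input_gradient(params, cache, targets[ti])
          contrib[, seq_len(P), ti] <- contrib[, seq_len(P), ti] +
            w * a[targets[ti]] * (G * Dx)
        }
      }
    }
  } else {
    for (si in seq_len(S)) {
      x <- X[si, ]
      for (bi in seq_len(B)) {
        seg <- path_segments(params, BGX[bi, ], x)
        dx <- x - BGX[bi, ]
        cache <- nn_forward(params, seg$points, mode = "infer")
        for (ti in seq_along(targets)) {
          G <- nn_input_gradient(params, cache, targets[ti])
          contrib[si, seq_len(P), ti] <- contrib[si, seq_len(P), ti] +
            (a[targets[ti]] / B) * colSums(seg$weights * G) * dx
        }
      }
    }
  }
  # merge inputs: gradient is the per-protein coefficient, constant
  if (length(merge_features)) {
    for (fi in seq_along(merge_features)) {
      f <- names(merge_features)[fi]
      bg_mean <- colMeans(bg_merge[[f]][, targets, drop = FALSE])
      xf <- merge_features[[f]][, targets, drop = FALSE]
      dx <- sweep(xf, 2L, bg_mean, "-")
      for (ti in seq_along(targets))
        contrib[, P + fi, ti] <- params$merge$C[targets[ti], f] * dx[, ti]
    }
  }
  pred_at <- function(Xe, mf) {
    fw <- nn_forward(params, Xe, mode = "infer")
    pred <- sweep(fw$decoded, 2L, a, "*")
    if (length(mf))
      for (f in names(mf))
        pred <- pred + sweep(mf[[f]], 2L, params$merge$C[, f], "*")
    sweep(pred, 2L, params$merge$b0, "+")[, targets, drop = FALSE]
  }
  prediction <- pred_at(X, merge_features)
  baseline <- colMeans(pred_at(BGX, bg_merge))
  structure(list(contributions = contrib, prediction = prediction,
                 baseline_prediction = stats::setNames(baseline, tids),
                 input_feature_ids = input_ids, target_protein_ids = tids,
                 n_background = B, method = method,
                 n_draws_effective = if (method == "sampled")
                   B * max(1L, ceiling(n_draws / B)) else NA_integer_),
            class = "attribution_result")
}

#' Maximum relative local-accuracy deviation of an attribution
#'
#' Local accuracy requires the contributions of all inputs to sum, for
#' each sample and target, to the prediction minus the baseline (the mean
#' background prediction). Returns the maximum over (sample, target) of
#' `|sum(contributions) - (f - baseline)| / (|f - baseline| + eps)`.
#'
#' @param attr an `attribution_result`.
#' @param eps guard against division by zero (default 1e-8).
#' @export
check_local_accuracy <- function(attr, eps = 1e-8) {
  stopifnot(inherits(attr, "attribution_result"))
  sums <- apply(attr$contributions, c(1, 3), sum)
  diff <- sweep(attr$prediction, 2L, attr$baseline_prediction, "-")
  max(abs(sums - diff) / (abs(diff) + eps))
}

#' Rank inputs by mean absolute contribution
#'
#' @param attr an `attribution_result`.
#' @param aggregation only `"mean_abs"` is implemented: the mean of
#'   `|contribution|` over samples and targets.
#' @return data.frame ordered by decreasing score; ties broken by input ID.
#' @export
rank_inputs <- function(attr, aggregation = "mean_abs") {
  stopifnot(inherits(attr, "attribution_result"),
            identical(aggregation, "mean_abs"))
  score <- apply(abs(attr$contributions), 2L, mean)
  ord <- order(-score, attr$input_feature_ids)
  data.frame(input_id = attr$input_feature_ids[ord], score = score[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Remove one or more inputs' contributions from predictions
#'
#' Subtracts the attributed contribution of the named input(s) from the
#' prediction of every (sample, target) pair. Removal is additive, so
#' removing a set of inputs equals sequential removal in any order; the
#' adjusted values feed re-association analyses that quantify how much a
#' component (e.g. one mRNA principal component) carries a trait signal.
#'
#' @param predictions samples x targets matrix aligned with `attr` (e.g.
#'   `attr$prediction`).
#' @param attr an `attribution_result`.
#' @param input_id character vector of inputs to remove.
#' @return adjusted predictions, same shape.
#' @export
remove_input_contribution <- function(predictions, attr, input_id) {
  stopifnot(inherits(attr, "attribution_result"))
  unknown <- setdiff(input_id, attr$input_feature_ids)
  if (length(unknown))
    stop("unknown input_id(s): ", paste(unknown, collapse = ", "))
  adj <- as.matrix(predictions)
  for (id in input_id) {
    ci <- match(id, attr$input_feature_ids)
    m <- attr$contributions[, ci, , drop = FALSE]
    dim(m) <- dim(attr$contributions)[c(1L, 3L)]
    adj <- adj - m
  }
  adj
}

partial_r2 <- function(y, trait, covariates = NULL) {
  ok <- stats::complete.cases(y, trait, covariates)
  y <- y[ok]; tr <- trait[ok]
  cv <- if (is.null(covariates)) NULL
        else as.matrix(as.data.frame(covariates))[ok, , drop = FALSE]
  X_red <- cbind(1, cv)
  X_full <- cbind(X_red, tr)
  rss <- function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  r_red <- rss(X_red)
  if (r_red == 0) return(0)
  (r_red - rss(X_full)) / r_red
}

#' Change in trait-explained variance after contribution removal
#'
#' For each target, computes the variance explained by the trait after
#' covariate adjustment (partial R-squared) in the original and the
#' adjusted predictions, and returns the difference in percent. Large
#' positive values flag inputs whose removal destroys the trait
#' association, i.e. the molecular components carrying the disease signal.
#'
#' @param original,adjusted samples x targets matrices.
#' @param trait per-sample trait values (non-constant).
#' @param covariates optional data.frame of per-sample covariates.
#' @return named per-target vector of delta partial R-squared, in percent.
#' @export
variance_explained_delta <- function(original, adjusted, trait,
                                     covariates = NULL) {
  original <- as.matrix(original)
  adjusted <- as.matrix(adjusted)
  stopifnot(identical(dim(original), dim(adjusted)))
  if (stats::var(trait, na.rm = TRUE) == 0) stop("trait is constant")
  out <- vapply(seq_len(ncol(original)), function(j) {
    100 * (partial_r2(original[, j], trait, covariates) -
             partial_r2(adjusted[, j], trait, covariates))
  }, numeric(1))
  stats::setNames(out, colnames(original))
}

#' Attribute a trained submodel's predictions on a dataset
#'
#' Convenience wrapper assembling the encoder input and merge features of
#' a [train_submodel()] fit for [expected_gradient_attribution()]. The
#' background defaults to the model's training samples (capped and
#' seeded); attribution is computed on the model's z-scored output scale.
#'
#' @param model a `trained_submodel` (principal-component encoder inputs
#'   recommended: their independence favours attribution accuracy).
#' @param dataset a [multi_omics_dataset()] with the samples to explain.
#' @param background_dataset dataset supplying background samples
#'   (default: `dataset` restricted to the model's training samples).
#' @param targets protein IDs or indices (default: all).
#' @inheritParams expected_gradient_attribution
#' @return an `attribution_result`.
#' @export
attribute_submodel <- function(model, dataset, background_dataset = NULL,
                               targets = NULL, n_draws = 200L, seed = 1L,
                               max_background = 100L) {
  stopifnot(inherits(model, "trained_submodel"))
  inp <- prediction_inputs(model, dataset)
  if (is.null(background_dataset)) {
    keep <- intersect(model$train_sample_ids, colnames(dataset$mrna))
    if (length(keep) < 2L)
      stop("no training samples available as background; supply one")
    background_dataset <- subset_dataset(dataset, keep)
  }
  bg <- prediction_inputs(model, background_dataset)
  expected_gradient_attribution(
    model, encoder_input = inp$Xenc,
    background = list(encoder_input = bg$Xenc, merge_features = bg$Xmerge),
    merge_features = inp$Xmerge, targets = targets, n_draws = n_draws,
    seed = seed, max_background = max_background)
}
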