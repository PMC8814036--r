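#' Configuration of one encoder/decoder/merge submodel
#'
#' Each submodel encodes one transcriptional layer (mRNA, pre-mRNA, or
#' 3'UTR length) through a variational encoder into a latent distribution,
#' decodes the latent mean (or a reparameterized draw during training) into
#' a proteome vector, and merges that decoded value per protein with the
#' gene's own transcript features through a linear-regression layer.
#'
#' @param encoder_source `"mrna"`, `"premrna"`, or `"utr"`.
#' @param encoder_representation `"hvg"` (most-variable features) or `"pc"`
#'   (principal components).
#' @param lr_inputs merge-layer inputs; must contain `"decoded"`, may add
#'   any of `"mrna"`, `"premrna"`, `"utr"` (the gene's own value).
#' @param hvg_size,pc_size encoder input sizes (defaults 5000 / 100).
#' @param latent_dim latent dimension (default 32).
#' @param hidden_dims encoder trunk widths; the decoder mirrors them in
#'   reverse. Default `c(800, 800)`.
#' @param kl_weight weight of the KL term in the loss (default 0.005; small
#'   because the decoder targets a different modality than the encoder
#'   input, so the latent prior acts only as a mild regularizer).
#' @param lr_scgen,lr_merge Adam learning rates for the encoder/decoder
#'   group (0.001) and the merge layer (0.01).
#' @param max_epochs,patience early-stopping budget (defaults 10000 / 30).
#' @param min_delta minimal validation-loss improvement counted as progress.
#' @param validation_fraction fraction of training samples held out to
#'   monitor validation loss (default 0.10).
#' @param batch_size minibatch size (default 64).
#' @param loss_target `"merged"` (reconstruction loss on the final merged
#'   prediction; joint end-to-end training, the default) or `"decoded"`
#'   (loss on the decoder output, with the merge layer fitted on top).
#' @param seed seed controlling validation split, initialization, batch
#'   order and latent draws.
#' @return a validated `submodel_config`.
#' @export
submodel_config <- function(encoder_source = c("mrna", "premrna", "utr"),
                            encoder_representation = c("hvg", "pc"),
                            lr_inputs = c("decoded", "mrna", "premrna", "utr"),
                            hvg_size = 5000L, pc_size = 100L,
                            latent_dim = 32L, hidden_dims = c(800L, 800L),
                            kl_weight = 0.005, lr_scgen = 0.001,
                            lr_merge = 0.01, max_epochs = 10000L,
                            patience = 30L, min_delta = 1e-4,
                            validation_fraction = 0.10, batch_size = 64L,
                            loss_target = c("merged", "decoded"),
                            seed = 1L) {
  encoder_source <- match.arg(encoder_source)
  encoder_representation <- match.arg(encoder_representation)
  loss_target <- match.arg(loss_target)
  lr_inputs <- unique(as.character(lr_inputs))
  if (!"decoded" %in% lr_inputs)
    stop("lr_inputs must contain 'decoded'")
  bad <- setdiff(lr_inputs, c("decoded", "mrna", "premrna", "utr"))
  if (length(bad)) stop("unknown lr_inputs: ", paste(bad, collapse = ", "))
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  if (patience < 1L) stop("patience must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  structure(list(encoder_source = encoder_source,
                 encoder_representation = encoder_representation,
                 lr_inputs = lr_inputs,
                 hvg_size = as.integer(hvg_size),
                 pc_size = as.integer(pc_size),
                 latent_dim = as.integer(latent_dim),
                 hidden_dims = as.integer(hidden_dims),
                 kl_weight = kl_weight, lr_scgen = lr_scgen,
                 lr_merge = lr_merge, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 validation_fraction = validation_fraction,
                 batch_size = as.integer(batch_size),
                 loss_target = loss_target, seed = as.integer(seed)),
            class = "submodel_config")
}

#' Enumerate the default ensemble grid of submodel configurations
#'
#' The default grid crosses the three encoder sources with the two encoder
#' representations and two merge-input sets (`decoded + mrna + premrna +
#' utr` and `decoded + mrna`), yielding twelve distinct submodels. Every
#' axis can be overridden; duplicated configurations after override raise
#' an error.
#'
#' @param sources encoder sources to include.
#' @param representations encoder representations to include.
#' @param lr_input_sets list of merge-input sets.
#' @param ... further arguments passed to every [submodel_config()]
#'   (e.g. `hvg_size`, `latent_dim`, `max_epochs`, `seed`).
#' @return list of `submodel_config` objects.
#' @export
enumerate_submodels <- function(sources = c("mrna", "premrna", "utr"),
                                representations = c("hvg", "pc"),
                                lr_input_sets = list(
                                  full = c("decoded", "mrna", "premrna", "utr"),
                                  mrna_only = c("decoded", "mrna")),
                                ...) {
  grid <- expand.grid(src = sources, repr = representations,
                      lrset = seq_along(lr_input_sets),
                      stringsAsFactors = FALSE)
  configs <- lapply(seq_len(nrow(grid)), function(i)
    submodel_config(encoder_source = grid$src[i],
                    encoder_representation = grid$repr[i],
                    lr_inputs = lr_input_sets[[grid$lrset[i]]], ...))
  keys <- vapply(configs, function(cf)
    paste(cf$encoder_source, cf$encoder_representation,
          paste(sort(cf$lr_inputs), collapse = "+"), sep = "|"),
    character(1))
  if (anyDuplicated(keys))
    stop("duplicate submodel configurations after override: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  names(configs) <- keys
  configs
}

#' Encode samples into a latent distribution
#'
#' @param model a trained submodel (or any list with `params` as produced
#'   by [submodel_params()]).
#' @param encoder_input samples x features matrix matching the model's
#'   feature space size.
#' @return list with `mu` and `logvar` (samples x latent_dim); `logvar` is
#'   clamped to `[-15, 15]`.
#' @export
encode <- function(model, encoder_input) {
  params <- model$params %||% model
  n_in <- nrow(if (length(params$scgen$enc)) params$scgen$enc[[1]]$W
               else params$scgen$mu$W)
  if (ncol(encoder_input) != n_in)
    stop("encoder input has ", ncol(encoder_input), " columns; expected ",
         n_in)
  fw <- nn_forward(params, as.matrix(encoder_input), mode = "infer")
  list(mu = fw$mu, logvar = fw$lv)
}

#' Draw latent vectors from an encoded distribution
#'
#' @param dist list with `mu` and `logvar`.
#' @param mode `"infer"` returns the mean exactly; `"train"` draws
#'   `z = mu + exp(logvar/2) * eps` with `eps ~ N(0, I)` from a seeded
#'   stream.
#' @param seed seed for the `"train"` draw.
#' @export
sample_latent <- function(dist, mode = c("infer", "train"), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "infer") return(dist$mu)
  set.seed(substream_seed(seed, "latent_draw"))
  eps <- matrix(stats::rnorm(length(dist$mu)), nrow(dist$mu))
  dist$mu + exp(dist$logvar / 2) * eps
}

#' Decode latent vectors into the decoded proteome
#'
#' @param model as in [encode()].
#' @param latent samples x latent_dim matrix.
#' @return samples x proteins matrix of decoded values.
#' @export
decode <- function(model, latent) {
  params <- model$params %||% model
  sg <- params$scgen
  latent <- as.matrix(latent)
  expected <- nrow(if (length(sg$dec)) sg$dec[[1]]$W else sg$out$W)
  if (ncol(latent) != expected)
    stop("latent has ", ncol(latent), " columns; expected ", expected)
  D <- latent
  for (l in sg$dec) D <- relu(sweep(D %*% l$W, 2L, l$b, "+"))
  sweep(D %*% sg$out$W, 2L, sg$out$b, "+")
}

#' Per-protein linear-regression merge
#'
#' Combines the decoded value of each protein with the gene's own
#' transcript features:
#' `yhat[s, g] = a[g] * decoded[s, g] + sum_f C[g, f] * x[s, g, f] + b0[g]`.
#' Weights are per protein and shared across samples.
#'
#' @param decoded samples x proteins matrix.
#' @param per_protein_features named list of samples x proteins matrices,
#'   one per configured merge input (missing gene values must already be
#'   imputed to 0 on the z-scored scale).
#' @param a,C,b0 merge weights: `a` and `b0` are per-protein vectors, `C`
#'   is proteins x inputs with column names matching
#'   `names(per_protein_features)`.
#' @return samples x proteins prediction matrix.
#' @export
lr_merge <- function(decoded, per_protein_features, a, C, b0) {
  pred <- mul_col(decoded, a)
  for (f in names(per_protein_features)) {
    if (!f %in% colnames(C)) stop("no merge coefficient column for ", f)
    pred <- pred + mul_col(per_protein_features[[f]], C[, f])
  }
  add_col(pred, b0)
}

#' Training loss: masked reconstruction error plus weighted KL divergence
#'
#' Mean squared error over observed protein cells plus
#' `kl_weight * mean(KL(N(mu, exp(logvar)) || N(0, 1)))` with the per-unit
#' closed form `0.5 * (exp(logvar) + mu^2 - 1 - logvar)`.
#'
#' @param prediction,target samples x proteins matrices.
#' @param mu,logvar latent distribution parameters.
#' @param kl_weight nonnegative scalar.
#' @param mask optional logical matrix of observed cells (default: non-NA
#'   cells of `target`). A fully masked batch is an error.
#' @return list with `loss`, `mse`, and `kl`.
#' @export
vae_loss <- function(prediction, target, mu, logvar, kl_weight = 0.005,
                     mask = NULL) {
  if (is.null(mask)) mask <- !is.na(target)
  n_obs <- sum(mask)
  if (n_obs == 0L) stop("loss undefined: all target cells are masked")
  resid <- prediction - target
  resid[!mask] <- 0
  mse <- sum(resid^2) / n_obs
  kl <- mean(0.5 * (exp(logvar) + mu^2 - 1 - logvar))
  list(loss = mse + kl_weight * kl, mse = mse, kl = kl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-scoring helpers for merge features and protein targets -------------------

fit_row_scaling <- function(values) {
  st <- row_stats(values)
  sd <- st$sd
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(center = st$mean, scale = sd)
}

apply_row_scaling <- function(values, scaling) {
  z <- (values - scaling$center) / scaling$scale
  z[is.na(z)] <- 0  # mean imputation on the z-scored scale
  z
}

# Build samples x proteins matrices of each protein gene's own transcript
# feature, z-scored with the supplied per-gene scaling.
build_merge_features <- function(dataset, protein_ids, lr_inputs, scalings) {
  out <- list()
  for (f in setdiff(lr_inputs, "decoded")) {
    layer <- dataset[[f]]
    if (is.null(layer)) stop("dataset lacks required merge layer: ", f)
    missing_g <- setdiff(protein_ids, rownames(layer))
    if (length(missing_g))
      stop("merge layer ", f, " lacks gene(s): ",
           paste(utils::head(missing_g, 5L), collapse = ", "))
    vals <- unclass(layer)[protein_ids, , drop = FALSE]
    out[[f]] <- t(apply_row_scaling(vals, scalings[[f]]))
  }
  out
}

#' Train one submodel on a multi-omics dataset
#'
#' Fits the encoder feature space on `feature_fit_sample_ids` (defaulting
#' to the training samples themselves; pass a disjoint set to mirror
#' leakage-free feature selection), splits off a seeded validation fraction,
#' z-scores the protein targets per protein with training-split statistics,
#' and optimizes the joint loss with Adam in two parameter groups
#' (encoder/decoder at `lr_scgen`, merge layer at `lr_merge`). Training
#' stops when validation loss fails to improve by `min_delta` for
#' `patience` consecutive epochs; the returned weights are those of the
#' best validation epoch.
#'
#' @param dataset an aligned [multi_omics_dataset()] with a protein layer.
#' @param config a [submodel_config()].
#' @param feature_fit_sample_ids samples used to fit the encoder feature
#'   space (defaults to all samples in `dataset`).
#' @param verbose print progress every 50 epochs.
#' @return a `trained_submodel` with weights, feature space, scaling
#'   statistics and training history.
#' @export
train_submodel <- function(dataset, config, feature_fit_sample_ids = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(dataset, "multi_omics_dataset"),
            inherits(config, "submodel_config"))
  if (is.null(dataset$protein)) stop("dataset has no protein targets")
  samples <- colnames(dataset$mrna)
  if (length(samples) < 20L) stop("need at least 20 training samples")
  if (is.null(feature_fit_sample_ids)) feature_fit_sample_ids <- samples

  src <- dataset[[config$encoder_source]]
  if (is.null(src)) stop("dataset lacks encoder source ",
                         config$encoder_source)
  size <- if (config$encoder_representation == "hvg") config$hvg_size
          else config$pc_size
  space <- fit_feature_space(src, kind = config$encoder_representation,
                             size = size,
                             fit_sample_ids = feature_fit_sample_ids)
  Xenc <- transform_features(space, src)[samples, , drop = FALSE]

  protein_ids <- rownames(dataset$protein)
  merge_layers <- setdiff(config$lr_inputs, "decoded")
  merge_scalings <- lapply(stats::setNames(merge_layers, merge_layers),
                           function(f) {
    layer <- dataset[[f]]
    if (is.null(layer)) stop("dataset lacks required merge layer: ", f)
    fit_row_scaling(unclass(layer)[protein_ids, samples, drop = FALSE])
  })
  Xmerge <- build_merge_features(dataset, protein_ids, config$lr_inputs,
                                 merge_scalings)
  Xmerge <- lapply(Xmerge, function(m) m[samples, , drop = FALSE])

  set.seed(substream_seed(config$seed, "train"))
  n <- length(samples)
  n_val <- max(1L, round(config$validation_fraction * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)

  Yraw <- t(unclass(dataset$protein)[, samples, drop = FALSE])
  prot_scaling <- fit_row_scaling(t(Yraw[tr_idx, , drop = FALSE]))
  Y <- t(apply_row_scaling(t(Yraw), prot_scaling))
  mask <- !is.na(Yraw)
  Y[!mask] <- 0

  params <- submodel_params(
    n_input = ncol(Xenc), hidden_dims = config$hidden_dims,
    latent_dim = config$latent_dim,
    dec_hidden_dims = rev(config$hidden_dims),
    n_proteins = length(protein_ids), merge_extra = merge_layers,
    seed = config$seed)
  state <- adam_init(params)
  lr_by_group <- list(scgen = config$lr_scgen, merge = config$lr_merge)

  eval_loss <- function(idx) {
    fw <- nn_forward(params, Xenc[idx, , drop = FALSE], mode = "infer")
    pred <- lr_merge(fw$decoded,
                     lapply(Xmerge, function(m) m[idx, , drop = FALSE]),
                     params$merge$a, params$merge$C, params$merge$b0)
    target <- if (config$loss_target == "merged") pred else fw$decoded
    vae_loss(target, Y[idx, , drop = FALSE], fw$mu, fw$lv,
             kl_weight = config$kl_weight,
             mask = mask[idx, , drop = FALSE])$loss
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = double(),
                        val_loss = double())
  stall <- 0L
  t_adam <- 0L
  # fixed seeded batch partition; slices cached, batch order reshuffled
  # every epoch
  ord0 <- sample(tr_idx)
  starts <- seq(1L, length(ord0), by = config$batch_size)
  batch_idx <- lapply(starts, function(s)
    ord0[s:min(s + config$batch_size - 1L, length(ord0))])
  batch_cache <- lapply(batch_idx, function(bt) list(
    X = Xenc[bt, , drop = FALSE],
    feats = lapply(Xmerge, function(m) m[bt, , drop = FALSE]),
    Y = Y[bt, , drop = FALSE],
    M = mask[bt, , drop = FALSE],
    n = length(bt)))
  for (epoch in seq_len(config$max_epochs)) {
    ep_loss <- 0
    for (bc in batch_cache[sample.int(length(batch_cache))]) {
      M <- bc$M
      if (!any(M)) next
      eps <- matrix(stats::rnorm(bc$n * config$latent_dim),
                    bc$n, config$latent_dim)
      fw <- nn_forward(params, bc$X, mode = "train", eps = eps)
      feats <- bc$feats
      pred <- lr_merge(fw$decoded, feats, params$merge$a, params$merge$C,
                       params$merge$b0)
      out <- if (config$loss_target == "merged") pred else fw$decoded
      resid <- out - bc$Y
      resid[!M] <- 0
      n_obs <- sum(M)
      loss <- sum(resid^2) / n_obs +
        config$kl_weight * mean(0.5 * (exp(fw$lv) + fw$mu^2 - 1 - fw$lv))
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch)
      ep_loss <- ep_loss + loss * bc$n
      d_out <- 2 * resid / n_obs
      if (config$loss_target == "merged") {
        g_merge <- list(
          a = colSums(d_out * fw$decoded),
          C = {
            gc_ <- matrix(0, length(protein_ids), length(merge_layers),
                          dimnames = list(NULL, merge_layers))
            for (f in merge_layers) gc_[, f] <- colSums(d_out * feats[[f]])
            gc_
          },
          b0 = colSums(d_out))
        d_decoded <- mul_col(d_out, params$merge$a)
      } else {
        g_merge <- NULL
        d_decoded <- d_out
      }
      kfac <- config$kl_weight / (bc$n * config$latent_dim)
      d_mu_extra <- kfac * fw$mu
      d_lv_extra <- kfac * 0.5 * (exp(fw$lv) - 1)
      g_scgen <- nn_backward(params, fw, d_decoded, d_mu_extra, d_lv_extra)
      g_scgen$d_input <- NULL
      grads <- list(scgen = g_scgen, merge = g_merge)
      t_adam <- t_adam + 1L
      st <- adam_step(params, grads, state, lr_by_group, t_adam)
      params <- st$params
      state <- st$state
    }
    val_loss <- eval_loss(val_idx)
    if (!is.finite(val_loss))
      stop("non-finite validation loss at epoch ", epoch)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = ep_loss / length(tr_idx),
                                val_loss = val_loss))
    if (val_loss < best$loss - config$min_delta) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (verbose && epoch %% 50L == 0L)
      message(sprintf("epoch %d: val_loss %.5f (best %.5f @ %d)",
                      epoch, val_loss, best$loss, best$epoch))
    if (stall >= config$patience) break
  }

  structure(list(config = config, feature_space = space, params = best$params,
                 merge_scalings = merge_scalings,
                 protein_scaling = prot_scaling, protein_ids = protein_ids,
                 history = history, stopped_epoch = nrow(history),
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 train_sample_ids = samples,
                 validation_sample_ids = samples[val_idx]),
            class = "trained_submodel")
}

#' @export
print.trained_submodel <- function(x, ...) {
  cat(sprintf(
    "trained_submodel: %s/%s -> %d proteins; merge inputs: %s\n",
    x$config$encoder_source, x$config$encoder_representation,
    length(x$protein_ids), paste(x$config$lr_inputs, collapse = ", ")))
  cat(sprintf("  stopped at epoch %d (best %d, val loss %.5f)\n",
              x$stopped_epoch, x$best_epoch, x$best_val_loss))
  invisible(x)
}

# Assemble encoder + merge inputs for prediction on any dataset.
prediction_inputs <- function(object, dataset) {
  src <- dataset[[object$config$encoder_source]]
  if (is.null(src)) stop("dataset lacks encoder source ",
                         object$config$encoder_source)
  Xenc <- transform_features(object$feature_space, src)
  Xmerge <- list()
  for (f in setdiff(object$config$lr_inputs, "decoded")) {
    layer <- dataset[[f]]
    if (is.null(layer)) stop("dataset lacks required merge layer: ", f)
    vals <- unclass(layer)[object$protein_ids, , drop = FALSE]
    Xmerge[[f]] <- t(apply_row_scaling(vals, object$merge_scalings[[f]]))
  }
  list(Xenc = Xenc, Xmerge = Xmerge, sample_ids = colnames(src))
}

#' Predict protein abundance for new samples
#'
#' Deterministic: the latent vector is the encoder mean, and the stored
#' per-protein target scaling is inverted so predictions are on the
#' original protein scale.
#'
#' @param object a `trained_submodel`.
#' @param dataset a [multi_omics_dataset()] supplying the encoder source
#'   and merge layers.
#' @param ... unused.
#' @return an [omics_matrix()] of predicted abundance, proteins x samples.
#' @export
predict.trained_submodel <- function(object, dataset, ...) {
  inp <- prediction_inputs(object, dataset)
  fw <- nn_forward(object$params, inp$Xenc, mode = "infer")
  pred <- lr_merge(fw$decoded, inp$Xmerge, object$params$merge$a,
                   object$params$merge$C, object$params$merge$b0)
  out <- t(pred) * object$protein_scaling$scale +
    object$protein_scaling$center
  omics_matrix(out, feature_ids = object$protein_ids,
               sample_ids = inp$sample_ids)
}

#' Train the full ensemble grid on one dataset
#'
#' @param dataset an aligned [multi_omics_dataset()] with protein targets.
#' @param grid list of [submodel_config()]s (default: the 12-member grid
#'   from [enumerate_submodels()]).
#' @param feature_fit_sample_ids passed to every [train_submodel()].
#' @param verbose print per-member progress.
#' @return an `ensemble_model`: list of `trained_submodel`s.
#' @export
train_ensemble <- function(dataset, grid = enumerate_submodels(),
                           feature_fit_sample_ids = NULL, verbose = FALSE) {
  members <- lapply(seq_along(grid), function(i) {
    if (verbose) message("training submodel ", i, "/", length(grid), ": ",
                         names(grid)[i])
    train_submodel(dataset, grid[[i]], feature_fit_sample_ids)
  })
  names(members) <- names(grid)
  structure(members, class = "ensemble_model")
}

zscore_rows <- function(values) {
  st <- row_stats(values)
  sd <- st$sd
  sd[sd == 0 | !is.finite(sd)] <- 1
  (values - st$mean) / sd
}

#' Equal-weight consensus prediction of an ensemble
#'
#' Each member's predictions are z-scored per protein (with that member's
#' own prediction statistics) and averaged with equal weights, so members
#' on different output scales contribute equally.
#'
#' @param ensemble an `ensemble_model` or plain list of `trained_submodel`s.
#' @param dataset a [multi_omics_dataset()].
#' @return an [omics_matrix()], proteins x samples, on the z-scored
#'   consensus scale.
#' @export
ensemble_predict <- function(ensemble, dataset) {
  stopifnot(length(ensemble) >= 1L)
  ids <- lapply(ensemble, function(m) m$protein_ids)
  if (!all(vapply(ids, identical, logical(1), y = ids[[1L]])))
    stop("ensemble members predict different protein sets")
  acc <- NULL
  for (m in ensemble) {
    p <- zscore_rows(unclass(predict(m, dataset)))
    acc <- if (is.null(acc)) p else acc + p
  }
  omics_matrix(acc / length(ensemble), feature_ids = ids[[1L]],
               sample_ids = colnames(acc))
}
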