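test_that("the default grid enumerates twelve distinct submodels", {
  grid <- enumerate_submodels()
  expect_length(grid, 12L)
  expect_equal(anyDuplicated(names(grid)), 0L)
  srcs <- vapply(grid, function(g) g$encoder_source, character(1))
  expect_true(all(table(srcs) == 4L))

  pc_only <- enumerate_submodels(representations = "pc")
  expect_length(pc_only, 6L)
  one_set <- enumerate_submodels(lr_input_sets = list(
    full = c("decoded", "mrna", "premrna", "utr")))
  expect_length(one_set, 6L)
  expect_error(enumerate_submodels(lr_input_sets = list(
    a = c("decoded", "mrna"), b = c("mrna", "decoded"))), "duplicate")
})

test_that("submodel_config validates its contract and echoes defaults", {
  expect_error(submodel_config(lr_inputs = c("mrna")), "decoded")
  expect_error(submodel_config(validation_fraction = 1), "\\(0, 1\\)")
  cf <- submodel_config()
  expect_equal(cf$lr_scgen, 0.001)
  expect_equal(cf$lr_merge, 0.01)
  expect_equal(cf$patience, 30L)
  expect_equal(cf$max_epochs, 10000L)
  expect_equal(cf$validation_fraction, 0.10)
  expect_equal(cf$hvg_size, 5000L)
  expect_equal(cf$pc_size, 100L)
})

test_that("encoder obeys zero-weight, duplication and clamp contracts", {
  p <- submodel_params(n_input = 5, hidden_dims = 8L, latent_dim = 3,
                       dec_hidden_dims = 8L, n_proteins = 4,
                       seed = 1L, zero_init = TRUE)
  p$scgen$mu$b <- c(0.5, -1, 2)
  X <- matrix(rnorm(20), 4, 5)
  enc <- encode(list(params = p), X)
  expect_true(all(apply(enc$mu, 1, function(r)
    all(r == c(0.5, -1, 2)))))

  p2 <- submodel_params(n_input = 5, hidden_dims = 8L, latent_dim = 3,
                        dec_hidden_dims = 8L, n_proteins = 4, seed = 2L)
  X2 <- rbind(X[1, ], X[1, ], X[2, ])
  enc2 <- encode(list(params = p2), X2)
  expect_identical(enc2$mu[1, ], enc2$mu[2, ])
  expect_identical(enc2$logvar[1, ], enc2$logvar[2, ])
  # clamp bounds hold even under extreme weights
  p2$scgen$lv$W[] <- 100
  enc3 <- encode(list(params = p2), X * 1e3)
  expect_true(all(enc3$logvar >= -15 & enc3$logvar <= 15))
  expect_error(encode(list(params = p2), X[, 1:3]), "expected 5")
})

test_that("latent sampling matches the reparameterization moments", {
  dist <- list(mu = matrix(1.5, 1, 1), logvar = matrix(log(0.49), 1, 1))
  expect_identical(sample_latent(dist, "infer"), dist$mu)
  lowvar <- list(mu = matrix(2, 1, 1), logvar = matrix(-15, 1, 1))
  expect_lt(abs(sample_latent(lowvar, "train", seed = 1) - 2), 1e-3)

  draws <- vapply(1:10000, function(i)
    sample_latent(dist, "train", seed = i)[1, 1], numeric(1))
  se_mean <- 0.7 / sqrt(10000)
  expect_lt(abs(mean(draws) - 1.5), 3 * se_mean)
  se_sd <- 0.7 / sqrt(2 * 9999)
  expect_lt(abs(sd(draws) - 0.7), 3 * se_sd)
})

test_that("decoder is exact in the linear case and locally linear", {
  p <- submodel_params(n_input = 3, hidden_dims = integer(0),
                       latent_dim = 4, dec_hidden_dims = integer(0),
                       n_proteins = 5, seed = 3L)
  Z <- matrix(rnorm(8), 2, 4)
  expect_equal(decode(list(params = p), Z),
               Z %*% p$scgen$out$W +
                 matrix(p$scgen$out$b, 2, 5, byrow = TRUE),
               tolerance = 1e-12)

  pz <- submodel_params(n_input = 3, hidden_dims = integer(0),
                        latent_dim = 4, dec_hidden_dims = 6L,
                        n_proteins = 5, seed = 4L, zero_init = TRUE)
  pz$scgen$out$b <- 1:5
  expect_true(all(decode(list(params = pz), Z) ==
                    matrix(1:5, 2, 5, byrow = TRUE)))

  # finite-difference directional derivative on a nonlinear decoder
  pn <- submodel_params(n_input = 3, hidden_dims = integer(0),
                        latent_dim = 4, dec_hidden_dims = c(8L, 8L),
                        n_proteins = 5, seed = 5L)
  z0 <- matrix(rnorm(4), 1, 4)
  h <- 1e-6
  dir <- matrix(rnorm(4), 1, 4)
  num <- (decode(list(params = pn), z0 + h * dir) -
            decode(list(params = pn), z0 - h * dir)) / (2 * h)
  hh <- 1e-3
  num2 <- (decode(list(params = pn), z0 + hh * dir) -
             decode(list(params = pn), z0 - hh * dir)) / (2 * hh)
  expect_lt(max(abs(num - num2)), 1e-3)
})

test_that("the merge layer is exact per-protein linear regression", {
  decoded <- matrix(2, 1, 1)
  feats <- list(mrna = matrix(4, 1, 1))
  C <- matrix(0.25, 1, 1, dimnames = list(NULL, "mrna"))
  expect_equal(lr_merge(decoded, feats, a = 0.5, C = C, b0 = 1)[1, 1], 3)

  # passthrough and raw-mRNA special cases
  d2 <- matrix(rnorm(6), 2, 3)
  f2 <- list(mrna = matrix(rnorm(6), 2, 3))
  C0 <- matrix(0, 3, 1, dimnames = list(NULL, "mrna"))
  expect_equal(lr_merge(d2, f2, a = rep(1, 3), C = C0, b0 = rep(0, 3)), d2)
  C1 <- matrix(1, 3, 1, dimnames = list(NULL, "mrna"))
  expect_equal(lr_merge(d2, f2, a = rep(0, 3), C = C1, b0 = rep(0, 3)),
               f2$mrna)
})

test_that("the loss matches its closed forms", {
  mu0 <- matrix(0, 1, 1); lv0 <- matrix(0, 1, 1)
  y <- matrix(1, 1, 1)
  expect_equal(vae_loss(y, y, mu0, lv0, kl_weight = 0.005)$loss, 0)
  expect_equal(vae_loss(y, y, mu0, lv0)$kl, 0)

  mu1 <- matrix(1, 1, 1)
  l <- vae_loss(matrix(sqrt(0.2) + 1, 1, 1), matrix(1, 1, 1), mu1, lv0,
                kl_weight = 0.005)
  expect_equal(l$kl, 0.5)
  expect_equal(l$loss, 0.2 + 0.0025, tolerance = 1e-12)

  expect_error(vae_loss(y, matrix(NA_real_, 1, 1), mu0, lv0), "masked")
})

test_that("training stops early on constant targets and learns linear maps", {
  cfg <- generative_config(n_samples = 60L, n_genes = 80L,
                           n_proteins = 20L, seed = 17L)
  sim <- simulate_dataset(cfg)
  const <- sim$dataset
  const$protein <- omics_matrix(
    matrix(3, nrow(const$protein), ncol(const$protein),
           dimnames = dimnames(const$protein)))
  # with a material improvement threshold, training on constant targets
  # stalls as soon as the output has decayed toward the constant
  sc <- submodel_config(encoder_source = "mrna",
                        encoder_representation = "pc", pc_size = 10L,
                        latent_dim = 4L, hidden_dims = 8L,
                        max_epochs = 200L, patience = 5L,
                        min_delta = 0.01, seed = 2L)
  m_const <- train_submodel(const, sc)
  expect_lte(m_const$stopped_epoch, m_const$best_epoch + sc$patience)
  expect_lt(m_const$stopped_epoch, 150L)

  # strong linear signal: validation loss must at least halve
  lin <- sim$dataset
  lin$protein <- omics_matrix(
    0.8 * unclass(lin$mrna)[rownames(lin$protein), ] +
      matrix(rnorm(length(lin$protein), sd = 0.1),
             nrow(lin$protein), dimnames = dimnames(lin$protein)))
  m_lin <- train_submodel(lin, submodel_config(
    encoder_source = "mrna", encoder_representation = "pc", pc_size = 10L,
    latent_dim = 4L, hidden_dims = 8L, max_epochs = 200L, patience = 30L,
    seed = 2L))
  h <- m_lin$history
  expect_lt(min(h$val_loss), 0.5 * h$val_loss[1])
})

test_that("training and prediction are deterministic and batch-invariant", {
  fx <- small_trained_submodel()
  m <- fx$model
  sc <- m$config
  m2 <- train_submodel(fx$sim$dataset, sc)
  expect_equal(m$history, m2$history, tolerance = 1e-12)

  pred <- predict(m, fx$sim$dataset)
  pred2 <- predict(m, fx$sim$dataset)
  expect_identical(pred, pred2)
  one <- subset_dataset(fx$sim$dataset, colnames(fx$sim$dataset$mrna)[5])
  pred_one <- predict(m, one)
  expect_equal(unclass(pred_one)[, 1], unclass(pred)[, 5],
               tolerance = 1e-12)
})

test_that("prediction beats the raw-mRNA baseline against noiseless truth", {
  fx <- small_trained_submodel()
  noiseless <- fx$sim$truth$noiseless_protein
  pred_r <- per_feature_correlation(predict(fx$model, fx$sim$dataset),
                                    noiseless)
  mrna_r <- per_feature_correlation(
    fx$sim$dataset$mrna[rownames(noiseless), ], noiseless)
  expect_gt(mean(pred_r$r, na.rm = TRUE), mean(mrna_r$r, na.rm = TRUE))
})

test_that("zeroing a merge input's coefficients equals removing the input", {
  fx <- small_trained_submodel()
  m <- fx$model
  inp <- transprot:::prediction_inputs(m, fx$sim$dataset)
  fw <- transprot:::nn_forward(m$params, inp$Xenc, mode = "infer")
  p_zero <- m$params
  p_zero$merge$C[, "utr"] <- 0
  with_utr <- lr_merge(fw$decoded, inp$Xmerge, p_zero$merge$a,
                       p_zero$merge$C, p_zero$merge$b0)
  without <- lr_merge(fw$decoded, inp$Xmerge[c("mrna", "premrna")],
                      p_zero$merge$a,
                      p_zero$merge$C[, c("mrna", "premrna"), drop = FALSE],
                      p_zero$merge$b0)
  expect_equal(with_utr, without, tolerance = 1e-14)
})

test_that("ensemble consensus is the equal-weight mean of scaled members", {
  cfg <- generative_config(n_samples = 60L, n_genes = 60L,
                           n_proteins = 15L, seed = 23L)
  sim <- simulate_dataset(cfg)
  grid <- enumerate_submodels(hvg_size = 20L, pc_size = 8L, latent_dim = 3L,
                              hidden_dims = 8L, max_epochs = 3L,
                              patience = 2L, seed = 3L)
  ens <- train_ensemble(sim$dataset, grid)
  expect_length(ens, 12L)
  cons <- ensemble_predict(ens, sim$dataset)
  manual <- Reduce(`+`, lapply(ens, function(m)
    transprot:::zscore_rows(unclass(predict(m, sim$dataset))))) / 12
  expect_lt(max(abs(unclass(cons) - manual)), 1e-12)

  single <- ensemble_predict(ens[1], sim$dataset)
  expect_equal(unclass(single),
               transprot:::zscore_rows(unclass(predict(ens[[1]],
                                                       sim$dataset))),
               tolerance = 1e-12)
})
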