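# Shared fixture builders and independent oracles.

# small omics matrix with readable ids
toy_matrix <- function(values, fprefix = "g", sprefix = "s") {
  values <- as.matrix(values)
  omics_matrix(values,
               feature_ids = paste0(fprefix, seq_len(nrow(values))),
               sample_ids = paste0(sprefix, seq_len(ncol(values))))
}

# Closed-form population Pearson correlation between a gene's mRNA and its
# protein under the generative model, from the drawn coefficients:
#   m = lambda . L + e_m
#   p = c m + w . L + b x + e_p,  x = 1(u > m3)
# with L_1 = N(0,1) + pw (2u - 1), other latent coordinates standard normal.
analytic_mrna_protein_r <- function(truth) {
  cfg <- truth$config
  d <- cfg$latent_dim_true
  pw <- cfg$progression_weight
  m3 <- cfg$milestone_times[3L]
  sigma_l <- c(1 + pw^2 / 3, rep(1, d - 1L))     # Var of latent coords
  cov_lx <- c(pw * m3 * (1 - m3), rep(0, d - 1L))  # Cov(L, x)
  var_x <- m3 * (1 - m3)
  lam <- truth$gene_loadings[truth$protein_gene_index, , drop = FALSE]
  w <- truth$protein_loadings
  cc <- unname(truth$per_gene_coupling)
  b <- unname(truth$true_effects)
  var_m <- rowSums(lam^2 %*% diag(sigma_l)) + cfg$mrna_noise_sd^2
  lam_sw <- rowSums((lam * w) %*% diag(sigma_l))  # lambda' Sigma w
  lam_cx <- as.vector(lam %*% cov_lx)
  w_cx <- as.vector(w %*% cov_lx)
  cov_mp <- cc * var_m + lam_sw + b * lam_cx
  var_p <- cc^2 * var_m + rowSums(w^2 %*% diag(sigma_l)) + b^2 * var_x +
    cfg$protein_noise_sd^2 + 2 * cc * (lam_sw + b * lam_cx) + 2 * b * w_cx
  cov_mp / sqrt(var_m * var_p)
}

empirical_mrna_protein_r <- function(dataset) {
  prot <- unclass(dataset$protein)
  mr <- unclass(dataset$mrna)[rownames(prot), , drop = FALSE]
  vapply(seq_len(nrow(prot)),
         function(i) stats::cor(mr[i, ], prot[i, ]), numeric(1))
}

# Brute-force BH step-up oracle: q_(i) = min_{j >= i} p_(j) * m / j, cap 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exact hypergeometric upper tail by direct enumeration over log-choose
# (log scale keeps large universes finite).
hyper_tail_oracle <- function(k, m, n2, U) {
  lo <- max(0L, m + n2 - U)
  hi <- min(m, n2)
  j <- lo:hi
  probs <- exp(lchoose(m, j) + lchoose(U - m, n2 - j) - lchoose(U, n2))
  sum(probs[j >= k])
}

# A tiny trained submodel on simulated data, shared across model tests.
small_trained_submodel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generative_config(n_samples = 120L, n_genes = 150L,
                               n_proteins = 40L, seed = 31L)
      sim <- simulate_dataset(cfg)
      sc <- submodel_config(encoder_source = "mrna",
                            encoder_representation = "pc",
                            pc_size = 20L, latent_dim = 6L,
                            hidden_dims = 16L, max_epochs = 60L,
                            patience = 10L, seed = 32L)
      cache <<- list(sim = sim, model = train_submodel(sim$dataset, sc))
    }
    cache
  }
})
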