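#' Configuration for the paired multi-omics generator
#'
#' Encodes the generative assumptions the rest of the package is built to
#' exploit: a low-dimensional shared latent tissue state drives every
#' transcriptional layer and the proteome; each protein couples to its own
#' mRNA with a small gene-specific coefficient (so the average per-gene
#' mRNA-protein correlation is low); a phenotype adds a per-protein effect
#' on top; and a planted one-dimensional disease progression runs through
#' the latent state, with amyloid, tau, and cognition milestones appearing
#' as monotone logistic curves along it.
#'
#' @param n_samples,n_genes,n_proteins counts (`n_proteins <= n_genes`).
#' @param latent_dim_true dimension of the shared latent tissue state.
#' @param loading_scale per-coordinate sd of gene loadings on the latent
#'   state (transcriptional layers).
#' @param protein_loading_scale per-coordinate sd of the protein-specific
#'   latent loadings (the tissue-state signal not visible in the gene's
#'   own mRNA).
#' @param translation_coupling length-2 numeric `c(mean, sd)` of the
#'   per-gene mRNA-to-protein coupling coefficient.
#' @param mrna_noise_sd,premrna_noise_sd,utr_noise_sd,protein_noise_sd
#'   measurement-noise standard deviations per layer.
#' @param phenotype_effect_sd sd of the per-protein diagnosis effect.
#' @param progression_weight strength of the planted 1-D progression in the
#'   first latent coordinate (0 disables it).
#' @param milestone_times increasing triple in (0,1): centers of the
#'   amyloid, tau, and cognition logistic curves along true pseudotime.
#' @param utr_missing_fraction fraction of genes whose 3'UTR length is
#'   missing for all samples (gene-level missingness).
#' @param seed master seed; every sub-stream is derived from it.
#' @return a validated `generative_config` list.
#' @export
generative_config <- function(n_samples = 600L, n_genes = 2000L,
                              n_proteins = 500L, latent_dim_true = 10L,
                              loading_scale = 0.3,
                              protein_loading_scale = 0.39,
                              translation_coupling = c(mean = 0.1, sd = 0.05),
                              mrna_noise_sd = 1, premrna_noise_sd = 1.3,
                              utr_noise_sd = 1, protein_noise_sd = 0.6,
                              phenotype_effect_sd = 0.3,
                              progression_weight = 1,
                              milestone_times = c(amyloid = 0.2, tau = 0.5,
                                                  cognition = 0.8),
                              utr_missing_fraction = 0.1, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_proteins = as.integer(n_proteins),
              latent_dim_true = as.integer(latent_dim_true),
              loading_scale = loading_scale,
              protein_loading_scale = protein_loading_scale,
              translation_coupling = c(mean = unname(translation_coupling[1]),
                                       sd = unname(translation_coupling[2])),
              mrna_noise_sd = mrna_noise_sd,
              premrna_noise_sd = premrna_noise_sd,
              utr_noise_sd = utr_noise_sd,
              protein_noise_sd = protein_noise_sd,
              phenotype_effect_sd = phenotype_effect_sd,
              progression_weight = progression_weight,
              milestone_times = milestone_times,
              utr_missing_fraction = utr_missing_fraction,
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_samples, n_genes, n_proteins, latent_dim_true) < 1L))
      stop("all counts must be >= 1")
    if (n_proteins > n_genes)
      stop("n_proteins (", n_proteins, ") must not exceed n_genes (",
           n_genes, ")")
    if (any(c(mrna_noise_sd, premrna_noise_sd, utr_noise_sd,
              protein_noise_sd) < 0))
      stop("noise sds must be non-negative")
    if (length(milestone_times) != 3L || any(diff(milestone_times) <= 0) ||
        any(milestone_times <= 0) || any(milestone_times >= 1))
      stop("milestone_times must be three strictly increasing values in (0,1)")
    if (utr_missing_fraction < 0 || utr_missing_fraction >= 1)
      stop("utr_missing_fraction must be in [0, 1)")
  })
  structure(cfg, class = "generative_config")
}

#' Simulate a paired multi-omics dataset with known ground truth
#'
#' Draws latent tissue states, gene loadings, per-gene translation
#' couplings and per-protein phenotype effects, and emits aligned mRNA,
#' pre-mRNA, 3'UTR-length and protein matrices together with per-sample
#' metadata whose amyloid/tau/cognition trajectories are monotone logistic
#' curves (slope 10) of the planted true pseudotime, centered at the
#' configured milestones. Identical configurations (including the seed)
#' produce bit-identical output.
#'
#' The protein layer follows
#' `protein_g = coupling_g * mRNA_g + w_g . latent + b_g * x + noise`,
#' where `x` is the binary diagnosis indicator.
#'
#' @param config a [generative_config()].
#' @return list with elements `dataset` (a [multi_omics_dataset()]) and
#'   `truth` (latent states, true pseudotime, drawn coefficients, the
#'   noiseless protein matrix, and per-protein phenotype effects).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  n <- config$n_samples; p <- config$n_genes; d <- config$latent_dim_true
  seed <- config$seed
  gene_ids <- sprintf("gene%04d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))

  u <- with_substream(seed, "pseudotime", stats::runif(n))
  L <- with_substream(seed, "latent",
                      matrix(stats::rnorm(n * d), n, d))
  L[, 1L] <- L[, 1L] + config$progression_weight * (2 * u - 1)

  lambda <- with_substream(seed, "gene_loadings",
                           matrix(stats::rnorm(p * d, sd = config$loading_scale),
                                  p, d))
  gamma <- with_substream(seed, "utr_loadings",
                          matrix(stats::rnorm(p * d,
                                              sd = 0.5 * config$loading_scale),
                                 p, d))
  signal <- lambda %*% t(L)  # genes x samples, shared by mRNA and pre-mRNA

  mrna <- signal + with_substream(seed, "mrna_noise",
    matrix(stats::rnorm(p * n, sd = config$mrna_noise_sd), p, n))
  premrna <- signal + with_substream(seed, "premrna_noise",
    matrix(stats::rnorm(p * n, sd = config$premrna_noise_sd), p, n))
  utr <- gamma %*% t(L) + with_substream(seed, "utr_noise",
    matrix(stats::rnorm(p * n, sd = config$utr_noise_sd), p, n))
  n_miss <- floor(config$utr_missing_fraction * p)
  utr_missing <- if (n_miss > 0L)
    with_substream(seed, "utr_missing", sample.int(p, n_miss)) else integer(0)
  utr[utr_missing, ] <- NA_real_

  prot_idx <- sort(with_substream(seed, "protein_genes",
                                  sample.int(p, config$n_proteins)))
  coupling <- with_substream(seed, "coupling",
    stats::rnorm(config$n_proteins, mean = config$translation_coupling["mean"],
                 sd = config$translation_coupling["sd"]))
  W <- with_substream(seed, "protein_loadings",
    matrix(stats::rnorm(config$n_proteins * d,
                        sd = config$protein_loading_scale),
           config$n_proteins, d))
  b <- with_substream(seed, "effects",
                      stats::rnorm(config$n_proteins,
                                   sd = config$phenotype_effect_sd))

  m3 <- config$milestone_times[3L]
  x <- as.numeric(u > m3)  # diagnosis indicator (AD analog)
  noiseless <- coupling * mrna[prot_idx, , drop = FALSE] +
    W %*% t(L) + outer(b, x)
  protein <- noiseless + with_substream(seed, "protein_noise",
    matrix(stats::rnorm(config$n_proteins * n, sd = config$protein_noise_sd),
           config$n_proteins, n))

  sig <- function(center) stats::plogis(10 * (u - center))
  md_noise <- with_substream(seed, "metadata", list(
    slope = stats::rnorm(n, sd = 0.5),
    age = round(stats::rnorm(n, 86, 5), 1),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.65, 0.35)),
    educ = pmax(8, round(stats::rnorm(n, 16, 2)))))
  metadata <- data.frame(
    sample_id = sample_ids,
    diagnosis = factor(ifelse(x > 0, "AD", "control"),
                       levels = c("control", "AD")),
    amyloid = sig(config$milestone_times[1L]),
    tau = sig(config$milestone_times[2L]),
    cognition = sig(m3),
    global_pathology = (sig(config$milestone_times[1L]) +
                          sig(config$milestone_times[2L])) / 2,
    cognition_slope = -(2 * u - 1) + md_noise$slope,
    age = md_noise$age,
    sex = md_noise$sex,
    education = md_noise$educ,
    stringsAsFactors = FALSE)

  dimnames(mrna) <- dimnames(premrna) <- dimnames(utr) <-
    list(gene_ids, sample_ids)
  prot_ids <- gene_ids[prot_idx]
  dimnames(protein) <- dimnames(noiseless) <- list(prot_ids, sample_ids)

  dataset <- multi_omics_dataset(
    mrna = omics_matrix(mrna), premrna = omics_matrix(premrna),
    utr = omics_matrix(utr), protein = omics_matrix(protein),
    metadata = metadata)
  truth <- list(latent_states = L, true_pseudotime = u,
                per_gene_coupling = stats::setNames(coupling, prot_ids),
                noiseless_protein = omics_matrix(noiseless),
                true_effects = stats::setNames(b, prot_ids),
                phenotype = x,
                gene_loadings = lambda, protein_loadings = W,
                protein_gene_index = prot_idx,
                utr_missing_genes = gene_ids[utr_missing],
                config = config)
  list(dataset = dataset, truth = truth)
}

#' Configuration of the replicate measurement-noise model
#'
#' The model behind the dissociation between low between-platform protein
#' abundance correlation and high fold-change concordance: measured protein
#' abundance is `p = b * x + N(0, sigma^2)` with the phenotype signal
#' `b * x` shared between replicate measurements and the noise independent.
#'
#' @param n_samples,n_proteins counts.
#' @param effect_sd sd of the per-protein phenotype effect `b`.
#' @param noise_sd measurement-noise sd `sigma` (>= 0).
#' @param phenotype_type `"binary"` (balanced case-control, default) or
#'   `"continuous"` (standard normal).
#' @param seed master seed.
#' @export
noise_model_config <- function(n_samples = 400L, n_proteins = 1000L,
                               effect_sd = 1, noise_sd = 1,
                               phenotype_type = c("binary", "continuous"),
                               seed = 1L) {
  phenotype_type <- match.arg(phenotype_type)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (effect_sd < 0) stop("effect_sd must be >= 0")
  if (n_samples < 2L || n_proteins < 1L) stop("invalid counts")
  structure(list(n_samples = as.integer(n_samples),
                 n_proteins = as.integer(n_proteins),
                 effect_sd = effect_sd, noise_sd = noise_sd,
                 phenotype_type = phenotype_type, seed = as.integer(seed)),
            class = "noise_model_config")
}

#' Simulate two replicate protein measurements sharing one phenotype signal
#'
#' Both replicates carry the identical `b * x` signal plus independent
#' `N(0, sigma^2)` noise, so the expected per-protein correlation between
#' replicates is `b^2 Var(x) / (b^2 Var(x) + sigma^2)` while per-protein
#' effect estimates remain concordant even under heavy noise.
#'
#' @param config a [noise_model_config()].
#' @return list with `rep1`, `rep2` ([omics_matrix()], proteins x samples),
#'   `phenotype` (per-sample values) and `truth` (per-protein effects `b`).
#' @export
simulate_replicate_pair <- function(config) {
  stopifnot(inherits(config, "noise_model_config"))
  n <- config$n_samples; p <- config$n_proteins; seed <- config$seed
  x <- if (config$phenotype_type == "binary") {
    with_substream(seed, "phenotype",
                   sample(rep(c(0, 1), length.out = n)))
  } else {
    with_substream(seed, "phenotype", stats::rnorm(n))
  }
  b <- with_substream(seed, "effects", stats::rnorm(p, sd = config$effect_sd))
  signal <- outer(b, x)
  rep1 <- signal + with_substream(seed, "noise_rep1",
    matrix(stats::rnorm(p * n, sd = config$noise_sd), p, n))
  rep2 <- signal + with_substream(seed, "noise_rep2",
    matrix(stats::rnorm(p * n, sd = config$noise_sd), p, n))
  prot_ids <- sprintf("prot%04d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))
  dimnames(rep1) <- dimnames(rep2) <- list(prot_ids, sample_ids)
  list(rep1 = omics_matrix(rep1), rep2 = omics_matrix(rep2),
       phenotype = stats::setNames(x, sample_ids),
       truth = stats::setNames(b, prot_ids))
}

#' Closed-form replicate correlation under the measurement-noise model
#'
#' @param b per-protein effects.
#' @param var_x phenotype variance.
#' @param noise_sd measurement-noise sd.
#' @return per-protein expected correlation between two replicates.
#' @export
replicate_correlation_closed_form <- function(b, var_x, noise_sd) {
  s <- b^2 * var_x
  if (noise_sd == 0) return(ifelse(s > 0, 1, NA_real_))
  s / (s + noise_sd^2)
}

#' Solve for the noise sd giving a target mean replicate correlation
#'
#' Inverts the closed form of [replicate_correlation_closed_form()] averaged
#' over the supplied effects, by monotone root finding in `sigma`.
#'
#' @inheritParams replicate_correlation_closed_form
#' @param target_mean_r desired mean per-protein replicate correlation.
#' @export
calibrate_noise_sd <- function(b, var_x, target_mean_r) {
  stopifnot(target_mean_r > 0, target_mean_r < 1, any(b != 0))
  f <- function(s) mean(replicate_correlation_closed_form(b, var_x, s)) -
    target_mean_r
  upper <- sqrt(max(b^2) * var_x) * 1e3 + 1
  stats::uniroot(f, c(1e-9, upper), tol = 1e-12)$root
}

#' Simulate a proteome dominated by a planted disease progression
#'
#' Generates a feature-by-sample matrix whose features follow module-wise
#' logistic trajectories of a planted pseudotime: each module has a stage
#' center along pseudotime, every member feature is a scaled (randomly
#' signed) logistic curve of slope `slope` centered near it, plus
#' independent Gaussian noise. Optionally a non-monotone (sine-shaped)
#' module is included. Clinical metadata carries the same milestone
#' sigmoids as [simulate_dataset()]. This is the ground-truth bench for
#' the trajectory and staging pipeline: the progression is the dominant
#' structure, as in a proteome whose major axis of variation is disease
#' state.
#'
#' @param n_samples number of samples (default 500).
#' @param features_per_module features per module (default 40).
#' @param module_centers named numeric vector of stage centers along
#'   pseudotime (defaults place one module in each of the early, mid and
#'   late windows defined by `milestone_times`).
#' @param include_sine_module add a non-monotone module (default `TRUE`).
#' @param noise_sd per-cell Gaussian noise sd (default 0.3; curve
#'   amplitudes are drawn in `[0.5, 1.5]`).
#' @param slope logistic slope shared with the clinical curves
#'   (default 10).
#' @param center_jitter_sd per-feature jitter of the module center
#'   (default 0.02).
#' @param milestone_times clinical milestone centers as in
#'   [generative_config()].
#' @param seed master seed.
#' @return list with `matrix` (an [omics_matrix()]), `metadata` (as in
#'   [simulate_dataset()]), `module_assignments` (feature -> module), and
#'   `truth` (`true_pseudotime`, module centers).
#' @export
simulate_progression_dataset <- function(n_samples = 500L,
                                         features_per_module = 40L,
                                         module_centers = c(early = 0.15,
                                                            mid = 0.40,
                                                            late = 0.70),
                                         include_sine_module = TRUE,
                                         noise_sd = 0.3, slope = 10,
                                         center_jitter_sd = 0.02,
                                         milestone_times = c(amyloid = 0.2,
                                                             tau = 0.5,
                                                             cognition = 0.8),
                                         seed = 1L) {
  stopifnot(n_samples >= 10L, features_per_module >= 1L, noise_sd >= 0)
  u <- with_substream(seed, "pseudotime", stats::runif(n_samples))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  modules <- names(module_centers)
  blocks <- list()
  assignments <- character(0)
  set.seed(substream_seed(seed, "curves"))
  for (m in modules) {
    # members of a module covary: one direction per module, positive scale
    amp <- sample(c(-1, 1), 1L) * stats::runif(features_per_module, 0.5, 1.5)
    ctr <- module_centers[[m]] +
      stats::rnorm(features_per_module, sd = center_jitter_sd)
    blk <- vapply(seq_len(features_per_module), function(i)
      amp[i] * stats::plogis(slope * (u - ctr[i])), numeric(n_samples))
    blocks[[m]] <- t(blk)
    assignments <- c(assignments,
                     stats::setNames(rep(m, features_per_module),
                                     sprintf("%s_f%03d", m,
                                             seq_len(features_per_module))))
  }
  if (include_sine_module) {
    # non-monotone hump: rises then falls over the progression (a half
    # sine period keeps the two ends of the trajectory dissimilar)
    amp <- sample(c(-1, 1), 1L) * stats::runif(features_per_module, 0.5, 1.5)
    phase <- stats::runif(features_per_module, -0.05, 0.05)
    blk <- vapply(seq_len(features_per_module), function(i)
      amp[i] * sin(pi * (u + phase[i])), numeric(n_samples))
    blocks[["sine"]] <- t(blk)
    assignments <- c(assignments,
                     stats::setNames(rep("sine", features_per_module),
                                     sprintf("sine_f%03d",
                                             seq_len(features_per_module))))
  }
  vals <- do.call(rbind, blocks)
  rownames(vals) <- names(assignments)
  colnames(vals) <- sample_ids
  vals <- vals + with_substream(seed, "noise",
    matrix(stats::rnorm(length(vals), sd = noise_sd), nrow(vals)))
  sig <- function(center) stats::plogis(slope * (u - center))
  metadata <- data.frame(
    sample_id = sample_ids,
    amyloid = sig(milestone_times[1L]),
    tau = sig(milestone_times[2L]),
    cognition = sig(milestone_times[3L]),
    global_pathology = (sig(milestone_times[1L]) +
                          sig(milestone_times[2L])) / 2,
    cognition_slope = -(2 * u - 1) +
      with_substream(seed, "slope_noise", stats::rnorm(n_samples, sd = 0.5)),
    stringsAsFactors = FALSE)
  list(matrix = omics_matrix(vals), metadata = metadata,
       module_assignments = assignments,
       truth = list(true_pseudotime = u, module_centers = module_centers,
                    milestone_times = milestone_times, slope = slope))
}
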