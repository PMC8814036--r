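test_that("top PCs reconstruct low-rank data and validate n", {
  set.seed(1)
  basis <- matrix(rnorm(10), 5, 2)
  scores <- matrix(rnorm(24), 12, 2)
  x <- scores %*% t(basis)
  m <- omics_matrix(t(x), feature_ids = paste0("f", 1:5),
                    sample_ids = paste0("s", 1:12))
  pcs <- top_pcs(m, n = 2)
  recon <- pcs %*% solve(crossprod(pcs), crossprod(pcs, scale(x, scale = FALSE)))
  expect_lt(max(abs(recon - scale(x, scale = FALSE))), 1e-8)

  dup <- omics_matrix(t(rbind(x, x[1, ])),
                      feature_ids = paste0("f", 1:5),
                      sample_ids = paste0("s", 1:13))
  pcs_dup <- top_pcs(dup, n = 2)
  expect_equal(pcs_dup[13, ], pcs_dup[1, ], tolerance = 1e-10)
  expect_error(top_pcs(m, n = 0), ">= 1")
  expect_error(top_pcs(m, n = 50), "exceeds")
})

test_that("kNN graph uses union symmetrization with index tie-breaks", {
  pts <- matrix(c(0, 1, 10), 3, 1)
  A <- knn_graph(pts, k = 1)
  expect_equal(A, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3),
               ignore_attr = TRUE)
  set.seed(2)
  B <- knn_graph(matrix(rnorm(40), 20, 2), k = 4)
  expect_identical(B, t(B))
  expect_true(all(diag(B) == 0))
  expect_true(all(rowSums(B) >= 4))
  full <- knn_graph(matrix(rnorm(12), 6, 2), k = 5)
  expect_true(all(full[upper.tri(full)] == 1))
  expect_error(knn_graph(pts, k = 3), "smaller")
})

test_that("spectral embedding orders a path graph by the Fiedler vector", {
  n <- 5
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  emb <- spectral_embedding(A, dim = 2)
  expect_true(all(diff(emb[, 1]) > 0) || all(diff(emb[, 1]) < 0))

  # permutation equivariance (up to the per-axis sign, which is free for
  # an antisymmetric eigenvector)
  set.seed(3)
  P <- sample(n)
  emb_p <- spectral_embedding(A[P, P], dim = 2)
  expect_lt(min(max(abs(emb_p[order(P), 1] - emb[, 1])),
                max(abs(emb_p[order(P), 1] + emb[, 1]))), 1e-8)

  # complete graph: flat nontrivial spectrum is flagged degenerate
  K <- matrix(1, 6, 6); diag(K) <- 0
  embk <- spectral_embedding(K, dim = 2)
  expect_true(attr(embk, "degenerate"))

  # disconnected graph: largest component embedded, the rest NA
  A2 <- matrix(0, 7, 7)
  A2[1:5, 1:5] <- A
  A2[6, 7] <- A2[7, 6] <- 1
  emb2 <- spectral_embedding(A2, dim = 2)
  expect_true(all(is.na(emb2[6:7, ])))
  expect_true(all(!is.na(emb2[1:5, ])))
})

test_that("principal path recovers orderings on lines and arcs", {
  set.seed(4)
  t0 <- sort(runif(200))
  line <- cbind(t0, 0.5 * t0) + matrix(rnorm(400, sd = 1e-4), 200)
  tr <- fit_trajectory(line, seed = 1)
  expect_gt(abs(cor(tr$pseudotime, t0, method = "spearman")), 0.99)
  expect_true(min(tr$pseudotime) == 0 && max(tr$pseudotime) == 1)
  expect_gte(nrow(tr$path), 2)

  arc <- cbind(cos(pi * t0), sin(pi * t0)) +
    matrix(rnorm(400, sd = 0.1), 200)
  tra <- fit_trajectory(arc, seed = 2)
  expect_gt(abs(cor(tra$pseudotime, t0, method = "spearman")), 0.9)

  # orientation freedom: the flipped embedding gives 1 - pseudotime in
  # the orientation-free sense
  trb <- fit_trajectory(arc[rev(seq_len(200)), ], seed = 2)
  expect_gt(abs(cor(trb$pseudotime, rev(tra$pseudotime),
                    method = "spearman")), 0.99)
  expect_error(fit_trajectory(matrix(1, 50, 2)), "degenerate")
})

test_that("pseudotime is invariant to sample permutation and rotation", {
  set.seed(5)
  t0 <- sort(runif(150))
  pts <- cbind(t0, 0.3 * sin(2 * t0)) + matrix(rnorm(300, sd = 0.02), 150)
  base <- fit_trajectory(pts, seed = 3)$pseudotime
  P <- sample(150)
  perm <- fit_trajectory(pts[P, ], seed = 3)$pseudotime
  expect_gt(abs(cor(perm[order(P)], base, method = "spearman")), 0.99)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- fit_trajectory(pts %*% R, seed = 3)$pseudotime
  expect_gt(abs(cor(rot, base, method = "spearman")), 0.99)
})

test_that("LOESS reproduces polynomials up to its degree", {
  set.seed(6)
  t0 <- runif(120)
  for (y in list(rep(2.5, 120), 3 * t0 - 1, 2 * t0^2 - t0 + 1)) {
    fit <- loess_fit(t0, y, degree = 2, span = 0.6)
    truth <- if (length(unique(y)) == 1) rep(y[1], 100) else {
      cf <- coef(lm(y ~ t0 + I(t0^2)))
      cf[1] + cf[2] * fit$grid + cf[3] * fit$grid^2
    }
    expect_lt(max(abs(fit$fitted - truth)), 1e-6)
  }
  expect_error(loess_fit(t0, rnorm(120), span = 0.01), "span too small")
})

test_that("milestone crossings match analytic and root-finding oracles", {
  ramp <- seq(0, 1, length.out = 101)
  expect_equal(milestone_pseudotime(ramp), 0.25, tolerance = 0.011)
  expect_true(is.na(milestone_pseudotime(rep(1, 50))))

  grid <- seq(0, 1, length.out = 101)
  f <- plogis(10 * (grid - 0.5))
  # dense numeric root finding for |f(t) - f(0)| = 0.25 * variation
  variation <- max(f) - min(f)
  root <- uniroot(function(t) plogis(10 * (t - 0.5)) - plogis(-5) -
                    0.25 * variation, c(0, 1), tol = 1e-10)$root
  expect_lt(abs(milestone_pseudotime(f) - root), 0.011)
})

test_that("stage classification separates planted curve shapes", {
  grid <- seq(0, 1, length.out = 100)
  curves <- list(
    pre_amyloid = plogis(10 * (grid - 0.05)),
    post_cognition = plogis(30 * (grid - 0.95)),
    wave = sin(2 * pi * grid))
  st <- classify_stage(curves, clinical_milestones = c(0.2, 0.5, 0.8))
  expect_equal(st$stage[st$module_id == "pre_amyloid"], "early")
  expect_equal(st$stage[st$module_id == "post_cognition"], "unspecified")
  expect_equal(st$stage[st$module_id == "wave"], "unspecified")
  expect_false(st$monotone[st$module_id == "wave"])
  expect_error(classify_stage(curves, c(0.5, 0.2, 0.8)), "increasing")
})

test_that("LMG shares are conservative and exact for orthogonal designs", {
  set.seed(7)
  n <- 80
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)   # exactly orthogonal, centered
  y <- 2 * x1 + 1 * x2 + rnorm(n)
  ri <- relative_importance(y, cbind(a = x1, b = x2))
  expect_lt(abs(sum(ri$shares) - ri$total_r2), 1e-10)
  marg <- vapply(list(x1, x2), function(x) {
    f <- lm(y ~ x); summary(f)$r.squared
  }, numeric(1))
  expect_lt(max(abs(ri$shares - marg)), 1e-10)

  one <- relative_importance(y, cbind(a = x1))
  expect_equal(unname(one$shares), one$total_r2, tolerance = 1e-12)

  for (i in 1:20) {
    set.seed(100 + i)
    X <- matrix(rnorm(60 * 4), 60, 4)
    yy <- X %*% rnorm(4) + rnorm(60)
    rr <- relative_importance(yy, X)
    expect_lt(abs(sum(rr$shares) - rr$total_r2), 1e-10)
  }
  expect_error(relative_importance(y, matrix(rnorm(80 * 7), 80, 7)),
               "at most 6")
})

test_that("the full pipeline recovers a planted progression robustly", {
  sd0 <- simulate_progression_dataset(n_samples = 300L,
                                      features_per_module = 25L, seed = 13L)
  anchor <- setNames(sd0$metadata$global_pathology,
                     sd0$metadata$sample_id)
  tr <- proteome_pseudotime(sd0$matrix, n_pcs = 30, k = 10,
                            orient_by = anchor, seed = 2)
  sp <- cor(tr$pseudotime, sd0$truth$true_pseudotime, method = "spearman")
  expect_gt(sp, 0.9)  # oriented: positive by the anchor
  rb <- pseudotime_robustness(sd0$matrix, k_values = c(10, 10),
                              pc_values = 30, seed = 2)
  expect_equal(rb$mean_abs_spearman, 1, tolerance = 1e-12)
})
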