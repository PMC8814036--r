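linear_params <- function(n_input, n_prot, seed) {
  # no hidden layers: f(x) = x W_mu W_out + const, an exactly linear map
  submodel_params(n_input = n_input, hidden_dims = integer(0),
                  latent_dim = n_input, dec_hidden_dims = integer(0),
                  n_proteins = n_prot, seed = seed)
}

test_that("attributions match the closed form for linear models", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- linear_params(4, 3, seed)
    X <- matrix(rnorm(20), 5, 4)
    BG <- matrix(rnorm(32), 8, 4)
    at <- expected_gradient_attribution(list(params = p), X,
                                        list(encoder_input = BG),
                                        n_draws = sample(c(1, 5, 40), 1))
    W <- p$scgen$mu$W %*% p$scgen$out$W
    for (t in 1:3) {
      closed <- sweep(X, 2, colMeans(BG), "-") *
        matrix(W[, t], 5, 4, byrow = TRUE)
      expect_lt(max(abs(at$contributions[, , t] - closed)), 1e-6)
    }
    expect_lt(check_local_accuracy(at), 1e-6)
  }
})

test_that("degenerate attribution cases are exact zeros", {
  p <- linear_params(3, 2, 5)
  bg_row <- matrix(rnorm(3), 1, 3)
  BG1 <- rbind(bg_row, bg_row)  # effectively one background point
  at <- expected_gradient_attribution(list(params = p), bg_row,
                                      list(encoder_input = BG1),
                                      n_draws = 10)
  expect_lt(max(abs(at$contributions)), 1e-12)

  # an input with zero weight downstream gets zero contribution
  p$scgen$mu$W[2, ] <- 0
  X <- matrix(rnorm(12), 4, 3)
  BG <- matrix(rnorm(15), 5, 3)
  at2 <- expected_gradient_attribution(list(params = p), X,
                                       list(encoder_input = BG),
                                       n_draws = 20)
  expect_lt(max(abs(at2$contributions[, 2, ])), 1e-12)
})

test_that("sampled-estimator accuracy improves with draws; exact is exact", {
  # nonlinear model: ReLU layers make the path integral non-trivial
  p <- submodel_params(n_input = 3, hidden_dims = 8L, latent_dim = 4,
                       dec_hidden_dims = 8L, n_proteins = 2, seed = 11)
  set.seed(12)
  X <- matrix(rnorm(9), 3, 3)
  BG <- matrix(rnorm(12), 4, 3)
  devs <- vapply(c(4, 40, 400), function(nd)
    check_local_accuracy(expected_gradient_attribution(
      list(params = p), X, list(encoder_input = BG), n_draws = nd,
      method = "sampled")),
    numeric(1))
  expect_lt(devs[3], devs[1])
  exact <- expected_gradient_attribution(list(params = p), X,
                                         list(encoder_input = BG))
  expect_lt(check_local_accuracy(exact), 1e-10)
  # both integrators agree in the large-draw limit
  big <- expected_gradient_attribution(list(params = p), X,
                                       list(encoder_input = BG),
                                       n_draws = 4000, method = "sampled")
  expect_lt(max(abs(big$contributions - exact$contributions)), 0.01)
})

test_that("input ranking follows mean absolute contribution with ID ties", {
  contrib <- array(0, dim = c(2, 3, 1),
                   dimnames = list(NULL, c("b", "a", "c"), "t1"))
  contrib[, 1, 1] <- c(1, -1)    # b: mean |c| = 1
  contrib[, 2, 1] <- c(1, 1)     # a: mean |c| = 1 (tie with b)
  contrib[, 3, 1] <- c(3, 1)     # c: mean |c| = 2
  attr <- structure(list(contributions = contrib,
                         prediction = matrix(0, 2, 1),
                         baseline_prediction = 0,
                         input_feature_ids = c("b", "a", "c"),
                         target_protein_ids = "t1"),
                    class = "attribution_result")
  rk <- rank_inputs(attr)
  expect_identical(rk$input_id, c("c", "a", "b"))
  expect_equal(rk$score, c(2, 1, 1))
})

test_that("contribution removal is additive and recovers the baseline", {
  p <- linear_params(4, 2, 21)
  set.seed(22)
  X <- matrix(rnorm(24), 6, 4)
  colnames(X) <- paste0("PC", 1:4)
  BG <- matrix(rnorm(40), 10, 4)
  at <- expected_gradient_attribution(list(params = p), X,
                                      list(encoder_input = BG),
                                      n_draws = 20)
  # removing everything leaves the baseline prediction
  adj_all <- remove_input_contribution(at$prediction, at,
                                       at$input_feature_ids)
  expect_lt(max(abs(sweep(adj_all, 2, at$baseline_prediction, "-"))), 1e-8)
  # order independence
  ab <- remove_input_contribution(
    remove_input_contribution(at$prediction, at, "PC1"), at, "PC2")
  ba <- remove_input_contribution(
    remove_input_contribution(at$prediction, at, "PC2"), at, "PC1")
  expect_equal(ab, ba, tolerance = 1e-14)
  # zero-contribution input leaves predictions unchanged
  p0 <- p
  p0$scgen$mu$W[3, ] <- 0
  at0 <- expected_gradient_attribution(list(params = p0), X,
                                       list(encoder_input = BG),
                                       n_draws = 20)
  expect_equal(remove_input_contribution(at0$prediction, at0, "PC3"),
               at0$prediction, tolerance = 1e-12)
  expect_error(remove_input_contribution(at$prediction, at, "nope"),
               "unknown input")
})

test_that("removing the trait-carrying input destroys the association", {
  # input 1 carries the trait; the model passes it through linearly
  set.seed(31)
  n <- 120
  trait <- rnorm(n)
  X <- cbind(trait + rnorm(n, sd = 0.2), matrix(rnorm(n * 3), n, 3))
  colnames(X) <- paste0("PC", 1:4)
  p <- linear_params(4, 1, 33)
  p$scgen$mu$W <- diag(4)
  p$scgen$out$W <- matrix(c(2, 0.1, 0.1, 0.1), 4, 1)
  BG <- X[1:30, ]
  at <- expected_gradient_attribution(list(params = p), X,
                                      list(encoder_input = BG),
                                      n_draws = 50)
  adj <- remove_input_contribution(at$prediction, at, "PC1")
  r2 <- function(y) summary(stats::lm(y ~ trait))$r.squared
  expect_lt(r2(adj[, 1]), 0.10 * r2(at$prediction[, 1]))
})

test_that("partial R-squared deltas match a direct OLS oracle", {
  set.seed(41)
  n <- 150
  trait <- rnorm(n)
  covars <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- 1.2 * trait + 0.5 * covars$age + rnorm(n)
  orig <- cbind(t1 = y)
  # full removal: replace by covariate-only noise
  adj <- cbind(t1 = 0.5 * covars$age + rnorm(n))
  d0 <- variance_explained_delta(orig, orig, trait, covars)
  expect_equal(unname(d0), 0)

  # oracle: partial R2 from nested lm fits
  pr2 <- function(yy) {
    full <- stats::lm(yy ~ trait + age + sex, data = cbind(covars))
    red <- stats::lm(yy ~ age + sex, data = covars)
    (sum(resid(red)^2) - sum(resid(full)^2)) / sum(resid(red)^2)
  }
  d <- variance_explained_delta(orig, adj, trait, covars)
  expect_equal(unname(d) / 100, pr2(y) - pr2(adj[, 1]), tolerance = 1e-6)
  expect_error(variance_explained_delta(orig, adj, rep(1, n), covars),
               "constant")
})
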