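# Internal feed-forward machinery for the encoder/decoder submodel.
# Dense layers with ReLU hidden activations; all shapes are samples x units.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# broadcast a length-ncol vector over the columns of M (fast sweep)
add_col <- function(M, v) M + rep(v, rep.int(nrow(M), length(v)))
mul_col <- function(M, v) M * rep(v, rep.int(nrow(M), length(v)))

LOGVAR_CLAMP <- c(-15, 15)

#' Initialize the parameter set of one encoder/decoder/merge submodel
#'
#' Weight layout: an encoder trunk of ReLU layers feeding two linear heads
#' (`mu`, `logvar`), a decoder of ReLU layers ending in a linear output over
#' proteins, and a per-protein merge layer with weight `a_g` on the decoded
#' value, one coefficient `c_{g,f}` per configured transcript feature, and
#' an intercept. He initialization for ReLU layers; the `logvar` head and
#' the merge coefficients start at zero (merge `a_g` starts at 1, i.e.
#' decoded passthrough).
#'
#' @param n_input encoder input dimension.
#' @param hidden_dims integer vector of encoder trunk widths (may be empty).
#' @param latent_dim latent dimension.
#' @param dec_hidden_dims integer vector of decoder widths (may be empty;
#'   empty gives a purely linear decoder).
#' @param n_proteins number of output proteins.
#' @param merge_extra character vector of merge inputs besides `decoded`.
#' @param seed integer seed for the initialization draws.
#' @param zero_init if `TRUE`, all weights start at zero (useful for
#'   inspecting the pure-bias behaviour of the network).
#' @return nested parameter list with `scgen` and `merge` groups.
#' @export
submodel_params <- function(n_input, hidden_dims, latent_dim, dec_hidden_dims,
                            n_proteins, merge_extra = character(0),
                            seed = 1L, zero_init = FALSE) {
  set.seed(substream_seed(seed, "init"))
  mk <- function(n_in, n_out, scale) {
    W <- if (zero_init) matrix(0, n_in, n_out)
         else matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out)
    list(W = W, b = numeric(n_out))
  }
  he <- function(n_in) sqrt(2 / n_in)
  dims <- c(n_input, hidden_dims)
  enc <- list()
  for (i in seq_along(hidden_dims))
    enc[[i]] <- mk(dims[i], dims[i + 1L], he(dims[i]))
  trunk_out <- dims[length(dims)]
  mu <- mk(trunk_out, latent_dim, sqrt(1 / trunk_out))
  lv <- mk(trunk_out, latent_dim, 0)  # start at logvar = 0
  lv$W[] <- 0
  ddims <- c(latent_dim, dec_hidden_dims)
  dec <- list()
  for (i in seq_along(dec_hidden_dims))
    dec[[i]] <- mk(ddims[i], ddims[i + 1L], he(ddims[i]))
  dec_out <- mk(ddims[length(ddims)], n_proteins,
                sqrt(1 / ddims[length(ddims)]))
  merge <- list(a = rep(1, n_proteins),
                C = matrix(0, n_proteins, length(merge_extra),
                           dimnames = list(NULL, merge_extra)),
                b0 = numeric(n_proteins))
  list(scgen = list(enc = enc, mu = mu, lv = lv, dec = dec,
                    out = dec_out),
       merge = merge)
}

# Forward pass through encoder trunk + heads + latent + decoder.
# mode "infer": z = mu; mode "train": z = mu + exp(logvar/2) * eps.
nn_forward <- function(params, X, mode = c("infer", "train"), eps = NULL) {
  mode <- match.arg(mode)
  sg <- params$scgen
  H <- X
  enc_pre <- list()
  for (i in seq_along(sg$enc)) {
    pre <- add_col(H %*% sg$enc[[i]]$W, sg$enc[[i]]$b)
    enc_pre[[i]] <- pre
    H <- relu(pre)
  }
  mu <- add_col(H %*% sg$mu$W, sg$mu$b)
  lv_raw <- add_col(H %*% sg$lv$W, sg$lv$b)
  lv <- pmin(pmax(lv_raw, LOGVAR_CLAMP[1]), LOGVAR_CLAMP[2])
  if (mode == "train") {
    if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu)), nrow(mu))
    z <- mu + exp(lv / 2) * eps
  } else {
    eps <- NULL
    z <- mu
  }
  D <- z
  dec_pre <- list()
  for (i in seq_along(sg$dec)) {
    pre <- add_col(D %*% sg$dec[[i]]$W, sg$dec[[i]]$b)
    dec_pre[[i]] <- pre
    D <- relu(pre)
  }
  decoded <- add_col(D %*% sg$out$W, sg$out$b)
  list(X = X, H = H, mu = mu, lv = lv, lv_raw = lv_raw, eps = eps, z = z,
       D = D, decoded = decoded, enc_pre = enc_pre, dec_pre = dec_pre,
       mode = mode)
}

# Backward pass. d_decoded: gradient of the loss w.r.t. the decoded output;
# d_mu_extra / d_lv_extra: additive gradients (e.g. from the KL term).
# Returns gradients mirroring params$scgen.
nn_backward <- function(params, cache, d_decoded,
                        d_mu_extra = NULL, d_lv_extra = NULL) {
  sg <- params$scgen
  g <- list(enc = vector("list", length(sg$enc)),
            dec = vector("list", length(sg$dec)))
  # decoder output layer
  g$out <- list(W = crossprod(cache$D, d_decoded), b = colSums(d_decoded))
  dD <- d_decoded %*% t(sg$out$W)
  for (i in rev(seq_along(sg$dec))) {
    dpre <- dD * (cache$dec_pre[[i]] > 0)
    inp <- if (i == 1L) cache$z else relu(cache$dec_pre[[i - 1L]])
    g$dec[[i]] <- list(W = crossprod(inp, dpre), b = colSums(dpre))
    dD <- dpre %*% t(sg$dec[[i]]$W)
  }
  dz <- dD
  d_mu <- dz
  if (!is.null(d_mu_extra)) d_mu <- d_mu + d_mu_extra
  if (identical(cache$mode, "train")) {
    d_lv <- dz * cache$eps * 0.5 * exp(cache$lv / 2)
  } else {
    d_lv <- matrix(0, nrow(dz), ncol(dz))
  }
  if (!is.null(d_lv_extra)) d_lv <- d_lv + d_lv_extra
  # clamp: zero gradient where the raw pre-clamp value was outside bounds
  d_lv <- d_lv * (cache$lv_raw > LOGVAR_CLAMP[1] &
                    cache$lv_raw < LOGVAR_CLAMP[2])
  g$mu <- list(W = crossprod(cache$H, d_mu), b = colSums(d_mu))
  g$lv <- list(W = crossprod(cache$H, d_lv), b = colSums(d_lv))
  dH <- d_mu %*% t(sg$mu$W) + d_lv %*% t(sg$lv$W)
  for (i in rev(seq_along(sg$enc))) {
    dpre <- dH * (cache$enc_pre[[i]] > 0)
    inp <- if (i == 1L) cache$X else relu(cache$enc_pre[[i - 1L]])
    g$enc[[i]] <- list(W = crossprod(inp, dpre), b = colSums(dpre))
    dH <- dpre %*% t(sg$enc[[i]]$W)
  }
  g$d_input <- dH
  g
}

# Gradient of decoded[, target] with respect to the encoder input, for all
# rows of the cached forward pass (infer mode: z = mu path only).
nn_input_gradient <- function(params, cache, target) {
  sg <- params$scgen
  n <- nrow(cache$X)
  G <- matrix(sg$out$W[, target], n, nrow(sg$out$W), byrow = TRUE)
  for (i in rev(seq_along(sg$dec))) {
    G <- G * (cache$dec_pre[[i]] > 0)
    G <- G %*% t(sg$dec[[i]]$W)
  }
  G <- G %*% t(sg$mu$W)  # z = mu at inference
  for (i in rev(seq_along(sg$enc))) {
    G <- G * (cache$enc_pre[[i]] > 0)
    G <- G %*% t(sg$enc[[i]]$W)
  }
  G
}

# --- Adam over the nested parameter tree -----------------------------------

adam_init <- function(params) {
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    list(m = x * 0, v = x * 0)
  }
  lapply(params, walk)
}

adam_step <- function(params, grads, state, lr_by_group, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s, lr) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], s[[nm]], lr)
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      return(list(p = p, s = s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  for (grp in names(lr_by_group)) {
    if (is.null(grads[[grp]])) next
    r <- upd(params[[grp]], grads[[grp]], state[[grp]], lr_by_group[[grp]])
    params[[grp]] <- r$p
    state[[grp]] <- r$s
  }
  list(params = params, state = state)
}

# Segment the straight path from background b to input x at every hidden
# ReLU sign change. Processing layers in forward order, each layer's
# preactivations are linear in t within the segments induced by earlier
# layers, so sign-change roots are exact linear interpolations. Returns
# segment midpoints (where the network gradient is constant) and segment
# widths; together they give the exact path integral of the gradient.
path_segments <- function(params, b, x) {
  ts <- c(0, 1)
  sg <- params$scgen
  n_enc <- length(sg$enc)
  n_relu <- n_enc + length(sg$dec)
  dx <- x - b
  at_t <- function(tt) outer(tt, dx) + matrix(b, length(tt), length(b),
                                              byrow = TRUE)
  if (n_relu > 0) {
    for (li in seq_len(n_relu)) {
      fw <- nn_forward(params, at_t(ts), mode = "infer")
      pre <- if (li <= n_enc) fw$enc_pre[[li]] else fw$dec_pre[[li - n_enc]]
      roots <- numeric(0)
      for (i in seq_len(length(ts) - 1L)) {
        v0 <- pre[i, ]
        v1 <- pre[i + 1L, ]
        cross <- which(v0 * v1 < 0)
        if (length(cross))
          roots <- c(roots, ts[i] + (ts[i + 1L] - ts[i]) *
                       v0[cross] / (v0[cross] - v1[cross]))
      }
      ts <- sort(unique(c(ts, roots)))
      ts <- ts[c(TRUE, diff(ts) > 1e-12)]
      if (ts[length(ts)] != 1) ts[length(ts)] <- 1
    }
  }
  mids <- (ts[-length(ts)] + ts[-1L]) / 2
  list(points = at_t(mids), weights = diff(ts))
}
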