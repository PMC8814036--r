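#' Top principal-component scores of an omics profile
#'
#' Centered (unscaled) PCA of the samples, components ordered by
#' decreasing variance. Missing cells are imputed to the feature mean
#' before decomposition.
#'
#' @param matrix an [omics_matrix()] (features x samples) or a plain
#'   samples x features numeric matrix.
#' @param n number of components (default 40).
#' @return samples x n score matrix.
#' @export
top_pcs <- function(matrix, n = 40L) {
  x <- if (is_omics_matrix(matrix)) t(unclass(matrix)) else as.matrix(matrix)
  if (n < 1L) stop("n must be >= 1")
  if (n > min(dim(x))) stop("n (", n, ") exceeds min(#features, #samples)")
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[!miss, j])
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n)
  scores <- pr$x[, seq_len(n), drop = FALSE]
  rownames(scores) <- rownames(x)
  scores
}

#' k-nearest-neighbour graph over samples
#'
#' Binary symmetric adjacency: an edge joins i and j when either is among
#' the other's k nearest Euclidean neighbours (union symmetrization).
#' Distance ties are broken by sample index; self-edges are excluded.
#'
#' @param scores samples x d coordinate matrix.
#' @param k neighbourhood size (default 10; must be < number of samples).
#' @return n x n 0/1 adjacency matrix.
#' @export
knn_graph <- function(scores, k = 10L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k >= n) stop("k (", k, ") must be smaller than the sample count (",
                   n, ")")
  D <- as.matrix(stats::dist(scores))
  A <- matrix(0L, n, n, dimnames = list(rownames(scores), rownames(scores)))
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    A[i, nb] <- 1L
  }
  A <- pmax(A, t(A))
  diag(A) <- 0L
  A
}

graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Spectral embedding of a sample graph
#'
#' Eigenvectors 2..(dim+1) of the symmetric normalized graph Laplacian
#' (ascending eigenvalues), degree-renormalized. The per-axis sign is
#' fixed by making each axis's largest-magnitude coordinate positive, so
#' the embedding is deterministic. If the graph is disconnected, the
#' largest component is embedded and the remaining samples get `NA`
#' coordinates, flagged in the `components` attribute.
#'
#' @param adjacency symmetric nonnegative adjacency matrix.
#' @param dim embedding dimension (default 2).
#' @return samples x dim coordinate matrix; attribute `degenerate` is set
#'   when the nontrivial spectrum is (near-)flat, as for a complete graph.
#' @export
spectral_embedding <- function(adjacency, dim = 2L) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  if (n == 0L) stop("empty graph")
  comp <- graph_components(A)
  main <- which(comp == which.max(tabulate(comp)))
  out <- matrix(NA_real_, n, dim,
                dimnames = list(rownames(A), paste0("SE", seq_len(dim))))
  Am <- A[main, main, drop = FALSE]
  deg <- rowSums(Am)
  deg[deg == 0] <- 1
  Dm <- 1 / sqrt(deg)
  L <- diag(length(main)) - (Dm * Am) * rep(Dm, each = length(main))
  L <- (L + t(L)) / 2
  eig <- eigen(L, symmetric = TRUE)
  idx <- rev(seq_len(length(main)))  # ascending eigenvalues
  evals <- eig$values[idx]
  evecs <- eig$vectors[, idx, drop = FALSE]
  take <- seq(2L, dim + 1L)
  if (max(take) > length(main)) stop("graph too small for dim = ", dim)
  emb <- evecs[, take, drop = FALSE] * Dm
  for (j in seq_len(ncol(emb))) {
    imax <- which.max(abs(emb[, j]))
    if (emb[imax, j] < 0) emb[, j] <- -emb[, j]
  }
  out[main, ] <- emb
  nontrivial <- evals[-1L]
  attr(out, "degenerate") <-
    (max(nontrivial) - min(nontrivial)) < 1e-10 * max(abs(nontrivial), 1e-12)
  attr(out, "components") <- comp
  out
}

polyline_length <- function(v) {
  if (nrow(v) < 2L) return(0)
  sum(sqrt(rowSums((v[-1L, , drop = FALSE] -
                      v[-nrow(v), , drop = FALSE])^2)))
}

# Project points onto a polyline; returns arc-length positions and the
# per-point segment index and within-segment coordinate.
project_to_polyline <- function(points, vertices) {
  nseg <- nrow(vertices) - 1L
  seg_len <- numeric(nseg)
  best_d <- rep(Inf, nrow(points))
  best_t <- numeric(nrow(points))
  best_seg <- integer(nrow(points))
  best_lambda <- numeric(nrow(points))
  cum <- 0
  cum_start <- numeric(nseg)
  for (s in seq_len(nseg)) {
    a <- vertices[s, ]; b <- vertices[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    lam <- if (len2 == 0) rep(0, nrow(points))
           else pmin(1, pmax(0, (sweep(points, 2L, a, "-") %*% ab) / len2))
    proj <- sweep(outer(as.vector(lam), ab), 2L, a, "+")
    d <- rowSums((points - proj)^2)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_seg[upd] <- s
    best_lambda[upd] <- lam[upd]
    cum_start[s] <- cum
    seg_len[s] <- sqrt(len2)
    cum <- cum + seg_len[s]
  }
  arc <- cum_start[best_seg] + best_lambda * seg_len[best_seg]
  list(arc = arc, segment = best_seg, lambda = best_lambda,
       dist2 = best_d, total_length = cum)
}

#' Fit a principal path through an embedding and assign pseudotime
#'
#' Seeded k-means partitions the samples into `n_clusters` clusters; the
#' cluster centers are ordered to minimize total polyline length, midpoints
#' are inserted, and the path is refined iteratively: samples are
#' projected onto their nearest segment, each vertex moves toward the
#' weighted mean of the samples projecting onto its adjacent segments,
#' blended with a smoothing pull (weight 0.1) toward the neighbouring
#' vertices, until the maximum vertex movement falls below `tol`.
#' Pseudotime is the arc-length position of each sample's projection,
#' min-max normalized to `[0, 1]`; its orientation is arbitrary unless
#' anchored downstream.
#'
#' @param embedding samples x d coordinates (rows with `NA` are dropped
#'   from fitting and get `NA` pseudotime).
#' @param n_clusters number of k-means clusters (default 3).
#' @param max_iter refinement iteration cap (default 100).
#' @param tol vertex-movement convergence tolerance (default 1e-6).
#' @param seed k-means seed.
#' @return a `trajectory_result` with `embedding`, `path` (ordered
#'   polyline vertices), `pseudotime` in `[0, 1]`, and `parameters`.
#' @export
fit_trajectory <- function(embedding, n_clusters = 3L, max_iter = 100L,
                           tol = 1e-6, seed = 1L) {
  emb <- as.matrix(embedding)
  ok <- stats::complete.cases(emb)
  pts <- emb[ok, , drop = FALSE]
  if (nrow(pts) <= n_clusters)
    stop("need more samples than clusters")
  if (sum(apply(pts, 2L, stats::var)) < 1e-20)
    stop("degenerate embedding: all points coincide")
  set.seed(substream_seed(seed, "kmeans"))
  km <- stats::kmeans(pts, centers = n_clusters, nstart = 10L,
                      iter.max = 100L)
  centers <- km$centers
  perms <- all_permutations(n_clusters)
  # orientation-free: keep orders whose first index < last index
  perms <- perms[vapply(perms, function(p) p[1L] < p[length(p)],
                        logical(1))]
  lens <- vapply(perms, function(p)
    polyline_length(centers[p, , drop = FALSE]), numeric(1))
  ordc <- perms[[which.min(lens)]]
  v <- centers[ordc, , drop = FALSE]
  # insert midpoints between consecutive centers
  vv <- matrix(NA_real_, 2L * nrow(v) - 1L, ncol(v))
  vv[seq(1L, nrow(vv), by = 2L), ] <- v
  for (i in seq_len(nrow(v) - 1L))
    vv[2L * i, ] <- (v[i, ] + v[i + 1L, ]) / 2
  v <- vv
  smooth_w <- 0.1
  for (it in seq_len(max_iter)) {
    pr <- project_to_polyline(pts, v)
    newv <- v
    for (j in seq_len(nrow(v))) {
      touching <- which(pr$segment == j - 1L | pr$segment == j)
      # weight samples by proximity of their projection to this vertex
      if (length(touching)) {
        wts <- numeric(length(touching))
        seg <- pr$segment[touching]
        lam <- pr$lambda[touching]
        wts[seg == j] <- 1 - lam[seg == j]
        wts[seg == j - 1L] <- lam[seg == j - 1L]
        if (sum(wts) > 1e-12) {
          target <- colSums(pts[touching, , drop = FALSE] * wts) / sum(wts)
          nbr <- c(j - 1L, j + 1L)
          nbr <- nbr[nbr >= 1L & nbr <= nrow(v)]
          nb_mean <- colMeans(v[nbr, , drop = FALSE])
          newv[j, ] <- (1 - smooth_w) * target + smooth_w * nb_mean
        }
      }
    }
    move <- max(abs(newv - v))
    v <- newv
    if (move < tol) break
  }
  pr <- project_to_polyline(pts, v)
  pt <- pr$arc
  rng <- range(pt)
  pt <- if (diff(rng) > 0) (pt - rng[1L]) / diff(rng) else rep(0, length(pt))
  pseudotime <- rep(NA_real_, nrow(emb))
  pseudotime[ok] <- pt
  names(pseudotime) <- rownames(emb)
  structure(list(embedding = emb, path = v, pseudotime = pseudotime,
                 parameters = list(n_clusters = n_clusters,
                                   max_iter = max_iter, tol = tol,
                                   seed = seed, iterations = it)),
            class = "trajectory_result")
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n),
                                                            i)[r])
  }
  out
}

#' Full proteome pseudotime pipeline
#'
#' Top PCs, kNN graph, spectral embedding, and principal-path pseudotime
#' in one call. When `orient_by` is given (a per-sample reference such as
#' global pathology), the pseudotime is flipped if needed so the
#' reference increases along it; otherwise the orientation is arbitrary.
#'
#' @param matrix an [omics_matrix()].
#' @param n_pcs number of PCs (default 40).
#' @param k kNN neighbourhood size (default 10).
#' @param n_clusters path clusters (default 3).
#' @param orient_by optional per-sample numeric anchor, named or matrix
#'   order.
#' @param seed seed for the path fit.
#' @return a `trajectory_result` (see [fit_trajectory()]).
#' @export
proteome_pseudotime <- function(matrix, n_pcs = 40L, k = 10L,
                                n_clusters = 3L, orient_by = NULL,
                                seed = 1L) {
  scores <- top_pcs(matrix, n = n_pcs)
  A <- knn_graph(scores, k = k)
  emb <- spectral_embedding(A, dim = 2L)
  res <- fit_trajectory(emb, n_clusters = n_clusters, seed = seed)
  if (!is.null(orient_by)) {
    anchor <- if (!is.null(names(orient_by)))
      orient_by[names(res$pseudotime)] else orient_by
    ct <- suppressWarnings(stats::cor(res$pseudotime, anchor,
                                      use = "complete.obs"))
    if (is.finite(ct) && ct < 0) {
      res$pseudotime <- 1 - res$pseudotime
      res$path <- res$path[rev(seq_len(nrow(res$path))), , drop = FALSE]
    }
  }
  res
}

#' LOESS fit of a response over pseudotime on an even grid
#'
#' Tricube-weighted local polynomial regression of the stated degree
#' (default 2), evaluated on an even pseudotime grid spanning the data.
#'
#' @param pseudotime,y paired numeric vectors (NAs dropped pairwise).
#' @param degree local polynomial degree (default 2).
#' @param span LOESS span (default 0.75).
#' @param grid_size number of evaluation points (default 100).
#' @return list with `grid` and `fitted`.
#' @export
loess_fit <- function(pseudotime, y, degree = 2L, span = 0.75,
                      grid_size = 100L) {
  ok <- !is.na(pseudotime) & !is.na(y)
  t0 <- pseudotime[ok]; y0 <- y[ok]
  if (length(unique(t0)) < degree + 2L)
    stop("too few distinct pseudotime values for degree ", degree)
  if (span * length(t0) < degree + 2L)
    stop("span too small: local windows would hold fewer than ",
         degree + 2L, " points")
  fit <- stats::loess(y0 ~ t0, degree = degree, span = span,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(t0), max(t0), length.out = grid_size)
  list(grid = grid, fitted = as.vector(stats::predict(fit,
                                                      newdata = data.frame(
                                                        t0 = grid))))
}

#' Milestone crossing time of a smoothed curve
#'
#' The overall variation of the curve is `max - min`; the milestone is
#' the earliest grid time at which the curve has moved away from its
#' starting value by at least `threshold` of that variation (default
#' 25%). Returns `NA` for a flat curve.
#'
#' @param curve list with `grid` and `fitted` (from [loess_fit()]) or a
#'   numeric vector on an implicit `[0, 1]` grid.
#' @param threshold fraction of overall variation (default 0.25).
#' @export
milestone_pseudotime <- function(curve, threshold = 0.25) {
  if (is.list(curve)) {
    grid <- curve$grid; f <- curve$fitted
  } else {
    f <- as.numeric(curve); grid <- seq(0, 1, length.out = length(f))
  }
  variation <- max(f) - min(f)
  if (variation == 0) return(NA_real_)
  hit <- which(abs(f - f[1L]) >= threshold * variation)
  if (!length(hit)) return(NA_real_)
  grid[hit[1L]]
}

#' Stage modules as early / mid / late along clinical milestones
#'
#' Each module's smoothed curve is tested for monotonicity by its
#' counter-trend movement: the total curve movement against the net
#' direction may make up at most `monotone_tol` of the total absolute
#' movement (a movement-weighted criterion, robust to numerically tiny
#' wiggles in flat stretches of the fit; smoothing-induced boundary
#' overshoot of a LOESS fit stays well below the default tolerance,
#' while a genuine rise-and-fall exceeds it several-fold). Non-monotone modules are
#' `"unspecified"`. Monotone modules are staged by their 25%-variation
#' crossing: `early` if at or before the amyloid milestone, `mid` if at
#' or before tau, `late` if at or before cognition, otherwise
#' `unspecified`. Ties at a milestone fall to the earlier stage.
#'
#' @param module_curves named list of curves (each a [loess_fit()] result
#'   or numeric vector).
#' @param clinical_milestones increasing numeric triple, e.g. from
#'   [milestone_pseudotime()] applied to amyloid, tau, and cognition
#'   curves.
#' @param threshold variation fraction for the crossing (default 0.25).
#' @param monotone_tol allowed counter-trend fraction of the total
#'   absolute movement (default 0.15).
#' @return data.frame with `module_id`, `crossing_pseudotime`, `monotone`,
#'   `stage`.
#' @export
classify_stage <- function(module_curves, clinical_milestones,
                           threshold = 0.25, monotone_tol = 0.15) {
  if (length(clinical_milestones) != 3L ||
      any(diff(clinical_milestones) <= 0))
    stop("clinical_milestones must be three increasing values")
  one <- function(curve) {
    f <- if (is.list(curve)) curve$fitted else as.numeric(curve)
    variation <- max(f) - min(f)
    d <- diff(f)
    total_move <- sum(abs(d))
    if (variation == 0 || total_move == 0)
      return(list(crossing = NA_real_, monotone = FALSE))
    net_dir <- if (sum(d) >= 0) 1 else -1
    counter <- sum(abs(d[sign(d) == -net_dir]))
    monotone <- (counter / total_move) <= monotone_tol
    list(crossing = milestone_pseudotime(curve, threshold),
         monotone = monotone)
  }
  rows <- lapply(names(module_curves), function(id) {
    r <- one(module_curves[[id]])
    stage <- if (!r$monotone || is.na(r$crossing)) "unspecified"
    else if (r$crossing <= clinical_milestones[1L]) "early"
    else if (r$crossing <= clinical_milestones[2L]) "mid"
    else if (r$crossing <= clinical_milestones[3L]) "late"
    else "unspecified"
    data.frame(module_id = id, crossing_pseudotime = r$crossing,
               monotone = r$monotone, stage = stage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' LMG relative importance of regression predictors
#'
#' Decomposes the R-squared of `outcome ~ predictors` into per-predictor
#' shares by averaging each predictor's sequential R-squared gain over
#' all predictor orderings. Shares sum to the total R-squared; orthogonal
#' predictors receive exactly their marginal R-squared.
#'
#' @param outcome numeric response.
#' @param predictors data.frame or matrix with at most 6 columns (the
#'   orderings grow factorially).
#' @return list with `shares` (named, summing to `total_r2`) and
#'   `total_r2`.
#' @export
relative_importance <- function(outcome, predictors) {
  X <- as.matrix(as.data.frame(predictors))
  p <- ncol(X)
  if (p > 6L) stop("at most 6 predictors supported (factorial orderings)")
  ok <- stats::complete.cases(outcome, X)
  y <- outcome[ok]; X <- X[ok, , drop = FALSE]
  if (qr(cbind(1, X))$rank < p + 1L) stop("design is rank-deficient")
  tss <- sum((y - mean(y))^2)
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / tss
  }
  subsets <- lapply(0:(2^p - 1L), function(m) which(bitwAnd(m,
    2^(seq_len(p) - 1L)) > 0))
  r2 <- vapply(subsets, r2_of, numeric(1))
  key <- vapply(subsets, function(s)
    paste0("s", paste(s, collapse = ",")), character(1))
  r2v <- stats::setNames(r2, key)
  shares <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (m in 0:(2^(p - 1L) - 1L)) {
      s <- others[which(bitwAnd(m, 2^(seq_len(p - 1L) - 1L)) > 0)]
      k <- length(s)
      wgt <- factorial(k) * factorial(p - k - 1L) / factorial(p)
      gain <- r2v[paste0("s", paste(sort(c(s, j)), collapse = ","))] -
        r2v[paste0("s", paste(s, collapse = ","))]
      shares[j] <- shares[j] + wgt * gain
    }
  }
  names(shares) <- colnames(X) %||% paste0("x", seq_len(p))
  list(shares = shares, total_r2 = r2_of(seq_len(p)))
}

#' Robustness of pseudotime to the graph and PCA settings
#'
#' Recomputes pseudotime over a grid of `k` and PC counts and reports the
#' mean pairwise absolute Spearman correlation between settings
#' (orientation-free).
#'
#' @param matrix an [omics_matrix()].
#' @param k_values,pc_values settings to cross.
#' @param seed path-fit seed (shared across settings).
#' @return list with `mean_abs_spearman` and the per-setting pseudotime
#'   matrix.
#' @export
pseudotime_robustness <- function(matrix, k_values = c(5L, 10L, 25L, 50L),
                                  pc_values = 40L, seed = 1L) {
  grid <- expand.grid(k = k_values, n_pcs = pc_values)
  if (nrow(grid) < 2L) stop("need at least 2 settings")
  pts <- lapply(seq_len(nrow(grid)), function(i)
    proteome_pseudotime(matrix, n_pcs = grid$n_pcs[i], k = grid$k[i],
                        seed = seed)$pseudotime)
  M <- do.call(cbind, pts)
  colnames(M) <- sprintf("k%d_pc%d", grid$k, grid$n_pcs)
  cors <- c()
  for (i in seq_len(ncol(M) - 1L))
    for (j in (i + 1L):ncol(M))
      cors <- c(cors, abs(stats::cor(M[, i], M[, j], method = "spearman",
                                     use = "complete.obs")))
  list(mean_abs_spearman = mean(cors), pseudotimes = M, settings = grid)
}
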