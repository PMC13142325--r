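# Self-contained UMAP layout. No UMAP package ships with this R
# distribution, so the standard construction is implemented directly:
# smooth-kNN affinities with per-point bandwidth calibration, fuzzy-union
# symmetrization, PCA initialization and a negative-sampling stochastic
# layout with the usual (a, b) attraction curve. Small-cohort scale only.

smooth_knn_affinities <- function(d_nn, n_iter = 64L) {
  k <- ncol(d_nn)
  target <- log2(k)
  t(apply(d_nn, 1, function(dr) {
    rho <- min(dr)
    lo <- 1e-8; hi <- 1e4
    for (it in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-pmax(dr - rho, 0) / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    exp(-pmax(dr - rho, 0) / ((lo + hi) / 2))
  }))
}

#' Two-dimensional UMAP embedding of the property space
#'
#' Deterministic under a fixed seed. Defaults (15 neighbours, min_dist
#' 0.1) follow common practice for cohort-scale data; `n_neighbors` is
#' clamped to `n - 1`.
#'
#' @param m a standardized `property_matrix` (or plain numeric matrix).
#' @param seed integer seed.
#' @param n_neighbors affinity neighbourhood size.
#' @param n_epochs layout optimization epochs.
#' @param min_dist minimum embedding distance (sets the attraction curve).
#' @return `n x 2` coordinate matrix.
#' @export
embed_umap <- function(m, seed = 1L, n_neighbors = 15L, n_epochs = 200L,
                       min_dist = 0.1) {
  x <- if (is.data.frame(m)) pm_values(m) else as.matrix(m)
  n <- nrow(x)
  if (n < 4L) stop("need at least four rows to embed")
  k <- min(n_neighbors, n - 1L)
  set.seed(seed)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(dr) order(dr)[seq_len(k)]))
  d_nn <- t(vapply(seq_len(n), function(i) d[i, nn[i, ]], numeric(k)))
  P <- matrix(0, n, n)
  A <- smooth_knn_affinities(d_nn)
  for (i in seq_len(n)) P[i, nn[i, ]] <- A[i, ]
  P <- P + t(P) - P * t(P)                    # fuzzy union
  # attraction curve parameters for spread 1; fitted constants for
  # min_dist = 0.1 are the widely used a = 1.577, b = 0.895
  ab <- if (abs(min_dist - 0.1) < 1e-9) c(1.577, 0.8951) else
    fit_ab(min_dist)
  a <- ab[1]; b <- ab[2]
  pc <- stats::prcomp(x, rank. = 2L)
  y <- pc$x[, 1:2, drop = FALSE]
  y <- y / max(1e-9, stats::sd(y)) * 1e-2     # small-scale init
  ed <- which(P > 0 & upper.tri(P), arr.ind = TRUE)
  wts <- P[ed]
  alpha0 <- 1
  n_neg <- 5L
  for (ep in seq_len(n_epochs)) {
    alpha <- alpha0 * (1 - (ep - 1) / n_epochs)
    ord <- sample.int(nrow(ed))
    for (e in ord) {
      if (stats::runif(1) > wts[e]) next
      i <- ed[e, 1]; j <- ed[e, 2]
      dv <- y[i, ] - y[j, ]
      d2 <- sum(dv * dv)
      grad <- (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
      g <- pmin(pmax(grad * dv, -4), 4)
      y[i, ] <- y[i, ] + alpha * g
      y[j, ] <- y[j, ] - alpha * g
      for (s in seq_len(n_neg)) {
        jn <- sample.int(n, 1L)
        if (jn == i) next
        dv <- y[i, ] - y[jn, ]
        d2 <- sum(dv * dv)
        grad <- (2 * b) / ((0.001 + d2) * (1 + a * d2^b))
        g <- pmin(pmax(grad * dv, -4), 4)
        y[i, ] <- y[i, ] + alpha * g
      }
    }
  }
  unname(y)
}

fit_ab <- function(min_dist, spread = 1) {
  xs <- seq(0, spread * 3, length.out = 300)
  target <- ifelse(xs < min_dist, 1, exp(-(xs - min_dist) / spread))
  fn <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * xs^(2 * b)) - target)^2)
  }
  p <- stats::optim(c(log(1.5), log(1)), fn)$par
  c(exp(p[1]), exp(p[2]))
}
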