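#' Assemble a property matrix from a list of property vectors
#'
#' @param vectors list of [compute_property_vector()] results.
#' @param pundiff optional numeric colony probabilities (same order).
#' @param groups optional group labels.
#' @return data frame with `id` (+ optional `pundiff`, `group`) and the 31
#'   property columns; class `property_matrix`.
#' @export
property_matrix <- function(vectors, pundiff = NULL, groups = NULL) {
  stopifnot(length(vectors) >= 1L)
  mat <- do.call(rbind, lapply(vectors, unclass))
  df <- data.frame(id = vapply(vectors, function(v) attr(v, "id"),
                               character(1)),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(pundiff)) df$pundiff <- pundiff
  if (!is.null(groups)) df$group <- groups
  class(df) <- c("property_matrix", "data.frame")
  df
}

pm_feature_columns <- function(m) intersect(property_names(), names(m))

pm_values <- function(m) as.matrix(m[, pm_feature_columns(m), drop = FALSE])

#' Standardize property columns to zero mean and unit sample SD
#'
#' Constant columns cannot be standardized and are dropped with a warning.
#'
#' @param m a `property_matrix` (or plain data frame with property
#'   columns).
#' @return the matrix with standardized property columns.
#' @export
standardize_matrix <- function(m) {
  if (nrow(m) < 2L) stop("need at least two colonies to standardize")
  for (cl in pm_feature_columns(m)) {
    s <- stats::sd(m[[cl]])
    if (!is.finite(s) || s == 0) {
      warning("dropping constant property column: ", cl)
      m[[cl]] <- NULL
    } else {
      m[[cl]] <- (m[[cl]] - mean(m[[cl]])) / s
    }
  }
  m
}

knn_graph <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  edges <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  igraph::simplify(g)          # union of mutual/one-sided edges
}

#' Cluster colonies on a k-nearest-neighbour graph with Leiden
#'
#' Builds the Euclidean kNN graph (k = 8, one-sided neighbour edges
#' unioned) on the standardized properties and runs Leiden community
#' detection with the modularity objective.
#'
#' @param m standardized `property_matrix`.
#' @param k neighbours per colony.
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed (Leiden is deterministic given the seed).
#' @return object of class `cluster_result`: `labels` (integer per
#'   colony), `k`, `resolution`, `per_cluster` (data frame with size and,
#'   when present, mean colony P_undiff), `effect_sizes` (see
#'   [cluster_effect_sizes()]).
#' @export
cluster_colonies <- function(m, k = 8L, resolution = 1.0, seed = 1L) {
  x <- pm_values(m)
  if (nrow(x) <= k) stop("need more colonies than neighbours")
  g <- knn_graph(x, k)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5L)
  labels <- igraph::membership(cl)
  per <- data.frame(cluster = sort(unique(as.integer(labels))))
  per$size <- as.integer(table(factor(labels, levels = per$cluster)))
  if (!is.null(m$pundiff))
    per$mean_pundiff <- vapply(per$cluster, function(cc)
      mean(m$pundiff[labels == cc]), numeric(1))
  es <- if (length(unique(labels)) >= 2L &&
            min(table(labels)) >= 2L)
    cluster_effect_sizes(m, labels) else NULL
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 resolution = resolution, per_cluster = per,
                 effect_sizes = es),
            class = "cluster_result")
}

#' Cohen's d of every property, one cluster versus the rest
#'
#' `d = (mean_c - mean_rest) / s_pooled` with the pooled standard
#' deviation `sqrt(((n_c-1) s_c^2 + (n_r-1) s_r^2) / (n_c + n_r - 2))`;
#' a zero pooled SD yields signed `Inf`. Within each cluster, properties
#' are ranked by decreasing `|d|`.
#'
#' @param m a `property_matrix`.
#' @param labels cluster labels, one per row.
#' @return data frame: `cluster`, `property`, `d`, `rank`.
#' @export
cluster_effect_sizes <- function(m, labels) {
  x <- pm_values(m)
  stopifnot(length(labels) == nrow(x))
  if (length(unique(labels)) < 2L) stop("need at least two clusters")
  out <- NULL
  for (cc in sort(unique(labels))) {
    inC <- labels == cc
    if (sum(inC) < 2L || sum(!inC) < 2L)
      stop("each cluster and its complement need at least two members")
    d <- vapply(colnames(x), function(p)
      cohens_d(x[inC, p], x[!inC, p]), numeric(1))
    df <- data.frame(cluster = cc, property = colnames(x), d = d,
                     row.names = NULL)
    df <- df[order(-abs(df$d)), ]
    df$rank <- seq_len(nrow(df))
    out <- rbind(out, df)
  }
  out
}

#' Cohen's d between two samples (pooled SD)
#' @param a,b numeric vectors.
#' @return standardized mean difference; signed `Inf` when the pooled SD
#'   is zero and the means differ, 0 when both are degenerate and equal.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  dm <- mean(a) - mean(b)
  if (sp2 <= 0) return(if (dm == 0) 0 else sign(dm) * Inf)
  dm / sqrt(sp2)
}

#' Pearson correlation of each property with the colony probability
#'
#' @param m a `property_matrix` with a `pundiff` column.
#' @return data frame: `property`, `r`, `p`, `slope`, `intercept`
#'   (least-squares line of property on P_undiff).
#' @export
property_pundiff_correlation <- function(m) {
  if (is.null(m$pundiff)) stop("property matrix lacks colony P_undiff")
  if (nrow(m) < 3L) stop("need at least three colonies")
  out <- NULL
  for (p in pm_feature_columns(m)) {
    ct <- stats::cor.test(m[[p]], m$pundiff)
    fit <- stats::lm(m[[p]] ~ m$pundiff)
    out <- rbind(out, data.frame(property = p,
                                 r = unname(ct$estimate),
                                 p = ct$p.value,
                                 slope = unname(stats::coef(fit)[2]),
                                 intercept = unname(stats::coef(fit)[1])))
  }
  out
}

#' Welch's t-test between two groups of a property
#'
#' @param m a `property_matrix` with a `group` column.
#' @param property property (or `"pundiff"`) to compare.
#' @param groups the two group labels; default the first two present.
#' @return `htest` object from [stats::t.test()] (unequal variances).
#' @export
welch_test <- function(m, property, groups = NULL) {
  if (is.null(m$group)) stop("property matrix lacks group labels")
  if (is.null(groups)) groups <- utils::head(unique(m$group), 2L)
  a <- m[[property]][m$group == groups[1]]
  b <- m[[property]][m$group == groups[2]]
  stats::t.test(a, b)
}

#' Adjusted Rand index between two labelings
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  expct <- si * sj / comb2(n)
  mx <- (si + sj) / 2
  if (mx == expct) return(1)
  (sij - expct) / (mx - expct)
}
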