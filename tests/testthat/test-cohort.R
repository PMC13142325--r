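mk_pm <- function(x, pundiff = NULL, groups = NULL) {
  colnames(x) <- utils::head(property_names(), ncol(x))
  df <- data.frame(id = paste0("c", seq_len(nrow(x))), x,
                   check.names = FALSE)
  if (!is.null(pundiff)) df$pundiff <- pundiff
  if (!is.null(groups)) df$group <- groups
  class(df) <- c("property_matrix", "data.frame")
  df
}

test_that("standardization gives exact z-scores and is idempotent", {
  pm <- mk_pm(cbind(c(1, 2, 3)))
  s <- standardize_matrix(pm)
  expect_equal(s$area, c(-1, 0, 1))
  s2 <- standardize_matrix(s)
  expect_equal(s2$area, s$area, tolerance = 1e-12)
  expect_error(standardize_matrix(pm[1, ]), "two colonies")
  pm2 <- mk_pm(cbind(c(1, 2, 3), c(5, 5, 5)))
  expect_warning(s3 <- standardize_matrix(pm2), "constant")
  expect_false("volume" %in% names(s3))
  set.seed(4)
  big <- standardize_matrix(mk_pm(matrix(stats::rnorm(50 * 31), 50)))
  vals <- as.matrix(big[, intersect(property_names(), names(big))])
  expect_lt(max(abs(colMeans(vals))), 1e-10)
  expect_lt(max(abs(apply(vals, 2, stats::sd) - 1)), 1e-10)
})

test_that("Leiden clustering separates well-separated blobs deterministically", {
  set.seed(12)
  x <- rbind(matrix(stats::rnorm(30 * 4), 30), matrix(stats::rnorm(30 * 4) + 10, 30))
  pm <- standardize_matrix(mk_pm(x))
  cl <- cluster_colonies(pm, k = 8L, seed = 5L)
  expect_length(unique(cl$labels), 2L)
  truth <- rep(1:2, each = 30)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  cl2 <- cluster_colonies(pm, k = 8L, seed = 5L)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_colonies(pm[1:8, ], k = 8L), "more colonies")
})

test_that("duplicated rows stay in the same cluster as their originals", {
  set.seed(13)
  x <- rbind(matrix(stats::rnorm(20 * 3), 20),
             matrix(stats::rnorm(20 * 3) + 8, 20))
  xd <- rbind(x, x[c(3, 25), ])
  pm <- standardize_matrix(mk_pm(xd))
  cl <- cluster_colonies(pm, k = 6L, seed = 2L)
  expect_equal(cl$labels[41], cl$labels[3])
  expect_equal(cl$labels[42], cl$labels[25])
})

test_that("Cohen's d matches hand computation, the formula oracle and its symmetries", {
  expect_equal(cohens_d(c(0, 1, 2), c(3, 4, 5)), -3)
  expect_equal(cohens_d(c(2, 4), c(2, 4)), 0)
  expect_equal(cohens_d(c(1, 1), c(0, 0)), Inf)
  expect_equal(cohens_d(c(1, 1), c(1, 1)), 0)
  set.seed(14)
  for (trial in 1:20) {
    a <- stats::rnorm(sample(3:12, 1)); b <- stats::rnorm(sample(3:12, 1), 1)
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
    expect_equal(cohens_d(b, a), -cohens_d(a, b))
    expect_equal(cohens_d(3 * a + 7, 3 * b + 7), cohens_d(a, b))
  }
})

test_that("per-cluster effect sizes rank properties by |d|", {
  set.seed(15)
  x <- cbind(c(stats::rnorm(10), stats::rnorm(10, 5)),
             stats::rnorm(20))
  pm <- mk_pm(x)
  labels <- rep(1:2, each = 10)
  es <- cluster_effect_sizes(pm, labels)
  expect_equal(nrow(es), 4L)
  top <- es[es$cluster == 1 & es$rank == 1, ]
  expect_equal(top$property, "area")        # the shifted column dominates
  d12 <- es$d[es$cluster == 1 & es$property == "area"]
  d21 <- es$d[es$cluster == 2 & es$property == "area"]
  expect_equal(d12, -d21)
  expect_error(cluster_effect_sizes(pm, rep(1, 20)), "two clusters")
})

test_that("property-probability correlations recover exact linear relations", {
  set.seed(16)
  pu <- stats::runif(30)
  pm <- mk_pm(cbind(2 * pu + 1, -3 * pu + 2, stats::rnorm(30)), pundiff = pu)
  co <- property_pundiff_correlation(pm)
  expect_equal(co$r[co$property == "area"], 1)
  expect_equal(co$r[co$property == "volume"], -1)
  expect_equal(co$slope[co$property == "area"], 2)
  expect_lt(abs(co$r[co$property == "mean_ri"]), 0.5)
  expect_error(property_pundiff_correlation(mk_pm(cbind(1:5))), "P_undiff")
})

test_that("Welch's test flags a true group difference", {
  set.seed(17)
  pm <- mk_pm(cbind(c(stats::rnorm(15), stats::rnorm(15, 4))),
              groups = rep(c("a", "b"), each = 15))
  wt <- welch_test(pm, "area")
  expect_lt(wt$p.value, 1e-6)
  expect_equal(wt$method, "Welch Two Sample t-test")
})

test_that("the UMAP embedding is 2D, seeded and separates blobs", {
  set.seed(18)
  x <- rbind(matrix(stats::rnorm(25 * 5), 25),
             matrix(stats::rnorm(25 * 5) + 12, 25))
  pm <- standardize_matrix(mk_pm(x))
  e1 <- embed_umap(pm, seed = 4L)
  expect_equal(dim(e1), c(50L, 2L))
  e2 <- embed_umap(pm, seed = 4L)
  expect_identical(e1, e2)
  g1 <- e1[1:25, , drop = FALSE]; g2 <- e1[26:50, , drop = FALSE]
  between <- sqrt(sum((colMeans(g1) - colMeans(g2))^2))
  within <- stats::quantile(c(
    sqrt(rowSums(sweep(g1, 2, colMeans(g1))^2)),
    sqrt(rowSums(sweep(g2, 2, colMeans(g2))^2))), 0.95)
  expect_gt(between, unname(within))
  expect_error(embed_umap(pm[1:3, ]), "four rows")
})

test_that("the adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(19)
  a <- sample(1:3, 60, replace = TRUE)
  b <- sample(1:3, 60, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.25)
})
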