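tiny_cfg <- function(...)
  arch_config(in_channels = 2L, blocks_per_stage = c(1L, 1L, 1L, 1L),
              stage_channels = c(8L, 16L, 32L, 64L), bam_reduction = 4L,
              bam_dilation = 2L, input_px = 32L, ...)

test_that("architecture config enforces its invariants", {
  expect_error(arch_config(stage_channels = c(256L, 512L, 1024L, 1024L)),
               "double")
  expect_error(arch_config(input_px = 100L), "divisible")
})

test_that("forward pass produces the configured stage shapes and 2 logits", {
  m <- build_classifier(tiny_cfg(), seed = 1)
  x <- array(stats::rnorm(2 * 32 * 32 * 2), c(2, 32, 32, 2))
  fo <- forward_classifier(m, x, record_stages = TRUE)
  expect_equal(fo$stage_shapes[[1]], c(8, 8, 8))
  expect_equal(fo$stage_shapes[[2]], c(16, 4, 4))
  expect_equal(fo$stage_shapes[[3]], c(32, 2, 2))
  expect_equal(fo$stage_shapes[[4]], c(64, 1, 1))
  expect_equal(dim(fo$logits), c(2L, 2L))
})

test_that("disabling the attention modules removes exactly their census", {
  m1 <- build_classifier(tiny_cfg(), seed = 1)
  m0 <- build_classifier(tiny_cfg(use_bam = FALSE), seed = 1)
  s1 <- summarize_architecture(m1)
  s0 <- summarize_architecture(m0)
  expect_equal(s1$n_conv_layers - s0$n_conv_layers, 12L)  # 4 convs per BAM
  expect_equal(s1$n_params - s0$n_params, s1$n_params_bam)
  # per-BAM parameter count follows the frozen micro-design:
  # 4ch + 18h^2 + 5h + 1 for channel width c and reduction h = c/r
  expected <- sum(vapply(c(8, 16, 32), function(c) {
    h <- c / 4
    4 * c * h + 18 * h^2 + 5 * h + 1
  }, numeric(1)))
  expect_equal(s1$n_params_bam, expected)
})

test_that("cosine annealing matches its closed form", {
  expect_equal(cosine_lr(0), 0.001)
  expect_equal(cosine_lr(8), 0.0005)             # cos(pi/2) = 0
  expect_equal(cosine_lr(16), 0.001)             # period restart
  expect_equal(cosine_lr(4, lr0 = 0.002, period = 8L), 0.001)
})

test_that("checkpoint selection is the argmax of val+blind, earliest on ties", {
  h <- data.frame(iteration = 0:1, val_accuracy = c(0.80, 0.90),
                  blindtest_accuracy = c(0.70, 0.85))
  expect_equal(select_checkpoint(h), 1L)
  h2 <- data.frame(iteration = 0:1, val_accuracy = c(0.9, 0.8),
                   blindtest_accuracy = c(0.8, 0.9))
  expect_equal(select_checkpoint(h2), 0L)
  expect_error(select_checkpoint(h[0, ]), "empty")
  set.seed(8)
  h3 <- data.frame(iteration = 0:299, val_accuracy = runif(300),
                   blindtest_accuracy = runif(300))
  best <- -Inf; best_i <- NA
  for (i in 1:300) {
    s <- h3$val_accuracy[i] + h3$blindtest_accuracy[i]
    if (s > best) { best <- s; best_i <- h3$iteration[i] }
  }
  expect_equal(select_checkpoint(h3), best_i)
})

test_that("predictions are proper probabilities and deterministic", {
  m <- build_classifier(tiny_cfg(), seed = 2)
  set.seed(3)
  ps <- structure(list(values = array(stats::runif(2 * 32 * 32 * 5),
                                      c(2, 32, 32, 5)),
                       labels = rep("unlabeled", 5)),
                  class = "ht_patch_set")
  p1 <- predict_patches(m, ps)
  p2 <- predict_patches(m, ps)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # zeroed head -> logits (0, 0) -> P_undiff exactly 0.5
  m$fc$W[] <- 0; m$fc$b[] <- 0
  expect_equal(predict_patches(m, ps), rep(0.5, 5))
  # shape mismatch errors
  bad <- structure(list(values = array(0, c(2, 16, 16, 1)),
                        labels = "unlabeled"), class = "ht_patch_set")
  expect_error(predict_patches(m, bad), "does not match")
})

test_that("analytic gradients match finite differences across layer types", {
  set.seed(42)
  m <- build_classifier(tiny_cfg(), seed = 7)
  layers <- htcolony:::model_layer_list(m)
  # move biases off zero so no ReLU sits exactly at its kink
  for (l in layers) if (!is.null(l$b)) l$b <- stats::rnorm(length(l$b), sd = 0.1)
  x <- array(stats::rnorm(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  yb <- rbind(c(1, 0, 1), c(0, 1, 0))
  lossfun <- function() {
    fo <- forward_classifier(m, x, training = TRUE)
    p <- htcolony:::softmax_cols(fo$logits)
    list(loss = -mean(colSums(yb * log(pmax(p, 1e-12)))), fo = fo, p = p)
  }
  htcolony:::zero_grads(layers)
  r <- lossfun()
  htcolony:::backward_classifier(m, (r$p - yb) / 3, r$fo$pool_dim)
  refs <- htcolony:::collect_param_refs(layers)
  set.seed(1)
  for (ri in sample(seq_along(refs), 20)) {
    p <- refs[[ri]]
    w <- p$env[[p$name]]
    i <- sample(length(w), 1)
    g <- p$env[[paste0("g", p$name)]][i]
    p$env[[p$name]][i] <- w[i] + 1e-6; lp <- lossfun()$loss
    p$env[[p$name]][i] <- w[i] - 1e-6; lm <- lossfun()$loss
    p$env[[p$name]][i] <- w[i]
    gn <- (lp - lm) / 2e-6
    expect_lt(abs(g - gn) / max(1e-6, abs(g) + abs(gn)), 1e-3)
  }
})

test_that("the network memorizes a 10-patch set (learnability smoke test)", {
  set.seed(5)
  labs <- rep(c("undifferentiated", "differentiating"), 5)
  vals <- array(stats::runif(2 * 32 * 32 * 10), c(2, 32, 32, 10))
  # give the classes a learnable mean shift
  vals[, , , labs == "undifferentiated"] <-
    vals[, , , labs == "undifferentiated"] * 0.5 + 0.4
  ps <- structure(list(values = vals, labels = labs,
                       origins = matrix(0, 10, 2),
                       colony_ids = rep("c", 10)),
                  class = "ht_patch_set")
  m <- build_classifier(tiny_cfg(), seed = 6)
  tc <- train_config(batch_size = 10L, subsample_frac = 1, lr = 0.005,
                     total_iterations = 60L, cosine_period = 60L, seed = 2L)
  res <- train_classifier(m, ps, ps, ps, tc)
  expect_lt(min(res$history$train_loss), 0.01)
  expect_equal(nrow(res$history), 60L)
  expect_true(all(res$history$val_accuracy >= 0 &
                    res$history$val_accuracy <= 1))
})

test_that("training rejects single-class sets and clamps oversized batches", {
  vals <- array(stats::runif(2 * 32 * 32 * 6), c(2, 32, 32, 6))
  one <- structure(list(values = vals,
                        labels = rep("undifferentiated", 6)),
                   class = "ht_patch_set")
  m <- build_classifier(tiny_cfg(), seed = 1)
  expect_error(train_classifier(m, one, one, one, train_config()),
               "both classes")
  two <- one; two$labels <- rep(c("undifferentiated", "differentiating"), 3)
  tc <- train_config(batch_size = 64L, subsample_frac = 0.5,
                     total_iterations = 1L, seed = 1L)
  expect_warning(train_classifier(m, two, two, two, tc), "clamped")
})

test_that("Grad-CAM maps are non-negative, finite, at stage-4 resolution", {
  m <- build_classifier(tiny_cfg(), seed = 9)
  p <- structure(list(values = array(stats::runif(2 * 32 * 32), c(2, 32, 32)),
                      origin = c(0, 0), label = "unlabeled",
                      colony_id = "c"), class = "ht_patch")
  cam <- compute_gradcam(m, p, "undifferentiated", pitch = c(0.31, 0.31))
  expect_s3_class(cam, "map2d")
  expect_true(all(is.finite(cam$values)) && all(cam$values >= 0))
  expect_equal(dim(attr(cam, "native")), c(1L, 1L))   # 32 px / 32
  expect_equal(dim(cam$values), c(32L, 32L))
  # constant input still yields a finite, defined map
  p0 <- p; p0$values[] <- 0.3
  cam0 <- compute_gradcam(m, p0, "differentiating", pitch = c(0.31, 0.31))
  expect_true(all(is.finite(cam0$values)))
  expect_error(compute_gradcam(m, p, "mystery"), "arg")
})
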