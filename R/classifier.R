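#' Architecture configuration for the colony patch classifier
#'
#' The default reproduces the network used for 79.6-um patches: a 50-layer
#' bottleneck residual backbone (blocks 3/4/6/3, stage widths
#' 256/512/1024/2048) taking the 12 z-slices of a patch as input channels,
#' with a bottleneck attention module (BAM) between consecutive stages and
#' a 2-logit head. With 256-px input the stage feature maps are 256x64x64,
#' 512x32x32, 1024x16x16 and 2048x8x8, and the network holds 23,981,749
#' trainable parameters across 65 convolutional layers.
#'
#' @param in_channels input channels (z slices per patch).
#' @param blocks_per_stage bottleneck blocks per stage.
#' @param stage_channels output channels per stage (strictly doubling).
#' @param bam_reduction channel-reduction ratio of the attention modules.
#' @param bam_dilation dilation of the two 3x3 convs in the spatial branch.
#' @param n_classes number of output classes (2).
#' @param input_px square input size in pixels (divisible by 32).
#' @param use_bam include the attention modules?
#' @return object of class `arch_config`.
#' @export
arch_config <- function(in_channels = 12L,
                        blocks_per_stage = c(3L, 4L, 6L, 3L),
                        stage_channels = c(256L, 512L, 1024L, 2048L),
                        bam_reduction = 16L, bam_dilation = 4L,
                        n_classes = 2L, input_px = 256L, use_bam = TRUE) {
  stopifnot(length(blocks_per_stage) == 4, length(stage_channels) == 4,
            all(blocks_per_stage >= 1))
  if (any(stage_channels[-1] != 2L * stage_channels[-4]))
    stop("stage_channels must double at each stage")
  if (input_px %% 32L != 0L)
    stop("input_px must be divisible by 32")
  structure(list(in_channels = as.integer(in_channels),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 stage_channels = as.integer(stage_channels),
                 bam_reduction = as.integer(bam_reduction),
                 bam_dilation = as.integer(bam_dilation),
                 n_classes = as.integer(n_classes),
                 input_px = as.integer(input_px),
                 use_bam = isTRUE(use_bam)),
            class = "arch_config")
}

# one pre-activation-free (classic) bottleneck residual block
make_bottleneck <- function(cin, cout, stride) {
  mid <- cout %/% 4L
  b <- list(conv1 = nn_conv(cin, mid, 1L, bias = FALSE), bn1 = nn_bn(mid),
            relu1 = nn_relu(),
            conv2 = nn_conv(mid, mid, 3L, stride = stride, pad = 1L,
                            bias = FALSE), bn2 = nn_bn(mid),
            relu2 = nn_relu(),
            conv3 = nn_conv(mid, cout, 1L, bias = FALSE), bn3 = nn_bn(cout),
            relu_out = nn_relu())
  if (cin != cout || stride != 1L) {
    b$proj <- nn_conv(cin, cout, 1L, stride = stride, bias = FALSE)
    b$proj_bn <- nn_bn(cout)
  }
  b
}

fwd_bottleneck <- function(b, x, training) {
  y <- fwd(b$conv1, x, training); y <- fwd(b$bn1, y, training)
  y <- fwd(b$relu1, y, training)
  y <- fwd(b$conv2, y, training); y <- fwd(b$bn2, y, training)
  conv2_act <- y <- fwd(b$relu2, y, training)
  y <- fwd(b$conv3, y, training); y <- fwd(b$bn3, y, training)
  s <- if (!is.null(b$proj)) fwd(b$proj_bn, fwd(b$proj, x, training), training) else x
  out <- fwd(b$relu_out, y + s, training)
  attr(out, "conv2_act") <- conv2_act
  out
}

bwd_bottleneck <- function(b, dout, conv2_grad_hook = NULL) {
  d <- bwd(b$relu_out, dout)
  dmain <- bwd(b$bn3, d); dmain <- bwd(b$conv3, dmain)
  if (!is.null(conv2_grad_hook)) conv2_grad_hook(dmain)
  dmain <- bwd(b$relu2, dmain)
  dmain <- bwd(b$bn2, dmain); dmain <- bwd(b$conv2, dmain)
  dmain <- bwd(b$relu1, dmain)
  dmain <- bwd(b$bn1, dmain); dmain <- bwd(b$conv1, dmain)
  dshort <- if (!is.null(b$proj)) bwd(b$proj, bwd(b$proj_bn, d)) else d
  dmain + dshort
}

# BAM caches live in a dedicated environment because the module itself is
# a plain list inside the model.
# Bottleneck attention module between stages. Channel branch: global
# average and global max descriptors, each through its own biased
# projection C -> C/r, ReLU, then a shared bias-free expansion C/r -> C.
# Spatial branch: bias-free 1x1 reduce, two biased dilated 3x3 convs, and a
# biased 1x1 collapse to one map. The two branches are broadcast-summed,
# squashed by a sigmoid and applied residually: out = x * (1 + att).
make_bam <- function(c, reduction, dilation) {
  h <- max(1L, c %/% reduction)
  list(c = c, h = h,
       fc_avg = nn_fc(c, h, bias = TRUE),
       fc_max = nn_fc(c, h, bias = TRUE),
       fc_out = nn_fc(h, c, bias = FALSE),
       sconv1 = nn_conv(c, h, 1L, bias = FALSE),
       srelu1 = nn_relu(),
       sconv2 = nn_conv(h, h, 3L, pad = dilation, dilation = dilation,
                        bias = TRUE),
       srelu2 = nn_relu(),
       sconv3 = nn_conv(h, h, 3L, pad = dilation, dilation = dilation,
                        bias = TRUE),
       srelu3 = nn_relu(),
       sconv4 = nn_conv(h, 1L, 1L, bias = TRUE),
       cache = new.env(parent = emptyenv()))
}

fwd_bam <- function(m, x, training) {
  d <- dim(x)
  avg <- gap_fwd(x)
  mx <- gmp_fwd(x)
  ha <- fwd(m$fc_avg, avg, training)
  hm <- fwd(m$fc_max, mx$values, training)
  hsum <- ha + hm
  hrelu <- hsum * (hsum > 0)
  ch_att <- fwd(m$fc_out, hrelu, training)             # (C, N)
  s <- fwd(m$sconv1, x, training); s <- fwd(m$srelu1, s, training)
  s <- fwd(m$sconv2, s, training); s <- fwd(m$srelu2, s, training)
  s <- fwd(m$sconv3, s, training); s <- fwd(m$srelu3, s, training)
  sp_att <- fwd(m$sconv4, s, training)                 # (1, H, W, N)
  pre <- array(0, d)
  for (n in seq_len(d[4]))
    pre[, , , n] <- rep(ch_att[, n], d[2] * d[3]) +
      rep(sp_att[1, , , n], each = d[1])
  att <- 1 / (1 + exp(-pre))
  m$cache$cc <- list(x = x, att = att, hmask = hsum > 0, mx_arg = mx$arg,
                     d = d)
  x * (1 + att)
}

bwd_bam <- function(m, dout) {
  cc <- m$cache$cc; m$cache$cc <- NULL
  x <- cc$x; att <- cc$att; d <- cc$d
  dx <- dout * (1 + att)
  dpre <- dout * x * att * (1 - att)
  # split the broadcast sum: channel grad sums over space, spatial over C
  dch <- matrix(0, d[1], d[4])
  dsp <- array(0, c(1L, d[2], d[3], d[4]))
  for (n in seq_len(d[4])) {
    g <- matrix(dpre[, , , n], d[1], d[2] * d[3])
    dch[, n] <- rowSums(g)
    dsp[1, , , n] <- colSums(g)
  }
  # spatial branch
  ds <- bwd(m$sconv4, dsp)
  ds <- bwd(m$srelu3, ds); ds <- bwd(m$sconv3, ds)
  ds <- bwd(m$srelu2, ds); ds <- bwd(m$sconv2, ds)
  ds <- bwd(m$srelu1, ds); ds <- bwd(m$sconv1, ds)
  dx <- dx + ds
  # channel branch
  dh <- bwd(m$fc_out, dch)
  dh <- dh * cc$hmask
  davg <- bwd(m$fc_avg, dh)
  dmax <- bwd(m$fc_max, dh)
  dx <- dx + gap_bwd(davg, d) + gmp_bwd(dmax, cc$mx_arg, d)
  dx
}

bam_layer_list <- function(m)
  list(m$fc_avg, m$fc_max, m$fc_out, m$sconv1, m$srelu1, m$sconv2, m$srelu2,
       m$sconv3, m$srelu3, m$sconv4)

bottleneck_layer_list <- function(b)
  Filter(Negate(is.null),
         list(b$conv1, b$bn1, b$relu1, b$conv2, b$bn2, b$relu2, b$conv3,
              b$bn3, b$proj, b$proj_bn, b$relu_out))

#' Build the colony patch classifier
#'
#' Stem: 7x7 stride-2 convolution to `stage_channels[1]/4` channels, batch
#' norm, ReLU, 3x3 stride-2 max pool. Four bottleneck stages follow (the
#' first at stride 1, the rest downsampling by 2 in their first block, in
#' both the convolutional and the projection path), with an attention
#' module between consecutive stages. Global average pooling and a fully
#' connected layer produce the two class logits.
#'
#' @param cfg an [arch_config].
#' @param seed integer seed for weight initialization.
#' @return object of class `ht_model`.
#' @export
build_classifier <- function(cfg = arch_config(), seed = 1L) {
  stopifnot(inherits(cfg, "arch_config"))
  set.seed(seed)
  stem_c <- cfg$stage_channels[1] %/% 4L
  stem <- list(conv = nn_conv(cfg$in_channels, stem_c, 7L, stride = 2L,
                              pad = 3L, bias = FALSE),
               bn = nn_bn(stem_c), relu = nn_relu(),
               pool = nn_maxpool(3L, 2L, 1L))
  stages <- vector("list", 4L)
  cin <- stem_c
  for (s in 1:4) {
    cout <- cfg$stage_channels[s]
    blocks <- vector("list", cfg$blocks_per_stage[s])
    for (bI in seq_len(cfg$blocks_per_stage[s])) {
      stride <- if (bI == 1L && s > 1L) 2L else 1L
      blocks[[bI]] <- make_bottleneck(cin, cout, stride)
      cin <- cout
    }
    stages[[s]] <- blocks
  }
  bams <- if (cfg$use_bam)
    lapply(1:3, function(s) make_bam(cfg$stage_channels[s],
                                     cfg$bam_reduction, cfg$bam_dilation))
  else NULL
  fc <- nn_fc(cfg$stage_channels[4], cfg$n_classes, bias = TRUE)
  m <- structure(list(cfg = cfg, stem = stem, stages = stages, bams = bams,
                      fc = fc,
                      classes = c("undifferentiated", "differentiating")),
                 class = "ht_model")
  m
}

model_layer_list <- function(m) {
  out <- list(m$stem$conv, m$stem$bn, m$stem$relu, m$stem$pool)
  for (s in 1:4) {
    for (b in m$stages[[s]]) out <- c(out, bottleneck_layer_list(b))
    if (!is.null(m$bams) && s <= 3)
      out <- c(out, bam_layer_list(m$bams[[s]]))
  }
  c(out, list(m$fc))
}

#' Forward pass of the classifier
#'
#' @param m an `ht_model`.
#' @param x input array `(C, H, W, N)` of normalized patches.
#' @param training use batch statistics and keep backward caches?
#' @param record_stages also return the per-stage output shapes?
#' @param capture_conv2 capture the activation of the second 3x3
#'   convolution of the final bottleneck block (the Grad-CAM hook site)?
#' @return list with `logits` (`n_classes x N`), and optionally
#'   `stage_shapes` and `conv2_act`.
#' @export
forward_classifier <- function(m, x, training = FALSE,
                               record_stages = FALSE,
                               capture_conv2 = FALSE) {
  stopifnot(inherits(m, "ht_model"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  y <- fwd(m$stem$conv, x, training)
  y <- fwd(m$stem$bn, y, training)
  y <- fwd(m$stem$relu, y, training)
  y <- fwd(m$stem$pool, y, training)
  stage_shapes <- vector("list", 4L)
  conv2_act <- NULL
  for (s in 1:4) {
    nb <- length(m$stages[[s]])
    for (bI in seq_len(nb)) {
      y <- fwd_bottleneck(m$stages[[s]][[bI]], y, training)
      if (capture_conv2 && s == 4L && bI == nb)
        conv2_act <- attr(y, "conv2_act")
      attr(y, "conv2_act") <- NULL
    }
    if (record_stages) stage_shapes[[s]] <- dim(y)[1:3]
    if (!is.null(m$bams) && s <= 3) y <- fwd_bam(m$bams[[s]], y, training)
  }
  pooled <- gap_fwd(y)
  logits <- fwd(m$fc, pooled, training)
  out <- list(logits = logits, pool_dim = dim(y))
  if (record_stages) out$stage_shapes <- stage_shapes
  if (capture_conv2) out$conv2_act <- conv2_act
  out
}

# backward from dlogits; optionally capture the gradient at the Grad-CAM
# hook site. Parameter gradients accumulate inside the layer environments.
backward_classifier <- function(m, dlogits, pool_dim,
                                capture_conv2 = FALSE) {
  hook_grad <- NULL
  dpool <- bwd(m$fc, dlogits)
  dy <- gap_bwd(dpool, pool_dim)
  for (s in 4:1) {
    if (!is.null(m$bams) && s <= 3) dy <- bwd_bam(m$bams[[s]], dy)
    nb <- length(m$stages[[s]])
    for (bI in nb:1) {
      hook <- NULL
      if (capture_conv2 && s == 4L && bI == nb)
        hook <- function(g) hook_grad <<- g
      dy <- bwd_bottleneck(m$stages[[s]][[bI]], dy, conv2_grad_hook = hook)
    }
  }
  dy <- bwd(m$stem$pool, dy)
  dy <- bwd(m$stem$relu, dy)
  dy <- bwd(m$stem$bn, dy)
  dy <- bwd(m$stem$conv, dy)
  list(dx = dy, conv2_grad = hook_grad)
}

#' Summarize the classifier architecture
#'
#' Counts the trainable parameters and convolutional layers and reports the
#' per-stage output shapes for the configured input size. The counts are
#' derived from the instantiated layer objects, not from a formula.
#'
#' @param m an `ht_model`.
#' @return list with `n_params`, `n_conv_layers`, `stage_shapes` (each
#'   `c(channels, height, width)`), `n_params_bam` (attention-module share).
#' @export
summarize_architecture <- function(m) {
  stopifnot(inherits(m, "ht_model"))
  layers <- model_layer_list(m)
  n_params <- n_params_of(layers)
  n_conv <- sum(vapply(layers, function(l) l$type == "conv", logical(1)))
  px <- m$cfg$input_px %/% 4L
  shapes <- list()
  for (s in 1:4) {
    if (s > 1) px <- px %/% 2L
    shapes[[s]] <- c(m$cfg$stage_channels[s], px, px)
  }
  bam_params <- if (is.null(m$bams)) 0 else
    sum(vapply(m$bams, function(b) n_params_of(bam_layer_list(b)),
               numeric(1)))
  list(n_params = n_params, n_conv_layers = n_conv, stage_shapes = shapes,
       n_params_bam = bam_params)
}

#' Training configuration
#'
#' Defaults follow the reference optimisation recipe: SGD with Nesterov
#' momentum 0.9, learning rate 0.001, weight decay 1e-4, batch size 256,
#' a fresh random 5 % subsample of the training set per iteration, cosine
#' annealing with period 16 iterations, 300 iterations in total.
#'
#' @param batch_size,lr,nesterov_momentum,weight_decay,subsample_frac
#'   optimiser settings.
#' @param cosine_period,total_iterations schedule settings.
#' @param seed integer seed controlling subsampling and batching.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 256L, lr = 0.001,
                         nesterov_momentum = 0.9, weight_decay = 1e-4,
                         subsample_frac = 0.05, cosine_period = 16L,
                         total_iterations = 300L, seed = 1L) {
  stopifnot(subsample_frac > 0, subsample_frac <= 1, cosine_period > 0)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 nesterov_momentum = nesterov_momentum,
                 weight_decay = weight_decay,
                 subsample_frac = subsample_frac,
                 cosine_period = as.integer(cosine_period),
                 total_iterations = as.integer(total_iterations),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr0 * (1 + cos(pi * (t mod P) / P)) / 2` for 0-based iteration
#' `t` and period `P`.
#'
#' @param iteration 0-based iteration index (vectorized).
#' @param lr0 base learning rate.
#' @param period annealing period in iterations.
#' @return learning rate(s).
#' @export
cosine_lr <- function(iteration, lr0 = 0.001, period = 16L)
  lr0 * (1 + cos(pi * (iteration %% period) / period)) / 2

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

eval_accuracy <- function(m, ps, batch = 64L) {
  p <- predict_patches(m, ps, batch = batch)
  pred <- ifelse(p > 0.5, "undifferentiated", "differentiating")
  mean(pred == ps$labels)
}

#' Train the patch classifier
#'
#' Minimizes the softmax cross-entropy between the two-class logits and the
#' patch labels with Nesterov SGD. Each iteration draws a fresh random
#' subsample (without replacement) of the training set and sweeps it in
#' mini-batches; the learning rate follows [cosine_lr()]. Validation and
#' blind-test accuracies are recorded every iteration and the returned
#' model carries the checkpoint with the highest `val + blind` sum
#' (earliest iteration on ties).
#'
#' @param m an `ht_model` (modified in place; also returned).
#' @param train,val,blind patch sets from [patch_set()], labelled.
#' @param cfg a [train_config].
#' @param verbose print per-iteration progress?
#' @return list with `model`, `history` (data frame: iteration, lr,
#'   train_loss, val_accuracy, blindtest_accuracy), `best_iteration`.
#' @export
train_classifier <- function(m, train, val, blind, cfg = train_config(),
                             verbose = FALSE) {
  stopifnot(inherits(m, "ht_model"), inherits(cfg, "train_config"))
  labs <- unique(train$labels)
  if (length(labs) < 2L)
    stop("training set must contain both classes")
  layers <- model_layer_list(m)
  set.seed(cfg$seed)
  n <- length(train$labels)
  nsub <- max(1L, round(cfg$subsample_frac * n))
  bs <- cfg$batch_size
  if (bs > nsub) {
    warning("batch size larger than the per-iteration subsample; clamped")
    bs <- nsub
  }
  hist <- data.frame(iteration = integer(0), lr = numeric(0),
                     train_loss = numeric(0), val_accuracy = numeric(0),
                     blindtest_accuracy = numeric(0))
  best <- -Inf; best_iter <- NA_integer_; best_snap <- NULL
  y_onehot <- function(lv)
    rbind(as.numeric(lv == "undifferentiated"),
          as.numeric(lv == "differentiating"))
  for (it in seq_len(cfg$total_iterations) - 1L) {
    lr <- cosine_lr(it, cfg$lr, cfg$cosine_period)
    sub <- sample.int(n, nsub)
    losses <- numeric(0)
    for (start in seq(1L, nsub, by = bs)) {
      idx <- sub[start:min(start + bs - 1L, nsub)]
      xb <- train$values[, , , idx, drop = FALSE]
      yb <- y_onehot(train$labels[idx])
      zero_grads(layers)
      fo <- forward_classifier(m, xb, training = TRUE)
      p <- softmax_cols(fo$logits)
      loss <- -mean(colSums(yb * log(pmax(p, 1e-12))))
      losses <- c(losses, loss)
      dlogits <- (p - yb) / ncol(p)
      backward_classifier(m, dlogits, fo$pool_dim)
      sgd_step(layers, lr, cfg$nesterov_momentum, cfg$weight_decay)
    }
    va <- eval_accuracy(m, val)
    ba <- eval_accuracy(m, blind)
    hist <- rbind(hist, data.frame(iteration = it, lr = lr,
                                   train_loss = mean(losses),
                                   val_accuracy = va,
                                   blindtest_accuracy = ba))
    if (va + ba > best) {
      best <- va + ba; best_iter <- it
      best_snap <- snapshot_params(layers)
    }
    if (verbose)
      message(sprintf("iter %3d lr %.5f loss %.4f val %.3f blind %.3f",
                      it, lr, mean(losses), va, ba))
  }
  if (!is.null(best_snap)) restore_params(layers, best_snap)
  list(model = m, history = hist, best_iteration = best_iter)
}

#' Select the checkpoint with the best validation + blind-test sum
#'
#' @param history data frame with `val_accuracy` and `blindtest_accuracy`
#'   columns (one row per iteration).
#' @return the 0-based iteration index of the best checkpoint (earliest on
#'   ties).
#' @export
select_checkpoint <- function(history) {
  if (is.null(history) || nrow(history) == 0L)
    stop("empty training history")
  s <- history$val_accuracy + history$blindtest_accuracy
  history$iteration[which.max(s)]
}

#' Predict per-patch undifferentiated probabilities
#'
#' Runs the network in evaluation mode (batch-norm running statistics) and
#' returns `P_undiff`, the softmax probability of the undifferentiated
#' class, for every patch.
#'
#' @param m a trained `ht_model`.
#' @param patches a [patch_set()].
#' @param batch mini-batch size for inference.
#' @return numeric vector of `P_undiff` values in `[0, 1]`.
#' @export
predict_patches <- function(m, patches, batch = 64L) {
  stopifnot(inherits(m, "ht_model"))
  n <- dim(patches$values)[4]
  px <- dim(patches$values)[2]
  if (px != m$cfg$input_px || dim(patches$values)[1] != m$cfg$in_channels)
    stop(sprintf("patch shape %dx%dpx does not match the model (%dx%dpx)",
                 dim(patches$values)[1], px, m$cfg$in_channels,
                 m$cfg$input_px))
  p <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fo <- forward_classifier(m, patches$values[, , , idx, drop = FALSE],
                             training = FALSE)
    p[idx] <- softmax_cols(fo$logits)[1, ]
  }
  p
}

#' Grad-CAM saliency map for one patch
#'
#' Gradient-weighted class activation mapping hooked at the second 3x3
#' convolution of the final bottleneck block (stage-4 resolution, 8x8 for
#' 256-px input): `cam = ReLU(sum_k alpha_k A_k)` with `alpha_k` the
#' spatial mean of the class-logit gradient on feature map `A_k`, bilinearly
#' upsampled to patch resolution.
#'
#' @param m an `ht_model`.
#' @param patch a single patch from [extract_patch()] (or an array
#'   `(C, H, W)`).
#' @param target_class `"undifferentiated"` or `"differentiating"`.
#' @param pitch pixel pitch `(dy, dx)` of the returned map, um.
#' @return a [map2d] of kind `"saliency"`; the pre-upsampling map is
#'   attached as attribute `"native"`.
#' @export
compute_gradcam <- function(m, patch, target_class = c("undifferentiated",
                                                       "differentiating"),
                            pitch = ht_default_pitch()[2:3]) {
  target_class <- match.arg(target_class)
  x <- if (inherits(patch, "ht_patch")) patch$values else patch
  stopifnot(length(dim(x)) == 3L)
  dim(x) <- c(dim(x), 1L)
  layers <- model_layer_list(m)
  for (l in layers) if (l$type == "bn") l$grad_eval <- TRUE
  on.exit(for (l in layers) if (l$type == "bn") l$grad_eval <- FALSE)
  fo <- forward_classifier(m, x, training = FALSE, capture_conv2 = TRUE)
  A <- fo$conv2_act
  cls <- match(target_class, m$classes)
  dlog <- matrix(0, m$cfg$n_classes, 1L)
  dlog[cls, 1] <- 1
  bk <- backward_classifier(m, dlog, fo$pool_dim, capture_conv2 = TRUE)
  dA <- bk$conv2_grad
  k <- dim(A)[1]
  alpha <- rowMeans(matrix(dA[, , , 1], k))
  cam <- matrix(0, dim(A)[2], dim(A)[3])
  Am <- matrix(A[, , , 1], k)
  cam[] <- colSums(Am * alpha)
  cam[cam < 0] <- 0
  native <- cam
  up <- EBImage::resize(cam, w = dim(x)[2], h = dim(x)[3])
  up[up < 0] <- 0
  out <- map2d(up, pitch = pitch, kind = "saliency")
  attr(out, "native") <- native
  out
}
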