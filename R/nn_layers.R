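# Minimal dense-tensor neural-network primitives.
#
# No deep-learning framework ships with this R distribution, so the layers
# needed by the colony classifier (2D convolution with stride/dilation,
# batch normalization, max/average pooling, fully connected, and the
# attention gate) are implemented here directly: forward passes lower
# convolutions to im2col + BLAS matrix products, and every layer carries an
# explicit backward pass so the network is trainable with plain SGD.
#
# Activations are dense double arrays of dim (C, H, W, N) -- channel
# fastest, batch last -- which makes per-channel reductions cheap row
# operations after a dim() reshape.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  class(e) <- c(paste0("ht_", type), "ht_layer")
  e
}

layer_params <- function(l) {
  nms <- intersect(c("W", "b", "gamma", "beta"), ls(l))
  nms[vapply(nms, function(nm) !is.null(l[[nm]]), logical(1))]
}

#### convolution ############################################################

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L, dilation = 1L,
                    bias = TRUE, rng = NULL) {
  W <- matrix(stats::rnorm(cout * cin * k * k, sd = sqrt(2 / (cin * k * k))),
              nrow = cout)
  l <- new_layer("conv", cin = cin, cout = cout, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad),
                 dilation = as.integer(dilation), W = W,
                 b = if (bias) numeric(cout) else NULL)
  l
}

conv_out_dim <- function(n, k, stride, pad, dilation)
  (n + 2L * pad - (k - 1L) * dilation - 1L) %/% stride + 1L

# cached im2col index matrix (C*k^2, Ho*Wo) into the zero-padded image
conv_idx <- function(l, C, H, W) {
  key <- paste(C, H, W, sep = "x")
  if (!is.null(l$idx_key) && identical(l$idx_key, key)) return(l$idx)
  k <- l$k; st <- l$stride; p <- l$pad; dil <- l$dilation
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- conv_out_dim(H, k, st, p, dil); Wo <- conv_out_dim(W, k, st, p, dil)
  iy0 <- (seq_len(Ho) - 1L) * st + 1L
  ix0 <- (seq_len(Wo) - 1L) * st + 1L
  idx <- matrix(0L, C * k * k, Ho * Wo)
  j <- 0L
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    j <- j + 1L
    Y <- iy0 + (ky - 1L) * dil
    X <- ix0 + (kx - 1L) * dil
    base <- C * (rep(Y - 1L, times = Wo) + Hp * rep(X - 1L, each = Ho))
    idx[((j - 1L) * C + 1L):(j * C), ] <- outer(seq_len(C), base, "+")
  }
  l$idx <- idx; l$idx_key <- key
  l$out_hw <- c(Ho, Wo); l$padded_hw <- c(Hp, Wp)
  idx
}

pad_plane <- function(xn, C, H, W, p) {
  if (p == 0L) return(xn)
  xp <- array(0, c(C, H + 2L * p, W + 2L * p))
  xp[, (p + 1L):(p + H), (p + 1L):(p + W)] <- xn
  xp
}

fwd.ht_conv <- function(l, x, training = FALSE) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  stopifnot(C == l$cin)
  if (l$k == 1L && l$pad == 0L) {
    Ho <- conv_out_dim(H, 1L, l$stride, 0L, 1L)
    Wo <- conv_out_dim(W, 1L, l$stride, 0L, 1L)
    l$out_hw <- c(Ho, Wo)
    sel <- NULL
    if (l$stride > 1L) {
      ys <- seq(1L, H, by = l$stride); xs <- seq(1L, W, by = l$stride)
      sel <- rep(ys, times = length(xs)) + H * rep(xs - 1L, each = length(ys))
    }
    l$sel <- sel
    out <- array(0, c(l$cout, Ho, Wo, N))
    for (n in seq_len(N)) {
      cols <- matrix(x[, , , n], C, H * W)
      if (!is.null(sel)) cols <- cols[, sel, drop = FALSE]
      y <- l$W %*% cols
      if (!is.null(l$b)) y <- y + l$b
      out[, , , n] <- y
    }
  } else {
    idx <- conv_idx(l, C, H, W)
    Ho <- l$out_hw[1]; Wo <- l$out_hw[2]
    out <- array(0, c(l$cout, Ho, Wo, N))
    for (n in seq_len(N)) {
      xp <- pad_plane(x[, , , n, drop = FALSE], C, H, W, l$pad)
      cols <- matrix(xp[idx], nrow = nrow(idx))
      y <- l$W %*% cols
      if (!is.null(l$b)) y <- y + l$b
      out[, , , n] <- y
    }
  }
  l$x <- x
  out
}

bwd.ht_conv <- function(l, dout) {
  x <- l$x
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Ho <- l$out_hw[1]; Wo <- l$out_hw[2]
  gW <- matrix(0, nrow(l$W), ncol(l$W))
  gb <- if (!is.null(l$b)) numeric(l$cout) else NULL
  dx <- array(0, d)
  if (l$k == 1L && l$pad == 0L) {
    sel <- l$sel
    for (n in seq_len(N)) {
      dy <- matrix(dout[, , , n], l$cout, Ho * Wo)
      cols <- matrix(x[, , , n], C, H * W)
      if (!is.null(sel)) cols <- cols[, sel, drop = FALSE]
      gW <- gW + tcrossprod(dy, cols)
      if (!is.null(gb)) gb <- gb + rowSums(dy)
      dcols <- crossprod(l$W, dy)
      dxn <- matrix(0, C, H * W)
      if (is.null(sel)) dxn <- dcols else dxn[, sel] <- dcols
      dx[, , , n] <- dxn
    }
  } else {
    idx <- conv_idx(l, C, H, W)
    k2 <- l$k * l$k
    Hp <- l$padded_hw[1]; Wp <- l$padded_hw[2]
    p <- l$pad
    for (n in seq_len(N)) {
      xp <- pad_plane(x[, , , n, drop = FALSE], C, H, W, p)
      cols <- matrix(xp[idx], nrow = nrow(idx))
      dy <- matrix(dout[, , , n], l$cout, Ho * Wo)
      gW <- gW + tcrossprod(dy, cols)
      if (!is.null(gb)) gb <- gb + rowSums(dy)
      dcols <- crossprod(l$W, dy)
      dxp <- numeric(C * Hp * Wp)
      for (j in seq_len(k2)) {
        rows <- ((j - 1L) * C + 1L):(j * C)
        ij <- idx[rows, ]
        dxp[ij] <- dxp[ij] + dcols[rows, ]
      }
      dim(dxp) <- c(C, Hp, Wp)
      dx[, , , n] <- if (p > 0L)
        dxp[, (p + 1L):(p + H), (p + 1L):(p + W), drop = FALSE] else dxp
    }
  }
  l$gW <- gW; if (!is.null(gb)) l$gb <- gb
  l$x <- NULL
  dx
}

#### batch normalization ####################################################

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", c = c, gamma = rep(1, c), beta = numeric(c),
            running_mean = numeric(c), running_var = rep(1, c),
            momentum = momentum, eps = eps)
}

fwd.ht_bn <- function(l, x, training = FALSE) {
  d <- dim(x); C <- d[1]; M <- prod(d[-1])
  xm <- x; dim(xm) <- c(C, M)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v <- pmax(v, 0)
    l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
    l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
  } else {
    mu <- l$running_mean; v <- l$running_var
  }
  istd <- 1 / sqrt(v + l$eps)
  xhat <- (xm - mu) * istd
  out <- xhat * l$gamma + l$beta
  l$last_training <- training
  if (training || isTRUE(l$grad_eval)) { l$xhat <- xhat; l$istd <- istd }
  dim(out) <- d
  out
}

bwd.ht_bn <- function(l, dout) {
  d <- dim(dout); C <- d[1]; M <- prod(d[-1])
  dy <- dout; dim(dy) <- c(C, M)
  xhat <- l$xhat; istd <- l$istd
  l$ggamma <- rowSums(dy * xhat)
  l$gbeta <- rowSums(dy)
  if (isTRUE(l$last_training)) {
    mdy <- rowMeans(dy)
    mdyx <- rowMeans(dy * xhat)
    dx <- (l$gamma * istd) * (dy - mdy - xhat * mdyx)
  } else {
    # frozen statistics: the normalization is an affine map
    dx <- (l$gamma * istd) * dy
  }
  dim(dx) <- d
  l$xhat <- NULL
  dx
}

#### relu ###################################################################

nn_relu <- function() new_layer("relu")

fwd.ht_relu <- function(l, x, training = FALSE) {
  l$mask <- x > 0
  x * l$mask
}

bwd.ht_relu <- function(l, dout) {
  dx <- dout * l$mask
  l$mask <- NULL
  dx
}

#### max pooling ############################################################

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))

fwd.ht_maxpool <- function(l, x, training = FALSE) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  k <- l$k; st <- l$stride; p <- l$pad
  Ho <- conv_out_dim(H, k, st, p, 1L); Wo <- conv_out_dim(W, k, st, p, 1L)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  # flatten channel+batch into planes; pool over the plane
  xp <- array(-Inf, c(C, Hp, Wp, N))
  xp[, (p + 1L):(p + H), (p + 1L):(p + W), ] <- x
  iy0 <- (seq_len(Ho) - 1L) * st + 1L
  ix0 <- (seq_len(Wo) - 1L) * st + 1L
  out <- array(-Inf, c(C, Ho, Wo, N))
  arg <- array(0L, c(C, Ho, Wo, N))
  j <- 0L
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    j <- j + 1L
    slab <- xp[, iy0 + (ky - 1L), ix0 + (kx - 1L), , drop = FALSE]
    upd <- slab > out
    out[upd] <- slab[upd]
    arg[upd] <- j
  }
  l$arg <- arg; l$in_dim <- d; l$out_hw <- c(Ho, Wo)
  out
}

bwd.ht_maxpool <- function(l, dout) {
  d <- l$in_dim; C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  k <- l$k; st <- l$stride; p <- l$pad
  Ho <- l$out_hw[1]; Wo <- l$out_hw[2]
  Hp <- H + 2L * p; Wp <- W + 2L * p
  dxp <- array(0, c(C, Hp, Wp, N))
  iy0 <- (seq_len(Ho) - 1L) * st + 1L
  ix0 <- (seq_len(Wo) - 1L) * st + 1L
  j <- 0L
  for (kx in seq_len(k)) for (ky in seq_len(k)) {
    j <- j + 1L
    sel <- l$arg == j
    if (!any(sel)) next
    add <- array(0, c(C, Ho, Wo, N))
    add[sel] <- dout[sel]
    dxp[, iy0 + (ky - 1L), ix0 + (kx - 1L), ] <-
      dxp[, iy0 + (ky - 1L), ix0 + (kx - 1L), , drop = FALSE] + add
  }
  l$arg <- NULL
  dxp[, (p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
}

#### global pooling #########################################################

# global average pool (C,H,W,N) -> (C,N)
gap_fwd <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  grp <- rep(seq_len(d[1]), d[2] * d[3])
  rowsum(xm, grp, reorder = TRUE) / (d[2] * d[3])
}

gap_bwd <- function(dpool, d) {
  scale <- 1 / (d[2] * d[3])
  out <- array(0, d)
  for (n in seq_len(d[4])) out[, , , n] <- dpool[, n] * scale
  out
}

# global max pool (C,H,W,N) -> list(values (C,N), arg (C,N) spatial index)
gmp_fwd <- function(x) {
  d <- dim(x)
  vals <- matrix(0, d[1], d[4]); arg <- matrix(0L, d[1], d[4])
  for (n in seq_len(d[4])) {
    m <- matrix(x[, , , n], d[1], d[2] * d[3])
    am <- max.col(m, ties.method = "first")
    vals[, n] <- m[cbind(seq_len(d[1]), am)]
    arg[, n] <- am
  }
  list(values = vals, arg = arg)
}

gmp_bwd <- function(dpool, arg, d) {
  out <- array(0, d)
  for (n in seq_len(d[4])) {
    m <- matrix(0, d[1], d[2] * d[3])
    m[cbind(seq_len(d[1]), arg[, n])] <- dpool[, n]
    out[, , , n] <- m
  }
  out
}

#### fully connected ########################################################

nn_fc <- function(cin, cout, bias = TRUE) {
  W <- matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)), nrow = cout)
  new_layer("fc", cin = cin, cout = cout, W = W,
            b = if (bias) numeric(cout) else NULL)
}

fwd.ht_fc <- function(l, x, training = FALSE) {
  l$x <- x
  y <- l$W %*% x
  if (!is.null(l$b)) y <- y + l$b
  y
}

bwd.ht_fc <- function(l, dout) {
  l$gW <- tcrossprod(dout, l$x)
  if (!is.null(l$b)) l$gb <- rowSums(dout)
  dx <- crossprod(l$W, dout)
  l$x <- NULL
  dx
}

#### dispatch ###############################################################

fwd <- function(l, x, training = FALSE) UseMethod("fwd")
bwd <- function(l, dout) UseMethod("bwd")

fwd_seq <- function(layers, x, training = FALSE) {
  for (l in layers) x <- fwd(l, x, training)
  x
}

bwd_seq <- function(layers, dout) {
  for (l in rev(layers)) dout <- bwd(l, dout)
  dout
}

#### optimizer ##############################################################

collect_param_refs <- function(layers) {
  out <- list()
  for (l in layers)
    for (nm in layer_params(l))
      out[[length(out) + 1L]] <- list(env = l, name = nm)
  out
}

n_params_of <- function(layers)
  sum(vapply(collect_param_refs(layers),
             function(p) length(p$env[[p$name]]), numeric(1)))

zero_grads <- function(layers) {
  for (l in layers)
    for (nm in layer_params(l)) l[[paste0("g", nm)]] <- NULL
  invisible(NULL)
}

# SGD with Nesterov momentum and decoupled-from-nothing L2 weight decay,
# matching the common framework update: v <- mu v + (g + wd w);
# w <- w - lr (g + wd w + mu v)
sgd_step <- function(layers, lr, momentum = 0.9, weight_decay = 0,
                     nesterov = TRUE) {
  for (l in layers) {
    for (nm in layer_params(l)) {
      g <- l[[paste0("g", nm)]]
      if (is.null(g)) next
      w <- l[[nm]]
      if (weight_decay > 0) g <- g + weight_decay * w
      vn <- paste0("v", nm)
      v <- l[[vn]]
      if (is.null(v)) v <- g * 0
      v <- momentum * v + g
      l[[vn]] <- v
      step <- if (nesterov) g + momentum * v else v
      l[[nm]] <- w - lr * step
    }
  }
  invisible(NULL)
}

# snapshots include BN running statistics so a restored checkpoint
# reproduces its recorded evaluation exactly
collect_state_refs <- function(layers) {
  out <- list()
  for (l in layers) {
    nms <- c(layer_params(l),
             intersect(c("running_mean", "running_var"), ls(l)))
    for (nm in nms) out[[length(out) + 1L]] <- list(env = l, name = nm)
  }
  out
}

snapshot_params <- function(layers) {
  lapply(collect_state_refs(layers), function(p) p$env[[p$name]])
}

restore_params <- function(layers, snap) {
  refs <- collect_state_refs(layers)
  stopifnot(length(refs) == length(snap))
  for (i in seq_along(refs)) refs[[i]]$env[[refs[[i]]$name]] <- snap[[i]]
  invisible(NULL)
}
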