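# Minimal neural-network engine: conv / transposed-conv / batch-norm /
# max-pool / dense / dropout layers with reverse-mode gradients and Adam.
# Written in vectorized base R: convolutions use precomputed im2col gather
# indices and a Matrix-sparse scatter operator for the backward pass, so all
# heavy arithmetic is BLAS matrix multiplication. Every layer is an
# environment holding its parameters, gradients and forward cache; gradients
# are verified against numerical differentiation in the test suite.
#
# Tensor layout is channel-first: feature maps are 4D arrays (C, H, W, N).
# With channels fastest, the (C, H*W*N) views needed by batch norm and the
# (F, P*N) views needed by convolutions are plain `dim<-` changes (no
# transposition), and per-channel vector ops recycle for free. Dense
# activations are matrices (D, N). All randomness (init, dropout, sampling)
# draws from the R RNG, so training is exactly reproducible under set.seed().

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  class(e) <- "nn_layer"
  e
}

conv_out_dim <- function(n, k, stride, p_lo, p_hi) {
  (n + p_lo + p_hi - k) %/% stride + 1L
}

# im2col base indices for one padded image (C, Hp, Wp); rows ordered
# (c, ki, kj), columns ordered (oi, oj).
im2col_index <- function(Hp, Wp, C, k, stride, Ho, Wo) {
  cc <- rep(seq_len(C), times = k * k)
  ki <- rep(rep(seq_len(k), each = C), times = k)
  kj <- rep(seq_len(k), each = C * k)
  base <- cc + C * (ki - 1L) + C * Hp * (kj - 1L)
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  outer(base, C * (oi - 1L) * stride + C * Hp * (oj - 1L) * stride, `+`)
}

pad_array <- function(x, p) {  # p = c(top, bottom, left, right) in (H, W)
  if (all(p == 0L)) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + p[1] + p[2], d[3] + p[3] + p[4], d[4]))
  out[, p[1] + seq_len(d[2]), p[3] + seq_len(d[3]), ] <- x
  out
}

unpad_array <- function(x, p, H, W) {
  if (all(p == 0L)) return(x)
  x[, p[1] + seq_len(H), p[3] + seq_len(W), , drop = FALSE]
}

# Shared geometry for conv and conv-transpose: the underlying convolution
# maps (Cin, Hin, Win) -> (F, Hout, Wout).
conv_machinery <- function(Hin, Win, Cin, k, stride, pad) {
  Hp <- Hin + pad[1] + pad[2]
  Wp <- Win + pad[3] + pad[4]
  Ho <- conv_out_dim(Hin, k, stride, pad[1], pad[2])
  Wo <- conv_out_dim(Win, k, stride, pad[3], pad[4])
  idx <- im2col_index(Hp, Wp, Cin, k, stride, Ho, Wo)
  scatter <- Matrix::sparseMatrix(i = as.integer(idx),
                                  j = seq_along(idx),
                                  x = 1,
                                  dims = c(Hp * Wp * Cin, length(idx)))
  list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx = as.integer(idx),
       k2C = k * k * Cin, P = Ho * Wo, scatter = scatter)
}

gather_idx <- function(mach, img_len, N, cache) {
  key <- as.character(N)
  if (is.null(cache[[key]]))
    cache[[key]] <- rep(mach$idx, times = N) +
      rep.int((seq_len(N) - 1L) * img_len, rep.int(length(mach$idx), N))
  cache[[key]]
}

# in_shape = (C, H, W)
layer_conv2d <- function(in_shape, filters, k = 3L, stride = 1L,
                         pad = c(1L, 1L, 1L, 1L)) {
  l <- new_layer("conv2d")
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  m <- conv_machinery(H, W, C, k, stride, pad)
  l$params$W <- matrix(rnorm(filters * m$k2C, sd = sqrt(2 / m$k2C)),
                       filters, m$k2C)
  l$params$b <- numeric(filters)
  l$in_shape <- in_shape
  l$out_shape <- c(filters, m$Ho, m$Wo)
  l$gcache <- list()
  l$forward <- function(x, training = FALSE) {
    N <- dim(x)[4]
    xp <- pad_array(x, pad)
    g <- gather_idx(m, m$Hp * m$Wp * C, N, l$gcache)
    xcol <- matrix(xp[g], m$k2C, m$P * N)
    y <- l$params$W %*% xcol + l$params$b
    l$cache <- list(xcol = xcol, N = N)
    dim(y) <- c(filters, m$Ho, m$Wo, N)
    y
  }
  l$backward <- function(dy) {
    N <- l$cache$N
    dim(dy) <- c(filters, m$P * N)
    l$grads$W <- dy %*% t(l$cache$xcol)
    l$grads$b <- rowSums(dy)
    dxcol <- crossprod(l$params$W, dy)
    dim(dxcol) <- c(m$k2C * m$P, N)
    dxp <- as.matrix(m$scatter %*% dxcol)
    dim(dxp) <- c(C, m$Hp, m$Wp, N)
    unpad_array(dxp, pad, H, W)
  }
  l
}

# Transposed convolution: the adjoint of a conv mapping
# (out_channels, out_hw) -> (in_shape). Upsamples when stride > 1.
layer_conv2d_transpose <- function(in_shape, out_channels, out_hw, k = 3L,
                                   stride = 2L, pad = c(1L, 1L, 1L, 1L)) {
  l <- new_layer("conv2d_transpose")
  Ci <- in_shape[1]; Hi <- in_shape[2]; Wi <- in_shape[3]
  Ho <- out_hw[1]; Wo <- out_hw[2]; Co <- out_channels
  m <- conv_machinery(Ho, Wo, Co, k, stride, pad)
  if (m$Ho != Hi || m$Wo != Wi)
    stop(sprintf("conv_transpose geometry mismatch: underlying conv gives %dx%d, input is %dx%d",
                 m$Ho, m$Wo, Hi, Wi))
  l$params$W <- matrix(rnorm(Ci * m$k2C, sd = sqrt(2 / (k * k * Ci))),
                       Ci, m$k2C)
  l$params$b <- numeric(Co)
  l$in_shape <- in_shape
  l$out_shape <- c(Co, Ho, Wo)
  l$gcache <- list()
  l$forward <- function(x, training = FALSE) {
    N <- dim(x)[4]
    dim(x) <- c(Ci, m$P * N)
    ycol <- crossprod(l$params$W, x)        # (k2*Co, P*N)
    dim(ycol) <- c(m$k2C * m$P, N)
    yp <- as.matrix(m$scatter %*% ycol)
    dim(yp) <- c(Co, m$Hp, m$Wp, N)
    l$cache <- list(xm = x, N = N)
    unpad_array(yp, pad, Ho, Wo) + l$params$b
  }
  l$backward <- function(dy) {
    N <- l$cache$N
    l$grads$b <- rowSums(matrix(dy, Co, Ho * Wo * N))
    dyp <- pad_array(dy, pad)
    g <- gather_idx(m, m$Hp * m$Wp * Co, N, l$gcache)
    gcol <- matrix(dyp[g], m$k2C, m$P * N)
    l$grads$W <- l$cache$xm %*% t(gcol)
    dx <- l$params$W %*% gcol               # (Ci, P*N)
    dim(dx) <- c(Ci, Hi, Wi, N)
    dx
  }
  l
}

layer_batchnorm <- function(in_shape, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("batchnorm")
  conv_mode <- length(in_shape) == 3L
  C <- in_shape[1]
  l$params$gamma <- rep(1, C)
  l$params$beta <- rep(0, C)
  l$run_mean <- rep(0, C)
  l$run_var <- rep(1, C)
  l$in_shape <- in_shape; l$out_shape <- in_shape
  l$forward <- function(x, training = FALSE) {
    dref <- dim(x)
    xm <- x
    dim(xm) <- c(C, length(xm) / C)
    M <- ncol(xm)
    if (training) {
      mu <- rowMeans(xm)
      v <- rowMeans(xm^2) - mu^2
      if (is.null(l$warm)) {
        # warm-start the running statistics from the first batch instead of
        # blending with the (0, 1) initialization
        l$run_mean <- mu
        l$run_var <- v * M / max(M - 1, 1)
        l$warm <- TRUE
      } else {
        l$run_mean <- momentum * l$run_mean + (1 - momentum) * mu
        l$run_var <- momentum * l$run_var + (1 - momentum) * v * M / max(M - 1, 1)
      }
    } else {
      mu <- l$run_mean
      v <- l$run_var
    }
    istd <- 1 / sqrt(v + eps)
    xhat <- (xm - mu) * istd
    y <- xhat * l$params$gamma + l$params$beta
    l$cache <- list(xhat = xhat, istd = istd, dref = dref,
                    training = training)
    dim(y) <- dref
    y
  }
  l$backward <- function(dy) {
    cc <- l$cache
    dim(dy) <- dim(cc$xhat)
    l$grads$gamma <- rowSums(dy * cc$xhat)
    l$grads$beta <- rowSums(dy)
    dxhat <- dy * l$params$gamma
    dxm <- if (cc$training) {
      (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat)) *
        cc$istd
    } else dxhat * cc$istd
    dim(dxm) <- cc$dref
    dxm
  }
  l
}

layer_relu <- function(in_shape) {
  l <- new_layer("relu")
  l$in_shape <- in_shape; l$out_shape <- in_shape
  l$forward <- function(x, training = FALSE) {
    l$cache <- x > 0
    x * l$cache
  }
  l$backward <- function(dy) dy * l$cache
  l
}

layer_maxpool2 <- function(in_shape) {
  l <- new_layer("maxpool2")
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  Ho <- H %/% 2L; Wo <- W %/% 2L
  l$in_shape <- in_shape; l$out_shape <- c(C, Ho, Wo)
  ro <- seq(1L, 2L * Ho, by = 2L)
  co <- seq(1L, 2L * Wo, by = 2L)
  l$forward <- function(x, training = FALSE) {
    s1 <- x[, ro, co, , drop = FALSE]
    s2 <- x[, ro + 1L, co, , drop = FALSE]
    s3 <- x[, ro, co + 1L, , drop = FALSE]
    s4 <- x[, ro + 1L, co + 1L, , drop = FALSE]
    k12 <- s1 >= s2
    v12 <- pmax(s1, s2)
    k34 <- s3 >= s4
    v34 <- pmax(s3, s4)
    kk <- v12 >= v34
    l$cache <- list(which4 = ifelse(kk, ifelse(k12, 1L, 2L),
                                    ifelse(k34, 3L, 4L)),
                    N = dim(x)[4])
    pmax(v12, v34)
  }
  l$backward <- function(dy) {
    N <- l$cache$N
    w4 <- l$cache$which4
    ii <- rep(rep(ro, each = C), times = Wo * N) + (w4 == 2L | w4 == 4L)
    jj <- rep(rep(co, each = C * Ho), times = N) + (w4 == 3L | w4 == 4L)
    nn <- rep(seq_len(N) - 1L, each = C * Ho * Wo)
    lin <- rep.int(seq_len(C), Ho * Wo * N) + C * (ii - 1L) +
      C * H * (jj - 1L) + C * H * W * nn
    dx <- numeric(C * H * W * N)
    dx[lin] <- dy
    dim(dx) <- c(C, H, W, N)
    dx
  }
  l
}

layer_flatten <- function(in_shape) {
  l <- new_layer("flatten")
  D <- prod(in_shape)
  l$in_shape <- in_shape; l$out_shape <- D
  l$forward <- function(x, training = FALSE) {
    l$cache <- dim(x)
    dim(x) <- c(D, dim(x)[4])
    x
  }
  l$backward <- function(dy) {
    dim(dy) <- l$cache
    dy
  }
  l
}

layer_reshape <- function(in_dim, out_shape) {
  l <- new_layer("reshape")
  l$in_shape <- in_dim; l$out_shape <- out_shape
  l$forward <- function(x, training = FALSE) {
    l$cache <- ncol(x)
    dim(x) <- c(out_shape, ncol(x))
    x
  }
  l$backward <- function(dy) {
    dim(dy) <- c(prod(out_shape), l$cache)
    dy
  }
  l
}

layer_dense <- function(in_dim, out_dim) {
  l <- new_layer("dense")
  l$params$W <- matrix(rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)),
                       out_dim, in_dim)
  l$params$b <- numeric(out_dim)
  l$in_shape <- in_dim; l$out_shape <- out_dim
  l$forward <- function(x, training = FALSE) {
    l$cache <- x
    l$params$W %*% x + l$params$b
  }
  l$backward <- function(dy) {
    l$grads$W <- dy %*% t(l$cache)
    l$grads$b <- rowSums(dy)
    crossprod(l$params$W, dy)
  }
  l
}

layer_dropout <- function(in_shape, rate) {
  l <- new_layer("dropout")
  l$in_shape <- in_shape; l$out_shape <- in_shape
  l$rate <- rate
  l$forward <- function(x, training = FALSE) {
    if (!training || rate <= 0) {
      l$cache <- NULL
      return(x)
    }
    mask <- (runif(length(x)) > rate) / (1 - rate)
    dim(mask) <- dim(x)
    l$cache <- mask
    x * mask
  }
  l$backward <- function(dy) if (is.null(l$cache)) dy else dy * l$cache
  l
}

net_forward <- function(layers, x, training = FALSE) {
  for (l in layers) x <- l$forward(x, training)
  x
}

net_backward <- function(layers, g) {
  for (l in rev(layers)) g <- l$backward(g)
  g
}

net_param_count <- function(layers) {
  sum(vapply(layers, function(l)
    sum(vapply(l$params, length, numeric(1))), numeric(1)))
}

# Adam update over all parameters of all layers (state kept per layer).
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (length(l$params) == 0L) next
    if (is.null(l$opt))
      l$opt <- list(m = lapply(l$params, function(p) p * 0),
                    v = lapply(l$params, function(p) p * 0))
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      l$opt$m[[nm]] <- beta1 * l$opt$m[[nm]] + (1 - beta1) * g
      l$opt$v[[nm]] <- beta2 * l$opt$v[[nm]] + (1 - beta2) * g^2
      mhat <- l$opt$m[[nm]] / (1 - beta1^t)
      vhat <- l$opt$v[[nm]] / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# Stack a list of (H x W) maps into a channel-first (1, H, W, N) batch.
maps_to_tensor <- function(maps) {
  H <- nrow(maps[[1]])
  W <- ncol(maps[[1]])
  x <- unlist(maps, use.names = FALSE)
  dim(x) <- c(1L, H, W, length(maps))
  x
}
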