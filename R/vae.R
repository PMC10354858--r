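#' VAE configuration
#'
#' Architecture and training hyperparameters of the variational autoencoder.
#' The encoder is three stride-2 convolution blocks (3x3 kernels, batch norm,
#' ReLU) with `filters` channels, followed by dense heads for the latent mean
#' and log-variance; the decoder mirrors it with transposed convolutions and
#' a linear output (inputs live in [-0.2, 0.2], so no squashing activation).
#'
#' @param latent_dim latent dimensionality.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param kl_weight weight of the KL term in the training objective.
#' @param recon_sigma Gaussian decoder noise scale; the reconstruction term
#'   is the summed squared error divided by `2 * recon_sigma^2` (the
#'   Gaussian log-likelihood up to a constant). The default matches the ~1%
#'   residual amplitude of error-free dose-difference maps.
#' @param filters channels of the three encoder blocks.
#' @param seed seed for weight initialization and training randomness.
#' @return A `vae_config` object.
#' @export
vae_config <- function(latent_dim = 30, epochs = 200, batch_size = 64,
                       learning_rate = 1e-3, kl_weight = 1,
                       recon_sigma = 0.01, filters = c(16, 32, 64),
                       seed = 1) {
  stopifnot(latent_dim >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, recon_sigma > 0, length(filters) == 3)
  structure(list(latent_dim = latent_dim, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 kl_weight = kl_weight, recon_sigma = recon_sigma,
                 filters = filters, seed = seed),
            class = "vae_config")
}

#' Closed-form KL divergence to the standard normal
#'
#' For a diagonal Gaussian latent with mean `mu` and variance `sigma`,
#' returns `-1/2 * sum(1 + log(sigma) - mu^2 - sigma)`, the KL divergence
#' from N(mu, sigma) to N(0, 1) summed over dimensions. `sigma` is the
#' variance vector (strictly positive).
#'
#' @param mu latent mean vector.
#' @param sigma latent variance vector, same length, all > 0.
#' @return scalar KL loss.
#' @examples
#' kl_loss(rep(0, 30), rep(1, 30))  # 0
#' @export
kl_loss <- function(mu, sigma) {
  if (length(mu) != length(sigma)) stop("mu and sigma lengths differ")
  if (any(sigma <= 0)) stop("sigma (variance) must be strictly positive")
  -0.5 * sum(1 + log(sigma) - mu^2 - sigma)
}

#' Reparameterization: sample a latent vector
#'
#' `z = mu + epsilon * sigma`, elementwise, with `epsilon` standard normal by
#' default. `sigma` here is the standard deviation.
#'
#' @param mu latent mean.
#' @param sigma latent standard deviation (same shape).
#' @param epsilon noise draw; defaults to a standard-normal sample.
#' @return latent vector `z`.
#' @export
reparameterize <- function(mu, sigma, epsilon = rnorm(length(mu))) {
  if (length(mu) != length(sigma) || length(epsilon) != length(mu))
    stop("mu, sigma and epsilon shapes differ")
  mu + epsilon * sigma
}

#' Evidence lower bound loss for one map
#'
#' Mean-squared error between input and reconstruction plus
#' `kl_weight * kl_loss(mu, sigma)`.
#'
#' @param input_map,reconstruction matrices of identical shape.
#' @param mu,sigma latent mean and variance vectors.
#' @param kl_weight weight of the KL term.
#' @return scalar loss.
#' @export
elbo_loss <- function(input_map, reconstruction, mu, sigma, kl_weight = 1) {
  if (!all(dim(input_map) == dim(reconstruction)))
    stop("input and reconstruction shapes differ")
  mean((input_map - reconstruction)^2) + kl_weight * kl_loss(mu, sigma)
}

build_vae <- function(config, input_dim = 27) {
  f <- config$filters
  n <- config$latent_dim
  # stride-2 'same'-style downsampling chain (27 -> 14 -> 7 -> 4 by default);
  # pads chosen so the transposed decoder mirrors the sizes exactly
  p1 <- c(1L, 1L, 1L, 1L)
  d1 <- conv_out_dim(input_dim, 3L, 2L, 1L, 1L)
  p2 <- if (d1 %% 2 == 0) c(1L, 0L, 1L, 0L) else c(1L, 1L, 1L, 1L)
  d2 <- conv_out_dim(d1, 3L, 2L, p2[1], p2[2])
  p3 <- if (d2 %% 2 == 0) c(1L, 0L, 1L, 0L) else c(1L, 1L, 1L, 1L)
  d3 <- conv_out_dim(d2, 3L, 2L, p3[1], p3[2])
  trunk <- list(
    layer_conv2d(c(1, input_dim, input_dim), f[1], stride = 2L, pad = p1),
    layer_batchnorm(c(f[1], d1, d1)), layer_relu(c(f[1], d1, d1)),
    layer_conv2d(c(f[1], d1, d1), f[2], stride = 2L, pad = p2),
    layer_batchnorm(c(f[2], d2, d2)), layer_relu(c(f[2], d2, d2)),
    layer_conv2d(c(f[2], d2, d2), f[3], stride = 2L, pad = p3),
    layer_batchnorm(c(f[3], d3, d3)), layer_relu(c(f[3], d3, d3)),
    layer_flatten(c(f[3], d3, d3)))
  feat <- d3 * d3 * f[3]
  head_mu <- list(layer_dense(feat, n))
  head_lv <- list(layer_dense(feat, n))
  decoder <- list(
    layer_dense(n, feat), layer_relu(feat),
    layer_reshape(feat, c(f[3], d3, d3)),
    layer_conv2d_transpose(c(f[3], d3, d3), f[2], c(d2, d2), stride = 2L,
                           pad = p3),
    layer_batchnorm(c(f[2], d2, d2)), layer_relu(c(f[2], d2, d2)),
    layer_conv2d_transpose(c(f[2], d2, d2), f[1], c(d1, d1), stride = 2L,
                           pad = p2),
    layer_batchnorm(c(f[1], d1, d1)), layer_relu(c(f[1], d1, d1)),
    layer_conv2d_transpose(c(f[1], d1, d1), 1L, c(input_dim, input_dim),
                           stride = 2L, pad = p1))
  structure(list(trunk = trunk, head_mu = head_mu, head_lv = head_lv,
                 decoder = decoder, config = config, input_dim = input_dim),
            class = "vae_model")
}

vae_layers <- function(model)
  c(model$trunk, model$head_mu, model$head_lv, model$decoder)

#' Train the variational autoencoder on error-free maps
#'
#' Minimizes the negative evidence lower bound with a Gaussian decoder
#' likelihood: summed squared reconstruction error scaled by
#' `1 / (2 * recon_sigma^2)` plus `kl_weight` times the closed-form KL
#' divergence, by Adam over minibatches. Per-epoch training losses and the
#' validation ELBO (deterministic latent, `z = mu`) are recorded.
#'
#' @param train_maps list of error-free maps (matrices, all the same size).
#' @param validation_maps optional list of validation maps.
#' @param config a [vae_config()].
#' @param verbose print per-epoch losses.
#' @return A trained `vae_model` with a `history` data frame
#'   (`epoch`, `elbo`, `recon_mse`, `kl`, `val_elbo`).
#' @export
train_vae <- function(train_maps, validation_maps = NULL,
                      config = vae_config(), verbose = FALSE) {
  if (length(train_maps) == 0L) stop("empty training set")
  input_dim <- nrow(train_maps[[1]])
  with_seed(config$seed, {
    model <- build_vae(config, input_dim)
    x_all <- maps_to_tensor(train_maps)
    x_val <- if (length(validation_maps)) maps_to_tensor(validation_maps)
    n <- length(train_maps)
    w_rec <- 1 / (2 * config$recon_sigma^2)
    hist <- vector("list", config$epochs)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_elbo <- ep_mse <- ep_kl <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        nb <- length(idx)
        xb <- x_all[, , , idx, drop = FALSE]
        h <- net_forward(model$trunk, xb, training = TRUE)
        mu <- net_forward(model$head_mu, h, training = TRUE)
        lv <- net_forward(model$head_lv, h, training = TRUE)
        eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
        sdv <- exp(lv / 2)
        z <- mu + eps * sdv
        xr <- net_forward(model$decoder, z, training = TRUE)
        diff <- xr - xb
        rec <- w_rec * sum(diff^2) / nb
        kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / nb
        loss <- rec + config$kl_weight * kl
        # gradients
        dxr <- (2 * w_rec / nb) * diff
        dz <- net_backward(model$decoder, dxr)
        dmu <- dz + config$kl_weight * mu / nb
        dlv <- dz * eps * 0.5 * sdv +
          config$kl_weight * (-0.5) * (1 - exp(lv)) / nb
        dh <- net_backward(model$head_mu, dmu) +
          net_backward(model$head_lv, dlv)
        net_backward(model$trunk, dh)
        step <- step + 1L
        adam_step(vae_layers(model), config$learning_rate, step)
        ep_elbo <- ep_elbo + loss * nb
        ep_mse <- ep_mse + sum(diff^2) / length(xb) * nb
        ep_kl <- ep_kl + kl * nb
      }
      val_elbo <- NA_real_
      if (!is.null(x_val)) {
        hv <- net_forward(model$trunk, x_val, training = FALSE)
        muv <- net_forward(model$head_mu, hv, training = FALSE)
        lvv <- net_forward(model$head_lv, hv, training = FALSE)
        xrv <- net_forward(model$decoder, muv, training = FALSE)
        nv <- dim(x_val)[4]
        val_elbo <- (w_rec * sum((xrv - x_val)^2) +
                       config$kl_weight *
                         (-0.5 * sum(1 + lvv - muv^2 - exp(lvv)))) / nv
      }
      hist[[ep]] <- data.frame(epoch = ep, elbo = ep_elbo / n,
                               recon_mse = ep_mse / n, kl = ep_kl / n,
                               val_elbo = val_elbo)
      if (verbose)
        message(sprintf("epoch %3d  elbo %.4f  mse %.6f  kl %.4f", ep,
                        ep_elbo / n, ep_mse / n, ep_kl / n))
    }
    model$history <- do.call(rbind, hist)
    model
  })
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf("VAE: %d-dim latent, %s filters, %d parameters%s\n",
              x$config$latent_dim,
              paste(x$config$filters, collapse = "/"),
              net_param_count(vae_layers(x)),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

#' Encode maps to latent statistics
#'
#' Deterministic forward pass (no sampling, batch norm in inference mode)
#' returning the latent mean and standard deviation per map.
#'
#' @param model a trained `vae_model`.
#' @param maps list of maps (matrices matching the training size).
#' @return list with `mu` and `sigma` matrices (`n_maps x latent_dim`).
#' @export
encode_maps <- function(model, maps) {
  if (!length(maps)) stop("no maps to encode")
  bad <- vapply(maps, function(m) !all(dim(m) == model$input_dim), logical(1))
  if (any(bad)) stop("maps with wrong shape: ", paste(which(bad), collapse = ", "))
  x <- maps_to_tensor(maps)
  h <- net_forward(model$trunk, x, training = FALSE)
  mu <- net_forward(model$head_mu, h, training = FALSE)
  lv <- net_forward(model$head_lv, h, training = FALSE)
  list(mu = t(mu), sigma = t(exp(lv / 2)))
}

#' Encode a single map
#' @param model trained `vae_model`.
#' @param map a matrix matching the training size.
#' @return list with `mu` and `sigma` vectors (latent mean and sd).
#' @export
encode_map <- function(model, map) {
  st <- encode_maps(model, list(map))
  list(mu = st$mu[1, ], sigma = st$sigma[1, ])
}

#' Reconstruct a map through the trained VAE
#'
#' Encodes to the latent mean (no sampling) and decodes.
#'
#' @param model trained `vae_model`.
#' @param map input matrix.
#' @return reconstructed matrix of the same size.
#' @export
reconstruct_map <- function(model, map) {
  if (!all(dim(map) == model$input_dim)) stop("map has the wrong shape")
  x <- maps_to_tensor(list(map))
  h <- net_forward(model$trunk, x, training = FALSE)
  mu <- net_forward(model$head_mu, h, training = FALSE)
  xr <- net_forward(model$decoder, mu, training = FALSE)
  matrix(xr, model$input_dim, model$input_dim)
}
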