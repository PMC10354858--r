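#' Supervised CNN configuration
#'
#' Three convolution blocks (3x3 conv, batch norm, ReLU, 2x2 max-pool) with
#' 16/32/64 filters, then dense layers 256 -> 32 -> 2 with dropout 0.2 and
#' 0.5 between them and a softmax output over the error-free / any-error
#' classes.
#'
#' @param filters conv filters per block.
#' @param dense_nodes dense layer widths; the last must be 2.
#' @param dropout_rates the two dropout rates.
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param seed reproducibility seed.
#' @return A `scnn_config` object.
#' @export
scnn_config <- function(filters = c(16, 32, 64), dense_nodes = c(256, 32, 2),
                        dropout_rates = c(0.2, 0.5), epochs = 200,
                        batch_size = 64, learning_rate = 1e-3, seed = 1) {
  stopifnot(length(filters) == 3, length(dense_nodes) == 3,
            dense_nodes[3] == 2, length(dropout_rates) == 2,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(filters = filters, dense_nodes = dense_nodes,
                 dropout_rates = dropout_rates, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = seed),
            class = "scnn_config")
}

#' Build the supervised CNN classifier
#'
#' @param config a [scnn_config()].
#' @param input_dim map edge length.
#' @return An `scnn_model` (untrained).
#' @export
build_scnn <- function(config = scnn_config(), input_dim = 27) {
  f <- config$filters
  dn <- config$dense_nodes
  dr <- config$dropout_rates
  with_seed(config$seed, {
    d0 <- input_dim
    layers <- list()
    cin <- 1L
    for (i in 1:3) {
      layers <- c(layers, list(
        layer_conv2d(c(cin, d0, d0), f[i], stride = 1L,
                     pad = c(1L, 1L, 1L, 1L)),
        layer_batchnorm(c(f[i], d0, d0)), layer_relu(c(f[i], d0, d0)),
        layer_maxpool2(c(f[i], d0, d0))))
      d0 <- d0 %/% 2L
      cin <- f[i]
    }
    feat <- d0 * d0 * f[3]
    layers <- c(layers, list(
      layer_flatten(c(f[3], d0, d0)),
      layer_dense(feat, dn[1]), layer_relu(dn[1]),
      layer_dropout(dn[1], dr[1]),
      layer_dense(dn[1], dn[2]), layer_relu(dn[2]),
      layer_dropout(dn[2], dr[2]),
      layer_dense(dn[2], dn[3])))
    structure(list(layers = layers, config = config, input_dim = input_dim),
              class = "scnn_model")
  })
}

#' @export
print.scnn_model <- function(x, ...) {
  cat(sprintf("S-CNN: %s filters, %s dense, %d parameters%s\n",
              paste(x$config$filters, collapse = "/"),
              paste(x$config$dense_nodes, collapse = "/"),
              net_param_count(x$layers),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

#' Class probabilities for a batch of maps
#'
#' Deterministic inference pass (dropout off, batch norm in inference mode).
#'
#' @param model an `scnn_model`.
#' @param maps list of maps.
#' @return `n x 2` matrix of softmax probabilities, columns
#'   `(error-free, any-error)`.
#' @export
scnn_predict <- function(model, maps) {
  x <- maps_to_tensor(maps)
  p <- t(softmax_cols(net_forward(model$layers, x, training = FALSE)))
  colnames(p) <- c("error_free", "any_error")
  p
}

# 9-fold expansion of an error-free map: 4 flips, the 4 flips dose-rescaled
# by `down`, and the identity rescaled by `up` (re-clipped).
expand_9fold <- function(map, down = 0.95, up = 1.05, clip = 0.2) {
  flips <- augment_flips(map)
  reclip <- function(m, k) pmin(pmax(m * k, -clip), clip)
  c(flips,
    lapply(flips, reclip, k = down),
    list(reclip(map, up)))
}

#' Assemble the labeled S-CNN datasets
#'
#' Training/validation inputs are the error-free maps (label "error-free")
#' and all error-condition maps (label "any-error") of the respective beam
#' splits; to balance the classes the error-free training maps are expanded
#' 9-fold through flipping and dose rescaling. Test maps keep their
#' beam-case structure for case-level scoring.
#'
#' @param dataset a [generate_dataset()] result (error conditions must be
#'   present for the train and validation splits).
#' @param size,clip map geometry.
#' @return list with `train`/`validation` (each `maps` + `labels`, 1 =
#'   any-error) and `test_cases` as in [assemble_vae_datasets()].
#' @export
assemble_scnn_datasets <- function(dataset, size = 27, clip = 0.2) {
  stopifnot(inherits(dataset, "qa_dataset"))
  splits <- vapply(dataset$beams, `[[`, "", "split")
  build_split <- function(which_split, expand_free) {
    maps <- list()
    labels <- integer(0)
    for (beam in dataset$beams[splits == which_split]) {
      kinds <- names(beam$conditions)
      missing <- setdiff(c("none", dataset$errors), kinds)
      if (length(missing))
        stop("beam ", beam$beam_id, " lacks conditions: ",
             paste(missing, collapse = ", "))
      for (kind in kinds) {
        mm <- build_case_maps(dataset, beam, kind, size, clip)
        if (kind == "none" && expand_free)
          mm <- do.call(c, lapply(mm, expand_9fold, clip = clip))
        maps <- c(maps, mm)
        labels <- c(labels, rep(as.integer(kind != "none"), length(mm)))
      }
    }
    list(maps = maps, labels = labels)
  }
  train <- build_split("train", expand_free = TRUE)
  validation <- build_split("validation", expand_free = FALSE)
  test_cases <- assemble_vae_datasets(dataset, augment = FALSE,
                                      size = size, clip = clip)$test_cases
  list(train = train, validation = validation, test_cases = test_cases)
}

#' Train the supervised CNN
#'
#' Cross-entropy training with Adam; per-epoch training loss/accuracy and
#' validation accuracy are recorded and the parameters of the best
#' validation-accuracy epoch are kept.
#'
#' @param datasets an [assemble_scnn_datasets()] result (or any list with
#'   `train$maps`, `train$labels`, optionally `validation`).
#' @param config a [scnn_config()].
#' @param verbose print per-epoch metrics.
#' @return A trained `scnn_model` with `history` and `best_epoch`.
#' @export
train_scnn <- function(datasets, config = scnn_config(), verbose = FALSE) {
  tr <- datasets$train
  if (length(tr$maps) == 0L) stop("empty training set")
  if (length(unique(tr$labels)) < 2L)
    stop("training data contain a single class")
  model <- build_scnn(config, input_dim = nrow(tr$maps[[1]]))
  with_seed(config$seed + 1L, {
    x_all <- maps_to_tensor(tr$maps)
    y_all <- tr$labels
    n <- length(y_all)
    has_val <- !is.null(datasets$validation) &&
      length(datasets$validation$maps) > 0L
    if (has_val) {
      x_val <- maps_to_tensor(datasets$validation$maps)
      y_val <- datasets$validation$labels
    }
    hist <- vector("list", config$epochs)
    best <- list(acc = -Inf, params = NULL, epoch = NA_integer_)
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- ep_correct <- 0
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        nb <- length(idx)
        xb <- x_all[, , , idx, drop = FALSE]
        yb <- y_all[idx]
        logits <- net_forward(model$layers, xb, training = TRUE)
        p <- softmax_cols(logits)
        pick <- cbind(yb + 1L, seq_len(nb))
        ep_loss <- ep_loss - sum(log(pmax(p[pick], 1e-12)))
        ep_correct <- ep_correct + sum((p[2, ] > 0.5) == (yb == 1L))
        dlogits <- p
        dlogits[pick] <- dlogits[pick] - 1
        net_backward(model$layers, dlogits / nb)
        step <- step + 1L
        adam_step(model$layers, config$learning_rate, step)
      }
      val_acc <- NA_real_
      if (has_val) {
        pv <- scnn_predict(model, datasets$validation$maps)
        val_acc <- mean((pv[, "any_error"] > 0.5) == (y_val == 1L))
        if (val_acc > best$acc) {
          best <- list(acc = val_acc,
                       params = lapply(model$layers, function(l)
                         list(params = l$params, run_mean = l$run_mean,
                              run_var = l$run_var)),
                       epoch = ep)
        }
      }
      hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n,
                               accuracy = ep_correct / n, val_acc = val_acc)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val %.3f", ep,
                        ep_loss / n, ep_correct / n, val_acc))
    }
    if (has_val && !is.null(best$params)) {
      for (i in seq_along(model$layers)) {
        model$layers[[i]]$params <- best$params[[i]]$params
        if (!is.null(best$params[[i]]$run_mean)) {
          model$layers[[i]]$run_mean <- best$params[[i]]$run_mean
          model$layers[[i]]$run_var <- best$params[[i]]$run_var
        }
      }
      model$best_epoch <- best$epoch
    }
    model$history <- do.call(rbind, hist)
    model
  })
}

#' Score a beam case with the supervised CNN
#'
#' Averages the any-error probability over the two plane maps.
#'
#' @param model trained `scnn_model`.
#' @param beam_case list with `beam_id`, `error_kind`, `maps` (two maps).
#' @return one-row data frame: `beam_id`, `error_kind`, `p_error_plane1`,
#'   `p_error_plane2`, `p_error_mean`.
#' @export
score_case_scnn <- function(model, beam_case) {
  if (length(beam_case$maps) != 2L) stop("beam case must carry two plane maps")
  p <- scnn_predict(model, beam_case$maps)[, "any_error"]
  data.frame(beam_id = beam_case$beam_id %||% NA_integer_,
             error_kind = beam_case$error_kind %||% NA_character_,
             p_error_plane1 = p[1], p_error_plane2 = p[2],
             p_error_mean = mean(p), stringsAsFactors = FALSE)
}

#' Score all test cases with the supervised CNN
#' @param model trained `scnn_model`.
#' @param test_cases list of beam cases.
#' @return data frame with one row per case.
#' @export
score_cases_scnn <- function(model, test_cases) {
  maps <- unlist(lapply(test_cases, `[[`, "maps"), recursive = FALSE)
  p <- scnn_predict(model, maps)[, "any_error"]
  i1 <- seq(1L, length(p), by = 2L)
  data.frame(
    beam_id = vapply(test_cases, function(cs) as.integer(cs$beam_id), 1L),
    error_kind = vapply(test_cases, `[[`, "", "error_kind"),
    p_error_plane1 = p[i1], p_error_plane2 = p[i1 + 1L],
    p_error_mean = (p[i1] + p[i1 + 1L]) / 2, stringsAsFactors = FALSE)
}
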