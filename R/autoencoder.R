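# Autoencoder / variational autoencoder dimensionality reduction.
#
# Architecture follows the pipeline's fixed design: tanh on every hidden
# layer and on the AE latent layer, sigmoid on the decoder output (hence the
# [0,1] normalization), MSE reconstruction loss, symmetric encoder/decoder.
# The VAE replaces the latent layer with linear mean/log-variance heads and
# adds a KL term; its deterministic encoding is the posterior mean.

.AE_LAYER_GRID <- 0:10
.AE_NODE_GRID <- c(200L, 400L, 600L, 800L, 1000L)
.AE_LATENT_GRID <- c(100L, 200L, 300L, 400L, 500L)

#' Autoencoder configuration
#'
#' Hyperparameters live on the tuning grid: hidden layers 0-10, nodes per
#' hidden layer in \{200, 400, ..., 1000\} (ignored when `n_hidden_layers =
#' 0`, meaning a direct input-to-latent map), latent dimension in
#' \{100, ..., 500\}.  The same sizes are used for the encoder and the
#' mirrored decoder.
#'
#' @param n_hidden_layers Hidden layers per side (0-10).
#' @param nodes_per_layer Width of each hidden layer.
#' @param latent_dim Latent dimension.
#' @param epochs Training epochs (default 10).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Optimizer step size.
#' @param batch_size Minibatch size.
#' @param seed RNG seed controlling init, shuffling and (VAE) noise.
#' @return An `AEConfig` list.
#' @export
ae_config <- function(n_hidden_layers = 2L, nodes_per_layer = 400L,
                      latent_dim = 100L, epochs = 10L, optimizer = "adam",
                      learning_rate = 1e-3, batch_size = 128L, seed = 1L) {
  n_hidden_layers <- as.integer(n_hidden_layers)
  stopifnot(n_hidden_layers %in% .AE_LAYER_GRID,
            latent_dim %in% .AE_LATENT_GRID,
            epochs >= 1L)
  if (n_hidden_layers > 0L && !(nodes_per_layer %in% .AE_NODE_GRID))
    stop("nodes_per_layer must be one of ",
         paste(.AE_NODE_GRID, collapse = ", "), call. = FALSE)
  structure(list(n_hidden_layers = n_hidden_layers,
                 nodes_per_layer = as.integer(nodes_per_layer),
                 latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "AEConfig")
}

# full grid as a data.frame (layers = 0 collapses the node axis)
.ae_grid <- function() {
  g1 <- expand.grid(n_hidden_layers = setdiff(.AE_LAYER_GRID, 0L),
                    nodes_per_layer = .AE_NODE_GRID,
                    latent_dim = .AE_LATENT_GRID)
  g0 <- expand.grid(n_hidden_layers = 0L, nodes_per_layer = NA_integer_,
                    latent_dim = .AE_LATENT_GRID)
  rbind(g0, g1)
}

#' @noRd
latent_matrix <- function(values, provenance = NULL) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(list(values = values, latent_dim = ncol(values),
                 provenance = provenance),
            class = "LatentMatrix")
}

#' @export
print.LatentMatrix <- function(x, ...) {
  cat("LatentMatrix:", nrow(x$values), "cells x", x$latent_dim, "dims\n")
  invisible(x)
}

.encoder_sizes <- function(n_genes, cfg) {
  hidden <- if (cfg$n_hidden_layers > 0L)
    rep(cfg$nodes_per_layer, cfg$n_hidden_layers) else integer(0)
  list(enc = c(n_genes, hidden, cfg$latent_dim),
       dec = c(cfg$latent_dim, rev(hidden), n_genes),
       n_hidden = length(hidden))
}

#' Train an autoencoder and encode the training data
#'
#' Trains a symmetric tanh autoencoder with sigmoid reconstruction output by
#' minibatch MSE minimization, then returns the frozen encoder and the
#' latent embedding of the training cells.
#'
#' @param norm A `NormalizedMatrix` from [normalize_counts()].
#' @param config An [ae_config()].
#' @return List with `model` (an `EncoderModel`) and `latent` (a
#'   `LatentMatrix`, cells x latent_dim).  The model stores the per-epoch
#'   training loss in `history`.
#' @export
train_autoencoder <- function(norm, config = ae_config()) {
  stopifnot(inherits(norm, "NormalizedMatrix"), inherits(config, "AEConfig"))
  x <- t(norm$values)
  sz <- .encoder_sizes(ncol(x), config)
  set.seed(config$seed)
  net <- nn_new(c(sz$enc, sz$dec[-1L]),
                c(rep("tanh", length(sz$enc) - 1L),
                  rep("tanh", length(sz$dec) - 2L), "sigmoid"))
  fit <- nn_fit(net, x, x, epochs = config$epochs,
                batch_size = config$batch_size,
                optimizer = config$optimizer, lr = config$learning_rate,
                loss = "mse")
  n_enc <- length(sz$enc) - 1L
  enc <- structure(list(layers = fit$net$layers[seq_len(n_enc)],
                        sizes = sz$enc), class = "scp_nn")
  dec <- structure(list(layers = fit$net$layers[-seq_len(n_enc)],
                        sizes = sz$dec), class = "scp_nn")
  model <- structure(list(kind = "ae", config = config, encoder = enc,
                          decoder = dec,
                          input_feature_ids = norm$feature_ids,
                          scaling_params = norm$scaling_params,
                          history = fit$history),
                     class = "EncoderModel")
  list(model = model, latent = encode(norm, model))
}

#' Train a variational autoencoder and encode the training data
#'
#' Same encoder/decoder stack as [train_autoencoder()], but the latent layer
#' is replaced by linear mean and log-variance heads; training minimizes
#' reconstruction MSE plus `kl_weight` times the KL divergence of the
#' diagonal-Gaussian posterior from the standard normal prior.  The
#' deterministic encoding is the posterior mean.
#'
#' @inheritParams train_autoencoder
#' @param kl_weight Weight of the KL term (default 1).
#' @return As [train_autoencoder()]; `model$history` is a data.frame with
#'   per-epoch reconstruction and KL components.
#' @export
train_vae <- function(norm, config = ae_config(), kl_weight = 1) {
  stopifnot(inherits(norm, "NormalizedMatrix"), inherits(config, "AEConfig"))
  x <- t(norm$values)
  d <- config$latent_dim
  sz <- .encoder_sizes(ncol(x), config)
  enc_sizes <- c(sz$enc[-length(sz$enc)], 2L * d)
  set.seed(config$seed)
  enc <- nn_new(enc_sizes, c(rep("tanh", length(enc_sizes) - 2L), "linear"))
  dec <- nn_new(sz$dec, c(rep("tanh", length(sz$dec) - 2L), "sigmoid"))
  st_e <- opt_init(enc, config$optimizer, config$learning_rate)
  st_d <- opt_init(dec, config$optimizer, config$learning_rate)

  n <- nrow(x)
  history <- data.frame(epoch = seq_len(config$epochs), recon = NA_real_,
                        kl = NA_real_)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    rec_tot <- 0; kl_tot <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      nb <- length(idx)
      fe <- nn_forward(enc, xb, training = TRUE)
      mu <- fe$out[, seq_len(d), drop = FALSE]
      lv <- pmin(pmax(fe$out[, d + seq_len(d), drop = FALSE], -10), 10)
      epsm <- matrix(stats::rnorm(nb * d), nb, d)
      z <- mu + exp(0.5 * lv) * epsm
      fd <- nn_forward(dec, z, training = TRUE)
      ls <- nn_loss(fd$out, xb, "mse")
      kl <- sum(0.5 * (mu^2 + exp(lv) - lv - 1)) / nb
      if (!is.finite(ls$value + kl))
        stop("non-finite VAE loss at epoch ", ep, call. = FALSE)
      bd <- nn_backward(dec, fd, ls$grad)
      dz <- bd$d_in
      dmu <- dz + kl_weight * mu / nb
      dlv <- dz * epsm * 0.5 * exp(0.5 * lv) +
        kl_weight * 0.5 * (exp(lv) - 1) / nb
      be <- nn_backward(enc, fe, cbind(dmu, dlv))
      up <- opt_step(dec, bd$grads, st_d); dec <- up$net; st_d <- up$state
      up <- opt_step(enc, be$grads, st_e); enc <- up$net; st_e <- up$state
      rec_tot <- rec_tot + ls$value * nb
      kl_tot <- kl_tot + kl * nb
    }
    history$recon[ep] <- rec_tot / n
    history$kl[ep] <- kl_tot / n
  }
  model <- structure(list(kind = "vae", config = config, encoder = enc,
                          decoder = dec, latent_dim = d,
                          input_feature_ids = norm$feature_ids,
                          scaling_params = norm$scaling_params,
                          history = history, kl_weight = kl_weight),
                     class = "EncoderModel")
  list(model = model, latent = encode(norm, model))
}

#' Encode cells with a trained encoder
#'
#' Pure function of the frozen weights: each cell's latent vector depends
#' only on that cell's normalized expression.  The input must be on the
#' model's feature space — use `normalize_counts(m, scaling =
#' model$scaling_params)` to project a new dataset onto it first.
#'
#' @param norm A `NormalizedMatrix` on the model's feature space.
#' @param model An `EncoderModel`.
#' @param min_feature_overlap Minimum fraction of the model's features that
#'   must be present (nonzero information) in the input when the input was
#'   projected from another dataset (default 0.5).
#' @return A `LatentMatrix` (cells x latent_dim).
#' @export
encode <- function(norm, model, min_feature_overlap = 0.5) {
  stopifnot(inherits(norm, "NormalizedMatrix"), inherits(model, "EncoderModel"))
  if (!identical(norm$feature_ids, model$input_feature_ids))
    stop("feature space mismatch: re-normalize the counts with ",
         "scaling = model$scaling_params", call. = FALSE)
  overlap <- norm$transfer_overlap %||% 1
  if (overlap < min_feature_overlap)
    stop("only ", round(100 * overlap), "% of the model's features are in ",
         "the new dataset (floor ", round(100 * min_feature_overlap),
         "%)", call. = FALSE)
  x <- t(norm$values)
  h <- nn_predict(model$encoder, x)
  if (model$kind == "vae")
    h <- h[, seq_len(model$latent_dim), drop = FALSE]
  rownames(h) <- norm$barcodes
  latent_matrix(h, provenance = model$kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random-search hyperparameter tuning for the autoencoder
#'
#' Samples `budget` distinct configurations from the tuning grid, trains
#' each on a random 90% of cells, and returns the configuration with the
#' lowest reconstruction MSE on the held-out 10%.
#'
#' @param norm A `NormalizedMatrix`.
#' @param budget Number of configurations to evaluate (capped at the grid
#'   size with a warning).
#' @param seed Master seed; sampling, splits and training all derive from it.
#' @param epochs Training epochs per candidate.
#' @param mode `"ae"` or `"vae"`.
#' @return The best `AEConfig`; attribute `"search"` is a data.frame of all
#'   evaluated configurations with their validation MSE.
#' @export
tune_autoencoder <- function(norm, budget = 20L, seed = 1L, epochs = 10L,
                             mode = c("ae", "vae")) {
  mode <- match.arg(mode)
  grid <- .ae_grid()
  if (budget > nrow(grid)) {
    warning("budget ", budget, " exceeds grid size ", nrow(grid),
            "; capped")
    budget <- nrow(grid)
  }
  set.seed(seed)
  picks <- grid[sample.int(nrow(grid), budget), , drop = FALSE]
  n <- length(norm$barcodes)
  val_idx <- sample.int(n, max(1L, round(0.1 * n)))
  tr <- .subset_norm(norm, setdiff(seq_len(n), val_idx))
  va <- .subset_norm(norm, val_idx)

  res <- numeric(budget)
  for (i in seq_len(budget)) {
    cfg <- ae_config(
      n_hidden_layers = picks$n_hidden_layers[i],
      nodes_per_layer = if (is.na(picks$nodes_per_layer[i])) 200L
                        else picks$nodes_per_layer[i],
      latent_dim = picks$latent_dim[i], epochs = epochs,
      seed = seed + i)
    fit <- if (mode == "ae") train_autoencoder(tr, cfg)
           else train_vae(tr, cfg)
    res[i] <- ae_validation_mse(va, fit$model)
  }
  best <- which.min(res)
  out <- ae_config(
    n_hidden_layers = picks$n_hidden_layers[best],
    nodes_per_layer = if (is.na(picks$nodes_per_layer[best])) 200L
                      else picks$nodes_per_layer[best],
    latent_dim = picks$latent_dim[best], epochs = epochs,
    seed = seed + best)
  attr(out, "search") <- cbind(picks, val_mse = res)
  out
}

#' Reconstruction MSE of an encoder model on held-out cells
#'
#' Encodes the cells and measures the mean squared reconstruction error
#' through the stored decoder; used by the tuner's model selection.
#'
#' @param norm A `NormalizedMatrix` on the model's feature space.
#' @param model An `EncoderModel` (must retain its decoder).
#' @return Mean squared reconstruction error.
#' @export
ae_validation_mse <- function(norm, model) {
  x <- t(norm$values)
  z <- encode(norm, model)$values
  mean((nn_predict(model$decoder, z) - x)^2)
}

.subset_norm <- function(norm, idx) {
  structure(list(values = norm$values[, idx, drop = FALSE],
                 cpk = norm$cpk[, idx, drop = FALSE],
                 feature_ids = norm$feature_ids,
                 barcodes = norm$barcodes[idx],
                 scaling_params = norm$scaling_params),
            class = "NormalizedMatrix")
}
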