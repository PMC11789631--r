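# Per-cell progression scoring: a multilayer feed-forward classifier is
# trained on the latent embedding with probabilistic (or binary) labels as
# soft targets.  The output layer is a two-way softmax; the reported score
# is the positive-class probability.  One independent model is trained per
# phenotype.

.CLF_LAYER_GRID <- 2:10
.CLF_NODE_GRID <- seq(50L, 500L, by = 50L)
.CLF_DROPOUT_GRID <- seq(0, 0.5, by = 0.1)
.CLF_ACT_GRID <- c("relu", "sigmoid", "tanh")
.CLF_OPT_GRID <- c("adam", "sgd")
.CLF_LR_GRID <- 10^(-(1:5))
.CLF_LOSS_GRID <- c("mse", "bce", "cce")

#' Classifier configuration
#'
#' The seven tunable hyperparameters and their grids: hidden layers 2-10,
#' nodes per layer \{50, ..., 500\}, dropout rate \{0, 0.1, ..., 0.5\}
#' (applied to the last hidden layer, before the output), hidden activation
#' \{relu, sigmoid, tanh\}, optimizer \{adam, sgd\}, learning rate
#' \{1e-1, ..., 1e-5\}, loss \{mse, bce, cce\}.  Output activation is fixed
#' to a two-way softmax; training runs a fixed 20 epochs.
#'
#' @param n_hidden_layers,nodes_per_layer,dropout_rate,hidden_activation
#'   See description.
#' @param optimizer,learning_rate,loss See description.
#' @param epochs Training epochs (default 20).
#' @param batch_size Minibatch size (default 32, the reference deep-learning stack's default).
#' @param seed RNG seed.
#' @return A `ClassifierConfig` list.
#' @export
classifier_config <- function(n_hidden_layers = 2L, nodes_per_layer = 100L,
                              dropout_rate = 0.2,
                              hidden_activation = "relu",
                              optimizer = "adam", learning_rate = 1e-3,
                              loss = "bce", epochs = 20L,
                              batch_size = 32L, seed = 1L) {
  stopifnot(n_hidden_layers %in% .CLF_LAYER_GRID,
            nodes_per_layer %in% .CLF_NODE_GRID,
            any(abs(dropout_rate - .CLF_DROPOUT_GRID) < 1e-9),
            hidden_activation %in% .CLF_ACT_GRID,
            optimizer %in% .CLF_OPT_GRID,
            any(abs(learning_rate - .CLF_LR_GRID) / learning_rate < 1e-9),
            loss %in% .CLF_LOSS_GRID,
            epochs >= 1L)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 nodes_per_layer = as.integer(nodes_per_layer),
                 dropout_rate = dropout_rate,
                 hidden_activation = hidden_activation,
                 optimizer = optimizer, learning_rate = learning_rate,
                 loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

#' @noRd
score_matrix <- function(scores) {
  stopifnot(is.matrix(scores), all(scores >= 0 & scores <= 1))
  structure(list(scores = scores, barcodes = rownames(scores),
                 phenotypes = colnames(scores)),
            class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat("ScoreMatrix:", nrow(x$scores), "cells x",
      ncol(x$scores), "phenotype(s):",
      paste(x$phenotypes, collapse = ", "), "\n")
  invisible(x)
}

# targets for one phenotype: matrix [1-p, p]
.soft_targets <- function(p) cbind(`0` = 1 - p, `1` = p)

.plabel_values <- function(plabels, barcodes) {
  if (inherits(plabels, "ProbabilisticLabels")) {
    v <- plabels$values[match(barcodes, plabels$barcodes)]
    if (anyNA(v))
      stop("probabilistic labels missing for some latent barcodes",
           call. = FALSE)
    v
  } else stop("expected a ProbabilisticLabels object", call. = FALSE)
}

# core trainer for one phenotype; x = latent values (cells x d), p in [0,1]
.train_one <- function(x, p, config) {
  set.seed(config$seed)
  sizes <- c(ncol(x), rep(config$nodes_per_layer, config$n_hidden_layers), 2L)
  acts <- c(rep(config$hidden_activation, config$n_hidden_layers), "softmax")
  net <- nn_new(sizes, acts)
  dropout <- rep(0, length(acts))
  if (config$dropout_rate > 0)
    dropout[config$n_hidden_layers] <- config$dropout_rate
  fit <- nn_fit(net, x, .soft_targets(p), epochs = config$epochs,
                batch_size = config$batch_size,
                optimizer = config$optimizer, lr = config$learning_rate,
                loss = config$loss, dropout = dropout)
  fit
}

#' Train a classifier with a fixed configuration
#'
#' The fast path: no hyperparameter search.  Trains one independent model
#' per phenotype on the latent features with the probabilistic labels as
#' soft softmax targets `[1 - p, p]`.  Supplying degenerate 0/1 labels
#' reproduces plain supervised training.
#'
#' @param latent A `LatentMatrix`.
#' @param plabels A `ProbabilisticLabels`, or a named list of them (one per
#'   phenotype).
#' @param config A [classifier_config()].
#' @param holdout_frac Optional fraction of cells excluded from training and
#'   scored afterward; threshold-0.5 accuracy against the thresholded labels
#'   is reported per phenotype.
#' @param seed Seed for the holdout split (model training uses
#'   `config$seed`).
#' @return List with `model` (a `ClassifierModel`), `scores` (a
#'   `ScoreMatrix` for all cells) and, when `holdout_frac` is set,
#'   `holdout` (data.frame of per-phenotype holdout accuracy).
#' @export
train_fixed <- function(latent, plabels, config = classifier_config(),
                        holdout_frac = NULL, seed = 1L) {
  stopifnot(inherits(latent, "LatentMatrix"))
  if (inherits(plabels, "ProbabilisticLabels"))
    plabels <- stats::setNames(list(plabels), plabels$phenotype)
  x <- latent$values
  bc <- rownames(x)
  n <- nrow(x)

  train_idx <- seq_len(n); hold_idx <- integer(0)
  if (!is.null(holdout_frac) && holdout_frac > 0) {
    set.seed(seed)
    hold_idx <- sort(sample.int(n, round(holdout_frac * n)))
    train_idx <- setdiff(seq_len(n), hold_idx)
  }

  nets <- list(); history <- list()
  scores <- matrix(NA_real_, n, length(plabels),
                   dimnames = list(bc, names(plabels)))
  holdout <- NULL
  for (ph in names(plabels)) {
    p <- .plabel_values(plabels[[ph]], bc)
    fit <- .train_one(x[train_idx, , drop = FALSE], p[train_idx], config)
    nets[[ph]] <- fit$net
    history[[ph]] <- fit$history
    scores[, ph] <- nn_predict(fit$net, x)[, 2L]
    if (length(hold_idx)) {
      acc <- mean((scores[hold_idx, ph] >= 0.5) ==
                    (p[hold_idx] >= 0.5))
      holdout <- rbind(holdout,
                       data.frame(phenotype = ph, n_holdout = length(hold_idx),
                                  accuracy = acc))
    }
  }
  model <- structure(list(config = config, nets = nets,
                          phenotypes = names(plabels),
                          latent_dim = ncol(x), history = history),
                     class = "ClassifierModel")
  out <- list(model = model, scores = score_matrix(scores))
  if (!is.null(holdout)) out$holdout <- holdout
  out
}

#' Random-search tuning followed by training
#'
#' Draws `budget` configurations from the hyperparameter grids, trains each
#' on 90% of the (non-holdout) cells and selects by validation loss on the
#' remaining 10%, then refits the winner as in [train_fixed()].  Holdout
#' cells, when requested, are excluded from both tuning and training.
#'
#' @inheritParams train_fixed
#' @param budget Number of configurations to evaluate (default 20).
#' @return As [train_fixed()]; the chosen configuration is in
#'   `$model$config`, and attribute `"search"` on the model holds the
#'   evaluated grid with validation losses (for the first phenotype).
#' @export
tune_and_train <- function(latent, plabels, budget = 20L,
                           holdout_frac = NULL, seed = 1L) {
  stopifnot(budget >= 1L, inherits(latent, "LatentMatrix"))
  if (inherits(plabels, "ProbabilisticLabels"))
    plabels <- stats::setNames(list(plabels), plabels$phenotype)
  x <- latent$values
  bc <- rownames(x)
  n <- nrow(x)
  set.seed(seed)
  hold_idx <- integer(0)
  if (!is.null(holdout_frac) && holdout_frac > 0)
    hold_idx <- sort(sample.int(n, round(holdout_frac * n)))
  avail <- setdiff(seq_len(n), hold_idx)
  val_idx <- sort(sample(avail, max(1L, round(0.1 * length(avail)))))
  tr_idx <- setdiff(avail, val_idx)

  # sample configurations
  draws <- data.frame(
    n_hidden_layers = sample(.CLF_LAYER_GRID, budget, TRUE),
    nodes_per_layer = sample(.CLF_NODE_GRID, budget, TRUE),
    dropout_rate = sample(.CLF_DROPOUT_GRID, budget, TRUE),
    hidden_activation = sample(.CLF_ACT_GRID, budget, TRUE),
    optimizer = sample(.CLF_OPT_GRID, budget, TRUE),
    learning_rate = sample(.CLF_LR_GRID, budget, TRUE),
    loss = sample(.CLF_LOSS_GRID, budget, TRUE),
    stringsAsFactors = FALSE)

  ph1 <- names(plabels)[1L]
  p <- .plabel_values(plabels[[ph1]], bc)
  val_loss <- numeric(budget)
  for (i in seq_len(budget)) {
    cfg <- classifier_config(
      n_hidden_layers = draws$n_hidden_layers[i],
      nodes_per_layer = draws$nodes_per_layer[i],
      dropout_rate = draws$dropout_rate[i],
      hidden_activation = draws$hidden_activation[i],
      optimizer = draws$optimizer[i],
      learning_rate = draws$learning_rate[i],
      loss = draws$loss[i], seed = seed + i)
    fit <- .train_one(x[tr_idx, , drop = FALSE], p[tr_idx], cfg)
    pred <- nn_predict(fit$net, x[val_idx, , drop = FALSE])
    val_loss[i] <- nn_loss(pred, .soft_targets(p[val_idx]), cfg$loss)$value
  }
  best <- which.min(val_loss)
  cfg <- classifier_config(
    n_hidden_layers = draws$n_hidden_layers[best],
    nodes_per_layer = draws$nodes_per_layer[best],
    dropout_rate = draws$dropout_rate[best],
    hidden_activation = draws$hidden_activation[best],
    optimizer = draws$optimizer[best],
    learning_rate = draws$learning_rate[best],
    loss = draws$loss[best], seed = seed + best)
  out <- train_fixed(latent, plabels,
                     config = cfg,
                     holdout_frac = holdout_frac, seed = seed)
  attr(out$model, "search") <- cbind(draws, val_loss = val_loss)
  out
}

#' Score cells with a pretrained classifier
#'
#' Pure, row-independent function of the frozen weights; used for
#' cross-dataset transfer of a model trained elsewhere.
#'
#' @param latent A `LatentMatrix` whose dimension matches the model.
#' @param model A `ClassifierModel`.
#' @return A `ScoreMatrix` (positive-class probability per phenotype).
#' @export
predict_scores <- function(latent, model) {
  stopifnot(inherits(latent, "LatentMatrix"),
            inherits(model, "ClassifierModel"))
  if (latent$latent_dim != model$latent_dim)
    stop("latent dimension ", latent$latent_dim,
         " does not match the model's expected input dimension ",
         model$latent_dim, call. = FALSE)
  x <- latent$values
  scores <- vapply(model$phenotypes,
                   function(ph) nn_predict(model$nets[[ph]], x)[, 2L],
                   numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(rownames(x), model$phenotypes))
  score_matrix(scores)
}

#' @export
predict.ClassifierModel <- function(object, latent, ...) {
  predict_scores(latent, object)
}

#' Save a trained model to a directory
#'
#' Works for both `EncoderModel` and `ClassifierModel`.  Writes a small JSON
#' manifest plus the serialized weights; [load_model()] restores an object
#' whose predictions are bit-identical to the original's.
#'
#' @param model The model object.
#' @param directory Output directory.
#' @return `directory`, invisibly.
#' @export
save_model <- function(model, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  cls <- class(model)[1L]
  manifest <- list(class = cls,
                   package = "scProgress",
                   config = unclass(model$config))
  if (cls == "ClassifierModel") {
    manifest$phenotypes <- model$phenotypes
    manifest$latent_dim <- model$latent_dim
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model, file.path(directory, "model.rds"), version = 2L)
  invisible(directory)
}

#' Load a model saved by [save_model()]
#' @param directory Model directory.
#' @return The restored model object.
#' @export
load_model <- function(directory) {
  f <- file.path(directory, "model.rds")
  if (!file.exists(f))
    stop("no model.rds under ", directory, call. = FALSE)
  readRDS(f)
}
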