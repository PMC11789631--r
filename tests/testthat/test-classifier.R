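test_that("configuration grids are enforced", {
  expect_error(classifier_config(n_hidden_layers = 1L))
  expect_error(classifier_config(nodes_per_layer = 60L))
  expect_error(classifier_config(dropout_rate = 0.35))
  expect_error(classifier_config(hidden_activation = "gelu"))
  expect_error(classifier_config(learning_rate = 3e-3))
  expect_error(classifier_config(loss = "hinge"))
  cfg <- classifier_config(n_hidden_layers = 3L, nodes_per_layer = 150L,
                           dropout_rate = 0.3, learning_rate = 1e-4)
  expect_s3_class(cfg, "ClassifierConfig")
})

test_that("fixed training is deterministic and scores stay in [0,1]", {
  pl <- planted_latent(n = 240L)
  plab <- structure(list(barcodes = rownames(pl$latent$values),
                         phenotype = "disease",
                         values = as.numeric(pl$class),
                         covered = rep(TRUE, 240L),
                         n_repeats_averaged = 1L),
                    class = "ProbabilisticLabels")
  cfg <- classifier_config(epochs = 6L, seed = 3L)
  a <- train_fixed(pl$latent, plab, cfg)
  b <- train_fixed(pl$latent, plab, cfg)
  expect_identical(a$model$nets, b$model$nets)
  expect_identical(a$scores$scores, b$scores$scores)
  expect_true(all(a$scores$scores >= 0 & a$scores$scores <= 1))
})

test_that("holdout evaluation reaches high accuracy on separable data", {
  pl <- planted_latent(n = 400L)
  plab <- structure(list(barcodes = rownames(pl$latent$values),
                         phenotype = "disease",
                         values = as.numeric(pl$class),
                         covered = rep(TRUE, 400L),
                         n_repeats_averaged = 1L),
                    class = "ProbabilisticLabels")
  fit <- train_fixed(pl$latent, plab, classifier_config(seed = 5L),
                     holdout_frac = 0.25, seed = 6L)
  expect_equal(fit$holdout$n_holdout, 100L)
  expect_gte(fit$holdout$accuracy, 0.95)
})

test_that("budget-1 tuning trains the single sampled configuration", {
  pl <- planted_latent(n = 150L)
  plab <- structure(list(barcodes = rownames(pl$latent$values),
                         phenotype = "disease",
                         values = as.numeric(pl$class),
                         covered = rep(TRUE, 150L),
                         n_repeats_averaged = 1L),
                    class = "ProbabilisticLabels")
  fit <- tune_and_train(pl$latent, plab, budget = 1L, seed = 9L)
  search <- attr(fit$model, "search")
  expect_equal(nrow(search), 1L)
  expect_equal(fit$model$config$n_hidden_layers, search$n_hidden_layers[1])
  expect_true(all(fit$scores$scores >= 0 & fit$scores$scores <= 1))
})

test_that("prediction is pure, transferable and serialization-stable", {
  pl <- planted_latent(n = 200L)
  plab <- structure(list(barcodes = rownames(pl$latent$values),
                         phenotype = "disease",
                         values = as.numeric(pl$class),
                         covered = rep(TRUE, 200L),
                         n_repeats_averaged = 1L),
                    class = "ProbabilisticLabels")
  fit <- train_fixed(pl$latent, plab, classifier_config(epochs = 6L))
  # predict on training latent reproduces training scores
  ps <- predict_scores(pl$latent, fit$model)
  expect_identical(ps$scores, fit$scores$scores)
  # save/load/predict bit-identical
  d <- tempfile("clf")
  save_model(fit$model, d)
  m2 <- load_model(d)
  expect_identical(predict_scores(pl$latent, m2)$scores, ps$scores)
  unlink(d, recursive = TRUE)
  # dimension mismatch names the expected input size
  bad <- latent_matrix(matrix(rnorm(40), 10, 4))
  expect_error(predict_scores(bad, fit$model), "dimension")
})

test_that("multiple phenotypes train independent models", {
  pl <- planted_latent(n = 200L)
  mk <- function(v, ph) structure(
    list(barcodes = rownames(pl$latent$values), phenotype = ph,
         values = v, covered = rep(TRUE, 200L), n_repeats_averaged = 1L),
    class = "ProbabilisticLabels")
  set.seed(2)
  plabs <- list(disease = mk(as.numeric(pl$class), "disease"),
                sex = mk(runif(200), "sex"))
  fit <- train_fixed(pl$latent, plabs, classifier_config(epochs = 4L))
  expect_equal(fit$model$phenotypes, c("disease", "sex"))
  expect_equal(colnames(fit$scores$scores), c("disease", "sex"))
})
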