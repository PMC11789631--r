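# Shared fixtures, built once per test session.  Small cohorts keep the
# suite fast; the acceptance tests use the default-size fixtures.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

small_cohort <- function(which = "mixed") {
  memo(paste0("cohort_", which), fixture_cohort(which, size = "small"))
}

# QC'd + normalized + encoded small cohort with aligned labels/truth
small_pipeline_inputs <- function(which = "mixed") {
  memo(paste0("pipe_", which), {
    co <- small_cohort(which)
    cm <- qc_filter(co$counts)
    norm <- normalize_counts(cm)
    truth <- co$truth[match(cm$barcodes, co$truth$barcode), ]
    labels <- co$labels[cm$barcodes, , drop = FALSE]
    class(labels) <- c("PhenotypeLabels", "data.frame")
    fit <- train_autoencoder(
      norm, ae_config(n_hidden_layers = 1L, nodes_per_layer = 200L,
                      latent_dim = 100L, epochs = 5L, seed = 5L))
    list(counts = cm, norm = norm, truth = truth, labels = labels,
         model = fit$model, latent = fit$latent)
  })
}

# hand-made latent with a planted, perfectly class-separating dimension
planted_latent <- function(n = 400L, d = 8L, seed = 42L) {
  set.seed(seed)
  cls <- rep(0:1, each = n / 2)
  v <- matrix(rnorm(n * d, 0, 1), n, d)
  v[, 1L] <- ifelse(cls == 1, 2, -2) + rnorm(n, 0, 0.3)
  rownames(v) <- sprintf("c%04d", seq_len(n))
  list(latent = latent_matrix(v),
       labels = phenotype_labels(data.frame(disease = cls), rownames(v)),
       class = cls)
}

random_count_matrix <- function(n_genes, n_cells, density = 0.2,
                                max_count = 50L) {
  k <- max(1L, round(n_genes * n_cells * density))
  i <- sample.int(n_genes, k, replace = TRUE)
  j <- sample.int(n_cells, k, replace = TRUE)
  x <- sample.int(max_count, k, replace = TRUE)
  m <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(n_genes, n_cells))
  count_matrix(m, sprintf("g%03d", seq_len(n_genes)),
               sprintf("bc%04d", seq_len(n_cells)))
}
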