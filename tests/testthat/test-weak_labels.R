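test_that("F1 with abstentions matches brute-force confusion counts", {
  # closed-form spot check: TP=3 FP=1 FN=1 -> 6/8
  expect_equal(f1_score(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 1, 0)), 0.75)
  # perfect prediction
  expect_equal(f1_score(c(1, 0, 1), c(1, 0, 1)), 1)
  # degenerate: no positives anywhere
  expect_equal(f1_score(c(0, 0), c(0, 0)), 0)
  expect_error(f1_score(c(1, 0), c(1, 0, 1)), "length")

  set.seed(5)
  for (i in 1:500) {
    n <- sample(3:40, 1)
    pred <- sample(c(0, 1, NA), n, replace = TRUE)
    truth <- sample(0:1, n, replace = TRUE)
    ok <- !is.na(pred)
    tp <- sum(ok & pred == 1 & truth == 1)
    fp <- sum(ok & pred == 1 & truth == 0)
    fn <- sum(ok & pred == 0 & truth == 1)
    want <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_identical(f1_score(pred, truth), want)
  }
})

test_that("Jaccard diversity matches set arithmetic on random bitmasks", {
  expect_equal(jaccard_diversity(c(TRUE, FALSE), NULL), 1)
  expect_equal(jaccard_diversity(c(TRUE, TRUE), c(TRUE, TRUE)), 0)
  expect_warning(d0 <- jaccard_diversity(c(FALSE, FALSE), c(FALSE, FALSE)),
                 "empty")
  expect_equal(d0, 1)
  set.seed(6)
  for (i in 1:500) {
    n <- sample(2:60, 1)
    a <- runif(n) < 0.4
    b <- runif(n) < 0.4
    want <- if (sum(a | b) == 0) 1 else 1 - sum(a & b) / sum(a | b)
    got <- if (sum(a | b) == 0) {
      suppressWarnings(jaccard_diversity(a, b))
    } else jaccard_diversity(a, b)
    expect_equal(got, want)
  }
})

test_that("candidate generation is seeded, sized, and finds separable rules", {
  pl <- planted_latent()
  dev_idx <- c(1:50, 201:250)  # both classes represented
  dev <- pl$latent$values[dev_idx, ]
  y <- pl$class[dev_idx]
  cand <- generate_candidates(dev, y, n_candidates = 12L, seed = 3L)
  expect_length(cand, 12L)
  cand2 <- generate_candidates(dev, y, n_candidates = 12L, seed = 3L)
  expect_equal(lapply(cand, `[[`, "features"),
               lapply(cand2, `[[`, "features"))
  expect_identical(vapply(cand, `[[`, numeric(1), "dev_f1"),
                   vapply(cand2, `[[`, numeric(1), "dev_f1"))
  # dimension 1 linearly separates the classes: some candidate is perfect
  expect_gte(max(vapply(cand, `[[`, numeric(1), "dev_f1")), 0.99)
  expect_error(generate_candidates(dev, rep(1, length(y)), 5L, 1L),
               "single class")
})

test_that("ensemble recovers a planted class signal", {
  pl <- planted_latent(n = 800L)
  fit <- fit_ensemble(pl$latent, pl$labels, "disease", n_iter = 15L,
                      seed = 11L)
  expect_gt(length(fit$ensemble$members), 0L)
  # selection bookkeeping: one score row per retained member
  expect_equal(nrow(fit$ensemble$scores), length(fit$ensemble$members))
  expect_true(all(fit$ensemble$scores$combined >= 0 &
                    fit$ensemble$scores$combined <= 1))
  # labels on the 90% split: thresholding recovers the planted classes
  truth <- pl$class[match(fit$plabels$barcodes,
                          rownames(pl$latent$values))]
  expect_gte(mean((fit$plabels$values >= 0.5) == truth), 0.9)
  expect_true(all(fit$plabels$values >= 0 & fit$plabels$values <= 1))
})

test_that("pure-noise latent yields uninformative labels", {
  set.seed(8)
  n <- 300L
  v <- matrix(rnorm(n * 6), n, 6)
  rownames(v) <- sprintf("c%03d", 1:n)
  cls <- sample(0:1, n, replace = TRUE)  # labels independent of features
  lab <- phenotype_labels(data.frame(disease = cls), rownames(v))
  pl <- repeat_and_average(latent_matrix(v), lab, "disease",
                          n_repeats = 4L, seed = 2L)
  expect_lt(mean(abs(pl$values - 0.5)), 0.15)
  # permutation check: observed label-class correlation is not extreme
  obs <- abs(cor(pl$values, cls))
  perm <- replicate(200, abs(cor(pl$values, sample(cls))))
  expect_gt(mean(perm >= obs), 0.01)
})

test_that("repeat averaging stays in [0,1] and matches a single run", {
  pl <- planted_latent(n = 200L)
  one <- repeat_and_average(pl$latent, pl$labels, "disease",
                           n_repeats = 1L, seed = 5L, n_iter = 8L)
  expect_true(all(one$values >= 0 & one$values <= 1))
  set.seed(5L)
  sd1 <- sample.int(.Machine$integer.max - 1L, 1L)
  single <- fit_ensemble(pl$latent, pl$labels, "disease", seed = sd1,
                         n_iter = 8L)
  idx <- match(single$plabels$barcodes, one$barcodes)
  expect_equal(one$values[idx], single$plabels$values)
})

test_that("variance reduction: averaging repeats helps more often than not", {
  # noisy planted signal so single repeats are imperfect
  set.seed(13)
  n <- 500L; d <- 8L
  cls <- rep(0:1, each = n / 2)
  v <- matrix(rnorm(n * d), n, d)
  v[, 1] <- ifelse(cls == 1, 2, -2) + rnorm(n, 0, 1.5)
  rownames(v) <- sprintf("c%04d", seq_len(n))
  pl <- list(latent = latent_matrix(v),
             labels = phenotype_labels(data.frame(disease = cls),
                                       rownames(v)),
             class = cls)
  wins <- 0L
  for (s in 1:5) {
    avg <- repeat_and_average(pl$latent, pl$labels, "disease",
                             n_repeats = 4L, seed = 100L + s, n_iter = 6L)
    one <- repeat_and_average(pl$latent, pl$labels, "disease",
                             n_repeats = 1L, seed = 100L + s, n_iter = 6L)
    c_avg <- cor(avg$values, pl$class)
    c_one <- cor(one$values, pl$class)
    wins <- wins + (c_avg >= c_one - 1e-8)
  }
  expect_gte(wins, 3L)
})

test_that("rebalancing reaches the target minority fraction", {
  pl <- planted_latent(n = 400L)
  # skew: keep 20 positives -> 5% minority
  idx <- c(which(pl$class == 0), which(pl$class == 1)[1:20])
  lv <- pl$latent$values[idx, ]
  lab <- pl$labels[idx, , drop = FALSE]
  class(lab) <- c("PhenotypeLabels", "data.frame")
  lat <- latent_matrix(lv)

  un <- rebalance(lat, lab, "disease", "undersample",
                  target_minority_frac = 0.2, seed = 1L)
  frac <- mean(un$labels$disease)
  expect_equal(sum(un$labels$disease), 20L)          # minority kept whole
  expect_equal(nrow(un$latent$values), 20L + 80L)    # closed-form majority
  expect_gte(frac, 0.2 - 1 / nrow(un$latent$values))

  ov <- rebalance(lat, lab, "disease", "oversample",
                  target_minority_frac = 0.2, seed = 1L)
  expect_equal(sum(ov$labels$disease), 50L)          # ceil(200*0.2/0.8)
  expect_gte(mean(ov$labels$disease), 0.2 - 1 / nrow(ov$latent$values))
  expect_false(anyDuplicated(rownames(ov$latent$values)) > 0)

  # balanced input returned unchanged
  bal <- rebalance(pl$latent, pl$labels, "disease", "undersample")
  expect_identical(bal$latent$values, pl$latent$values)

  only1 <- pl$labels[pl$class == 1, , drop = FALSE]
  class(only1) <- c("PhenotypeLabels", "data.frame")
  expect_error(rebalance(latent_matrix(pl$latent$values[pl$class == 1, ]),
                         only1, "disease", "undersample"), "both classes")
})
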