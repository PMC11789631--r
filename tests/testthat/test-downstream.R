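mk_scores <- function(s, phenotype = "disease") {
  m <- matrix(s, ncol = 1, dimnames = list(sprintf("c%04d", seq_along(s)),
                                           phenotype))
  scProgress:::score_matrix(m)
}

test_that("group assignment follows the right-closed threshold convention", {
  sc <- mk_scores(c(0.5, 0.6))
  g <- assign_groups(sc, "disease", 0.55, c("low", "high"))
  expect_equal(as.character(g$group), c("low", "high"))

  # boundary: score exactly at the threshold goes low
  sc2 <- mk_scores(rep(0.5, 4))
  g2 <- assign_groups(sc2, "disease", 0.5, c("low", "high"))
  expect_true(all(g2$group == "low"))

  expect_error(assign_groups(sc, "disease", c(0.6, 0.4)), "ascending")
  expect_error(assign_groups(sc, "disease", c(0, 0.5)), "thresholds")
  expect_error(assign_groups(sc, "age", 0.5), "age")
})

test_that("group counts match brute-force binning on random inputs", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    s <- runif(n)
    k <- sample(1:4, 1)
    th <- sort(runif(k, 0.05, 0.95))
    while (any(diff(th) == 0)) th <- sort(runif(k, 0.05, 0.95))
    g <- assign_groups(mk_scores(s), "disease", th)
    # brute force: group index = 1 + number of thresholds strictly below s
    want <- vapply(s, function(x) 1L + sum(x > th), integer(1))
    expect_equal(as.integer(g$group), want)
    expect_equal(nrow(g), n)  # partition: every cell in exactly one group
  }
})

test_that("score-correlated genes recover constructed and planted signals", {
  pin <- small_pipeline_inputs("mixed")
  norm <- pin$norm
  n <- length(norm$barcodes)
  # gene constructed to equal the score exactly -> r = 1
  s <- runif(n)
  v2 <- norm$values
  v2[1, ] <- s           # overwrite gene 1 with the score itself
  v2[2, ] <- 0.3         # constant gene
  norm2 <- norm; norm2$values <- v2
  sc <- mk_scores(s)
  sc$scores <- matrix(s, ncol = 1,
                      dimnames = list(norm$barcodes, "disease"))
  sc$barcodes <- norm$barcodes
  res <- correlated_genes(norm2, sc, "disease")
  expect_true(norm$feature_ids[1] %in% res$positive)
  expect_true(norm$feature_ids[2] %in% res$flagged_constant)
  expect_false(norm$feature_ids[2] %in% res$positive)
  expect_equal(unname(res$r[1]), 1)
})

test_that("score-correlated genes need aligned cells", {
  pin <- small_pipeline_inputs("mixed")
  s <- mk_scores(runif(10))
  expect_error(correlated_genes(pin$norm, s, "disease"), "aligned")
})

test_that("differential expression: t statistics match stats::t.test", {
  pin <- small_pipeline_inputs("mixed")
  norm <- pin$norm
  n <- length(norm$barcodes)
  grp <- data.frame(barcode = norm$barcodes,
                    group = factor(rep(c("a", "b"), length.out = n)),
                    score = NA)
  class(grp) <- c("GroupAssignment", "data.frame")
  de <- differential_expression(norm, grp, "a", "b")
  all_tab <- attr(de, "all")
  ia <- which(grp$group == "a"); ib <- which(grp$group == "b")
  for (g in sample(nrow(all_tab), 12)) {
    tt <- t.test(norm$cpk[g, ia], norm$cpk[g, ib], var.equal = TRUE)
    expect_equal(all_tab$t[g], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(all_tab$p[g], tt$p.value, tolerance = 1e-8)
  }
  # reported set satisfies both criteria
  expect_true(all(abs(all_tab$log2_fc[match(de$gene, all_tab$gene)]) >
                    log2(1.25) - 1e-12))
  expect_true(all(de$p < 0.05))
})

test_that("identical groups report no genes; planted fold changes are found", {
  pin <- small_pipeline_inputs("mixed")
  norm <- pin$norm
  # duplicated cells in both groups: exact null
  nm <- scProgress:::.subset_norm(norm, rep(1:60, 2))
  colnames(nm$values) <- nm$barcodes <- sprintf("d%03d", 1:120)
  colnames(nm$cpk) <- nm$barcodes
  grp <- data.frame(barcode = nm$barcodes,
                    group = factor(rep(c("a", "b"), each = 60)), score = NA)
  class(grp) <- c("GroupAssignment", "data.frame")
  expect_equal(nrow(differential_expression(nm, grp, "a", "b")), 0L)

  # planted 2-fold genes at n = 100/group, NB-like noise
  set.seed(10)
  G <- 300L
  base <- exp(rnorm(G, 3, 0.4))
  up <- 1:30
  m1 <- matrix(rnbinom(G * 100, mu = base, size = 5), G, 100)
  mu2 <- base; mu2[up] <- mu2[up] * 2
  m2 <- matrix(rnbinom(G * 100, mu = mu2, size = 5), G, 100)
  cpk <- cbind(m1, m2)
  ids <- sprintf("g%03d", 1:G)
  bcs <- sprintf("c%03d", 1:200)
  dimnames(cpk) <- list(ids, bcs)
  nn <- structure(list(values = cpk, cpk = cpk, feature_ids = ids,
                       barcodes = bcs, scaling_params = NULL),
                  class = "NormalizedMatrix")
  grp2 <- data.frame(barcode = bcs,
                     group = factor(rep(c("ctl", "up"), each = 100)),
                     score = NA)
  class(grp2) <- c("GroupAssignment", "data.frame")
  de <- differential_expression(nn, grp2, "up", "ctl")
  hit <- intersect(de$gene[de$direction == "up"], ids[up])
  expect_gte(length(hit) / length(up), 0.9)

  expect_error(differential_expression(nn, grp2[1:101, ], "up", "ctl"),
               "at least 2")
})
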