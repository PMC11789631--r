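# Synthetic single-cell cohort generator with known per-cell ground truth.
#
# The generative model is deliberately simple: each cell carries a latent
# disease severity s in [0,1] drawn from its donor class's Beta mixture
# (patients default to a bimodal progressed/early mixture, mirroring the
# within-patient heterogeneity the scoring method is built for; controls sit
# near 0).  A subset of genes loads log-linearly on severity,
# mu_g(s) = base_g * exp(beta_g * s), with beta spanning +/- effect_size.
# Sex is donor-uniform with marker genes switched on/off; age is a graded
# donor-level covariate with its own log-linear gene loadings.  Counts are
# negative binomial (var = mu + phi * mu^2) with lognormal cell library
# sizes and per-donor random log-mean shifts.  Binary labels are derived
# from donor metadata, optionally with donor-level label noise.

#' Specification of a synthetic cohort
#'
#' @param n_donors_per_class Donors per class (patients and controls each).
#' @param n_cells_per_donor Cells per donor.
#' @param n_genes Total genes (including marker and mitochondrial genes).
#' @param n_severity_genes Genes whose mean loads on severity.
#' @param severity_mixture Per-class Beta-mixture of cell severities: a list
#'   with elements `patient` and `control`, each
#'   `list(weights, shape1, shape2)` (vectors, one entry per component) and
#'   optionally `values` for point-mass components (overrides the shapes).
#'   Default: patients 60% Beta(5,2) "progressed" + 40% Beta(2,8) "early";
#'   controls Beta(1.5,12).
#' @param effect_size Maximum absolute log-fold loading of severity (and
#'   age) genes; 0 switches the signal off.
#' @param nb_dispersion NB overdispersion phi, `var = mu + phi * mu^2`.
#' @param mito_frac_mean Expected mitochondrial read fraction.
#' @param donor_effect_sd SD of per-donor per-gene log-mean shifts.
#' @param label_noise Fraction of donors whose disease label is flipped.
#' @param n_sex_genes,n_age_genes Marker/loaded gene counts.
#' @param mean_library_size Mean cell library size (lognormal).
#' @param seed Sampling seed: donors, cell severities, library sizes and
#'   counts.  Two cohorts differing only in `seed` are independent cohorts
#'   of the same disease.
#' @param biology_seed Seed for the gene-level architecture (which genes
#'   load on severity/age/sex, their effect sizes, base expression, donor
#'   factor directions).  Fixed by default so that cohorts share a feature
#'   space and transfer between them is meaningful.
#' @return A `CohortSpec` list.
#' @export
cohort_spec <- function(n_donors_per_class = 4L, n_cells_per_donor = 150L,
                        n_genes = 600L, n_severity_genes = 80L,
                        severity_mixture = list(
                          patient = list(weights = c(0.6, 0.4),
                                         shape1 = c(5, 2),
                                         shape2 = c(2, 8)),
                          control = list(weights = 1,
                                         shape1 = 1.5, shape2 = 12)),
                        effect_size = 2, nb_dispersion = 0.3,
                        mito_frac_mean = 0.02, donor_effect_sd = 0.1,
                        label_noise = 0, n_sex_genes = 10L,
                        n_age_genes = 40L, mean_library_size = 3000,
                        seed = 1L, biology_seed = 20L) {
  stopifnot(n_donors_per_class >= 1L, n_cells_per_donor >= 1L,
            n_genes >= 10L, n_severity_genes >= 0L,
            effect_size >= 0, nb_dispersion >= 0,
            label_noise >= 0, label_noise <= 1)
  if (n_severity_genes + n_sex_genes + n_age_genes + 5L > n_genes)
    stop("n_severity_genes + marker genes exceed n_genes", call. = FALSE)
  for (cls in c("patient", "control")) {
    mx <- severity_mixture[[cls]]
    if (abs(sum(mx$weights) - 1) > 1e-8)
      stop("severity mixture weights for ", cls, " must sum to 1",
           call. = FALSE)
  }
  structure(as.list(environment()), class = "CohortSpec")
}

.draw_severity <- function(mx, n) {
  comp <- sample.int(length(mx$weights), n, replace = TRUE,
                     prob = mx$weights)
  s <- numeric(n)
  for (j in seq_along(mx$weights)) {
    k <- sum(comp == j)
    if (k == 0L) next
    s[comp == j] <- if (!is.null(mx$values))
      rep(mx$values[j], k)
    else stats::rbeta(k, mx$shape1[j], mx$shape2[j])
  }
  s
}

#' Simulate a cohort with known ground truth
#'
#' @param spec A [cohort_spec()].
#' @return List with `counts` (a `CountMatrix`), `labels` (a
#'   `PhenotypeLabels` with columns disease, age, sex) and `truth` (a
#'   data.frame with per-cell barcode, donor, class, severity, age value and
#'   sex; attributes `"severity_genes"`, `"age_genes"`, `"sex_genes"` list
#'   the loaded gene ids).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  G <- spec$n_genes
  set.seed(spec$biology_seed)  # gene-level architecture (shared biology)
  n_mito <- 5L
  n_donors <- 2L * spec$n_donors_per_class
  n_cells <- n_donors * spec$n_cells_per_donor

  gene_ids <- sprintf("G%04d", seq_len(G))
  symbols <- gene_ids
  # disjoint special gene sets
  pool <- sample(G - n_mito)  # mito genes are the last n_mito
  sev_g <- sort(pool[seq_len(spec$n_severity_genes)])
  pool <- pool[-seq_len(spec$n_severity_genes)]
  sex_g <- sort(pool[seq_len(spec$n_sex_genes)])
  pool <- pool[-seq_len(spec$n_sex_genes)]
  age_g <- sort(pool[seq_len(spec$n_age_genes)])
  mito_g <- (G - n_mito + 1L):G
  symbols[mito_g] <- paste0("MT-", seq_len(n_mito))

  base <- exp(stats::rnorm(G, 0, 1))
  beta_sev <- numeric(G)
  if (spec$n_severity_genes > 0L)
    beta_sev[sev_g] <- seq(-spec$effect_size, spec$effect_size,
                           length.out = spec$n_severity_genes)
  beta_age <- numeric(G)
  beta_age[age_g] <- seq(-spec$effect_size, spec$effect_size,
                         length.out = spec$n_age_genes)
  gamma_sex <- numeric(G)
  gamma_sex[sex_g] <- 2  # on/off markers

  # Donor effects are low-rank: a few shared expression programs with
  # donor-specific scores (library chemistry, composition), not an
  # independent per-gene fingerprint — iid per-gene shifts would make donor
  # identity, rather than cell state, the most learnable class signal.
  # The factor directions are part of the shared biology.
  q <- 3L
  donor_load <- matrix(stats::rnorm(G * q), G, q)

  set.seed(spec$seed)  # cohort sampling: donors, cells, counts

  # donors: class, sex alternating, age graded across donors within class
  donor_class <- rep(c(1L, 0L), each = spec$n_donors_per_class)
  donor_sex <- rep_len(c(0L, 1L), n_donors)
  donor_age <- stats::ave(seq_len(n_donors), donor_class,
                          FUN = function(i) seq(0.1, 0.9,
                                                length.out = length(i)))
  donor_label <- donor_class
  if (spec$label_noise > 0) {
    flip <- stats::runif(n_donors) < spec$label_noise
    donor_label[flip] <- 1L - donor_label[flip]
  }
  donor_fac <- matrix(stats::rnorm(q * n_donors), q, n_donors)
  donor_shift <- spec$donor_effect_sd / sqrt(q) * donor_load %*% donor_fac

  counts <- matrix(0L, G, n_cells)
  truth <- data.frame(barcode = sprintf("cell%05d", seq_len(n_cells)),
                      donor = NA_character_, class = NA_integer_,
                      severity = NA_real_, age = NA_real_,
                      sex = NA_integer_, disease_label = NA_integer_)
  size <- if (spec$nb_dispersion > 0) 1 / spec$nb_dispersion else Inf
  for (d in seq_len(n_donors)) {
    idx <- (d - 1L) * spec$n_cells_per_donor + seq_len(spec$n_cells_per_donor)
    mx <- spec$severity_mixture[[if (donor_class[d] == 1L) "patient"
                                 else "control"]]
    s <- .draw_severity(mx, length(idx))
    lib <- stats::rlnorm(length(idx), log(spec$mean_library_size), 0.3)
    # G x cells matrix of relative weights
    w <- base * exp(outer(beta_sev, s) + donor_shift[, d] +
                      beta_age * donor_age[d] + gamma_sex * donor_sex[d])
    w[mito_g, ] <- 0
    wsum <- colSums(w)
    # mitochondrial genes get a fixed share of the transcriptome
    w[mito_g, ] <- spec$mito_frac_mean / (1 - spec$mito_frac_mean) /
      n_mito * matrix(wsum, n_mito, length(idx), byrow = TRUE)
    mu <- sweep(w, 2L, lib / colSums(w), "*")
    cnt <- if (is.finite(size))
      stats::rnbinom(length(mu), mu = as.numeric(mu), size = size)
    else stats::rpois(length(mu), as.numeric(mu))
    counts[, idx] <- matrix(cnt, G)
    truth$donor[idx] <- sprintf("donor%02d", d)
    truth$class[idx] <- donor_class[d]
    truth$severity[idx] <- s
    truth$age[idx] <- donor_age[d]
    truth$sex[idx] <- donor_sex[d]
    truth$disease_label[idx] <- donor_label[d]
  }

  cm <- count_matrix(methods::as(counts, "CsparseMatrix"),
                     gene_ids, truth$barcode, symbols)
  labels <- phenotype_labels(
    data.frame(disease = truth$disease_label,
               age = as.integer(truth$age > 0.5),
               sex = truth$sex),
    truth$barcode)
  attr(truth, "severity_genes") <- gene_ids[sev_g]
  attr(truth, "age_genes") <- gene_ids[age_g]
  attr(truth, "sex_genes") <- gene_ids[sex_g]
  list(counts = cm, labels = labels, truth = truth)
}

#' Canned fixture cohorts
#'
#' Three fixed-seed cohorts used throughout the tests and documentation:
#' `"separable"` (patient cells all at severity 1, controls at 0 — the
#' supervised limit), `"mixed"` (the default bimodal patient mixture), and
#' `"null"` (`effect_size = 0`: labels independent of expression).
#'
#' @param which One of `"separable"`, `"mixed"`, `"null"`.
#' @param size `"small"` (test-suite scale) or `"default"`.
#' @return The [simulate_cohort()] result.
#' @export
fixture_cohort <- function(which = c("mixed", "separable", "null"),
                           size = c("default", "small")) {
  which <- match.arg(which)
  size <- match.arg(size)
  donors <- if (size == "small") 3L else 5L
  cells <- if (size == "small") 80L else 200L
  genes <- if (size == "small") 300L else 800L
  sev <- if (size == "small") 50L else 100L
  spec <- switch(which,
    mixed = cohort_spec(n_donors_per_class = donors,
                        n_cells_per_donor = cells, n_genes = genes,
                        n_severity_genes = sev, seed = 101L),
    separable = cohort_spec(n_donors_per_class = donors,
                            n_cells_per_donor = cells, n_genes = genes,
                            n_severity_genes = sev,
                            severity_mixture = list(
                              patient = list(weights = 1, shape1 = NA,
                                             shape2 = NA, values = 1),
                              control = list(weights = 1, shape1 = NA,
                                             shape2 = NA, values = 0)),
                            seed = 102L),
    null = cohort_spec(n_donors_per_class = donors,
                       n_cells_per_donor = cells, n_genes = genes,
                       n_severity_genes = sev, effect_size = 0,
                       donor_effect_sd = 0, seed = 103L))
  simulate_cohort(spec)
}

#' Write the canned fixtures to disk
#'
#' Emits each cohort as a feature-barcode triplet plus `labels.csv` and
#' `truth.csv`, so every fixture round-trips through
#' [read_feature_barcode_matrix()].
#'
#' @param directory Output root; one subdirectory per fixture.
#' @param size Passed to [fixture_cohort()].
#' @return The directory, invisibly.
#' @export
default_fixtures <- function(directory = tempfile("fixtures"),
                             size = "default") {
  for (w in c("separable", "mixed", "null")) {
    co <- fixture_cohort(w, size = size)
    d <- file.path(directory, w)
    write_feature_barcode_matrix(co$counts, d)
    write_labels(co$labels, file.path(d, "labels.csv"))
    utils::write.csv(co$truth, file.path(d, "truth.csv"), row.names = FALSE)
  }
  invisible(directory)
}
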