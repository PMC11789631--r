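# Conversion of donor-level binary labels into per-cell probabilistic labels
# by iterative generation, scoring and pruning of shallow decision-tree
# heuristics (labeling functions).  A heuristic is a depth-limited rpart tree
# over a random subset of 1-3 latent dimensions; its confidence for a cell is
# the leaf probability of the positive class, and it abstains when that
# confidence is within `nu` of 0.5.  Candidates are scored on a random dev
# split by a weighted average of F1 and coverage diversity (1 - Jaccard
# similarity to the ensemble's coverage); the winner joins the ensemble and
# low-F1 members are pruned.  The remaining cells receive the mean confidence
# of the non-abstaining members.

.NU_GRID <- seq(0, 0.25, by = 0.05)

#' F1 score with abstentions
#'
#' `2 * TP / (2 * TP + FP + FN)` where abstaining predictions (`NA`) are
#' excluded from the confusion counts; defined as 0 when the denominator is
#' 0.
#'
#' @param predicted 0/1 vector with `NA` for abstentions.
#' @param truth 0/1 vector of the same length.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth lengths differ", call. = FALSE)
  use <- !is.na(predicted)
  p <- predicted[use]; t <- truth[use]
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

#' Coverage diversity of a heuristic against an ensemble
#'
#' One minus the Jaccard similarity between the heuristic's coverage set
#' (cells where it does not abstain) and the union of the ensemble members'
#' coverage sets.  An empty ensemble has diversity 1 (the first heuristic is
#' maximally novel).
#'
#' @param cov_h Logical coverage vector of the assessed heuristic.
#' @param cov_ensemble Logical coverage vector of the ensemble union, or
#'   `NULL` for an empty ensemble.
#' @return Diversity in `[0, 1]`.
#' @export
jaccard_diversity <- function(cov_h, cov_ensemble = NULL) {
  if (is.null(cov_ensemble)) return(1)
  stopifnot(length(cov_h) == length(cov_ensemble))
  uni <- sum(cov_h | cov_ensemble)
  if (uni == 0) {
    warning("both coverage sets empty; diversity defined as 1")
    return(1)
  }
  1 - sum(cov_h & cov_ensemble) / uni
}

# confidence of one heuristic on a latent matrix (plain matrix, cells x d)
.heuristic_confidence <- function(h, values) {
  df <- as.data.frame(values[, h$features, drop = FALSE])
  names(df) <- paste0("L", h$features)
  as.numeric(stats::predict(h$tree, newdata = df)[, "1"])
}

# 0/1/NA votes after applying the abstain margin
.heuristic_votes <- function(h, values) {
  conf <- .heuristic_confidence(h, values)
  v <- as.numeric(conf > 0.5)
  v[abs(conf - 0.5) <= h$nu] <- NA
  v
}

#' Generate candidate decision-tree heuristics on a dev split
#'
#' Each candidate is a depth-limited classification tree fit on a random
#' subset of 1-3 latent dimensions; its abstain margin is the smallest value
#' in \{0, 0.05, ..., 0.25\} maximizing non-abstaining F1 on the dev split.
#'
#' @param dev Numeric matrix of dev-split latent vectors (cells x dims).
#' @param dev_labels 0/1 vector for the dev split.
#' @param n_candidates Number of candidates.
#' @param seed RNG seed.
#' @param max_depth Tree depth cap (default 2).
#' @param max_features Maximum size of the random feature subset (default 3).
#' @param fit_frac Fraction of the dev split used to fit each tree; the
#'   remainder scores it.  Out-of-sample scoring stops overfit micro-leaves
#'   from earning perfect in-sample F1 and crowding out genuinely
#'   informative heuristics.
#' @return List of heuristic objects (`tree`, `features`, `nu`, `dev_f1`).
#' @export
generate_candidates <- function(dev, dev_labels, n_candidates = 10L,
                                seed = 1L, max_depth = 2L,
                                max_features = 3L, fit_frac = 0.5) {
  if (length(unique(dev_labels)) < 2L)
    stop("dev split contains a single class; rebalance or reseed",
         call. = FALSE)
  set.seed(seed)
  d <- ncol(dev)
  n <- nrow(dev)
  y <- factor(dev_labels, levels = c(0, 1))
  # fit/score halves, redrawn until both halves hold both classes
  repeat {
    fit_idx <- sort(sample.int(n, max(4L, round(fit_frac * n))))
    score_idx <- setdiff(seq_len(n), fit_idx)
    if (length(unique(dev_labels[fit_idx])) == 2L &&
        length(unique(dev_labels[score_idx])) == 2L) break
  }
  minb <- max(3L, round(0.05 * length(fit_idx)))
  lapply(seq_len(n_candidates), function(i) {
    k <- sample.int(min(max_features, d), 1L)
    feats <- sort(sample.int(d, k))
    df <- as.data.frame(dev[fit_idx, feats, drop = FALSE])
    names(df) <- paste0("L", feats)
    df$.y <- y[fit_idx]
    tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                         control = rpart::rpart.control(
                           maxdepth = max_depth, minsplit = 2L * minb,
                           minbucket = minb, cp = 0.001, xval = 0L))
    h <- list(tree = tree, features = feats, nu = 0)
    # abstain margin: smallest nu maximizing held-out, non-abstaining F1
    f1s <- vapply(.NU_GRID, function(nu) {
      h$nu <- nu
      f1_score(.heuristic_votes(h, dev[score_idx, , drop = FALSE]),
               dev_labels[score_idx])
    }, numeric(1))
    h$nu <- .NU_GRID[which.max(f1s)]
    h$dev_f1 <- max(f1s)
    h
  })
}

#' Fit a heuristic ensemble and compute probabilistic labels
#'
#' One round of the weak-labeling procedure: a random `dev_frac` of cells is
#' held out to develop heuristics; up to `n_iter` iterations each generate
#' `n_candidates` candidate trees, score them by
#' `w_f1 * F1 + (1 - w_f1) * diversity`, admit the best, and prune members
#' whose dev F1 has fallen below `prune_frac` times the best member's.
#' Iteration stops early when the admitted candidate neither adds dev
#' coverage nor improves on any retained member's F1.  The remaining cells
#' then receive the mean confidence of the retained collection; cells on
#' which every member abstains are flagged as uncovered.
#'
#' @param latent A `LatentMatrix`.
#' @param labels A `PhenotypeLabels` aligned to the latent rows.
#' @param phenotype Column of `labels` to convert.
#' @param dev_frac Fraction of cells in the dev split (default 0.1).
#' @param n_iter Maximum iterations (default 50).
#' @param n_candidates Candidates per iteration (default 15).
#' @param w_f1 Weight of F1 in the combined score (default 0.5).
#' @param prune_frac Relative F1 pruning threshold (default 0.5).
#' @param seed RNG seed.
#' @return List with `ensemble` (members, their scores and selection order,
#'   dev indices) and `plabels` (a `ProbabilisticLabels` for the non-dev
#'   cells with a `covered` flag).
#' @export
fit_ensemble <- function(latent, labels, phenotype, dev_frac = 0.1,
                         n_iter = 50L, n_candidates = 15L, w_f1 = 0.5,
                         prune_frac = 0.5, seed = 1L) {
  stopifnot(inherits(latent, "LatentMatrix"))
  if (!phenotype %in% names(labels))
    stop("phenotype '", phenotype, "' not in labels", call. = FALSE)
  values <- latent$values
  y <- labels[[phenotype]]
  stopifnot(nrow(values) == length(y))
  n <- nrow(values)

  set.seed(seed)
  dev_idx <- sort(sample.int(n, max(2L, round(dev_frac * n))))
  if (length(unique(y[dev_idx])) < 2L)
    stop("dev split contains a single class; rebalance() the data or use ",
         "another seed", call. = FALSE)
  dev <- values[dev_idx, , drop = FALSE]
  dev_y <- y[dev_idx]

  members <- list()
  scores <- data.frame(iteration = integer(0), f1 = numeric(0),
                       diversity = numeric(0), combined = numeric(0))
  cov_union <- NULL
  for (it in seq_len(n_iter)) {
    cand <- generate_candidates(dev, dev_y, n_candidates,
                                seed = seed + 7919L * it)
    covs <- lapply(cand, function(h) !is.na(.heuristic_votes(h, dev)))
    f1 <- vapply(cand, `[[`, numeric(1), "dev_f1")
    div <- vapply(covs, jaccard_diversity, numeric(1),
                  cov_ensemble = cov_union)
    comb <- w_f1 * f1 + (1 - w_f1) * div
    best <- which.max(comb)
    new_cov <- if (is.null(cov_union)) covs[[best]] else
      covs[[best]] | cov_union
    adds_coverage <- is.null(cov_union) || sum(new_cov) > sum(cov_union)
    # quality gain: the admitted candidate outperforms some retained member
    adds_quality <- length(members) == 0L ||
      f1[best] > min(vapply(members, `[[`, numeric(1), "dev_f1"))
    members[[length(members) + 1L]] <- cand[[best]]
    scores <- rbind(scores, data.frame(iteration = it, f1 = f1[best],
                                       diversity = div[best],
                                       combined = comb[best]))
    cov_union <- new_cov
    # prune members whose dev F1 trails the best member
    mf1 <- vapply(members, `[[`, numeric(1), "dev_f1")
    keep <- mf1 >= prune_frac * max(mf1)
    members <- members[keep]
    scores <- scores[keep, , drop = FALSE]
    if (!adds_coverage && !adds_quality && it > 1L) break
  }

  # Probabilistic labels: mean confidence over the full retained collection.
  # Abstention determines the coverage flag (and drove selection), but is
  # not used to gate the average: gating would hand the ambiguous region to
  # whichever low-skill members happen to vote there, and the F1 criterion
  # admits positively-biased voters, which inflates the labels of
  # healthy-like cells.
  rest_idx <- setdiff(seq_len(n), dev_idx)
  rest <- values[rest_idx, , drop = FALSE]
  conf <- vapply(members, .heuristic_confidence, numeric(nrow(rest)),
                 values = rest)
  conf <- matrix(conf, nrow = nrow(rest))
  nus <- vapply(members, `[[`, numeric(1), "nu")
  active <- sweep(abs(conf - 0.5), 2L, nus, ">")
  covered <- rowSums(active) > 0
  if (!any(covered))
    stop("no cell outside the dev split is covered by any heuristic; ",
         "increase dev_frac or n_iter", call. = FALSE)
  vals <- rowMeans(conf)

  bc <- rownames(values) %||% as.character(seq_len(n))
  ensemble <- structure(list(members = members, scores = scores,
                             phenotype = phenotype, dev_indices = dev_idx),
                        class = "HeuristicEnsemble")
  plabels <- structure(list(barcodes = bc[rest_idx], phenotype = phenotype,
                            values = vals, covered = covered,
                            n_repeats_averaged = 1L),
                       class = "ProbabilisticLabels")
  list(ensemble = ensemble, plabels = plabels)
}

#' Repeat weak labeling with fresh dev splits and average
#'
#' Runs [fit_ensemble()] `n_repeats` times with independent random dev
#' splits and averages each cell's probabilistic label over the repeats in
#' which it was outside the dev split.  Cells on which every heuristic of
#' every repeat abstained are flagged (`covered = FALSE`); cells that fell
#' in every dev split keep their binary label as a fallback.
#'
#' @inheritParams fit_ensemble
#' @param n_repeats Number of repeats (default 10).
#' @param ... Passed on to [fit_ensemble()].
#' @return A `ProbabilisticLabels` covering every cell.
#' @export
repeat_and_average <- function(latent, labels, phenotype, n_repeats = 10L,
                               seed = 1L, ...) {
  stopifnot(n_repeats >= 1L)
  n <- nrow(latent$values)
  bc <- rownames(latent$values) %||% as.character(seq_len(n))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  sums <- numeric(n); cnts <- integer(n); covcnt <- integer(n)
  for (r in seq_len(n_repeats)) {
    fit <- fit_ensemble(latent, labels, phenotype, seed = rep_seeds[r], ...)
    idx <- match(fit$plabels$barcodes, bc)
    sums[idx] <- sums[idx] + fit$plabels$values
    cnts[idx] <- cnts[idx] + 1L
    covcnt[idx[fit$plabels$covered]] <- covcnt[idx[fit$plabels$covered]] + 1L
  }
  covered <- covcnt > 0L
  # a cell lands in a dev split (and is unlabeled) in ~dev_frac of repeats;
  # cells in every dev split keep their binary label as fallback
  vals <- ifelse(cnts > 0L, sums / pmax(cnts, 1L), labels[[phenotype]])
  structure(list(barcodes = bc, phenotype = phenotype, values = vals,
                 covered = covered, n_repeats_averaged = n_repeats),
            class = "ProbabilisticLabels")
}

#' @export
print.ProbabilisticLabels <- function(x, ...) {
  cat("ProbabilisticLabels for '", x$phenotype, "': ", length(x$values),
      " cells, ", sum(!x$covered), " uncovered (fallback), ",
      x$n_repeats_averaged, " repeat(s)\n", sep = "")
  invisible(x)
}

#' Rebalance a skewed cohort before weak labeling
#'
#' Probabilistic labels degrade when one class dominates; at least ~20%
#' minority-class cells are needed.  Undersampling removes majority cells at
#' random; oversampling duplicates minority cells at random (duplicates get
#' suffixed barcodes).
#'
#' @param latent A `LatentMatrix`.
#' @param labels A `PhenotypeLabels` aligned to it.
#' @param phenotype Phenotype defining the classes.
#' @param strategy `"undersample"` or `"oversample"`.
#' @param target_minority_frac Minimum minority fraction (default 0.2).
#' @param seed RNG seed.
#' @return List with rebalanced `latent` and `labels`; attribute
#'   `"source_barcodes"` maps rows back to original cells.
#' @export
rebalance <- function(latent, labels, phenotype,
                      strategy = c("undersample", "oversample"),
                      target_minority_frac = 0.2, seed = 1L) {
  strategy <- match.arg(strategy)
  y <- labels[[phenotype]]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to rebalance", call. = FALSE)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (n_min / (n_min + n_maj) >= target_minority_frac) {
    out <- list(latent = latent, labels = labels)
    attr(out, "source_barcodes") <- rownames(latent$values)
    return(out)
  }
  set.seed(seed)
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  if (strategy == "undersample") {
    n_keep <- floor(n_min * (1 - target_minority_frac) /
                      target_minority_frac)
    idx <- sort(c(min_idx, sample(maj_idx, n_keep)))
    src <- rownames(latent$values)[idx]
    new_bc <- src
  } else {
    n_need <- ceiling(n_maj * target_minority_frac /
                        (1 - target_minority_frac))
    extra <- sample(min_idx, n_need - n_min, replace = TRUE)
    idx <- c(seq_len(length(y)), extra)
    src <- rownames(latent$values)[idx]
    new_bc <- src
    dup <- seq_along(extra)
    new_bc[length(y) + dup] <- paste0(src[length(y) + dup], "_dup", dup)
  }
  lv <- latent$values[idx, , drop = FALSE]
  rownames(lv) <- new_bc
  lb <- labels[idx, , drop = FALSE]
  rownames(lb) <- new_bc
  class(lb) <- class(labels)
  out <- list(latent = latent_matrix(lv, provenance = latent$provenance),
              labels = lb)
  attr(out, "source_barcodes") <- src
  out
}
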