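# Score-based read-outs: threshold scores into progression groups, find
# score-correlated genes, and run fold-change/t-test differential expression
# between score-defined groups.

#' Assign cells to progression groups by score thresholds
#'
#' Cells fall into group `k` when their score lies in `(t[k-1], t[k]]`
#' (right-closed; a cell exactly at a threshold goes to the lower group, so
#' "score > t" defines the high side strictly).  `K` thresholds give `K + 1`
#' groups.
#'
#' @param scores A `ScoreMatrix`.
#' @param phenotype Phenotype column to threshold.
#' @param thresholds Strictly ascending values in (0, 1).
#' @param group_names Optional names, length `length(thresholds) + 1`
#'   (default `group1` ... low to high).
#' @return A `GroupAssignment`: data.frame with `barcode`, `group` (factor,
#'   levels low to high) and `score`; attribute `"thresholds"`.
#' @export
assign_groups <- function(scores, phenotype, thresholds,
                          group_names = NULL) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  if (!phenotype %in% scores$phenotypes)
    stop("phenotype '", phenotype, "' not in scores", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending", call. = FALSE)
  k <- length(thresholds)
  if (is.null(group_names)) group_names <- paste0("group", seq_len(k + 1L))
  stopifnot(length(group_names) == k + 1L)
  s <- scores$scores[, phenotype]
  g <- cut(s, breaks = c(-Inf, thresholds, Inf), labels = group_names,
           right = TRUE)
  out <- data.frame(barcode = scores$barcodes, group = g, score = s,
                    row.names = NULL)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("GroupAssignment", "data.frame")
  out
}

#' Genes correlated with a progression score
#'
#' Per-gene Pearson correlation between normalized expression and the score;
#' returns the genes with `r > r_min` (positive list) and `r < -r_min`
#' (negative list).  Zero-variance genes get `r = 0` and are flagged.  To
#' intersect across two datasets, call once per dataset and intersect the
#' lists.
#'
#' @param norm A `NormalizedMatrix`.
#' @param scores A `ScoreMatrix` on the same cells.
#' @param phenotype Score column to use.
#' @param r_min Correlation cutoff (default 0.1).
#' @return List with `positive`, `negative` (character vectors of gene ids),
#'   `r` (named vector of all correlations) and `flagged_constant`.
#' @export
correlated_genes <- function(norm, scores, phenotype, r_min = 0.1) {
  stopifnot(inherits(norm, "NormalizedMatrix"),
            inherits(scores, "ScoreMatrix"))
  if (!identical(norm$barcodes, scores$barcodes))
    stop("cells of the matrix and the scores are not aligned", call. = FALSE)
  s <- scores$scores[, phenotype]
  x <- norm$values
  sds <- apply(x, 1L, stats::sd)
  const <- sds == 0 | stats::sd(s) == 0
  r <- rep(0, nrow(x))
  names(r) <- norm$feature_ids
  if (any(!const))
    r[!const] <- as.numeric(stats::cor(t(x[!const, , drop = FALSE]), s))
  list(positive = names(r)[r > r_min & !const],
       negative = names(r)[r < -r_min & !const],
       r = r,
       flagged_constant = names(r)[const])
}

#' Differential expression between two score-defined groups
#'
#' Per-gene fold change of library-size-normalized mean expression
#' (`g1 / g2`, pseudocount `1e-9`) and a two-sided unpaired t-test (classic
#' equal-variance Student's by default; set `var_equal = FALSE` for Welch).
#' The reported set satisfies fold change > `fc_min` in either direction AND
#' raw `p < p_max` — no multiple-testing correction, matching the
#' fold-change-plus-t-test convention.
#'
#' @param norm A `NormalizedMatrix` (the pre-rescale `cpk` slot is used for
#'   fold changes; the t-test runs on the same scale).
#' @param groups A `GroupAssignment`.
#' @param g1,g2 Group labels to contrast (g1 = numerator).
#' @param fc_min Fold-change cutoff (default 1.25).
#' @param p_max p-value cutoff (default 0.05).
#' @param var_equal Classic Student's t-test (default) or Welch.
#' @return data.frame of the reported genes: `gene`, `log2_fc`, `t`, `p`,
#'   `direction` (`"up"` in g1 or `"down"`); attribute `"all"` holds the
#'   unfiltered table.
#' @export
differential_expression <- function(norm, groups, g1, g2, fc_min = 1.25,
                                    p_max = 0.05, var_equal = TRUE) {
  stopifnot(inherits(norm, "NormalizedMatrix"),
            inherits(groups, "GroupAssignment"))
  i1 <- which(groups$group == g1 & groups$barcode %in% norm$barcodes)
  i2 <- which(groups$group == g2 & groups$barcode %in% norm$barcodes)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("both groups need at least 2 cells (", g1, ": ", length(i1),
         ", ", g2, ": ", length(i2), ")", call. = FALSE)
  x <- norm$cpk
  c1 <- match(groups$barcode[i1], norm$barcodes)
  c2 <- match(groups$barcode[i2], norm$barcodes)
  x1 <- x[, c1, drop = FALSE]; x2 <- x[, c2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 1
  tstat[!is.finite(tstat)] <- 0

  eps <- 1e-9
  fc <- (m1 + eps) / (m2 + eps)
  all_tab <- data.frame(gene = norm$feature_ids,
                        log2_fc = log2(fc), t = tstat, p = p,
                        direction = ifelse(fc >= 1, "up", "down"),
                        row.names = NULL)
  hit <- (fc > fc_min | fc < 1 / fc_min) & p < p_max
  out <- all_tab[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_tab
  out
}
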