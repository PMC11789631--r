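#' Quality-control parameters
#'
#' Per-cell filters applied before normalization: detected-gene range, total
#' UMI range, and maximum fraction of reads from mitochondria-derived genes
#' (identified by a gene-symbol prefix; `"MT-"` for human GRCh38).
#'
#' @param min_genes,max_genes Detected-gene bounds (defaults 100 and 7000).
#' @param min_umi,max_umi Total-UMI bounds (defaults 500 and 20000).
#' @param max_mito_frac Maximum mitochondrial read fraction (default 0.05).
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes.
#' @return A `QCParams` list.
#' @export
qc_params <- function(min_genes = 100, max_genes = 7000,
                      min_umi = 500, max_umi = 20000,
                      max_mito_frac = 0.05, mito_prefix = "MT-") {
  stopifnot(min_genes < max_genes, min_umi < max_umi,
            max_mito_frac >= 0, max_mito_frac <= 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umi = min_umi, max_umi = max_umi,
                 max_mito_frac = max_mito_frac, mito_prefix = mito_prefix),
            class = "QCParams")
}

#' Filter cells on detected genes, total UMI and mitochondrial fraction
#'
#' Keeps exactly the cells satisfying all three criteria:
#' `min_genes <= detected genes <= max_genes`,
#' `min_umi <= total UMI <= max_umi`, and mitochondrial read fraction
#' `<= max_mito_frac`.  Genes are never removed.
#'
#' @param m A `CountMatrix`.
#' @param params A [qc_params()] object.
#' @return The filtered `CountMatrix`; attribute `"qc_report"` holds per-
#'   criterion removal counts and the survivor count.
#' @export
qc_filter <- function(m, params = qc_params()) {
  stopifnot(inherits(m, "CountMatrix"))
  counts <- m$counts
  n_genes <- Matrix::colSums(counts > 0)
  n_umi <- Matrix::colSums(counts)
  mito <- startsWith(m$feature_symbols, params$mito_prefix)
  mito_frac <- if (any(mito)) {
    as.numeric(Matrix::colSums(counts[mito, , drop = FALSE])) /
      pmax(n_umi, 1)
  } else rep(0, ncol(counts))

  ok_genes <- n_genes >= params$min_genes & n_genes <= params$max_genes
  ok_umi <- n_umi >= params$min_umi & n_umi <= params$max_umi
  ok_mito <- mito_frac <= params$max_mito_frac
  keep <- ok_genes & ok_umi & ok_mito
  if (!any(keep))
    stop("no cells remain after QC; relax the thresholds in qc_params()",
         call. = FALSE)

  out <- count_matrix(counts[, keep, drop = FALSE],
                      m$feature_ids, m$barcodes[keep], m$feature_symbols)
  attr(out, "qc_report") <- data.frame(
    criterion = c("gene_range", "umi_range", "mito_frac", "any", "kept"),
    n = c(sum(!ok_genes), sum(!ok_umi), sum(!ok_mito), sum(!keep), sum(keep))
  )
  out
}

#' Total-count normalize and rescale a count matrix
#'
#' Two steps: (1) each cell's counts are divided by its total UMI count and
#' multiplied by `scale_factor` (counts per 10k by default), then `log1p`-
#' transformed; (2) each gene is min-max rescaled to `[0, 1]` so the values
#' match the sigmoid output range of the autoencoder decoder.  Constant genes
#' (min = max) map to 0.  The per-gene scaling parameters are stored so the
#' identical transform can be replayed on a new dataset when predicting with
#' a pretrained model.
#'
#' @param m A `CountMatrix` (after [qc_filter()]).
#' @param scaling Optional stored scaling from a previous call (transfer
#'   mode): a list with `feature_ids`, `gene_min`, `gene_max`,
#'   `scale_factor`, `log1p`.  Genes in the stored set absent from `m` are
#'   filled with 0; extra genes in `m` are dropped with a warning.  Rescaled
#'   values are clipped to `[0, 1]`.
#' @param scale_factor Library-size target before `log1p` (default 1e4).
#' @param log1p Apply `log1p` after library-size scaling.
#' @return A `NormalizedMatrix`: list with `values` (dense genes x cells in
#'   `[0,1]`), `cpk` (the pre-rescale library-size-normalized matrix, used
#'   for fold changes), `feature_ids`, `barcodes` and `scaling_params`.
#' @export
normalize_counts <- function(m, scaling = NULL, scale_factor = 1e4,
                             log1p = TRUE) {
  stopifnot(inherits(m, "CountMatrix"))
  totals <- as.numeric(Matrix::colSums(m$counts))
  if (any(totals == 0))
    stop("cells with zero total UMI present; run qc_filter() first",
         call. = FALSE)

  if (!is.null(scaling)) {
    scale_factor <- scaling$scale_factor
    log1p <- scaling$log1p
  }
  cpk <- as.matrix(m$counts %*% Matrix::Diagonal(x = scale_factor / totals))
  dimnames(cpk) <- list(m$feature_ids, m$barcodes)
  x <- if (log1p) log1p(cpk) else cpk

  if (is.null(scaling)) {
    gmin <- apply(x, 1L, min)
    gmax <- apply(x, 1L, max)
    rng <- gmax - gmin
    vals <- (x - gmin) / ifelse(rng == 0, 1, rng)
    vals[rng == 0, ] <- 0
    scaling <- list(feature_ids = m$feature_ids, gene_min = gmin,
                    gene_max = gmax, scale_factor = scale_factor,
                    log1p = log1p)
  } else {
    # transfer mode: project onto the training feature space
    extra <- setdiff(m$feature_ids, scaling$feature_ids)
    if (length(extra))
      warning(length(extra),
              " genes absent from the training feature set were dropped")
    vals <- matrix(0, length(scaling$feature_ids), ncol(x),
                   dimnames = list(scaling$feature_ids, m$barcodes))
    common <- intersect(scaling$feature_ids, m$feature_ids)
    if (length(common) == 0L)
      stop("no overlap with the training feature set", call. = FALSE)
    idx <- match(common, scaling$feature_ids)
    rng <- scaling$gene_max[idx] - scaling$gene_min[idx]
    v <- (x[common, , drop = FALSE] - scaling$gene_min[idx]) /
      ifelse(rng == 0, 1, rng)
    v[rng == 0, ] <- 0
    vals[idx, ] <- pmin(pmax(v, 0), 1)
    cpk2 <- matrix(0, length(scaling$feature_ids), ncol(cpk),
                   dimnames = dimnames(vals))
    cpk2[idx, ] <- cpk[common, , drop = FALSE]
    cpk <- cpk2
  }

  out <- structure(list(values = vals, cpk = cpk,
                        feature_ids = rownames(vals), barcodes = m$barcodes,
                        scaling_params = scaling),
                   class = "NormalizedMatrix")
  if (!is.null(out$scaling_params) && !identical(m$feature_ids, scaling$feature_ids))
    out$transfer_overlap <-
      length(intersect(scaling$feature_ids, m$feature_ids)) /
      length(scaling$feature_ids)
  out
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "cells, values in [0,1]\n")
  invisible(x)
}
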