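# Dip-type unimodality test with Monte-Carlo calibration.
#
# The statistic is the smallest, over a grid of candidate modes m, of the
# sup-distance between the empirical CDF and the best mode-constrained
# unimodal CDF: the greatest convex minorant of the ECDF left of m glued to
# the least concave majorant right of m.  Small values mean the sample is
# well approximated by some unimodal distribution; bimodal samples force a
# large distance for every candidate mode.  The null distribution is
# obtained by recomputing the same statistic on Uniform(0,1) samples of the
# same size, which calibrates the test exactly for the statistic used.
# Null tables are cached per sample size within a session.

.dip_cache <- new.env(parent = emptyenv())

# sup-distance between the ECDF of sorted x and the glued GCM/LCM fit for
# one candidate mode index im
.dip_dev_one <- function(xs, Fs, im) {
  n <- length(xs)
  dev <- 0
  # greatest convex minorant on [1, im] of points (xs, Fs)
  if (im >= 2L) {
    hull <- c(1L)
    for (i in 2:im) {
      while (length(hull) >= 2L) {
        a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
        # drop b if it lies above segment a-i
        if ((Fs[b] - Fs[a]) * (xs[i] - xs[a]) >=
            (Fs[i] - Fs[a]) * (xs[b] - xs[a]))
          hull <- hull[-length(hull)]
        else break
      }
      hull <- c(hull, i)
    }
    fit <- stats::approx(xs[hull], Fs[hull], xout = xs[1:im],
                         ties = "ordered")$y
    # ECDF is a step function: deviation measured at the data points,
    # both against F_i and the left limit F_{i-1}
    dev <- max(dev, abs(Fs[1:im] - fit),
               abs(c(0, Fs[seq_len(im - 1L)]) - fit))
  }
  # least concave majorant on [im, n]
  if (im <= n - 1L) {
    hull <- c(im)
    for (i in (im + 1L):n) {
      while (length(hull) >= 2L) {
        a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
        if ((Fs[b] - Fs[a]) * (xs[i] - xs[a]) <=
            (Fs[i] - Fs[a]) * (xs[b] - xs[a]))
          hull <- hull[-length(hull)]
        else break
      }
      hull <- c(hull, i)
    }
    fit <- stats::approx(xs[hull], Fs[hull], xout = xs[im:n],
                         ties = "ordered")$y
    dev <- max(dev, abs(Fs[im:n] - fit),
               abs(c(Fs[im - ifelse(im > 1L, 1L, 0L)],
                     Fs[im:(n - 1L)]) - fit))
  }
  dev
}

#' Dip-type unimodality statistic
#'
#' @param x Numeric sample (ties are jittered deterministically by rank).
#' @param n_modes Size of the candidate-mode grid (quantile-spaced; all
#'   points when the sample is smaller).
#' @return The statistic (non-negative; larger = less unimodal).
#' @export
dip_statistic <- function(x, n_modes = 50L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) return(0)
  xs <- sort(x)
  # break ties so the ECDF support is strictly increasing
  if (any(duplicated(xs))) {
    span <- max(xs) - min(xs)
    if (span == 0) return(0)
    xs <- xs + seq(0, span * 1e-9, length.out = n)
  }
  Fs <- seq_len(n) / n
  cand <- if (n <= n_modes) seq_len(n) else
    unique(round(stats::quantile(seq_len(n), probs = seq(0, 1,
                                                         length.out = n_modes))))
  min(vapply(cand, function(im) .dip_dev_one(xs, Fs, im), numeric(1)))
}

#' Monte-Carlo dip test of unimodality
#'
#' Tests the null of unimodality against multimodality; the p-value is the
#' fraction of Uniform(0,1) samples of the same size whose statistic is at
#' least as large as the observed one (uniform is the least-favorable
#' unimodal null for dip-type statistics).
#'
#' @param x Numeric sample.
#' @param n_sim Null simulations (default 500).
#' @param seed Seed for the null simulation and any subsampling.
#' @param max_n Larger samples are subsampled to this size for speed.
#' @return List with `statistic`, `p_value`, `n`.
#' @export
dip_test <- function(x, n_sim = 500L, seed = 1L, max_n = 500L) {
  x <- x[is.finite(x)]
  set.seed(seed)
  if (length(x) > max_n) x <- sample(x, max_n)
  n <- length(x)
  stat <- dip_statistic(x)
  key <- paste(n, n_sim, seed, sep = "_")
  if (is.null(.dip_cache[[key]])) {
    .dip_cache[[key]] <- vapply(seq_len(n_sim), function(i)
      dip_statistic(stats::runif(n)), numeric(1))
  }
  null <- .dip_cache[[key]]
  list(statistic = stat,
       p_value = (1 + sum(null >= stat)) / (1 + n_sim),
       n = n)
}
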