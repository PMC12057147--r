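# Adjusted mutual information between binned affinities and binned scores.
#
# AMI = (MI - E[MI]) / (max(H(x), H(y)) - E[MI]), with E[MI] taken under the
# permutation (hypergeometric) model of random contingency tables with the
# observed margins. Natural logarithms throughout; the ratio is unit-free.

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

mi_table <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
    }
  }
  unname(mi)
}

# exact expected MI under the hypergeometric model of fixed margins
expected_mi <- function(a, b, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lgamma(ai + 1) + lgamma(bj + 1) +
          lgamma(n - ai + 1) + lgamma(n - bj + 1) -
          lgn - lgamma(nij + 1) - lgamma(ai - nij + 1) -
          lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
        emi <- emi + exp(lp) * (nij / n) * log(n * nij / (ai * bj))
      }
    }
  }
  emi
}

#' Adjusted mutual information of two binned variables
#'
#' Chance-corrected mutual information between two integer/factor bin
#' assignments. Identical partitions give 1; independent variables give
#' values near 0 (possibly slightly negative). When either variable
#' collapses into a single bin the measure is undefined and 0 is returned
#' with a warning.
#'
#' @param xb,yb Bin labels (factor, integer or character), same length.
#' @return AMI in (-1, 1\].
#' @export
ami_binned <- function(xb, yb) {
  keep <- !is.na(xb) & !is.na(yb)
  xb <- xb[keep]; yb <- yb[keep]
  n <- length(xb)
  if (n < 2L) stop("need at least 2 points after binning", call. = FALSE)
  tab <- table(xb, yb)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("a variable collapsed into a single bin; AMI undefined, returning 0")
    return(0)
  }
  hx <- entropy_counts(rowSums(tab))
  hy <- entropy_counts(colSums(tab))
  mi <- mi_table(tab)
  emi <- expected_mi(rowSums(tab), colSums(tab), n)
  denom <- max(hx, hy) - emi
  if (abs(denom) < 1e-12) {
    warning("degenerate AMI denominator; returning 0")
    return(0)
  }
  unname((mi - emi) / denom)
}

#' Affinity bin-edge presets
#'
#' Affinities are compared by order of magnitude, so the presets use full
#' and half decades (10^0.5 = 3.16-fold steps) over 0-100 micromolar.
#'
#' @return Named list of three numeric edge vectors.
#' @export
affinity_bin_presets <- function() {
  list(half_decades = c(0, 0.316, 1, 3.16, 10, 31.6, 100),
       decades = c(0, 1, 10, 100),
       offset_half_decades = c(0, 0.316, 3.16, 31.6, 100))
}

#' Bin continuous scores
#'
#' @param x Numeric scores.
#' @param method `"geometric"` (log-spaced edges between the observed range;
#'   values are shifted to be positive first if needed), `"linear"`
#'   (equal-width edges), or `"quantile"` (equal-count bins).
#' @param k Number of bins (default 6).
#' @param edges Optional explicit edges (overrides `method`); set these from
#'   the full dataset to keep sub-dataset binnings comparable.
#' @return Integer bin labels.
#' @export
bin_scores <- function(x, method = c("geometric", "linear", "quantile"),
                       k = 6L, edges = NULL) {
  method <- match.arg(method)
  if (is.null(edges)) {
    lo <- min(x); hi <- max(x)
    if (lo == hi) return(rep(1L, length(x)))
    edges <- switch(method,
      linear = seq(lo, hi, length.out = k + 1L),
      geometric = {
        shift <- if (lo <= 0) -lo + 1e-6 * (hi - lo) else 0
        exp(seq(log(lo + shift), log(hi + shift), length.out = k + 1L)) - shift
      },
      quantile = unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1L),
                                        names = FALSE))
    )
    edges[1L] <- min(edges[1L], lo); edges[length(edges)] <- max(edges[length(edges)], hi)
  }
  as.integer(cut(x, breaks = edges, include.lowest = TRUE))
}

#' AMI between scores and affinities under one binning strategy
#'
#' @param scores Numeric scoring-metric values.
#' @param kd Affinities in micromolar.
#' @param affinity_edges Bin edges for the affinities (see
#'   [affinity_bin_presets()]).
#' @param score_binning `"geometric"`, `"linear"` or `"quantile"`.
#' @param k_bins Number of score bins (default 6).
#' @param score_edges Optional fixed score edges (from the full dataset).
#' @return AMI value.
#' @export
ami <- function(scores, kd, affinity_edges = affinity_bin_presets()$decades,
                score_binning = "quantile", k_bins = 6L, score_edges = NULL) {
  stopifnot(is.numeric(scores), is.numeric(kd), length(scores) == length(kd))
  yb <- as.integer(cut(kd, breaks = affinity_edges, include.lowest = TRUE))
  xb <- bin_scores(scores, score_binning, k_bins, edges = score_edges)
  ami_binned(xb, yb)
}

#' Maximum AMI over the nine binning strategies
#'
#' Evaluates all combinations of the three affinity edge presets and the
#' three score binning methods and reports the maximum, the headline figure
#' for each metric/sub-dataset cell.
#'
#' @inheritParams ami
#' @return List with `max_ami`, `best_strategy` (affinity preset x score
#'   method) and the 3 x 3 `grid` of values.
#' @export
ami_grid <- function(scores, kd, k_bins = 6L) {
  presets <- affinity_bin_presets()
  methods <- c("geometric", "linear", "quantile")
  grid <- matrix(NA_real_, length(presets), length(methods),
                 dimnames = list(names(presets), methods))
  for (i in seq_along(presets)) {
    for (j in seq_along(methods)) {
      grid[i, j] <- suppressWarnings(
        ami(scores, kd, affinity_edges = presets[[i]],
            score_binning = methods[j], k_bins = k_bins))
    }
  }
  best <- which(grid == max(grid), arr.ind = TRUE)[1L, ]
  list(max_ami = max(grid),
       best_strategy = paste(rownames(grid)[best[1L]], colnames(grid)[best[2L]],
                             sep = " x "),
       grid = grid)
}
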