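# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and first-principles formulas only.

# AUROC by exhaustive enumeration over all cuts of a single parameter:
# staircase frontier (max TPR per FPR), conservative lower-staircase area
oracle_single_auroc <- function(values, labels, direction) {
  cuts <- c(-Inf, sort(unique(values)), Inf)
  pts <- matrix(NA_real_, length(cuts), 2)
  for (k in seq_along(cuts)) {
    pred <- if (direction == "gt") values > cuts[k] else values < cuts[k]
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_along(values)) {
      if (labels[i] == "binder") {
        if (pred[i]) tp <- tp + 1 else fn <- fn + 1
      } else {
        if (pred[i]) fp <- fp + 1 else tn <- tn + 1
      }
    }
    pts[k, ] <- c(fp / (fp + tn), tp / (tp + fn))
  }
  pts <- rbind(pts, c(0, 0), c(1, 1))
  # frontier: for each distinct fpr, max tpr; dominated points removed
  fprs <- sort(unique(pts[, 1]))
  frontier <- cbind(fprs, vapply(fprs, function(f) max(pts[pts[, 1] == f, 2]),
                                 numeric(1)))
  keep <- rep(TRUE, nrow(frontier))
  best <- -Inf
  for (i in seq_len(nrow(frontier))) {
    if (frontier[i, 2] < best) keep[i] <- FALSE else best <- frontier[i, 2]
  }
  frontier <- frontier[keep, , drop = FALSE]
  area <- 0
  for (i in seq_len(nrow(frontier) - 1)) {
    area <- area + (frontier[i + 1, 1] - frontier[i, 1]) * frontier[i, 2]
  }
  unname(area)
}

# mutual information of two label vectors, natural log, from the definition
oracle_mi <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (xv in unique(x)) {
    for (yv in unique(y)) {
      nij <- sum(x == xv & y == yv)
      if (nij > 0) {
        pij <- nij / n
        mi <- mi + pij * log(pij / ((sum(x == xv) / n) * (sum(y == yv) / n)))
      }
    }
  }
  mi
}

oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

# all permutations of 1..n (n small) by recursion
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# AMI with E[MI] as the exact average of MI over all n! label permutations
# (the permutation model the hypergeometric formula summarizes)
oracle_ami <- function(x, y) {
  perms <- all_perms(length(y))
  emi <- mean(vapply(perms, function(p) oracle_mi(x, y[p]), numeric(1)))
  (oracle_mi(x, y) - emi) / (max(oracle_entropy(x), oracle_entropy(y)) - emi)
}

# OLS by the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}
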