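# Composite-threshold binder classification and genetic-algorithm training.
#
# A threshold set carries one cut per score parameter; a vector is called a
# binder only when ALL ten strict inequalities hold (confidence and pLDDT
# above their cuts, every PAE below). The GA explores cut combinations,
# archives the (FPR, TPR) of every set it evaluates, and reports the Pareto
# frontier of the archive as its ROC. The archive is pre-seeded with every
# point of each parameter's exhaustive single-parameter ROC, so the
# composite frontier AUROC can never fall below the best single parameter.

#' Construct a composite threshold set
#'
#' @param cuts Named numeric vector with one cut per parameter in
#'   [score_vector_params()]. Directions are fixed by parameter semantics:
#'   confidence and pLDDT cuts are strict lower bounds (`>`), PAE cuts are
#'   strict upper bounds (`<`).
#' @param name Label for the set.
#' @return An object of class `threshold_set`: data.frame with columns
#'   `parameter`, `cut`, `direction`.
#' @export
threshold_set <- function(cuts, name = "custom") {
  params <- score_vector_params()
  if (!setequal(names(cuts), params)) {
    stop("cuts must name each of the ten score parameters exactly once",
         call. = FALSE)
  }
  cuts <- cuts[params]
  out <- data.frame(parameter = params, cut = as.numeric(cuts),
                    direction = param_direction(params),
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("threshold_set", "data.frame")
  out
}

#' Shipped exclusive (low false-positive) threshold set
#'
#' The published composite cut set tuned to minimize false positives
#' (reported rates on its training data: 5.5% false positive, 28.1% false
#' negative).
#' @return A [threshold_set()].
#' @export
thresholds_exclusive <- function() {
  threshold_set(c(conf_2c = 0.78, plddt_2c = 95.4, ltop_2c = 4.97,
                  ptol_2c = 9.03, dimer_2c = 0.922,
                  conf_1c = 0.88, plddt_1c = 34.8, ltop_1c = 8.14,
                  ptol_1c = 10.99, dimer_1c = 1.158),
                name = "exclusive")
}

#' Shipped inclusive (low false-negative) threshold set
#'
#' The published composite cut set tuned to minimize false negatives
#' (reported rates on its training data: 27.9% false positive, 7.5% false
#' negative).
#' @return A [threshold_set()].
#' @export
thresholds_inclusive <- function() {
  threshold_set(c(conf_2c = 0.62, plddt_2c = 69.4, ltop_2c = 4.80,
                  ptol_2c = 3.35, dimer_2c = 1.103,
                  conf_1c = 0.77, plddt_1c = 35.4, ltop_1c = 11.30,
                  ptol_1c = 13.73, dimer_1c = 1.249),
                name = "inclusive")
}

#' Write / read a threshold set as JSON
#'
#' @param thresholds A [threshold_set()].
#' @param path JSON file path.
#' @return `write_thresholds` returns the path invisibly; `read_thresholds`
#'   returns a [threshold_set()].
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(list(name = attr(thresholds, "name"),
                            cuts = as.list(stats::setNames(thresholds$cut,
                                                           thresholds$parameter))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(unlist(x$cuts), name = x$name)
}

# logical vector: does each row of X (n x 10 named matrix/data.frame) pass
# every strict inequality of the cut vector?
passes_all <- function(X, cuts, directions) {
  ok <- rep(TRUE, nrow(X))
  for (k in seq_along(cuts)) {
    v <- X[[k]]
    ok <- ok & if (directions[k] == "gt") v > cuts[k] else v < cuts[k]
  }
  ok
}

#' Classify score vectors against a threshold set
#'
#' A vector is a binder only if all ten conditions hold simultaneously
#' (strict inequalities); a value exactly at a cut fails that condition.
#'
#' @param vectors data.frame containing the ten columns of
#'   [score_vector_params()].
#' @param thresholds A [threshold_set()].
#' @return Character vector of `"binder"` / `"nonbinder"`.
#' @export
classify <- function(vectors, thresholds) {
  params <- thresholds$parameter
  missing <- setdiff(params, names(vectors))
  if (length(missing) > 0L) {
    stop(sprintf("score vectors lack columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(vectors[params])) stop("score vectors contain missing fields",
                                   call. = FALSE)
  ok <- passes_all(vectors[params], thresholds$cut, thresholds$direction)
  ifelse(ok, "binder", "nonbinder")
}

#' Error rates of a threshold set on labeled vectors
#'
#' @param vectors Labeled score vectors (column `label` with values
#'   `"binder"` / `"nonbinder"`).
#' @param thresholds A [threshold_set()].
#' @param label_col Name of the label column.
#' @return List with the confusion counts (`tp`, `fp`, `tn`, `fn`), `fpr`
#'   (FP / (FP + TN)), `fnr` (FN / (FN + TP)) and `accuracy`.
#' @export
evaluate_thresholds <- function(vectors, thresholds, label_col = "label") {
  if (nrow(vectors) == 0L) stop("no vectors to evaluate", call. = FALSE)
  lab <- vectors[[label_col]]
  if (is.null(lab) || !all(lab %in% c("binder", "nonbinder"))) {
    stop("every vector must be labeled binder or nonbinder", call. = FALSE)
  }
  pred <- classify(vectors, thresholds)
  tp <- sum(pred == "binder" & lab == "binder")
  fp <- sum(pred == "binder" & lab == "nonbinder")
  tn <- sum(pred == "nonbinder" & lab == "nonbinder")
  fn <- sum(pred == "nonbinder" & lab == "binder")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
       accuracy = (tp + tn) / nrow(vectors))
}

# --- ROC machinery ---------------------------------------------------------

# Pareto frontier (max TPR at each FPR) of a set of (fpr, tpr) points,
# with the trivial endpoints added; returned sorted by FPR.
pareto_frontier <- function(points) {
  pts <- rbind(points[, c("fpr", "tpr")], data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  pts <- pts[order(pts$fpr, -pts$tpr), , drop = FALSE]
  keep <- !duplicated(pts$fpr)
  pts <- pts[keep, , drop = FALSE]
  best <- cummax(pts$tpr)
  pts <- pts[pts$tpr >= best - 1e-15 & pts$tpr == best, , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

# conservative lower-staircase area under sorted frontier points
staircase_auc <- function(frontier) {
  x <- frontier$fpr; y <- frontier$tpr
  sum(diff(x) * y[-length(y)])
}

roc_curve <- function(points, provenance = "composite") {
  frontier <- pareto_frontier(points)
  structure(list(points = frontier, auroc = staircase_auc(frontier),
                 provenance = provenance),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %s: %d frontier points, AUROC %.4f\n",
              x$provenance, nrow(x$points), x$auroc))
  invisible(x)
}

# (fpr, tpr) of each candidate cut for one parameter; vectorized sweep
sweep_param <- function(values, labels, direction, cuts) {
  pos <- sort(values[labels == "binder"])
  neg <- sort(values[labels == "nonbinder"])
  np <- length(pos); nn <- length(neg)
  if (direction == "gt") {
    tpr <- (np - findInterval(cuts, pos)) / np  # count pos > cut
    fpr <- (nn - findInterval(cuts, neg)) / nn
  } else {
    # count x < cut: findInterval with left-open intervals counts x < cut
    tpr <- findInterval(cuts, pos, left.open = TRUE) / np
    fpr <- findInterval(cuts, neg, left.open = TRUE) / nn
  }
  data.frame(cut = cuts, fpr = fpr, tpr = tpr)
}

#' Exhaustive single-parameter ROC
#'
#' Sweeps every observed value of one score parameter as a strict cut (in
#' the direction implied by the parameter's semantics), collects the
#' (FPR, TPR) points and returns the staircase frontier with its
#' conservative (lower-staircase) AUROC.
#'
#' @param vectors Labeled score vectors.
#' @param parameter One of [score_vector_params()] (or any numeric column).
#' @param label_col Name of the label column.
#' @return A `roc_curve` object (fields `points`, `auroc`, `provenance`).
#' @export
single_param_roc <- function(vectors, parameter, label_col = "label") {
  lab <- vectors[[label_col]]
  if (length(unique(lab)) < 2L) {
    stop("need at least one binder and one nonbinder", call. = FALSE)
  }
  v <- vectors[[parameter]]
  cuts <- c(-Inf, sort(unique(v)), Inf)
  pts <- sweep_param(v, lab, param_direction(parameter), cuts)
  out <- roc_curve(pts, provenance = parameter)
  out$cuts <- pts
  out
}

# --- genetic-algorithm composite training ----------------------------------

#' Default GA configuration
#'
#' @param population Individuals per generation.
#' @param generations Number of generations.
#' @param mutation_scale Gaussian mutation standard deviation as a fraction
#'   of each parameter's observed range.
#' @param mutation_prob Per-gene mutation probability.
#' @param tournament Tournament size for selection.
#' @param elitism Fraction of the population carried over unchanged.
#' @param seed RNG seed for a reproducible run.
#' @return A list of GA settings.
#' @export
ga_config <- function(population = 200L, generations = 300L,
                      mutation_scale = 0.05, mutation_prob = 0.25,
                      tournament = 3L, elitism = 0.05, seed = NULL) {
  list(population = as.integer(population),
       generations = as.integer(generations),
       mutation_scale = mutation_scale, mutation_prob = mutation_prob,
       tournament = as.integer(tournament), elitism = elitism, seed = seed)
}

# evaluate a matrix of candidate cut rows; returns data.frame(fpr, tpr)
eval_candidates <- function(cut_matrix, X, lab, directions) {
  np <- sum(lab == "binder"); nn <- sum(lab == "nonbinder")
  is_pos <- lab == "binder"
  res <- apply(cut_matrix, 1L, function(cuts) {
    ok <- passes_all(X, cuts, directions)
    c(fpr = sum(ok & !is_pos) / nn, tpr = sum(ok & is_pos) / np)
  })
  as.data.frame(t(res))
}

#' Train a composite threshold set with a genetic algorithm
#'
#' Evolves ten-parameter cut sets; every set evaluated during the run
#' contributes one (FPR, TPR) point to an archive, and the reported ROC is
#' the Pareto frontier of that archive (plus the trivial endpoints), whose
#' conservative staircase area is the training AUROC -- a lower bound on the
#' attainable composite AUROC, since the ten-dimensional cut space cannot be
#' traversed exhaustively. The archive is seeded with every point of each
#' parameter's exhaustive single-parameter ROC (that parameter's cut
#' combined with fully permissive cuts elsewhere), so the composite frontier
#' dominates every single-parameter ROC by construction. Individual fitness
#' for selection is Youden's J (TPR - FPR).
#'
#' @param vectors Labeled score vectors (both classes present).
#' @param config A [ga_config()].
#' @param selection How the single reported best set is picked from the
#'   frontier: `"youden"` maximizes TPR - FPR, `"accuracy"` maximizes
#'   training accuracy.
#' @param label_col Name of the label column.
#' @return List with `thresholds` (a [threshold_set()]), `roc` (a
#'   `roc_curve`), `best_point` (its FPR/TPR) and `n_evaluated`.
#' @export
train_composite <- function(vectors, config = ga_config(),
                            selection = c("youden", "accuracy"),
                            label_col = "label") {
  selection <- match.arg(selection)
  lab <- vectors[[label_col]]
  if (length(unique(lab)) < 2L) {
    stop("need both classes to train", call. = FALSE)
  }
  params <- score_vector_params()
  X <- vectors[params]
  directions <- param_direction(params)
  np <- sum(lab == "binder"); nn <- sum(lab == "nonbinder")

  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(config$seed)
  }

  permissive <- ifelse(directions == "gt", -Inf, Inf)
  lo <- vapply(X, min, numeric(1)); hi <- vapply(X, max, numeric(1))
  rng <- pmax(hi - lo, .Machine$double.eps)

  # archive seeding: exhaustive per-parameter sweeps, each cut extended with
  # permissive values elsewhere (classification identical to the single
  # parameter alone, so no re-evaluation is needed)
  archive_pts <- list(); archive_cuts <- list()
  seed_pop <- matrix(rep(permissive, length(params)), ncol = length(params),
                     byrow = TRUE)[0, , drop = FALSE]
  for (k in seq_along(params)) {
    sw <- single_param_roc(vectors, params[k], label_col)$cuts
    cuts_k <- matrix(rep(permissive, nrow(sw)), ncol = length(params), byrow = TRUE)
    cuts_k[, k] <- sw$cut
    archive_pts[[length(archive_pts) + 1L]] <- sw[, c("fpr", "tpr")]
    archive_cuts[[length(archive_cuts) + 1L]] <- cuts_k
    # population seed: this parameter's Youden-optimal cut
    best_k <- which.max(sw$tpr - sw$fpr)
    ind <- permissive; ind[k] <- sw$cut[best_k]
    seed_pop <- rbind(seed_pop, ind)
  }

  pop_n <- config$population
  n_random <- max(pop_n - nrow(seed_pop), 0L)
  random_pop <- vapply(seq_along(params), function(k) {
    stats::runif(n_random, lo[k] - 0.05 * rng[k], hi[k] + 0.05 * rng[k])
  }, numeric(n_random))
  if (n_random == 1L) random_pop <- matrix(random_pop, nrow = 1L)
  pop <- rbind(seed_pop, random_pop)[seq_len(max(pop_n, nrow(seed_pop))), , drop = FALSE]
  colnames(pop) <- params

  n_elite <- max(1L, ceiling(config$elitism * nrow(pop)))
  for (gen in seq_len(config$generations)) {
    pts <- eval_candidates(pop, X, lab, directions)
    archive_pts[[length(archive_pts) + 1L]] <- pts
    archive_cuts[[length(archive_cuts) + 1L]] <- pop
    fitness <- pts$tpr - pts$fpr
    if (gen == config$generations) break
    ord <- order(-fitness)
    elite <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    n_child <- nrow(pop) - n_elite
    pick <- function() {
      cand <- sample.int(nrow(pop), config$tournament)
      cand[which.max(fitness[cand])]
    }
    children <- matrix(NA_real_, n_child, ncol(pop), dimnames = list(NULL, params))
    for (c_i in seq_len(n_child)) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      mix <- stats::runif(ncol(pop)) < 0.5
      child <- ifelse(mix, p1, p2)
      mut <- stats::runif(ncol(pop)) < config$mutation_prob
      if (any(mut)) {
        base <- child
        # mutating a permissive (infinite) gene re-anchors it in the data range
        base[!is.finite(base)] <- ifelse(directions[!is.finite(base)] == "gt",
                                         lo[!is.finite(base)], hi[!is.finite(base)])
        child[mut] <- base[mut] +
          stats::rnorm(sum(mut), 0, config$mutation_scale * rng[mut])
      }
      children[c_i, ] <- child
    }
    pop <- rbind(elite, children)
  }

  all_pts <- do.call(rbind, archive_pts)
  all_cuts <- do.call(rbind, archive_cuts)
  roc <- roc_curve(all_pts, provenance = "composite")

  # pick the reported set: best frontier point by the chosen rule
  frontier_idx <- which(!duplicated(paste(all_pts$fpr, all_pts$tpr)) &
                          paste(all_pts$fpr, all_pts$tpr) %in%
                          paste(roc$points$fpr, roc$points$tpr))
  cand_pts <- all_pts[frontier_idx, , drop = FALSE]
  cand_cuts <- all_cuts[frontier_idx, , drop = FALSE]
  score <- if (selection == "youden") {
    cand_pts$tpr - cand_pts$fpr
  } else {
    (cand_pts$tpr * np + (1 - cand_pts$fpr) * nn) / (np + nn)
  }
  best <- order(-score, cand_pts$fpr)[1L]
  cuts <- cand_cuts[best, ]
  names(cuts) <- params
  list(thresholds = threshold_set(cuts, name = paste0("ga_", selection)),
       roc = roc,
       best_point = cand_pts[best, , drop = FALSE],
       n_evaluated = nrow(all_pts))
}

#' Learning curve of the composite classifier
#'
#' For each training fraction, repeats `iterations` random stratified
#' train/test splits, trains the GA on the training part, takes the most
#' accurate threshold set along the training ROC, and records its accuracy
#' on the held-out part.
#'
#' @param vectors Labeled score vectors.
#' @param fractions Training fractions in (0, 1).
#' @param iterations Splits per fraction (default 10).
#' @param config A [ga_config()].
#' @param seed RNG seed for the splits.
#' @param label_col Name of the label column.
#' @return data.frame with columns `fraction`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
learning_curve <- function(vectors, fractions, iterations = 10L,
                           config = ga_config(), seed = NULL,
                           label_col = "label") {
  stopifnot(all(fractions > 0 & fractions < 1))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  lab <- vectors[[label_col]]
  rows <- lapply(fractions, function(f) {
    acc <- vapply(seq_len(iterations), function(i) {
      train_idx <- unlist(lapply(c("binder", "nonbinder"), function(cl) {
        idx <- which(lab == cl)
        k <- round(f * length(idx))
        if (k < 1L || k >= length(idx)) {
          stop(sprintf("fraction %.2f leaves an empty side for class %s", f, cl),
               call. = FALSE)
        }
        sample(idx, k)
      }))
      cfg <- config; cfg$seed <- NULL  # splits drive the stream; GA inherits it
      fit <- train_composite(vectors[train_idx, , drop = FALSE], cfg,
                             selection = "accuracy", label_col = label_col)
      evaluate_thresholds(vectors[-train_idx, , drop = FALSE],
                          fit$thresholds, label_col)$accuracy
    }, numeric(1))
    data.frame(fraction = f, mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc))
  })
  do.call(rbind, rows)
}
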