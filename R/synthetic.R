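# Synthetic prediction fixtures: ColabFold-dialect run directories with
# controllable geometry and scores, labeled score-vector datasets, and
# affinity-relation data for parameter recovery.
#
# The LC8 geometry is an idealized deterministic C-alpha trace, not real
# coordinates: every geometric operation downstream depends only on pairwise
# distances and the beta3/G63 landmarks, so an extended trace with the right
# contact pattern exercises the same code paths as a real structure. PAE
# matrices are block-structured (interface blocks on a flat background)
# because the extraction operators consume only block means.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

CA_SPACING <- 3.8   # Angstrom spacing of the idealized trace
DIMER_GAP <- 4.9    # protomer-protomer offset; gives contacts within 8 A
GROOVE_GAP <- 2.45  # client offset between the protomer planes

#' Configuration of one synthetic run directory
#'
#' @param n_structures Structures in the run (e.g. 5 or 25).
#' @param client_count 1 or 2 client copies.
#' @param bound Place the client in the binding groove (`TRUE`) or displaced
#'   by `unbound_offset` (`FALSE`).
#' @param window A [sequence_window()]; a default 16-mer is used when `NULL`.
#' @param anchor 1-based client residue that sits on the G63 landmark.
#' @param plddt,ltop,ptol,dimer Target scores per structure (scalar or
#'   length `n_structures`): uniform pLDDT and the three PAE block means.
#' @param ptm,iptm Predicted TM-scores per structure.
#' @param pae_background Background PAE for non-interface cells.
#' @param groove_distance Client offset (Angstrom) out of the dimer plane.
#' @param unbound_offset Displacement (Angstrom) applied when `bound` is
#'   `FALSE`.
#' @param seed RNG seed (only consumed when jitter is added downstream).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_structures = 3L, client_count = 1L, bound = TRUE,
                           window = NULL, anchor = 8L,
                           plddt = 90, ltop = 3.0, ptol = 5.0, dimer = 1.0,
                           ptm = 0.80, iptm = 0.85,
                           pae_background = 12, groove_distance = 3.0,
                           unbound_offset = 50, seed = NULL) {
  if (is.null(window)) {
    window <- sequence_window("synthetic", 0L, 16L, "ASPSRGTQTEVSAGLK")
  }
  rec <- function(v) rep_len(as.numeric(v), n_structures)
  stopifnot(client_count %in% c(1L, 2L), n_structures >= 1L,
            groove_distance > 0, unbound_offset > 0)
  cfg <- list(n_structures = as.integer(n_structures),
              client_count = as.integer(client_count), bound = isTRUE(bound),
              window = window, anchor = as.integer(anchor),
              plddt = rec(plddt), ltop = rec(ltop), ptol = rec(ptol),
              dimer = rec(dimer), ptm = rec(ptm), iptm = rec(iptm),
              pae_background = pae_background,
              groove_distance = groove_distance,
              unbound_offset = unbound_offset, seed = seed)
  ok <- function(v, lo, hi) all(v >= lo & v <= hi)
  if (!ok(cfg$plddt, 0, 100) || !ok(cfg$ltop, 0, PAE_MAX) ||
      !ok(cfg$ptol, 0, PAE_MAX) || !ok(cfg$dimer, 0, PAE_MAX) ||
      !ok(cfg$pae_background, 0, PAE_MAX) ||
      !ok(cfg$ptm, 0, 1) || !ok(cfg$iptm, 0, 1)) {
    stop("invalid fixture config: score outside its valid range", call. = FALSE)
  }
  class(cfg) <- "fixture_config"
  cfg
}

# idealized coordinates for one synthetic structure
synthetic_coords <- function(cfg) {
  n_lc8 <- nchar(lc8_sequence())
  i <- seq_len(n_lc8)
  a <- cbind(CA_SPACING * i, 0, 0)
  b <- cbind(CA_SPACING * i, DIMER_GAP, 0)
  L <- nchar(cfg$window$sequence)
  j <- seq_len(L)
  z <- cfg$groove_distance + if (cfg$bound) 0 else cfg$unbound_offset
  client_x <- CA_SPACING * (LC8_G63 + j - cfg$anchor)
  cl1 <- cbind(client_x, GROOVE_GAP, z)
  chains <- list(A = a, B = b, C = cl1)
  if (cfg$client_count == 2L) chains$D <- cbind(client_x, GROOVE_GAP, -z)
  chains
}

# build the block-structured PAE matrix for one structure
synthetic_pae <- function(cfg, chains, k) {
  ns <- vapply(chains, nrow, integer(1))
  n <- sum(ns)
  offs <- c(0, cumsum(ns))[seq_along(ns)]
  names(offs) <- names(chains)
  pae <- matrix(cfg$pae_background, n, n)
  diag(pae) <- 0

  b3 <- c(offs[["A"]] + lc8_beta3_residues(),
          offs[["B"]] + lc8_beta3_residues())
  coords <- do.call(rbind, chains)

  client_ids <- setdiff(names(chains), c("A", "B"))
  for (id in client_ids) {
    rows <- offs[[id]] + seq_len(ns[[id]])
    d <- pairwise_dist(coords[rows, , drop = FALSE], coords[b3, , drop = FALSE])
    bound <- rows[apply(d, 1L, min) <= 8.0]
    region <- if (length(bound) > 0L) bound else rows  # unbound fallback block
    pae[b3, region] <- cfg$ltop[k]
    pae[region, b3] <- cfg$ptol[k]
  }

  # inter-protomer contact cells, C-terminal 3 residues excluded
  n_lc8 <- ns[["A"]]
  ia <- offs[["A"]] + seq_len(n_lc8 - 3L)
  ib <- offs[["B"]] + seq_len(n_lc8 - 3L)
  d <- pairwise_dist(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE])
  hit <- which(d <= 8.0, arr.ind = TRUE)
  pae[cbind(ia[hit[, 1L]], ib[hit[, 2L]])] <- cfg$dimer[k]
  pae[cbind(ib[hit[, 2L]], ia[hit[, 1L]])] <- cfg$dimer[k]
  pae
}

#' Generate a synthetic ColabFold-style run directory
#'
#' Writes, per structure, a score JSON (uniform per-residue pLDDT, a
#' block-structured PAE matrix whose interface blocks carry the configured
#' means, and pTM/ipTM consistent with the 0.2/0.8 confidence identity) and
#' a C-alpha-only PDB of the idealized LC8 dimer with the client chain(s)
#' either seated in the groove or displaced. Structures are ranked by
#' descending confidence. The directory parses with [parse_run_dir()] and
#' round-trips to exactly the configured scores.
#'
#' @param cfg A [fixture_config()].
#' @param path Output directory (created if needed).
#' @return The path, invisibly. The run manifest records the generator
#'   settings.
#' @export
gen_run_dir <- function(cfg, path) {
  stopifnot(inherits(cfg, "fixture_config"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  chains <- synthetic_coords(cfg)
  coords <- do.call(rbind, chains)
  ns <- vapply(chains, nrow, integer(1))
  chain_vec <- rep(names(chains), ns)
  resno <- unlist(lapply(ns, seq_len), use.names = FALSE)

  conf <- compute_confidence(cfg$ptm, cfg$iptm)
  ord <- order(-conf)  # rank 1 = most confident

  w <- cfg$window
  man <- list(run_id = sprintf("%s_%d_%d_%dc%s", w$protein_id, w$start, w$end,
                               cfg$client_count, if (w$is_mutant) "_AAA" else ""),
              client_count = cfg$client_count,
              lc8_chains = c("A", "B"),
              client_chains = setdiff(names(chains), c("A", "B")),
              lc8_ortholog = "synthetic idealized trace (human DYNLL1 numbering)",
              window = list(protein_id = w$protein_id, start = w$start,
                            end = w$end, sequence = w$sequence,
                            is_mutant = w$is_mutant))
  jsonlite::write_json(man, file.path(path, "run.json"), auto_unbox = TRUE,
                       digits = NA)

  for (r in seq_along(ord)) {
    k <- ord[r]
    pae <- synthetic_pae(cfg, chains, k)
    scores <- list(plddt = rep(cfg$plddt[k], sum(ns)),
                   pae = lapply(seq_len(nrow(pae)), function(i) pae[i, ]),
                   ptm = cfg$ptm[k], iptm = cfg$iptm[k],
                   max_pae = PAE_MAX)
    jsonlite::write_json(scores,
                         file.path(path, sprintf("pred_rank_%03d.json", r)),
                         auto_unbox = TRUE, digits = NA)
    bio3d::write.pdb(file = file.path(path, sprintf("pred_rank_%03d.pdb", r)),
                     xyz = as.numeric(t(coords)),
                     resno = resno, chain = chain_vec,
                     resid = rep("ALA", sum(ns)),
                     elety = rep("CA", sum(ns)))
  }
  invisible(path)
}

# default class-conditional score means; the nonbinder column reflects the
# clearly separated class structure seen in real binder/nonbinder screens
SCORE_CLASS_MEANS <- data.frame(
  param = c("conf", "plddt", "ltop", "ptol", "dimer"),
  binder = c(0.86, 90, 3.5, 5.5, 1.00),
  nonbinder = c(0.55, 55, 13.0, 16.0, 1.60),
  sd = c(0.06, 8, 2.5, 3.0, 0.25)
)

score_bounds <- function(param) {
  switch(param, conf = c(0, 1), plddt = c(0, 100), c(0.001, PAE_MAX))
}

#' Generate a labeled score-vector dataset
#'
#' Class-conditional Gaussian draws of the ten linked score parameters,
#' truncated to their valid ranges. `separation` scales the
#' binder-to-nonbinder mean gap (1 = the default, clearly separated classes;
#' 0 = identical class distributions, the null case). Optionally the
#' 1-client binder scores are made bimodal, mimicking the weak-binder mode
#' in which half-bound predictions look like nonbinders.
#'
#' @param n_binders,n_nonbinders Rows per class (>= 1).
#' @param separation Effect-size multiplier (scalar, or named per-parameter
#'   vector over `conf`, `plddt`, `ltop`, `ptol`, `dimer`).
#' @param bimodal_1c Probability that a binder's 1-client scores are drawn
#'   from the nonbinder component (default 0: unimodal).
#' @param seed RNG seed.
#' @return data.frame with the ten [score_vector_params()] columns and
#'   `label`.
#' @export
gen_score_dataset <- function(n_binders, n_nonbinders, separation = 1,
                              bimodal_1c = 0, seed = NULL) {
  stopifnot(n_binders >= 1L, n_nonbinders >= 1L)
  if (is.null(names(separation))) {
    separation <- stats::setNames(rep_len(separation, 5L), SCORE_CLASS_MEANS$param)
  }
  with_seed(seed, {
    n <- n_binders + n_nonbinders
    label <- c(rep("binder", n_binders), rep("nonbinder", n_nonbinders))
    weak <- stats::runif(n) < bimodal_1c  # binders whose 1c mode is poor
    out <- data.frame(row.names = seq_len(n))
    for (i in seq_len(nrow(SCORE_CLASS_MEANS))) {
      p <- SCORE_CLASS_MEANS$param[i]
      mb <- SCORE_CLASS_MEANS$binder[i]
      mn <- mb + (SCORE_CLASS_MEANS$nonbinder[i] - mb) * separation[[p]]
      sdv <- SCORE_CLASS_MEANS$sd[i]
      bounds <- score_bounds(p)
      for (sfx in c("1c", "2c")) {
        mu <- ifelse(label == "binder", mb, mn)
        if (sfx == "1c") mu[label == "binder" & weak] <- mn
        v <- stats::rnorm(n, mu, sdv)
        out[[paste0(p, "_", sfx)]] <- pmin(pmax(v, bounds[1]), bounds[2])
      }
    }
    out$label <- label
    rownames(out) <- NULL
    out
  })
}

#' Generate a linear score-affinity relation
#'
#' Draws scores uniformly and sets Kd = slope * score + intercept + Gaussian
#' noise, floored at a small positive value -- the data-generating process
#' assumed by the anchor-class affinity models, used for parameter-recovery
#' checks of [linear_fit()].
#'
#' @param slope,intercept Line coefficients (Kd in micromolar per score
#'   unit).
#' @param noise_sd Gaussian noise standard deviation (micromolar).
#' @param n Number of points (>= 3).
#' @param score_range Range the scores are drawn from.
#' @param seed RNG seed.
#' @return data.frame with columns `score` and `kd`.
#' @export
gen_affinity_relation <- function(slope, intercept, noise_sd, n,
                                  score_range = c(0, 10), seed = NULL) {
  stopifnot(n >= 3L, noise_sd >= 0)
  with_seed(seed, {
    score <- stats::runif(n, score_range[1], score_range[2])
    kd <- pmax(slope * score + intercept + stats::rnorm(n, 0, noise_sd), 1e-3)
    data.frame(score = score, kd = kd)
  })
}
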