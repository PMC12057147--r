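# The five per-structure interface scores, best-structure selection, and
# linking of 1-client / 2-client runs into 10-parameter score vectors.
#
# All geometric criteria are defined on C-alpha positions. Client residues
# are referred to by their 1-based position within the client chain; window
# coordinates stay 0-based half-open.

SCORE_PARAMS <- c("conf", "plddt", "ltop", "ptol", "dimer")

#' Names of the ten linked score-vector columns
#' @return Character vector `conf_1c ... dimer_2c`.
#' @export
score_vector_params <- function() {
  c(paste0(SCORE_PARAMS, "_1c"), paste0(SCORE_PARAMS, "_2c"))
}

# comparison direction implied by a parameter's semantics:
# confidence and pLDDT are good when high, PAEs when low
param_direction <- function(parameter) {
  base <- sub("_(1c|2c)(_best|_avg)?$", "", parameter)
  ifelse(base %in% c("conf", "plddt"), "gt", "lt")
}

pairwise_dist <- function(a, b) {
  # |a_i - b_j| for row vectors of two x3 matrices
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(sq, 0))
}

#' Client residues bound to the LC8 beta3 strand
#'
#' A client residue counts as bound when its C-alpha lies within `cutoff` of
#' any beta3 C-alpha of either LC8 protomer. An empty result means the
#' predictor left the client unbound.
#'
#' @param model A [structure_model()].
#' @param client_chain Chain id of the client.
#' @param beta3_residues LC8 residue numbers of the beta3 strand.
#' @param cutoff Contact cutoff in Angstroms (default 8).
#' @return Sorted integer vector of client residue positions (1-based within
#'   the chain); possibly empty.
#' @export
find_bound_region <- function(model, client_chain,
                              beta3_residues = lc8_beta3_residues(),
                              cutoff = 8.0) {
  stopifnot(length(beta3_residues) > 0L)
  cl <- chain_rows(model, client_chain)
  b3 <- beta3_rows(model, beta3_residues)
  d <- pairwise_dist(model$coords[cl, , drop = FALSE],
                     model$coords[b3, , drop = FALSE])
  which(apply(d, 1L, min) <= cutoff)
}

# global rows of the beta3 residues of both protomers
beta3_rows <- function(model, beta3_residues = lc8_beta3_residues()) {
  ids <- lc8_chain_ids(model)
  unlist(lapply(ids, function(id) chain_rows(model, id)[beta3_residues]),
         use.names = FALSE)
}

#' Locate the client anchor residue
#'
#' The anchor (motif position 0) is the client residue whose C-alpha is
#' closest to G63 of either LC8 protomer; ties go to the lower client index.
#'
#' @inheritParams find_bound_region
#' @param g63 LC8 residue number of the landmark glycine (default 63).
#' @return The 1-based client residue position.
#' @export
find_anchor <- function(model, client_chain, g63 = LC8_G63) {
  cl <- chain_rows(model, client_chain)
  g_rows <- vapply(lc8_chain_ids(model),
                   function(id) chain_rows(model, id)[g63], integer(1))
  d <- pairwise_dist(model$coords[cl, , drop = FALSE],
                     model$coords[g_rows, , drop = FALSE])
  which.min(apply(d, 1L, min))  # which.min takes the first (lowest) index on ties
}

#' Mean directional PAE between two residue sets
#'
#' PAE is directional: `pae[i, j]` is the expected error at residue j when
#' the structures are aligned at residue i. The LC8-to-client (LtoP) score
#' aligns on beta3, the client-to-LC8 (PtoL) score is the transpose
#' direction; the two differ in practice and are evaluated separately.
#'
#' @param pae Square PAE matrix.
#' @param from_set,to_set Disjoint, nonempty global residue index sets;
#'   `from_set` is aligned on.
#' @return Mean of `pae[from, to]`.
#' @export
directional_pae <- function(pae, from_set, to_set) {
  if (length(from_set) == 0L || length(to_set) == 0L) {
    stop("no interface", call. = FALSE)
  }
  if (length(intersect(from_set, to_set)) > 0L) {
    stop("from_set and to_set must be disjoint", call. = FALSE)
  }
  mean(pae[from_set, to_set])
}

#' Mean PAE across the LC8 dimer interface
#'
#' Averages `pae[i, j]` and `pae[j, i]` over inter-protomer C-alpha pairs
#' within `cutoff`, after dropping the flexible C-terminal residues of each
#' protomer. Tracked throughout an analysis as a control that the LC8 dimer
#' itself stayed well predicted.
#'
#' @param model A [structure_model()].
#' @param cutoff Contact cutoff in Angstroms (default 8).
#' @param cterm_exclude Number of C-terminal residues dropped per protomer
#'   (default 3).
#' @return Mean interface PAE.
#' @export
dimer_interface_pae <- function(model, cutoff = 8.0, cterm_exclude = 3L) {
  ids <- lc8_chain_ids(model)
  ra <- chain_rows(model, ids[1L]); rb <- chain_rows(model, ids[2L])
  keep <- function(r) r[seq_len(length(r) - cterm_exclude)]
  ra <- keep(ra); rb <- keep(rb)
  d <- pairwise_dist(model$coords[ra, , drop = FALSE],
                     model$coords[rb, , drop = FALSE])
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) stop("protomers not in contact", call. = FALSE)
  i <- ra[hit[, 1L]]; j <- rb[hit[, 2L]]
  mean(c(model$pae[cbind(i, j)], model$pae[cbind(j, i)]))
}

#' Compute the five interface scores of one structure
#'
#' Extracts (1) the model confidence, (2) the mean pLDDT over the bound
#' client region plus the beta3 residues contacting it, (3) the mean PAE of
#' beta3 aligned on itself toward the bound client (LtoP), (4) the transpose
#' direction (PtoL), and (5) the LC8 dimer-interface PAE. In two-client
#' models the per-groove values (one per client chain) are averaged. A
#' structure whose client never touches beta3 is still scored -- the pLDDT
#' and PAE means then fall back to the full client span -- and is flagged
#' `unbound`; nonbinders must keep their poor scores for classifier
#' training.
#'
#' @param model A [structure_model()].
#' @param beta3_residues LC8 beta3 residue numbers.
#' @param cutoff Contact cutoff in Angstroms.
#' @param cterm_exclude C-terminal residues excluded from the dimer
#'   interface.
#' @return An object of class `interface_scores`: a list with fields
#'   `confidence`, `avg_plddt_bind`, `pae_ltop`, `pae_ptol`, `pae_dimer`,
#'   `anchor_index`, `bound_region` (list per client chain) and `unbound`.
#' @export
score_structure <- function(model, beta3_residues = lc8_beta3_residues(),
                            cutoff = 8.0, cterm_exclude = 3L) {
  clients <- client_chain_ids(model)
  b3 <- beta3_rows(model, beta3_residues)
  grooves <- lapply(clients, function(ch) {
    cl_rows <- chain_rows(model, ch)
    bound <- find_bound_region(model, ch, beta3_residues, cutoff)
    unbound <- length(bound) == 0L
    region <- if (unbound) seq_along(cl_rows) else bound
    region_rows <- cl_rows[region]
    # beta3 residues in contact with the bound region
    d <- pairwise_dist(model$coords[b3, , drop = FALSE],
                       model$coords[region_rows, , drop = FALSE])
    b3_contact <- b3[apply(d, 1L, min) <= cutoff]
    plddt_rows <- union(region_rows, b3_contact)
    list(bound = bound, unbound = unbound,
         plddt = mean(model$plddt[plddt_rows]),
         ltop = directional_pae(model$pae, b3, region_rows),
         ptol = directional_pae(model$pae, region_rows, b3))
  })
  names(grooves) <- clients
  bound_region <- lapply(grooves, `[[`, "bound")
  anchor <- find_anchor(model, clients[1L])
  structure(
    list(confidence = model$confidence,
         avg_plddt_bind = mean(vapply(grooves, `[[`, numeric(1), "plddt")),
         pae_ltop = mean(vapply(grooves, `[[`, numeric(1), "ltop")),
         pae_ptol = mean(vapply(grooves, `[[`, numeric(1), "ptol")),
         pae_dimer = dimer_interface_pae(model, cutoff, cterm_exclude),
         anchor_index = anchor,
         bound_region = bound_region,
         unbound = any(vapply(grooves, `[[`, logical(1), "unbound"))),
    class = "interface_scores"
  )
}

#' Score every structure of a run
#'
#' @param run A [prediction_run()].
#' @inheritParams score_structure
#' @return data.frame with one row per structure: `rank`, the five scores
#'   (`conf`, `plddt`, `ltop`, `ptol`, `dimer`), `anchor_index`, `unbound`.
#' @export
score_run <- function(run, beta3_residues = lc8_beta3_residues(),
                      cutoff = 8.0, cterm_exclude = 3L) {
  rows <- lapply(run$structures, function(m) {
    s <- score_structure(m, beta3_residues, cutoff, cterm_exclude)
    data.frame(rank = m$rank, conf = s$confidence, plddt = s$avg_plddt_bind,
               ltop = s$pae_ltop, ptol = s$pae_ptol, dimer = s$pae_dimer,
               anchor_index = s$anchor_index, unbound = s$unbound)
  })
  do.call(rbind, rows)
}

#' Select the best structure of a run
#'
#' Models are re-sorted by the mean pLDDT of the binding interface rather
#' than by the predictor's own confidence ranking, which discriminates
#' binders less well. Ties go to the lower (better) confidence rank.
#'
#' @param run A [prediction_run()].
#' @inheritParams score_structure
#' @return The winning [structure_model()].
#' @export
select_best <- function(run, beta3_residues = lc8_beta3_residues(),
                        cutoff = 8.0, cterm_exclude = 3L) {
  tab <- score_run(run, beta3_residues, cutoff, cterm_exclude)
  ord <- order(-tab$plddt, tab$rank)
  run$structures[[ord[1L]]]
}

run_best_scores <- function(run, ...) {
  tab <- score_run(run, ...)
  tab[order(-tab$plddt, tab$rank)[1L], , drop = FALSE]
}

#' Link one-client and two-client runs into ten-parameter vectors
#'
#' Joins runs on window identity (protein, coordinates, sequence, mutant
#' status) and combines the best-structure scores from each side into one
#' row of ten parameters. Windows present on only one side are reported as
#' orphans (attribute `"orphans"`) and excluded.
#'
#' @param one_client,two_client Lists of [prediction_run()]s.
#' @param labels Optional data.frame with columns `protein_id`, `start`,
#'   `end`, `is_mutant`, `label` (one of `"binder"`, `"nonbinder"`,
#'   `"unknown"`).
#' @inheritParams score_structure
#' @return data.frame with the window columns, the ten score columns named
#'   as in [score_vector_params()], and `label`.
#' @export
link_runs <- function(one_client, two_client, labels = NULL,
                      beta3_residues = lc8_beta3_residues(),
                      cutoff = 8.0, cterm_exclude = 3L) {
  side_table <- function(runs, suffix) {
    if (length(runs) == 0L) {
      return(data.frame(key = character(0)))
    }
    keys <- vapply(runs, function(r) window_key(r$window), character(1))
    if (anyDuplicated(keys)) stop("ambiguous link: duplicate window on one side",
                                  call. = FALSE)
    rows <- lapply(runs, function(r) {
      best <- run_best_scores(r, beta3_residues, cutoff, cterm_exclude)
      w <- r$window
      out <- data.frame(key = window_key(w), protein_id = w$protein_id,
                        start = w$start, end = w$end, sequence = w$sequence,
                        is_mutant = w$is_mutant, stringsAsFactors = FALSE)
      for (p in SCORE_PARAMS) out[[paste0(p, "_", suffix)]] <- best[[p]]
      out
    })
    do.call(rbind, rows)
  }
  t1 <- side_table(one_client, "1c")
  t2 <- side_table(two_client, "2c")
  common <- intersect(t1$key, t2$key)
  orphans <- c(setdiff(t1$key, t2$key), setdiff(t2$key, t1$key))
  if (length(common) == 0L) {
    out <- data.frame()
    attr(out, "orphans") <- orphans
    return(out)
  }
  a <- t1[match(common, t1$key), , drop = FALSE]
  b <- t2[match(common, t2$key), paste0(SCORE_PARAMS, "_2c"), drop = FALSE]
  out <- cbind(a[, setdiff(names(a), "key"), drop = FALSE], b)
  rownames(out) <- NULL
  out$label <- "unknown"
  if (!is.null(labels)) {
    lk <- paste(labels$protein_id, labels$start, labels$end,
                ifelse(labels$is_mutant, "AAA", "WT"), sep = "|")
    ok <- paste(out$protein_id, out$start, out$end,
                ifelse(out$is_mutant, "AAA", "WT"), sep = "|")
    hit <- match(ok, lk)
    out$label[!is.na(hit)] <- labels$label[hit[!is.na(hit)]]
  }
  attr(out, "orphans") <- orphans
  out
}
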