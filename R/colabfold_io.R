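# Reading ColabFold-style prediction directories.
#
# A run directory holds one JSON score file and one PDB coordinate file per
# predicted structure, named with a `rank_NNN` token (ColabFold convention),
# plus a `run.json` manifest recording the client window, the client count
# and the chain layout. Only C-alpha atoms are consumed downstream, so
# full-atom PDBs are accepted but reduced at parse time.

DEFAULT_JSON_KEYS <- list(plddt = "plddt", pae = "pae",
                          ptm = "ptm", iptm = "iptm")

#' Weighted model confidence from pTM and ipTM
#'
#' AlphaFold-Multimer ranks its models by a confidence score that weights
#' the interface-specific ipTM at 80% and the global pTM at 20%.
#'
#' @param ptm,iptm Predicted TM-scores in \[0, 1\].
#' @return `0.2 * ptm + 0.8 * iptm`.
#' @export
#' @examples
#' compute_confidence(0.5, 1.0)  # 0.90
compute_confidence <- function(ptm, iptm) {
  stopifnot(is.numeric(ptm), is.numeric(iptm))
  if (any(ptm < 0 | ptm > 1) || any(iptm < 0 | iptm > 1)) {
    stop("ptm and iptm must lie in [0, 1]", call. = FALSE)
  }
  0.2 * ptm + 0.8 * iptm
}

#' Construct a structure model
#'
#' One predicted structure with its confidence scores and C-alpha trace.
#' Validation enforces the score ranges (pLDDT in \[0, 100\], PAE in
#' \[0, 31.5\]), matching dimensions, and consistency of the stored
#' confidence with `0.2 * ptm + 0.8 * iptm`.
#'
#' @param rank Rank of the model within its run (1 = most confident).
#' @param plddt Per-residue pLDDT over all chains, in order.
#' @param pae Square PAE matrix over all residues of all chains; entry
#'   `[i, j]` is the expected error at residue j when aligned on residue i.
#' @param ptm,iptm Predicted TM-scores.
#' @param chain_layout data.frame with columns `chain_id` and `n` giving the
#'   ordered chains (LC8 protomers first, then client chains).
#' @param coords Numeric matrix (total residues x 3) of C-alpha positions in
#'   Angstroms, rows in chain order.
#' @param confidence Optional; computed from ptm/iptm when missing.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(rank, plddt, pae, ptm, iptm, chain_layout,
                            coords, confidence = NULL) {
  n <- sum(chain_layout$n)
  plddt <- as.numeric(plddt)
  pae <- as.matrix(pae)
  if (length(plddt) != n) stop("plddt length != total residue count", call. = FALSE)
  if (any(plddt < 0 | plddt > 100)) stop("plddt outside [0, 100]", call. = FALSE)
  if (nrow(pae) != n || ncol(pae) != n) {
    stop("pae must be square with side = total residue count", call. = FALSE)
  }
  if (any(pae < 0 | pae > PAE_MAX)) {
    stop(sprintf("pae outside [0, %.1f]", PAE_MAX), call. = FALSE)
  }
  if (!is.matrix(coords) || nrow(coords) != n || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix", call. = FALSE)
  }
  conf <- compute_confidence(ptm, iptm)
  if (!is.null(confidence) && abs(confidence - conf) > 1e-6) {
    stop("stored confidence inconsistent with 0.2*ptm + 0.8*iptm", call. = FALSE)
  }
  structure(
    list(rank = as.integer(rank), plddt = plddt, pae = pae,
         ptm = ptm, iptm = iptm, confidence = conf,
         chain_layout = chain_layout, coords = coords),
    class = "structure_model"
  )
}

# global residue row indices of a chain within a model
chain_rows <- function(model, chain_id) {
  lay <- model$chain_layout
  k <- match(chain_id, lay$chain_id)
  if (is.na(k)) stop(sprintf("unknown chain '%s'", chain_id), call. = FALSE)
  offset <- if (k == 1L) 0L else sum(lay$n[seq_len(k - 1L)])
  offset + seq_len(lay$n[k])
}

lc8_chain_ids <- function(model) model$chain_layout$chain_id[1:2]
client_chain_ids <- function(model) {
  ids <- model$chain_layout$chain_id
  ids[-(1:2)]
}

#' Construct a prediction run
#'
#' @param run_id Run identifier.
#' @param window The [sequence_window()] that was co-predicted.
#' @param client_count 1 or 2 client copies.
#' @param structures List of [structure_model()]s; sorted by rank on
#'   construction. All must share a chain layout.
#' @return An object of class `prediction_run`.
#' @export
prediction_run <- function(run_id, window, client_count, structures) {
  stopifnot(inherits(window, "sequence_window"),
            client_count %in% c(1L, 2L), length(structures) > 0L)
  layouts <- lapply(structures, function(s) s$chain_layout)
  ref <- layouts[[1L]]
  same <- vapply(layouts, function(l) identical(l$chain_id, ref$chain_id) &&
                   identical(l$n, ref$n), logical(1))
  if (!all(same)) stop("structures do not share a chain layout", call. = FALSE)
  ranks <- vapply(structures, function(s) s$rank, integer(1))
  structures <- structures[order(ranks)]
  structure(
    list(run_id = as.character(run_id), window = window,
         client_count = as.integer(client_count), structures = structures),
    class = "prediction_run"
  )
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf("<prediction_run> %s: %d-client, %d structures, window %s[%d,%d)\n",
              x$run_id, x$client_count, length(x$structures),
              x$window$protein_id, x$window$start, x$window$end))
  invisible(x)
}

read_ca_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop(sprintf("no C-alpha atoms in %s", path), call. = FALSE)
  list(chain = ca$chain, resno = ca$resno,
       coords = cbind(ca$x, ca$y, ca$z))
}

#' Parse a ColabFold-style run directory
#'
#' Reads the `run.json` manifest, the per-structure `*rank_NNN*.json` score
#' files (keys configurable, ColabFold defaults: `plddt`, `pae`, `ptm`,
#' `iptm`) and the matching `*rank_NNN*.pdb` coordinate files. A combined
#' `scores.json` (an array of per-model score objects carrying a `rank`
#' field) is accepted in place of per-model files. Chains are reordered so
#' the two LC8 protomers come first, as declared in the manifest.
#'
#' @param path Run directory.
#' @param json_keys Named list mapping the fields `plddt`, `pae`, `ptm`,
#'   `iptm` to the keys used in the score files.
#' @return A [prediction_run()].
#' @export
parse_run_dir <- function(path, json_keys = DEFAULT_JSON_KEYS) {
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path), call. = FALSE)
  manifest_path <- file.path(path, "run.json")
  if (!file.exists(manifest_path)) stop("run.json manifest missing", call. = FALSE)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  w <- man$window
  window <- sequence_window(w$protein_id, w$start, w$end, w$sequence,
                            is_mutant = isTRUE(w$is_mutant),
                            anchor_offset = if (is.null(w$anchor_offset))
                              NA_integer_ else w$anchor_offset)
  client_count <- as.integer(man$client_count)
  lc8_chains <- as.character(man$lc8_chains)
  client_chains <- as.character(man$client_chains)

  combined <- file.path(path, "scores.json")
  if (file.exists(combined)) {
    raw <- jsonlite::read_json(combined, simplifyVector = FALSE)
    score_list <- lapply(raw, function(s) {
      list(rank = as.integer(s$rank), scores = s)
    })
  } else {
    jsons <- list.files(path, pattern = "rank_\\d+.*\\.json$", full.names = TRUE)
    jsons <- jsons[basename(jsons) != "run.json"]
    if (length(jsons) == 0L) stop("no structures", call. = FALSE)
    score_list <- lapply(jsons, function(f) {
      rk <- as.integer(sub(".*rank_(\\d+).*", "\\1", basename(f)))
      list(rank = rk, scores = jsonlite::read_json(f, simplifyVector = FALSE),
           file = f)
    })
  }
  if (length(score_list) == 0L) stop("no structures", call. = FALSE)

  pdbs <- list.files(path, pattern = "rank_\\d+.*\\.pdb$", full.names = TRUE)
  pdb_ranks <- as.integer(sub(".*rank_(\\d+).*", "\\1", basename(pdbs)))

  structures <- lapply(score_list, function(entry) {
    s <- entry$scores
    get_key <- function(field) {
      v <- s[[json_keys[[field]]]]
      if (is.null(v)) {
        stop(sprintf("score file for rank %d lacks key '%s'%s",
                     entry$rank, json_keys[[field]],
                     if (field == "iptm") " (monomer-style output?)" else ""),
             call. = FALSE)
      }
      v
    }
    plddt <- as.numeric(unlist(get_key("plddt")))
    pae <- do.call(rbind, lapply(get_key("pae"), function(r) as.numeric(unlist(r))))
    ptm <- as.numeric(get_key("ptm"))
    iptm <- as.numeric(get_key("iptm"))

    pdb_path <- pdbs[match(entry$rank, pdb_ranks)]
    if (is.na(pdb_path)) {
      stop(sprintf("no PDB file for rank %d", entry$rank), call. = FALSE)
    }
    ca <- read_ca_pdb(pdb_path)
    # enforce LC8-first chain order
    order_ids <- c(lc8_chains, client_chains)
    if (!setequal(unique(ca$chain), order_ids)) {
      stop("inconsistent run: PDB chains do not match manifest", call. = FALSE)
    }
    idx <- order(match(ca$chain, order_ids), ca$resno)
    chain <- ca$chain[idx]
    coords <- ca$coords[idx, , drop = FALSE]
    layout <- data.frame(chain_id = order_ids,
                         n = vapply(order_ids, function(id) sum(chain == id),
                                    integer(1)),
                         stringsAsFactors = FALSE, row.names = NULL)
    if (length(plddt) != nrow(coords)) {
      stop("inconsistent run: residue counts differ between JSON and PDB",
           call. = FALSE)
    }
    structure_model(rank = entry$rank, plddt = plddt, pae = pae,
                    ptm = ptm, iptm = iptm,
                    chain_layout = layout, coords = coords)
  })

  prediction_run(run_id = man$run_id, window = window,
                 client_count = client_count, structures = structures)
}
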