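# Window parsing and FASTA preparation for LC8 co-prediction runs.
#
# Coordinates are 0-based half-open throughout the package; they are
# converted to 1-based residue numbering only when printed for people.

#' Construct a sequence window
#'
#' A `sequence_window` is a client subsequence with protein-relative
#' coordinates, optionally carrying an anchor position and an AAA-mutant
#' flag. Windows are the unit that gets co-predicted with the LC8 dimer.
#'
#' @param protein_id Identifier of the parent protein.
#' @param start,end 0-based half-open residue coordinates in the parent.
#' @param sequence Amino-acid string; `end - start` must equal its length.
#' @param is_mutant Logical; `TRUE` when the anchoring triad has been
#'   mutated to AAA (nonbinder control).
#' @param anchor_offset Window-relative 0-based index of the anchor residue,
#'   or `NA` when unknown.
#' @return An object of class `sequence_window`.
#' @export
sequence_window <- function(protein_id, start, end, sequence,
                            is_mutant = FALSE, anchor_offset = NA_integer_) {
  sequence <- assert_aa(sequence)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start >= 0L, end > start)
  if (end - start != nchar(sequence)) {
    stop("end - start must equal the sequence length", call. = FALSE)
  }
  # screens use 10-71 residue clients (16 is the default parse length), but
  # shorter slices are legal for targeted runs; a triad needs 3 residues
  if (nchar(sequence) < 3L) {
    stop("window too short", call. = FALSE)
  }
  structure(
    list(protein_id = as.character(protein_id), start = start, end = end,
         sequence = sequence, is_mutant = isTRUE(is_mutant),
         anchor_offset = as.integer(anchor_offset)),
    class = "sequence_window"
  )
}

#' @export
print.sequence_window <- function(x, ...) {
  cat(sprintf("<sequence_window> %s [%d,%d) %s%s\n", x$protein_id,
              x$start, x$end, x$sequence,
              if (x$is_mutant) " (AAA mutant)" else ""))
  invisible(x)
}

#' Key identifying a window (used to link one- and two-client runs)
#' @param w A `sequence_window`.
#' @return A single string.
#' @export
window_key <- function(w) {
  paste(w$protein_id, w$start, w$end, w$sequence,
        if (w$is_mutant) "AAA" else "WT", sep = "|")
}

#' Parse a protein into overlapping client windows
#'
#' Splits a protein sequence into fixed-length windows with a fixed overlap
#' (defaults: 16-residue windows overlapping by 8, the parsing used for
#' whole-protein LC8 binding-site scans). Window starts advance by
#' `window - overlap`; when the final stride would overshoot the sequence,
#' one last window is anchored at the sequence end so every residue is
#' covered.
#'
#' @param sequence Amino-acid string.
#' @param protein_id Identifier stored in each window.
#' @param window Window length (default 16).
#' @param overlap Overlap between consecutive windows (default 8);
#'   `0 <= overlap < window`.
#' @return A list of [sequence_window()] objects ordered by start.
#' @export
#' @examples
#' w <- make_windows(strrep("ACDEFGHI", 4), "toy")
#' vapply(w, function(x) x$start, integer(1))  # 0 8 16
make_windows <- function(sequence, protein_id = "protein",
                         window = 16L, overlap = 8L) {
  sequence <- assert_aa(sequence)
  window <- as.integer(window); overlap <- as.integer(overlap)
  stopifnot(window > 0L, overlap >= 0L, overlap < window)
  L <- nchar(sequence)
  if (L < window) stop("sequence too short", call. = FALSE)
  stride <- window - overlap
  starts <- seq.int(0L, L - window, by = stride)
  # end-anchored final window when the regular stride does not reach the end
  if (starts[length(starts)] + window < L) starts <- c(starts, L - window)
  lapply(starts, function(s) {
    sequence_window(protein_id, s, s + window,
                    substr(sequence, s + 1L, s + window))
  })
}

#' Summarize windows as a manifest table
#'
#' @param windows A list of [sequence_window()] objects.
#' @return A data.frame with one row per window.
#' @export
windows_manifest <- function(windows) {
  do.call(rbind, lapply(windows, function(w) {
    data.frame(protein_id = w$protein_id, start = w$start, end = w$end,
               sequence = w$sequence, is_mutant = w$is_mutant,
               anchor_offset = w$anchor_offset,
               stringsAsFactors = FALSE)
  }))
}

#' Mutate the anchoring triad of a window to AAA
#'
#' Replaces the anchor residue and its two flanking residues with alanines,
#' producing the standard nonbinder control. Coordinates are unchanged and
#' `is_mutant` is set.
#'
#' @param w A [sequence_window()].
#' @param anchor_offset Window-relative 0-based index of the anchor residue;
#'   the triad spans `anchor_offset - 1 .. anchor_offset + 1`, so the anchor
#'   may not sit on the first or last residue.
#' @return A new `sequence_window` with the AAA triad.
#' @export
#' @examples
#' w <- sequence_window("p", 0, 8, "SRGVQVLV")
#' mutate_anchor_aaa(w, 4)$sequence  # "SRGAAALV"
mutate_anchor_aaa <- function(w, anchor_offset) {
  stopifnot(inherits(w, "sequence_window"))
  anchor_offset <- as.integer(anchor_offset)
  n <- nchar(w$sequence)
  if (anchor_offset < 1L || anchor_offset > n - 2L) {
    stop("triad out of bounds", call. = FALSE)
  }
  # triad occupies 0-based positions anchor-1 .. anchor+1
  seq2 <- paste0(substr(w$sequence, 1L, anchor_offset - 1L),
                 "AAA",
                 substr(w$sequence, anchor_offset + 3L, n))
  sequence_window(w$protein_id, w$start, w$end, seq2,
                  is_mutant = TRUE, anchor_offset = anchor_offset)
}

#' Write a multi-chain FASTA input for one co-prediction run
#'
#' Emits the LC8 dimer (two identical chains) followed by one or two copies
#' of the client window, which is the chain layout every downstream parser
#' assumes (LC8 protomers first, clients after).
#'
#' @param w A [sequence_window()].
#' @param client_count 1 or 2 copies of the client.
#' @param lc8_sequence LC8 ortholog sequence (default human DYNLL1).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_prediction_fasta <- function(w, client_count = 2L,
                                   lc8_sequence = lc8screen::lc8_sequence(),
                                   path) {
  stopifnot(inherits(w, "sequence_window"), client_count %in% c(1L, 2L))
  lc8_sequence <- assert_aa(lc8_sequence, "lc8_sequence")
  base <- sprintf("%s_%d_%d_%dc%s", w$protein_id, w$start, w$end,
                  client_count, if (w$is_mutant) "_AAA" else "")
  seqs <- c(rep(lc8_sequence, 2L), rep(w$sequence, client_count))
  ids <- c(paste0(base, "_LC8_A"), paste0(base, "_LC8_B"),
           paste0(base, "_client_", seq_len(client_count)))
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
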