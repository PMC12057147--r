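#' LC8 (human DYNLL1) reference sequence
#'
#' The 89-residue sequence of human dynein light chain LC8 (DYNLL1,
#' UniProt P63167), used by default when writing prediction inputs and when
#' generating synthetic fixtures. The ortholog actually paired with each
#' client is configurable everywhere this constant is consumed and is
#' recorded in run metadata.
#'
#' @return A single character string of length 89.
#' @export
#' @examples
#' nchar(lc8_sequence())       # 89
#' substr(lc8_sequence(), 63, 63)  # "G", the anchor landmark G63
lc8_sequence <- function() {
  "MCDRKAVIKNADMSEEMQQDSVECATQALEKYNIEKDIAAHIKKEFDKKYNPTWHCIVGRNFGSYVTHETKHFIYFYLGQVAILLFKSG"
}

#' Default LC8 beta3 residue span
#'
#' Residues (1-based LC8 numbering) taken as the beta3 strand that pairs with
#' the incoming client strand. LC8 numbering places the anchor landmark at
#' G63; the default span 60-67 brackets it. Configurable in every function
#' that consumes it because published structures delimit beta3 slightly
#' differently.
#'
#' @return Integer vector of residue numbers.
#' @export
lc8_beta3_residues <- function() 60:67

# residue number (1-based, LC8 numbering) of the glycine used to define
# anchor position 0 of the client motif
LC8_G63 <- 63L

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# PAE values are bounded by the predictor's binning scheme
PAE_MAX <- 31.5

assert_aa <- function(sequence, what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-amino-acid characters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(toupper(sequence))
}
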