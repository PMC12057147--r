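# Builders for small hand-specified structure models used across tests.

# a model with explicit per-chain coordinates and an optionally explicit PAE
make_model <- function(chains, pae = NULL, plddt = NULL,
                       ptm = 0.8, iptm = 0.9, rank = 1L) {
  ns <- vapply(chains, nrow, integer(1))
  n <- sum(ns)
  if (is.null(pae)) pae <- matrix(5, n, n)
  if (is.null(plddt)) plddt <- rep(80, n)
  layout <- data.frame(chain_id = names(chains), n = unname(ns),
                       stringsAsFactors = FALSE)
  structure_model(rank = rank, plddt = plddt, pae = pae, ptm = ptm,
                  iptm = iptm, chain_layout = layout,
                  coords = do.call(rbind, unname(chains)))
}

# idealized LC8 dimer traces matching the synthetic generator's geometry
lc8_dimer_chains <- function(spacing = 3.8, gap = 4.9) {
  n <- nchar(lc8_sequence())
  i <- seq_len(n)
  list(A = cbind(spacing * i, 0, 0), B = cbind(spacing * i, gap, 0))
}

# client chain of length L whose residue `anchor` sits over LC8 residue 63
client_chain <- function(L, anchor, z = 3.0, y = 2.45, spacing = 3.8) {
  j <- seq_len(L)
  cbind(spacing * (63 + j - anchor), y, z)
}

# a ten-column score-vector row that passes every cut of a threshold set by
# the given margin (positive margin = pass side)
vector_passing <- function(thresholds, margin = 0.01) {
  cuts <- stats::setNames(thresholds$cut, thresholds$parameter)
  dirs <- stats::setNames(thresholds$direction, thresholds$parameter)
  out <- as.data.frame(as.list(ifelse(dirs == "gt", cuts + margin, cuts - margin)))
  names(out) <- names(cuts)
  out
}
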