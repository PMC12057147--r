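# Qualitative Bayesian evidence ledger: per-evidence log-odds in decibels
# for pairwise hypothesis comparisons, additive totals with priors, and
# derived third comparisons.
#
# A decibel here is 10 * log10 of a likelihood ratio; independent evidence
# adds, and a prior enters as one more additive offset.

#' Construct an evidence ledger
#'
#' Long-format table of per-evidence log-odds contributions: one row per
#' (evidence item, hypothesis comparison) pair.
#'
#' @param id Evidence identifiers (e.g. `"E1"`).
#' @param comparison Pairwise comparison names (e.g. `"Hn/Hs"`); a name like
#'   `"A/B"` means the log-odds of hypothesis A over hypothesis B.
#' @param db Contribution in decibels (may be negative).
#' @param description Optional free-text description per row.
#' @return data.frame of class `evidence_ledger`.
#' @export
evidence_ledger <- function(id, comparison, db, description = "") {
  db <- as.numeric(db)
  stopifnot(all(is.finite(db)))
  out <- data.frame(id = as.character(id), comparison = as.character(comparison),
                    db = db, description = rep_len(description, length(db)),
                    stringsAsFactors = FALSE)
  class(out) <- c("evidence_ledger", "data.frame")
  out
}

#' Read an evidence ledger from CSV or YAML
#'
#' CSV needs columns `id`, `comparison`, `db` (and optionally
#' `description`); YAML is a list of items each with `id`, `description`,
#' and a `contributions` map from comparison name to dB value.
#'
#' @param path File path; format chosen by extension.
#' @return An [evidence_ledger()].
#' @export
read_evidence_ledger <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    items <- yaml::read_yaml(path)
    rows <- lapply(items, function(it) {
      data.frame(id = it$id,
                 comparison = names(it$contributions),
                 db = as.numeric(unlist(it$contributions)),
                 description = if (is.null(it$description)) "" else it$description,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.null(df$description)) df$description <- ""
  }
  evidence_ledger(df$id, df$comparison, df$db, df$description)
}

#' The packaged example evidence ledger
#'
#' Nine evidence items (E1-E9) weighing three hypotheses about what the
#' structure predictor learned: Hs (pure structural memorization), Hn (the
#' natural energy function), Hi (an inaccurate energy function sharing the
#' natural minima), scored pairwise as Hn/Hs and Hi/Hs in decibels.
#'
#' @return An [evidence_ledger()].
#' @export
example_evidence_ledger <- function() {
  read_evidence_ledger(system.file("extdata", "evidence_ledger.csv",
                                   package = "lc8screen", mustWork = TRUE))
}

#' Total log-odds of a comparison
#'
#' Sum of every evidence contribution for the comparison plus the prior.
#' Evidence items that never mention the comparison contribute 0, with a
#' warning.
#'
#' @param ledger An [evidence_ledger()].
#' @param comparison Comparison name.
#' @param prior_db Prior log-odds in decibels (default 0, i.e. indifferent).
#' @return Total in decibels.
#' @export
ledger_total <- function(ledger, comparison, prior_db = 0) {
  rows <- ledger[ledger$comparison == comparison, , drop = FALSE]
  missing <- setdiff(unique(ledger$id), rows$id)
  if (length(missing) > 0L) {
    warning(sprintf("items with no '%s' contribution treated as 0 dB: %s",
                    comparison, paste(missing, collapse = ", ")))
  }
  prior_db + sum(rows$db)
}

#' Derive a third comparison by subtraction
#'
#' Given totals for A/B and C/B (a shared base hypothesis B), the A/C
#' log-odds is their difference.
#'
#' @param comparison_ab,comparison_cb Totals in decibels.
#' @return `comparison_ab - comparison_cb`, in decibels.
#' @export
#' @examples
#' derive_comparison(86, -3)  # Hi/Hn = 89 dB from Hi/Hs and Hn/Hs
derive_comparison <- function(comparison_ab, comparison_cb) {
  comparison_ab - comparison_cb
}

#' Totals report for every comparison in a ledger
#'
#' @param ledger An [evidence_ledger()].
#' @param priors Named numeric vector of priors in decibels, e.g.
#'   `c("Hn/Hs" = -45, "Hi/Hs" = -30)`; unnamed comparisons get 0.
#' @return data.frame with columns `comparison`, `evidence_db`, `prior_db`,
#'   `total_db` (values are exact sums; round only for display).
#' @export
ledger_report <- function(ledger, priors = numeric(0)) {
  comps <- unique(ledger$comparison)
  rows <- lapply(comps, function(cmp) {
    ev <- sum(ledger$db[ledger$comparison == cmp])
    pr <- if (cmp %in% names(priors)) priors[[cmp]] else 0
    data.frame(comparison = cmp, evidence_db = ev, prior_db = pr,
               total_db = ev + pr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
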