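# Correlating prediction scores with measured binding affinities, and
# predicting rough dissociation constants for new sites.

#' Build an affinity record table
#'
#' @param motif Character vector of 8-residue binding motifs.
#' @param anchor_class `"TQT"` or `"notTQT"`, per motif.
#' @param kd Dissociation constants in micromolar (> 0, finite).
#' @return data.frame of class `affinity_records`.
#' @export
affinity_records <- function(motif, anchor_class, kd) {
  motif <- toupper(motif)
  if (any(nchar(motif) != 8L)) stop("motifs must be 8 residues long", call. = FALSE)
  for (m in motif) assert_aa(m, "motif")
  if (!all(anchor_class %in% c("TQT", "notTQT"))) {
    stop("anchor_class must be TQT or notTQT", call. = FALSE)
  }
  kd <- as.numeric(kd)
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be finite and > 0",
                                                call. = FALSE)
  out <- data.frame(motif = motif, anchor_class = anchor_class, kd = kd,
                    stringsAsFactors = FALSE)
  class(out) <- c("affinity_records", "data.frame")
  out
}

#' Join prediction windows to known-affinity motifs
#'
#' A row is joined to a record whenever the record's 8-mer occurs as a
#' substring of the row's client window sequence. One record may match many
#' windows (and so appear multiple times), and windows matching no record
#' are dropped.
#'
#' @param table data.frame with a `sequence` column (e.g. linked score
#'   vectors or a window manifest).
#' @param records An [affinity_records()] table.
#' @return The joined data.frame with added columns `motif`, `anchor_class`,
#'   `kd`, and `len` (client window length).
#' @export
match_affinities <- function(table, records) {
  hits <- lapply(seq_len(nrow(records)), function(i) {
    idx <- which(grepl(records$motif[i], table$sequence, fixed = TRUE))
    if (length(idx) == 0L) return(NULL)
    out <- table[idx, , drop = FALSE]
    out$motif <- records$motif[i]
    out$anchor_class <- records$anchor_class[i]
    out$kd <- records$kd[i]
    out
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- cbind(table[0, , drop = FALSE],
                 data.frame(motif = character(0), anchor_class = character(0),
                            kd = numeric(0)))
  }
  out$len <- nchar(out$sequence)
  rownames(out) <- NULL
  out
}

# per-structure ten-parameter vectors for a linked run pair, matched by rank
structure_vectors <- function(one_run, two_run, ...) {
  s1 <- score_run(one_run, ...)
  s2 <- score_run(two_run, ...)
  n <- min(nrow(s1), nrow(s2))
  out <- data.frame(rank = seq_len(n))
  for (p in SCORE_PARAMS) {
    out[[paste0(p, "_1c")]] <- s1[[p]][seq_len(n)]
    out[[paste0(p, "_2c")]] <- s2[[p]][seq_len(n)]
  }
  out
}

#' Fraction of a run's structures that pass a threshold set
#'
#' Structures of the linked one-client and two-client runs are paired by
#' rank to form per-structure ten-parameter vectors; the success rate is the
#' fraction of those vectors classified as binders. Its logarithm behaves
#' like a pseudo binding free energy.
#'
#' @param one_run,two_run Linked [prediction_run()]s (1-client, 2-client).
#' @param thresholds A [threshold_set()].
#' @param ... Passed to [score_run()].
#' @return A fraction in \[0, 1\].
#' @export
success_rate <- function(one_run, two_run, thresholds = thresholds_exclusive(),
                         ...) {
  sv <- structure_vectors(one_run, two_run, ...)
  if (nrow(sv) == 0L) stop("empty run", call. = FALSE)
  mean(classify(sv, thresholds) == "binder")
}

#' The 21 per-prediction scoring metrics
#'
#' Best-structure and across-structure-average values of the five interface
#' scores, for the 1-client and the 2-client run (20 metrics), plus the
#' success rate against a threshold set (1 metric). "Best" rows are selected
#' by binding-interface pLDDT, as in [select_best()].
#'
#' @inheritParams success_rate
#' @return One-row data.frame with columns `<param>_<1c|2c>_best`,
#'   `<param>_<1c|2c>_avg`, `success_rate`, and `n_structures`.
#' @export
metric_table <- function(one_run, two_run, thresholds = thresholds_exclusive(),
                         ...) {
  out <- data.frame(row.names = 1L)
  for (side in list(list(run = one_run, sfx = "1c"),
                    list(run = two_run, sfx = "2c"))) {
    tab <- score_run(side$run, ...)
    best <- tab[order(-tab$plddt, tab$rank)[1L], , drop = FALSE]
    for (p in SCORE_PARAMS) {
      out[[paste0(p, "_", side$sfx, "_best")]] <- best[[p]]
      out[[paste0(p, "_", side$sfx, "_avg")]] <- mean(tab[[p]])
    }
  }
  out$success_rate <- success_rate(one_run, two_run, thresholds, ...)
  out$n_structures <- min(length(one_run$structures), length(two_run$structures))
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit of affinity on a score
#'
#' Fits Kd (micromolar, linear scale) on a single score by OLS and reports
#' the coefficient of determination, the root-mean-square error of the
#' residuals, and the two-sided p-value for a non-zero slope.
#'
#' @param x Numeric predictor (a scoring metric).
#' @param y Numeric response (Kd in micromolar).
#' @return List of class `fit_result`: `slope`, `intercept`, `r2`, `rmse`,
#'   `p`, `n`.
#' @export
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r2 = sm$r.squared,
         rmse = sqrt(mean(stats::residuals(fit)^2)),
         p = sm$coefficients[2L, 4L],
         n = length(x)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n=%d  Kd = %.4g + %.4g * score  R2=%.3f RMSE=%.3g p=%.3g\n",
              x$n, x$intercept, x$slope, x$r2, x$rmse, x$p))
  invisible(x)
}

#' Multiple-testing adjustment of p-values
#'
#' @param ps Numeric vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` (min(1, m p)) or `"benjamini_hochberg"`
#'   (step-up adjusted values).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(ps, method = c("bonferroni", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]",
                                               call. = FALSE)
  stats::p.adjust(ps, method = if (method == "bonferroni") "bonferroni" else "BH")
}

#' Grid of affinity fits across scoring metrics
#'
#' Runs [linear_fit()] of Kd on each listed metric column and attaches
#' Bonferroni and Benjamini-Hochberg corrected p-values computed across the
#' whole grid.
#'
#' @param joined Output of [match_affinities()] carrying metric columns and
#'   `kd`.
#' @param metrics Metric column names (default: every `_best`/`_avg` column
#'   present plus `success_rate`).
#' @return data.frame with one row per metric: `metric`, `slope`,
#'   `intercept`, `r2`, `rmse`, `p`, `p_bonferroni`, `p_bh`, `n`.
#' @export
fit_grid <- function(joined, metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- grep("(_best|_avg)$|^success_rate$", names(joined), value = TRUE)
  }
  rows <- lapply(metrics, function(m) {
    f <- tryCatch(linear_fit(joined[[m]], joined$kd), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(metric = m, slope = f$slope, intercept = f$intercept,
               r2 = f$r2, rmse = f$rmse, p = f$p, n = f$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out) > 0L) {
    out$p_bonferroni <- adjust_pvalues(out$p, "bonferroni")
    out$p_bh <- adjust_pvalues(out$p, "benjamini_hochberg")
  }
  out
}

#' Pseudo dissociation constant from bound/unbound structure counts
#'
#' Treats a prediction's structure set as a toy equilibrium of `n_total`
#' molecules: pseudo-Kd = (#unbound)^2 / #bound. With no bound structures
#' the quantity is undefined and `NA` is returned.
#'
#' @param n_bound Structures classified as bound.
#' @param n_total Total structures (> 0).
#' @return Numeric pseudo-Kd, or `NA` when `n_bound` is 0.
#' @export
pseudo_kd <- function(n_bound, n_total) {
  stopifnot(n_total > 0, n_bound >= 0, n_bound <= n_total)
  if (n_bound == 0) return(NA_real_)
  (n_total - n_bound)^2 / n_bound
}

#' Anchor-class affinity models
#'
#' The shipped linear inversions mapping a score to a predicted Kd:
#' for TQT-anchored sites, Kd = (best 1-client dimer PAE - 0.89) / 0.0035;
#' for any other anchor, Kd = (mean across structures of the 1-client
#' PtoL PAE - 4.45) / 0.135.
#'
#' @param anchor_class `"TQT"` or `"notTQT"`.
#' @return List with `predictor` (metric column name), `intercept`, `slope`.
#' @export
affinity_model <- function(anchor_class = c("TQT", "notTQT")) {
  anchor_class <- match.arg(anchor_class)
  if (anchor_class == "TQT") {
    list(predictor = "dimer_1c_best", intercept = 0.89, slope = 0.0035)
  } else {
    list(predictor = "ptol_1c_avg", intercept = 4.45, slope = 0.135)
  }
}

#' Predict a rough binding affinity for a site
#'
#' Applies the anchor-class [affinity_model()] to the appropriate scoring
#' metric. The linear inversion inevitably goes negative for the
#' best-scoring sites; predictions below 1 micromolar are floored at 1
#' micromolar, the resolution limit of these rough models.
#'
#' @param scores Named list or one-row data.frame holding the model's
#'   predictor metric (see [affinity_model()]), or a single number taken as
#'   the predictor value.
#' @param anchor_class `"TQT"` or `"notTQT"`.
#' @return Predicted Kd in micromolar (>= 1).
#' @export
#' @examples
#' predict_affinity(1.03, "TQT")  # (1.03 - 0.89) / 0.0035 = 40
#' predict_affinity(0.50, "TQT")  # negative raw value -> 1
predict_affinity <- function(scores, anchor_class = c("TQT", "notTQT")) {
  anchor_class <- match.arg(anchor_class)
  model <- affinity_model(anchor_class)
  x <- if (is.numeric(scores) && length(scores) == 1L && is.null(names(scores))) {
    scores
  } else {
    v <- scores[[model$predictor]]
    if (is.null(v) || is.na(v)) {
      stop(sprintf("missing predictor '%s'", model$predictor), call. = FALSE)
    }
    v
  }
  raw <- (x - model$intercept) / model$slope
  max(raw, 1)
}

#' Filter predicted binding sites
#'
#' Drops candidate sites whose predicted affinity exceeds `kd_max`
#' (extrapolation beyond the calibrated range) and sites whose anchor falls
#' inside a structured domain (LC8 binds only disordered regions). Intervals
#' are 0-based half-open on protein coordinates.
#'
#' @param sites data.frame with columns `protein_id`, `anchor_pos` (0-based
#'   protein coordinate of the anchor) and `predicted_kd` (micromolar);
#'   other columns (e.g. the admitting threshold set) pass through.
#' @param structured data.frame of structured-domain intervals with columns
#'   `protein_id`, `start`, `end`; may be empty or `NULL`.
#' @param kd_max Affinity cutoff in micromolar (default 40).
#' @return The retained subset of `sites`.
#' @export
filter_predictions <- function(sites, structured = NULL, kd_max = 40) {
  keep <- sites$predicted_kd <= kd_max
  if (!is.null(structured) && nrow(structured) > 0L) {
    if (any(structured$end <= structured$start)) {
      stop("malformed interval: end <= start", call. = FALSE)
    }
    in_domain <- vapply(seq_len(nrow(sites)), function(i) {
      any(structured$protein_id == sites$protein_id[i] &
            structured$start <= sites$anchor_pos[i] &
            sites$anchor_pos[i] < structured$end)
    }, logical(1))
    keep <- keep & !in_domain
  }
  sites[keep, , drop = FALSE]
}

#' Select a homogeneous sub-dataset
#'
#' Filters a joined affinity table with a small expression over anchor class
#' and client window length, the selectors used to build homogeneous
#' sub-datasets: `"TQT"`, `"!TQT"`, `"len=14"`, `"len!=12"`, combined with
#' `&` (AND) and `||` (OR), e.g. `"TQT&len=14"` or `"TQT&len!=12||14"`
#' (length neither 12 nor 14).
#'
#' @param joined data.frame with columns `anchor_class` and `len`.
#' @param expr Selector expression; `""` or `"full"` keeps everything.
#' @return The matching rows.
#' @export
subset_affinity <- function(joined, expr) {
  expr <- gsub(" ", "", expr)
  if (expr == "" || tolower(expr) == "full") return(joined)
  term_mask <- function(term) {
    if (term == "TQT") return(joined$anchor_class == "TQT")
    if (term == "!TQT") return(joined$anchor_class != "TQT")
    m <- regmatches(term, regexec("^len(!?=)([0-9|]+)$", term))[[1]]
    if (length(m) == 0L) {
      m <- regmatches(term, regexec("^(<)([0-9]+)$", term))[[1]]
      if (length(m) == 3L) return(joined$len < as.integer(m[3]))
      stop(sprintf("cannot parse selector term '%s'", term), call. = FALSE)
    }
    lens <- as.integer(strsplit(m[3], "||", fixed = TRUE)[[1]])
    hit <- joined$len %in% lens
    if (m[2] == "!=") !hit else hit
  }
  mask <- Reduce(`&`, lapply(strsplit(expr, "&", fixed = TRUE)[[1]], term_mask))
  joined[mask, , drop = FALSE]
}
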