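test_that("affinity records join to windows by 8-mer substring", {
  rec <- affinity_records(c("SRGTQTEM", "DKSTQTDV"), c("TQT", "TQT"), c(2, 30))
  tab <- data.frame(sequence = c("AASRGTQTEMAVSGLK",  # contains record 1
                                 "AAAAAAAAAAAAAAAA",  # no match
                                 "PPSRGTQTEMPPPPPP"), # contains record 1 again
                    stringsAsFactors = FALSE)
  joined <- match_affinities(tab, rec)
  expect_equal(nrow(joined), 2)
  expect_equal(unique(joined$motif), "SRGTQTEM")
  expect_equal(joined$len, c(16, 16))

  expect_equal(nrow(match_affinities(tab[2, , drop = FALSE], rec)), 0)
  expect_error(affinity_records("SHORT", "TQT", 1), "8 residues")
  expect_error(affinity_records("SRGTQTEM", "TQT", -1), "finite and > 0")
})

test_that("linear_fit matches the normal equations and flags degeneracy", {
  # exact line (lm warns about the perfect fit; the fit itself is the point)
  x <- c(1, 2, 3, 4); y <- 2 * x + 1
  f <- suppressWarnings(linear_fit(x, y))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_equal(f$rmse, 0, tolerance = 1e-12)

  # 4-point toy set vs normal-equation oracle
  x2 <- c(0.5, 1.7, 3.1, 4.0); y2 <- c(2.2, 1.1, 5.9, 4.4)
  f2 <- linear_fit(x2, y2)
  o <- oracle_ols(x2, y2)
  expect_equal(f2$slope, unname(o["slope"]))
  expect_equal(f2$intercept, unname(o["intercept"]))

  # independent response: r2 near 0 at large n
  set.seed(4)
  xr <- runif(5000); yr <- rnorm(5000)
  expect_lt(linear_fit(xr, yr)$r2, 0.01)

  expect_error(linear_fit(c(1, 1, 1), c(1, 2, 3)), "degenerate predictor")
  expect_error(linear_fit(1:2, 1:2), "at least 3")
})

test_that("p-value adjustment follows Bonferroni and BH step-up", {
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "benjamini_hochberg"), 0.03)
  # hand-computed BH step-up: p_(i) * m / i, then enforce monotonicity
  ps <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(ps, "benjamini_hochberg"),
               c(0.04, 0.04, 0.04, 0.04))
  ps2 <- c(0.001, 0.02, 0.1, 0.9)
  expect_equal(adjust_pvalues(ps2, "benjamini_hochberg"),
               pmin(1, cummax(rev(cummin(rev(ps2 * 4 / 1:4))))))
  expect_true(all(adjust_pvalues(ps2, "bonferroni") >= ps2))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pseudo-Kd handles its boundary cases", {
  expect_equal(pseudo_kd(25, 50), 25)
  expect_true(is.na(pseudo_kd(0, 50)))
  expect_equal(pseudo_kd(50, 50), 0)
  expect_error(pseudo_kd(5, 0))
})

test_that("affinity prediction applies the anchor-class inversions and floor", {
  # TQT model: (x - 0.89) / 0.0035
  expect_equal(predict_affinity(1.03, "TQT"), (1.03 - 0.89) / 0.0035)
  expect_equal(predict_affinity(1.03, "TQT"), 40)
  # negative raw value floors at 1
  expect_equal(predict_affinity(0.50, "TQT"), 1)
  # notTQT model: (x - 4.45) / 0.135
  expect_equal(predict_affinity(5.80, "notTQT"), 10)

  # named-score interface picks the model's predictor column
  row <- data.frame(dimer_1c_best = 1.03, ptol_1c_avg = 5.80)
  expect_equal(predict_affinity(row, "TQT"), 40)
  expect_equal(predict_affinity(row, "notTQT"), 10)
  expect_error(predict_affinity(data.frame(other = 1), "TQT"), "missing predictor")
})

test_that("site filtering drops weak and structured-domain predictions", {
  sites <- data.frame(protein_id = "p", anchor_pos = c(100, 200, 300, 400),
                      predicted_kd = c(50, 15, 15, 40))
  structured <- data.frame(protein_id = "p", start = 250, end = 350)
  kept <- filter_predictions(sites, structured)
  # 50 uM dropped (over 40), anchor 300 dropped (inside [250,350)), 40 kept
  expect_equal(kept$anchor_pos, c(200, 400))
  # interval bounds are half-open
  edge <- data.frame(protein_id = "p", anchor_pos = c(250, 350),
                     predicted_kd = c(10, 10))
  expect_equal(filter_predictions(edge, structured)$anchor_pos, 350)
  # no structured intervals: only the affinity rule applies
  expect_equal(nrow(filter_predictions(sites, NULL)), 3)
  expect_error(filter_predictions(sites,
                                  data.frame(protein_id = "p", start = 5, end = 5)),
               "malformed interval")
  # output is always a subset of input
  expect_true(all(kept$anchor_pos %in% sites$anchor_pos))
})

test_that("metric table carries 21 metrics matching hand arithmetic", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_run_dir(fixture_config(n_structures = 2, client_count = 1,
                             plddt = c(92, 88), ltop = c(3, 5), ptol = c(5, 7),
                             dimer = c(1.0, 1.2), ptm = c(0.8, 0.7),
                             iptm = c(0.9, 0.8)), d1)
  gen_run_dir(fixture_config(n_structures = 2, client_count = 2,
                             plddt = c(97, 93), ltop = c(2, 4), ptol = c(4, 6),
                             dimer = c(0.8, 1.0), ptm = c(0.85, 0.75),
                             iptm = c(0.95, 0.85)), d2)
  one <- parse_run_dir(d1); two <- parse_run_dir(d2)
  mt <- metric_table(one, two)

  metric_cols <- grep("(_best|_avg)$|^success_rate$", names(mt), value = TRUE)
  expect_length(metric_cols, 21)
  # best by interface pLDDT; averages over both structures
  expect_equal(mt$plddt_1c_best, 92)
  expect_equal(mt$ltop_1c_best, 3)
  expect_equal(mt$ltop_1c_avg, 4)
  expect_equal(mt$conf_1c_best, 0.2 * 0.8 + 0.8 * 0.9)
  expect_equal(mt$conf_1c_avg, mean(c(0.88, 0.78)))
  expect_equal(mt$dimer_2c_avg, 0.9)
  expect_equal(mt$plddt_2c_best, 97)
  # constant-score run: best equals average
  d3 <- withr::local_tempdir(); d4 <- withr::local_tempdir()
  gen_run_dir(fixture_config(n_structures = 3, client_count = 1), d3)
  gen_run_dir(fixture_config(n_structures = 3, client_count = 2), d4)
  mt2 <- metric_table(parse_run_dir(d3), parse_run_dir(d4))
  for (p in c("conf", "plddt", "ltop", "ptol", "dimer")) {
    expect_equal(mt2[[paste0(p, "_1c_best")]], mt2[[paste0(p, "_1c_avg")]])
  }
})

test_that("success rate is the fraction of rank-paired structures passing", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  # two good structures, one hopeless (fails every cut on the 1c side)
  gen_run_dir(fixture_config(n_structures = 3, client_count = 1,
                             plddt = c(96, 96, 5), ltop = c(2, 2, 30),
                             ptol = c(4, 4, 30), dimer = c(0.8, 0.8, 10),
                             ptm = c(0.9, 0.85, 0.3), iptm = c(0.95, 0.9, 0.2)),
              d1)
  gen_run_dir(fixture_config(n_structures = 3, client_count = 2,
                             plddt = 96, ltop = 2, ptol = 4, dimer = 0.8,
                             ptm = c(0.9, 0.85, 0.8), iptm = c(0.95, 0.9, 0.85)),
              d2)
  one <- parse_run_dir(d1); two <- parse_run_dir(d2)
  sr <- success_rate(one, two, thresholds_exclusive())
  expect_equal(sr, 2 / 3)

  # tightening any threshold never increases the success rate
  t0 <- thresholds_exclusive()
  for (k in seq_len(10)) {
    tight <- t0
    tight$cut[k] <- tight$cut[k] + if (tight$direction[k] == "gt") 1 else -0.5
    expect_lte(success_rate(one, two, tight), sr)
  }
})

test_that("sub-dataset selectors parse anchor class and length filters", {
  df <- data.frame(anchor_class = c("TQT", "TQT", "notTQT", "notTQT"),
                   len = c(14, 16, 16, 12))
  expect_equal(nrow(subset_affinity(df, "full")), 4)
  expect_equal(nrow(subset_affinity(df, "TQT")), 2)
  expect_equal(nrow(subset_affinity(df, "!TQT")), 2)
  expect_equal(subset_affinity(df, "TQT&len=14")$len, 14)
  expect_equal(nrow(subset_affinity(df, "len!=12||14")), 2)
  expect_equal(subset_affinity(df, "len=12||14")$len, c(14, 12))
  expect_equal(subset_affinity(df, "<16")$len, c(14, 12))
  expect_error(subset_affinity(df, "bogus=1"), "cannot parse")
})
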