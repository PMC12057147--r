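test_that("directional PAE averages the requested block, directionally", {
  pae <- matrix(5, 4, 4)
  expect_equal(directional_pae(pae, 1:2, 3:4), 5)
  expect_equal(directional_pae(pae, 3:4, 1:2), 5)

  # asymmetric blocks: rows 1-2 -> cols 3-4 mean 2, transpose mean 7
  pae2 <- matrix(0, 4, 4)
  pae2[1:2, 3:4] <- c(1, 3, 2, 2)   # mean 2
  pae2[3:4, 1:2] <- c(6, 8, 7, 7)   # mean 7
  expect_equal(directional_pae(pae2, 1:2, 3:4), 2)
  expect_equal(directional_pae(pae2, 3:4, 1:2), 7)

  expect_error(directional_pae(pae, integer(0), 3:4), "no interface")
  expect_error(directional_pae(pae, 1:2, 2:3), "disjoint")
})

test_that("bound region matches brute-force distances on synthetic geometry", {
  ch <- lc8_dimer_chains()
  ch$C <- client_chain(16, anchor = 8)
  m <- make_model(ch)
  got <- find_bound_region(m, "C")
  # oracle: plain double loop over client x beta3 C-alpha pairs
  b3_coords <- rbind(ch$A[lc8_beta3_residues(), ], ch$B[lc8_beta3_residues(), ])
  expected <- integer(0)
  for (j in seq_len(nrow(ch$C))) {
    for (k in seq_len(nrow(b3_coords))) {
      if (sqrt(sum((ch$C[j, ] - b3_coords[k, ])^2)) <= 8) {
        expected <- union(expected, j)
        break
      }
    }
  }
  expect_equal(got, sort(expected))
  expect_true(length(got) > 0)

  # displaced client -> empty set; zero cutoff -> empty set
  ch$C <- client_chain(16, anchor = 8, z = 50)
  m_far <- make_model(ch)
  expect_length(find_bound_region(m_far, "C"), 0)
  expect_length(find_bound_region(m, "C", cutoff = 0), 0)
  expect_error(find_bound_region(m, "Z"), "unknown chain")
})

test_that("anchor is the client residue nearest G63, ties to lower index", {
  ch <- lc8_dimer_chains()
  ch$C <- client_chain(16, anchor = 7)
  expect_equal(find_anchor(make_model(ch), "C"), 7)

  # exact tie: residues 4 and 5 equidistant from G63 of chain A
  g63 <- ch$A[63, ]
  tie <- matrix(rep(c(200, 0, 50), each = 10), ncol = 3)  # all far away
  tie[4, ] <- g63 + c(-2, 3, 0)
  tie[5, ] <- g63 + c(2, 3, 0)
  ch$C <- tie
  expect_equal(find_anchor(make_model(ch), "C"), 4)

  # single-residue client
  ch$C <- matrix(g63 + c(0, 3, 0), ncol = 3)
  expect_equal(find_anchor(make_model(ch), "C"), 1)
})

test_that("dimer interface PAE averages contacting pairs both ways", {
  ch <- lc8_dimer_chains()
  ch$C <- client_chain(16, anchor = 8)
  n <- sum(vapply(ch, nrow, integer(1)))

  pae <- matrix(10, n, n)
  ra <- 1:86; rb <- 89 + (1:86)  # C-terminal 3 excluded
  for (i in ra) for (j in rb) {
    if (sqrt(sum((rbind(ch$A, ch$B)[i, ] - rbind(ch$A, ch$B)[j, ])^2)) <= 8) {
      pae[i, j] <- 0.9; pae[j, i] <- 1.1
    }
  }
  m <- make_model(ch, pae = pae)
  expect_equal(dimer_interface_pae(m), 1.0)

  # separated protomers
  ch2 <- ch
  ch2$B <- ch2$B + matrix(rep(c(0, 100, 0), each = 89), ncol = 3)
  expect_error(dimer_interface_pae(make_model(ch2)), "not in contact")
})

test_that("structure scores equal configured block means, incl. 2-client averaging", {
  d <- withr::local_tempdir()
  gen_run_dir(fixture_config(n_structures = 1, plddt = 90, ltop = 3,
                             ptol = 7, dimer = 1.05), d)
  s <- score_structure(parse_run_dir(d)$structures[[1]])
  expect_equal(s$avg_plddt_bind, 90)
  expect_equal(s$pae_ltop, 3)
  expect_equal(s$pae_ptol, 7)
  expect_equal(s$pae_dimer, 1.05)
  expect_false(s$unbound)

  # 2-client grooves averaged: hand-average of per-groove means
  d2 <- withr::local_tempdir()
  gen_run_dir(fixture_config(n_structures = 1, client_count = 2), d2)
  run2 <- parse_run_dir(d2)
  m2 <- run2$structures[[1]]
  s2 <- score_structure(m2)
  expect_length(s2$bound_region, 2)
  # asymmetric pLDDT: groove C client residues at 80, groove D at 90, all
  # LC8 residues (incl. the full beta3 spans, which contact both grooves
  # by construction) at 85
  rows_C <- 2 * 89 + s2$bound_region$C
  rows_D <- 2 * 89 + 16 + s2$bound_region$D
  plddt <- m2$plddt
  plddt[] <- 85
  plddt[rows_C] <- 80; plddt[rows_D] <- 90
  m3 <- m2; m3$plddt <- plddt
  s3 <- score_structure(m3)
  n_b3 <- length(lc8_beta3_residues()) * 2
  groove_C <- mean(c(rep(80, length(rows_C)), rep(85, n_b3)))
  groove_D <- mean(c(rep(90, length(rows_D)), rep(85, n_b3)))
  expect_equal(s3$avg_plddt_bind, mean(c(groove_C, groove_D)))

  # unbound structures are scored and flagged, not dropped
  d3 <- withr::local_tempdir()
  gen_run_dir(fixture_config(n_structures = 1, bound = FALSE,
                             plddt = 55, ltop = 14, ptol = 16), d3)
  s4 <- score_structure(parse_run_dir(d3)$structures[[1]])
  expect_true(s4$unbound)
  expect_equal(s4$avg_plddt_bind, 55)
  expect_equal(s4$pae_ltop, 14)
})

test_that("best structure maximizes interface pLDDT with rank tiebreak", {
  d <- withr::local_tempdir()
  gen_run_dir(fixture_config(n_structures = 3, plddt = c(70, 95, 80),
                             ptm = c(0.9, 0.8, 0.7), iptm = c(0.9, 0.8, 0.7)), d)
  run <- parse_run_dir(d)
  expect_equal(select_best(run)$rank, 2)  # the plddt-95 structure

  d2 <- withr::local_tempdir()
  gen_run_dir(fixture_config(n_structures = 2, plddt = c(90, 90),
                             ptm = c(0.9, 0.8), iptm = c(0.9, 0.8)), d2)
  expect_equal(select_best(parse_run_dir(d2))$rank, 1)

  d3 <- withr::local_tempdir()
  gen_run_dir(fixture_config(n_structures = 1), d3)
  run3 <- parse_run_dir(d3)
  expect_equal(select_best(run3)$rank, run3$structures[[1]]$rank)
})

test_that("linking joins matched windows and reports orphans", {
  mk_run <- function(start, clients, mutant = FALSE, dir) {
    seqs <- "ASPSRGTQTEVSAGLK"
    w <- sequence_window("p1", start, start + 16, seqs, is_mutant = mutant)
    gen_run_dir(fixture_config(n_structures = 1, client_count = clients,
                               window = w), dir)
    parse_run_dir(dir)
  }
  base <- withr::local_tempdir()
  dirs <- file.path(base, sprintf("r%d", 1:7))
  one <- list(mk_run(0, 1, dir = dirs[1]), mk_run(8, 1, dir = dirs[2]),
              mk_run(16, 1, dir = dirs[3]))
  two <- list(mk_run(0, 2, dir = dirs[4]), mk_run(8, 2, dir = dirs[5]))

  linked <- link_runs(one, two)
  expect_equal(nrow(linked), 2)
  expect_length(attr(linked, "orphans"), 1)
  expect_true(all(score_vector_params() %in% names(linked)))
  expect_false(anyNA(linked[score_vector_params()]))

  # WT and AAA variants of the same window stay distinct
  one_aaa <- c(one[1], list(mk_run(0, 1, mutant = TRUE, dir = dirs[6])))
  two_aaa <- c(two[1], list(mk_run(0, 2, mutant = TRUE, dir = dirs[7])))
  linked2 <- link_runs(one_aaa, two_aaa)
  expect_equal(nrow(linked2), 2)
  expect_equal(sort(linked2$is_mutant), c(FALSE, TRUE))

  # duplicate window on one side is ambiguous
  expect_error(link_runs(c(one[1], one[1]), two), "ambiguous link")
  # empty inputs
  expect_equal(nrow(link_runs(list(), list())), 0)

  # labels attach by window identity
  labels <- data.frame(protein_id = "p1", start = 0, end = 16,
                       is_mutant = FALSE, label = "binder")
  linked3 <- link_runs(one, two, labels = labels)
  expect_equal(linked3$label[linked3$start == 0], "binder")
  expect_equal(linked3$label[linked3$start == 8], "unknown")
})

test_that("scores are independent of structure file order", {
  d <- withr::local_tempdir()
  gen_run_dir(fixture_config(n_structures = 3, plddt = c(95, 85, 90),
                             ptm = c(0.85, 0.65, 0.75),
                             iptm = c(0.92, 0.72, 0.82)), d)
  ref <- score_run(parse_run_dir(d))
  # rename files so directory listing order is shuffled; ranks in names stay
  files <- list.files(d, pattern = "^pred_rank", full.names = TRUE)
  for (f in files) {
    file.rename(f, file.path(d, paste0("zz_", basename(f))))
  }
  again <- score_run(parse_run_dir(d))
  expect_equal(again, ref)
})
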