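test_that("DNA mass per cell matches hand arithmetic and scales in ploidy", {
  k <- ruler_constants()
  expect_equal(dna_mass_per_cell(k),
               2 * 3.1e9 * 615.8771 / 6.02214076e23, tolerance = 1e-12)
  expect_equal(dna_mass_per_cell(k) * 1e12, 6.34, tolerance = 2e-3)
  k4 <- ruler_constants(ploidy = 4)
  expect_equal(dna_mass_per_cell(k4), 2 * dna_mass_per_cell(k))
  expect_error(ruler_constants(ploidy = 0), "> 0")
})

test_that("two-protein hand example reproduces mass and copies", {
  # A: I=100, MW=50 kDa; histone H: I=50, MW=25 kDa
  qm <- toy_quant(matrix(c(100, 50), 2), "g", scale = "raw",
                  mw = c(5e4, 2.5e4), is_histone = c(FALSE, TRUE))
  ct <- estimate_copies(qm)
  m_dna <- dna_mass_per_cell(ruler_constants())
  expect_equal(ct$mass_per_cell_pg["P001", 1], m_dna * 1e12 * 100 / 50,
               tolerance = 1e-12)                       # 12.68 pg
  expect_equal(ct$copies_per_cell["P001", 1],
               (m_dna * 100 / 50) / 5e4 * 6.02214076e23,
               tolerance = 1e-12)                       # ~1.53e8
  expect_equal(ct$copies_per_cell["P001", 1] / 1.53e8, 1, tolerance = 5e-3)
})

test_that("per-sample mass conservation holds exactly", {
  sim <- simulate_atlas(sim_config(n_proteins = 400, tissue_groups = NULL,
                                   n_strict_markers_per_type = 3,
                                   n_fisher_markers_per_type = 3,
                                   n_enriched_per_type = 5, seed = 14))
  ct <- estimate_copies(sim$quant)
  x <- sim$quant$intensities
  hist <- sim$quant$proteins$is_histone
  expected <- dna_mass_per_cell(ct$constants) * 1e12 *
    colSums(x, na.rm = TRUE) / colSums(x[hist, ], na.rm = TRUE)
  expect_equal(ct$totals$total_mass_pg, unname(expected),
               tolerance = 1e-9)
})

test_that("copies are invariant to global intensity rescaling", {
  qm <- toy_quant(matrix(c(100, 7, 50), 3), "g", scale = "raw",
                  mw = c(5e4, 3e4, 2.5e4),
                  is_histone = c(FALSE, FALSE, TRUE))
  base <- estimate_copies(qm)$copies_per_cell
  for (c_ in c(1024, 3.7, 1e-6)) {
    q2 <- qm
    q2$intensities <- qm$intensities * c_
    expect_equal(estimate_copies(q2)$copies_per_cell, base,
                 tolerance = 1e-12)
  }
  # power-of-two rescaling is exact in floating point: bit identical
  q2 <- qm
  q2$intensities <- qm$intensities * 1024
  expect_identical(estimate_copies(q2)$copies_per_cell, base)
})

test_that("ruler recovers synthetic truth", {
  # zero noise: exact recovery
  sim0 <- simulate_atlas(sim_config(noise_cv = 0, mnar = FALSE, seed = 15,
                                    tissue_groups = NULL))
  ct0 <- estimate_copies(sim0$quant)
  for (s in c("hHEP_1", "hKC_3")) {
    t_ <- sim0$quant$samples$cell_type[sim0$quant$samples$sample_id == s]
    tru <- sim0$truth$true_copies[, t_]
    est <- ct0$copies_per_cell[, s]
    ok <- tru > 0
    expect_lt(max(abs(est[ok] / tru[ok] - 1)), 1e-9)
  }
  # CV 20%, no missingness: median log-ratio error within 0.15 decades
  sim <- simulate_atlas(sim_config(mnar = FALSE, seed = 16,
                                   tissue_groups = NULL))
  ct <- estimate_copies(sim$quant)
  err <- abs(log10(ct$copies_per_cell /
                     sim$truth$true_copies[, sim$quant$samples$cell_type]))
  expect_lte(median(err[is.finite(err)]), 0.15)
})

test_that("ruler validates its inputs", {
  qm <- toy_quant(matrix(c(1, 2), 2), "g", scale = "raw",
                  mw = c(1e4, 1e4), is_histone = c(FALSE, TRUE))
  expect_error(estimate_copies(log_transform(qm)), "raw")
  q2 <- qm; q2$proteins$is_histone <- FALSE
  expect_error(estimate_copies(q2), "histone")
  q3 <- qm; q3$intensities[2, 1] <- NA
  expect_error(estimate_copies(q3), "s01")
  q4 <- qm; q4$proteins$mw_da[1] <- NA
  expect_error(estimate_copies(q4), "P001")
})

test_that("group means average copies over valid replicates", {
  x <- matrix(c(10, 5, 20, 5, NA, 5), 2)   # protein1: 10,20,NA; hist const
  qm <- toy_quant(x, c("a", "a", "b"), scale = "raw",
                  mw = c(5e4, 2.5e4), is_histone = c(FALSE, TRUE))
  gm <- group_mean_copies(estimate_copies(qm))
  ct <- estimate_copies(qm)
  expect_equal(gm$copies_per_cell["P001", "a"],
               mean(ct$copies_per_cell["P001", 1:2]))
  expect_true(is.na(gm$copies_per_cell["P001", "b"]))
})

test_that("complex stoichiometry reports ratios, flags and totals", {
  ct <- toy_copy_table(matrix(c(100, 50, 400), 3, 1,
                              dimnames = list(c("P001", "P002", "P003"),
                                              "g1")))
  cx <- annotation_set(list(CPLX = c("P001", "P002", "P003")))
  st <- complex_stoichiometry(ct, cx, fold = 2)
  expect_equal(st$subunits$ratio_to_mean,
               c(100, 50, 400) / (550 / 3), tolerance = 1e-12)
  expect_identical(st$subunits$within_fold, c(TRUE, FALSE, FALSE))
  expect_equal(st$complexes$mean_copies, 550 / 3)
  expect_equal(st$complexes$total_copies, 550)
  # equal copies: all ratios 1, all within fold
  cte <- toy_copy_table(matrix(80, 3, 1,
                               dimnames = list(c("P001", "P002", "P003"),
                                               "g1")))
  ste <- complex_stoichiometry(cte, cx)
  expect_true(all(ste$subunits$ratio_to_mean == 1))
  expect_true(all(ste$subunits$within_fold))
  # pairwise ratio 80/100 = 0.8
  ctp <- toy_copy_table(matrix(c(80, 100), 2, 1,
                               dimnames = list(c("P001", "P002"), "g1")))
  stp <- complex_stoichiometry(ctp, annotation_set(list(F1 = c("P001",
                                                               "P002"))),
                               pairwise = TRUE)
  expect_equal(stp$pairs$ratio, 0.8)
  # < 2 quantified members: not evaluable, no error
  st1 <- complex_stoichiometry(ctp, annotation_set(list(solo = "P001")))
  expect_false(st1$complexes$evaluable)
  expect_null(st1$subunits)
  # ratios invariant under intensity rescaling upstream of the ruler
  qm <- toy_quant(matrix(c(100, 50, 400, 30), 4), "g", scale = "raw",
                  mw = rep(2e4, 4),
                  is_histone = c(FALSE, FALSE, FALSE, TRUE))
  cx2 <- annotation_set(list(C = c("P001", "P002", "P003")))
  r1 <- complex_stoichiometry(estimate_copies(qm), cx2)$subunits$ratio_to_mean
  qm$intensities <- qm$intensities * 17.3
  r2 <- complex_stoichiometry(estimate_copies(qm), cx2)$subunits$ratio_to_mean
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("pathway copy sums respect KEGG double counting and conserve", {
  ct <- toy_copy_table(matrix(c(10, 20, 30), 3, 1,
                              dimnames = list(c("P001", "P002", "P003"),
                                              "g1")))
  pw <- annotation_set(list(single = "P002", empty = character(0),
                            left = c("P001", "P002"), right = "P003"))
  ps <- pathway_copy_sums(ct, pw)
  expect_equal(ps$total_copies[ps$pathway == "single"], 20)
  expect_equal(ps$total_copies[ps$pathway == "empty"], 0)
  expect_equal(ps$n_members[ps$pathway == "empty"], 0)
  # disjoint partition sums to the total copies
  expect_equal(sum(ps$total_copies[ps$pathway %in% c("left", "right")]),
               ct$totals$total_copies)
})
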