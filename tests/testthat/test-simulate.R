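small_cfg <- function(...) {
  sim_config(n_proteins = 300, n_strict_markers_per_type = 3,
             n_fisher_markers_per_type = 3, n_enriched_per_type = 5,
             tissue_groups = NULL, ...)
}

test_that("generation is deterministic in (config, seed)", {
  a <- simulate_atlas(small_cfg(seed = 11))
  b <- simulate_atlas(small_cfg(seed = 11))
  expect_identical(a$quant$intensities, b$quant$intensities)
  expect_identical(a$truth$true_copies, b$truth$true_copies)
  expect_false(identical(
    a$quant$intensities,
    simulate_atlas(small_cfg(seed = 12))$quant$intensities))
  c1 <- simulate_cohort(small_cfg(seed = 11))
  c2 <- simulate_cohort(small_cfg(seed = 11))
  expect_identical(c1$quant$intensities, c2$quant$intensities)
  expect_identical(c1$truth$covariates, c2$truth$covariates)
})

test_that("zero-noise intensities reproduce copy*MW ratios exactly", {
  sim <- simulate_atlas(small_cfg(noise_cv = 0, mnar = FALSE, seed = 2))
  x <- sim$quant$intensities
  tc <- sim$truth$true_copies
  mw <- sim$truth$molecular_weights
  s <- "hHEP_2"
  pos <- which(tc[, "hHEP"] > 0)
  i <- pos[1]; j <- pos[25]
  expect_equal(unname(x[i, s] / x[j, s]),
               unname((tc[i, "hHEP"] * mw[i]) / (tc[j, "hHEP"] * mw[j])),
               tolerance = 1e-12)
})

test_that("MNAR mask follows the logistic law and is monotone", {
  sim <- simulate_atlas(sim_config(seed = 4, tissue_groups = NULL))
  pre <- sim$truth$premask_intensities
  obs <- sim$quant$intensities
  li <- log10(pre)
  mid <- sim$truth$mnar_midpoint
  slope <- sim$truth$config$mnar_slope
  hist_rows <- rownames(pre) %in% sim$truth$histone_ids
  # oracle: evaluate the logistic mask probability on the pre-mask matrix
  expect_equal(sim$truth$miss_prob[!hist_rows, ][!is.na(li[!hist_rows, ])],
               plogis((mid - li[!hist_rows, ][!is.na(li[!hist_rows, ])]) /
                        slope),
               tolerance = 1e-12)
  # low-intensity entries drop out far more often than high-intensity ones
  low <- !is.na(li) & li < mid - 2 * slope & !hist_rows
  high <- !is.na(li) & li > mid + 2 * slope & !hist_rows
  masked <- !is.na(pre) & is.na(obs)
  expect_gt(mean(masked[low]), mean(masked[high]))
  # empirical missingness non-increasing over intensity bins (with
  # binomial slack in sparse bins)
  bins <- cut(li[!is.na(li) & !hist_rows], breaks = 10)
  rate <- tapply(masked[!is.na(li) & !hist_rows], bins, mean)
  rate <- rate[!is.na(rate)]
  expect_true(all(diff(rate) <= 0.05))
  # histones are never masked
  expect_false(any(masked[hist_rows, ]))
})

test_that("planted markers are absent outside their target cell type", {
  sim <- simulate_atlas(small_cfg(seed = 6))
  tc <- sim$truth$true_copies
  types <- names(sim$truth$config$cell_types)
  for (t in types) {
    for (kind in c("strict", "fisher")) {
      ids <- sim$truth$marker_ids[[kind]][[t]]
      expect_true(all(tc[ids, t] > 0))
      expect_true(all(tc[ids, setdiff(types, t)] == 0))
      # zero copies mean zero generated intensity (missing) before masking
      cols <- sim$quant$samples$cell_type %in% setdiff(types, t)
      expect_true(all(is.na(sim$truth$premask_intensities[ids, cols])))
    }
  }
})

test_that("true copies span at least six decades with defaults", {
  for (s in 1:10) {
    tc <- simulate_atlas(sim_config(seed = s))$truth$true_copies
    v <- tc[tc[, 1] > 0, 1]
    expect_gte(dynamic_range(v), 6)
  }
})

test_that("histone mass share matches the configured fraction", {
  sim <- simulate_atlas(sim_config(seed = 9))
  tc <- sim$truth$true_copies
  mw <- sim$truth$molecular_weights
  hist <- rownames(tc) %in% sim$truth$histone_ids
  share <- colSums(tc[hist, ] * mw[hist]) / colSums(tc * mw)
  expect_equal(unname(share), rep(0.04, ncol(tc)), tolerance = 0.01 / 0.04)
})

test_that("cohort global null yields approximately standard normal t stats", {
  sim <- simulate_cohort(sim_config(n_proteins = 1500, effect_fraction = 0,
                                    mnar = FALSE, seed = 21))
  x <- log2(sim$quant$intensities)
  g <- sim$quant$samples$group
  a <- x[, g == "control"]; b <- x[, g == "NASH"]
  tstat <- apply(x, 1, function(r) {
    t.test(r[g == "control"], r[g == "NASH"], var.equal = TRUE)$statistic
  })
  expect_equal(mean(tstat), 0, tolerance = 0.08)
  expect_equal(sd(tstat), 1, tolerance = 0.08)
})

test_that("planted cohort effects average to the configured log2fc", {
  sim <- simulate_cohort(sim_config(seed = 22, mnar = FALSE))
  eff <- sim$truth$effect_ids
  x <- log2(sim$quant$intensities)
  g <- sim$quant$samples$group
  d <- vapply(seq_len(nrow(eff)), function(i) {
    r <- x[eff$protein_id[i], ]
    mean(r[g == eff$group[i]]) - mean(r[g != eff$group[i]])
  }, numeric(1))
  expect_equal(mean(d), 1, tolerance = 0.05)
  # oracle: the planted expectation equals the truth matrix difference
  tl <- sim$truth$true_log2
  d0 <- vapply(seq_len(nrow(eff)), function(i) {
    tl[eff$protein_id[i], eff$group[i]] -
      mean(tl[eff$protein_id[i], colnames(tl) != eff$group[i]])
  }, numeric(1))
  expect_equal(d0, rep(1, nrow(eff)))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_proteins = 50, n_strict_markers_per_type = 20),
               "demand")
  expect_error(sim_config(histone_mass_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(noise_cv = -0.1))
  expect_error(simulate_cohort(sim_config(cohort_groups = c(a = 5, b = 1))),
               "n >= 2")
  expect_error(sim_config(cell_types = c(3, 3)), "named")
})

test_that("simulation round-trips through the exchange files", {
  sim <- simulate_atlas(small_cfg(seed = 13))
  dir <- tempfile()
  write_simulation(sim, dir)
  back <- read_protein_groups(
    file.path(dir, "protein_groups.tsv"),
    samples = read_sample_metadata(file.path(dir, "sample_metadata.csv")))
  expect_equal(back$intensities, sim$quant$intensities, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 13)
  markers <- read_gmt(file.path(dir, "truth_markers.gmt"))
  expect_identical(markers$sets$strict_hHEP,
                   sim$truth$marker_ids$strict$hHEP)
})
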