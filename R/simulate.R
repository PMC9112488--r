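#' Configuration for the synthetic-data generator
#'
#' Builds the parameter set for [simulate_atlas()] and [simulate_cohort()].
#' Defaults emulate the study design the analysis targets: four primary
#' liver cell types with three biological replicates each plus three tissue
#' groups with six replicates (atlas), and a three-group disease cohort of
#' 15 controls, 20 NASH and 10 cirrhosis samples with age and sex
#' covariates. Protein abundances follow a log-normal law wide enough to
#' span more than six orders of magnitude; measurement noise is
#' multiplicative; missingness is abundance-dependent (MNAR, logistic in
#' log10 intensity); a fixed share of total protein mass is carried by core
#' histones so the proteomic ruler applies.
#'
#' @param n_proteins number of protein groups (including histones).
#' @param cell_types named integer vector: cell-type label -> replicates.
#' @param tissue_groups named integer vector of tissue groups, or `NULL`.
#' @param cohort_groups named integer vector: cohort group -> sample count.
#' @param log10_copy_mean,log10_copy_sd log10 copies-per-cell law.
#' @param n_histones number of core histone proteins.
#' @param histone_mass_fraction share of total cell protein mass in
#'   histones (the ruler anchors histone mass to DNA mass, so this fixes
#'   total protein mass per cell at `m_DNA / histone_mass_fraction`).
#' @param noise_cv multiplicative measurement coefficient of variation.
#' @param mnar enable abundance-dependent missingness.
#' @param mnar_midpoint log10 intensity at which the missingness
#'   probability is 0.5; `NA` (default) places it at the
#'   `mnar_quantile`-quantile of the generated log10 intensities.
#' @param mnar_slope logistic steepness, log10-intensity units.
#' @param mnar_quantile quantile used when `mnar_midpoint` is `NA`.
#' @param n_strict_markers_per_type,n_fisher_markers_per_type planted
#'   cell-type-unique proteins per type (zero copies in all other cell
#'   types). Strict markers are abundant enough to be detected in every
#'   replicate; the Fisher-grade list extends the panel.
#' @param marker_log10_mean,marker_log10_sd abundance law of planted
#'   markers in their target type (copies per cell, log10).
#' @param n_enriched_per_type,enriched_log2fc per type, number of proteins
#'   with an elevated (not exclusive) abundance in that type, and the
#'   planted log2 fold change; these form the cell-type-characteristic
#'   blocks recovered by clustering.
#' @param effect_fraction,effect_log2fc cohort: fraction of proteins with a
#'   planted group effect, and its size in log2 units.
#' @param age_range,sex_balance cohort covariate generators: uniform age
#'   range in years and fraction of female samples per group.
#' @param age_coef,age_effect_fraction optional age confounding: log2
#'   change per year applied to a random protein subset.
#' @param seed integer seed; every random choice flows from it.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_proteins = 2000L,
                       cell_types = c(hHEP = 3L, hLSEC = 3L,
                                      hHSC = 3L, hKC = 3L),
                       tissue_groups = c(Liver = 6L, HepA = 6L, PorV = 6L),
                       cohort_groups = c(control = 15L, NASH = 20L,
                                         cirrhosis = 10L),
                       log10_copy_mean = 4.0,
                       log10_copy_sd = 1.2,
                       n_histones = 8L,
                       histone_mass_fraction = 0.04,
                       noise_cv = 0.20,
                       mnar = TRUE,
                       mnar_midpoint = NA_real_,
                       mnar_slope = 0.3,
                       mnar_quantile = 0.10,
                       n_strict_markers_per_type = 10L,
                       n_fisher_markers_per_type = 20L,
                       marker_log10_mean = 5.0,
                       marker_log10_sd = 0.5,
                       n_enriched_per_type = 50L,
                       enriched_log2fc = 2.0,
                       effect_fraction = 0.10,
                       effect_log2fc = 1.0,
                       age_range = c(30, 70),
                       sex_balance = 0.5,
                       age_coef = 0,
                       age_effect_fraction = 0,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              cell_types = cell_types, tissue_groups = tissue_groups,
              cohort_groups = cohort_groups,
              log10_copy_mean = log10_copy_mean,
              log10_copy_sd = log10_copy_sd,
              n_histones = as.integer(n_histones),
              histone_mass_fraction = histone_mass_fraction,
              noise_cv = noise_cv, mnar = isTRUE(mnar),
              mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
              mnar_quantile = mnar_quantile,
              n_strict_markers_per_type =
                as.integer(n_strict_markers_per_type),
              n_fisher_markers_per_type =
                as.integer(n_fisher_markers_per_type),
              marker_log10_mean = marker_log10_mean,
              marker_log10_sd = marker_log10_sd,
              n_enriched_per_type = as.integer(n_enriched_per_type),
              enriched_log2fc = enriched_log2fc,
              effect_fraction = effect_fraction,
              effect_log2fc = effect_log2fc,
              age_range = age_range, sex_balance = sex_balance,
              age_coef = age_coef,
              age_effect_fraction = age_effect_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_proteins > 0, cfg$n_histones > 0,
            cfg$log10_copy_sd > 0, cfg$noise_cv >= 0,
            cfg$mnar_slope > 0)
  if (is.null(names(cfg$cell_types)) || any(cfg$cell_types <= 0)) {
    stop("cell_types must be a named vector of positive replicate counts")
  }
  if (!is.null(cfg$tissue_groups) &&
      (is.null(names(cfg$tissue_groups)) || any(cfg$tissue_groups <= 0))) {
    stop("tissue_groups must be NULL or a named vector of positive counts")
  }
  for (f in c("histone_mass_fraction", "effect_fraction", "sex_balance",
              "mnar_quantile", "age_effect_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$histone_mass_fraction == 0) {
    stop("histone_mass_fraction must be > 0 (the ruler needs histones)")
  }
  per_type <- cfg$n_strict_markers_per_type +
    cfg$n_fisher_markers_per_type + cfg$n_enriched_per_type
  demand <- per_type * length(cfg$cell_types)
  if (demand > cfg$n_proteins - cfg$n_histones) {
    stop("marker/enriched demand (", demand,
         " proteins) exceeds available non-histone proteins (",
         cfg$n_proteins - cfg$n_histones, ")")
  }
  invisible(cfg)
}

# molecular weights (Da) cycled over planted histones; values in the range
# of the human core histone families (H4 ~11.4 kDa ... H3 ~15.4 kDa)
histone_mw_pool <- c(14135, 13906, 15404, 11367, 13553, 15328, 11360, 14045)
histone_gene_pool <- c("H2AC4", "H2BC5", "H3C1", "H4C1", "H2AZ1", "H3-3A",
                       "H4C3", "H2AX", "H2AC11", "H2BC12", "H3C2", "H4C5")

#' Simulate an atlas-style dataset (cell types and tissues) with truth
#'
#' Generates a raw-intensity [quant_matrix()] plus a `SimTruth` record.
#' Intensities follow `I = k * copies * MW * eps` with `eps` log-normal of
#' mean 1 and CV `noise_cv` and `k` an arbitrary per-run scale (so any
#' ruler-style analysis must be scale invariant). Core histone copies are
#' fixed so that total histone mass per cell equals the DNA mass per
#' diploid cell (the ruler anchor) and make up `histone_mass_fraction` of
#' total protein mass. Strict and Fisher-grade marker proteins are planted
#' with zero copies outside their target cell type; enriched blocks get an
#' elevated abundance in one type. After noise, entries are masked missing
#' with probability `plogis((midpoint - log10 I) / slope)` — low-abundance
#' entries drop out first; histone rows are never masked (drop-out of the
#' ruler anchor is an orthogonal failure mode, not simulated).
#'
#' @param config a [sim_config()].
#' @return A list with elements `quant` (`QuantMatrix`) and `truth`
#'   (`SimTruth`: true copies per cell type/tissue, molecular weights,
#'   histone IDs, planted marker and enriched sets, the per-run scale, the
#'   realized MNAR midpoint, the pre-mask intensity matrix and the masking
#'   probabilities, plus config and seed).
#' @export
simulate_atlas <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    nh <- config$n_histones
    n_free <- n - nh
    types <- names(config$cell_types)
    tissues <- names(config$tissue_groups)
    groups <- c(types, tissues)

    ids <- sprintf("P%05d", seq_len(n))
    genes <- sprintf("GENE%04d", seq_len(n))
    hist_rows <- seq.int(n_free + 1L, n)
    genes[hist_rows] <- rep_len(histone_gene_pool, nh)
    mw <- numeric(n)
    mw[seq_len(n_free)] <- 10^stats::rnorm(n_free, 4.65, 0.25)
    mw[hist_rows] <- rep_len(histone_mw_pool, nh)

    base <- stats::rnorm(n_free, config$log10_copy_mean,
                         config$log10_copy_sd)
    copies <- matrix(10^base, n_free, length(groups),
                     dimnames = list(ids[seq_len(n_free)], groups))

    per_type <- config$n_strict_markers_per_type +
      config$n_fisher_markers_per_type + config$n_enriched_per_type
    planted <- sample.int(n_free, per_type * length(types))
    marker_strict <- marker_fisher <- enriched <- list()
    offset <- 0L
    for (t in types) {
      take <- function(k) {
        out <- planted[offset + seq_len(k)]
        offset <<- offset + k
        out
      }
      s_idx <- take(config$n_strict_markers_per_type)
      f_idx <- take(config$n_fisher_markers_per_type)
      e_idx <- take(config$n_enriched_per_type)
      for (idx in list(s_idx, f_idx)) {
        if (length(idx)) {
          copies[idx, types] <- 0
          copies[idx, t] <- 10^stats::rnorm(length(idx),
                                            config$marker_log10_mean,
                                            config$marker_log10_sd)
        }
      }
      if (length(e_idx)) {
        copies[e_idx, t] <- copies[e_idx, t] * 2^config$enriched_log2fc
      }
      marker_strict[[t]] <- ids[s_idx]
      marker_fisher[[t]] <- ids[f_idx]
      enriched[[t]] <- ids[e_idx]
    }

    k_const <- ruler_constants()
    m_dna <- dna_mass_per_cell(k_const)
    # histone copies: total histone mass per cell == DNA mass (ruler anchor)
    w <- stats::rgamma(nh, shape = 5)
    hist_copies <- (w / sum(w)) * m_dna * k_const$avogadro / mw[hist_rows]
    # one global rescale of non-histone copies so the histone share of total
    # protein mass ~ histone_mass_fraction (global, to keep per-type
    # intensity offsets out of the null)
    nonhist_mass <- colSums(copies * mw[seq_len(n_free)]) / k_const$avogadro
    target_mass <- m_dna * (1 - config$histone_mass_fraction) /
      config$histone_mass_fraction
    copies <- copies * (target_mass / mean(nonhist_mass))

    true_copies <- rbind(copies,
                         matrix(hist_copies, nh, length(groups),
                                dimnames = list(ids[hist_rows], groups)))

    samples <- do.call(rbind, lapply(groups, function(g) {
      reps <- c(config$cell_types, config$tissue_groups)[[g]]
      data.frame(sample_id = paste0(g, "_", seq_len(reps)),
                 group = g,
                 cell_type = if (g %in% types) g else NA_character_,
                 tissue = if (g %in% tissues) g else NA_character_,
                 replicate = seq_len(reps),
                 stringsAsFactors = FALSE)
    }))

    k_scale <- 10^stats::runif(1, -2, 2)
    expected <- true_copies[, samples$group, drop = FALSE] * mw * k_scale
    eps <- 1
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log1p(config$noise_cv^2))
      eps <- matrix(stats::rlnorm(length(expected), -sdlog^2 / 2, sdlog),
                    nrow(expected), ncol(expected))
    }
    premask <- expected * eps
    premask[premask == 0] <- NA_real_  # structural absence, not drop-out

    intens <- premask
    miss_prob <- matrix(0, nrow(intens), ncol(intens))
    midpoint <- NA_real_
    if (config$mnar) {
      li <- log10(intens)
      midpoint <- if (is.na(config$mnar_midpoint)) {
        stats::quantile(li, config$mnar_quantile, na.rm = TRUE,
                        names = FALSE)
      } else config$mnar_midpoint
      miss_prob <- stats::plogis((midpoint - li) / config$mnar_slope)
      miss_prob[is.na(miss_prob)] <- 0
      miss_prob[hist_rows, ] <- 0
      drop <- matrix(stats::runif(length(intens)), nrow(intens)) < miss_prob
      intens[drop] <- NA_real_
    }
    colnames(intens) <- samples$sample_id
    colnames(premask) <- samples$sample_id

    proteins <- data.frame(protein_id = ids, gene_name = genes, mw_da = mw,
                           is_histone = seq_len(n) %in% hist_rows,
                           stringsAsFactors = FALSE)
    qm <- quant_matrix(intens, proteins, samples, scale = "raw")
    truth <- structure(list(
      true_copies = true_copies,
      molecular_weights = stats::setNames(mw, ids),
      histone_ids = ids[hist_rows],
      marker_ids = list(strict = marker_strict, fisher = marker_fisher),
      enriched_ids = enriched,
      effect_ids = NULL,
      covariates = NULL,
      scale_k = k_scale,
      mnar_midpoint = midpoint,
      premask_intensities = premask,
      miss_prob = miss_prob,
      seed = config$seed,
      config = config
    ), class = "SimTruth")
    list(quant = qm, truth = truth)
  })
}

#' Simulate a three-group cohort with covariates and planted effects
#'
#' Baseline log2 intensities per protein derive from the same log-normal
#' abundance law as the atlas. A fraction `effect_fraction` of proteins
#' receives a planted shift of `effect_log2fc` log2 units in one randomly
#' chosen group; age is uniform on `age_range` and sex is balanced per
#' group according to `sex_balance`; an optional age coefficient confounds
#' a stated protein subset. Gaussian noise on the log2 scale matches
#' `noise_cv`; MNAR masking as in [simulate_atlas()].
#'
#' @param config a [sim_config()]; `cohort_groups` must be nonempty with
#'   every group of size >= 2.
#' @return A list with `quant` (raw-scale `QuantMatrix`) and `truth`
#'   (`SimTruth` with the planted effect table, the per-group expected log2
#'   matrix, and the covariate table).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  grp <- config$cohort_groups
  if (is.null(grp) || !length(grp)) stop("cohort_groups must be nonempty")
  if (any(grp < 2)) {
    stop("every cohort group needs n >= 2 (downstream tests undefined): ",
         paste(names(grp)[grp < 2], collapse = ", "))
  }
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    ids <- sprintf("P%05d", seq_len(n))
    genes <- sprintf("GENE%04d", seq_len(n))
    mw <- 10^stats::rnorm(n, 4.65, 0.25)
    copies <- 10^stats::rnorm(n, config$log10_copy_mean,
                              config$log10_copy_sd)
    k_scale <- 10^stats::runif(1, -2, 2)
    baseline <- log2(k_scale * copies * mw)

    groups <- names(grp)
    true_log2 <- matrix(baseline, n, length(groups),
                        dimnames = list(ids, groups))
    ne <- round(config$effect_fraction * n)
    effect_tab <- NULL
    if (ne > 0) {
      eff_idx <- sample.int(n, ne)
      eff_grp <- sample(groups, ne, replace = TRUE)
      for (i in seq_len(ne)) {
        true_log2[eff_idx[i], eff_grp[i]] <-
          true_log2[eff_idx[i], eff_grp[i]] + config$effect_log2fc
      }
      effect_tab <- data.frame(protein_id = ids[eff_idx], group = eff_grp,
                               log2fc = config$effect_log2fc,
                               stringsAsFactors = FALSE)
    }

    samples <- do.call(rbind, lapply(groups, function(g) {
      ng <- grp[[g]]
      nf <- round(config$sex_balance * ng)
      data.frame(sample_id = paste0(g, "_", seq_len(ng)), group = g,
                 replicate = seq_len(ng),
                 age = stats::runif(ng, config$age_range[1],
                                    config$age_range[2]),
                 sex = sample(c(rep("F", nf), rep("M", ng - nf))),
                 stringsAsFactors = FALSE)
    }))
    ns <- nrow(samples)

    L <- true_log2[, samples$group, drop = FALSE]
    na_prot <- round(config$age_effect_fraction * n)
    age_idx <- integer(0)
    if (na_prot > 0 && config$age_coef != 0) {
      age_idx <- sample.int(n, na_prot)
      age_c <- samples$age - mean(config$age_range)
      L[age_idx, ] <- L[age_idx, ] +
        config$age_coef * matrix(age_c, na_prot, ns, byrow = TRUE)
    }
    sd_log2 <- sqrt(log1p(config$noise_cv^2)) / log(2)
    if (sd_log2 > 0) {
      L <- L + matrix(stats::rnorm(length(L), 0, sd_log2), n, ns)
    }
    premask <- 2^L
    intens <- premask
    miss_prob <- matrix(0, n, ns)
    midpoint <- NA_real_
    if (config$mnar) {
      li <- log10(intens)
      midpoint <- if (is.na(config$mnar_midpoint)) {
        stats::quantile(li, config$mnar_quantile, na.rm = TRUE,
                        names = FALSE)
      } else config$mnar_midpoint
      miss_prob <- stats::plogis((midpoint - li) / config$mnar_slope)
      drop <- matrix(stats::runif(length(intens)), n) < miss_prob
      intens[drop] <- NA_real_
    }
    colnames(intens) <- samples$sample_id
    colnames(premask) <- samples$sample_id

    proteins <- data.frame(protein_id = ids, gene_name = genes, mw_da = mw,
                           is_histone = FALSE, stringsAsFactors = FALSE)
    qm <- quant_matrix(intens, proteins, samples, scale = "raw")
    truth <- structure(list(
      true_copies = NULL,
      true_log2 = true_log2,
      molecular_weights = stats::setNames(mw, ids),
      histone_ids = character(0),
      marker_ids = NULL,
      enriched_ids = NULL,
      effect_ids = effect_tab,
      age_protein_ids = ids[age_idx],
      covariates = samples[, c("sample_id", "age", "sex")],
      scale_k = k_scale,
      mnar_midpoint = midpoint,
      premask_intensities = premask,
      miss_prob = miss_prob,
      seed = config$seed,
      config = config
    ), class = "SimTruth")
    list(quant = qm, truth = truth)
  })
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$true_copies)) {
    cat("  true copies:", nrow(x$true_copies), "proteins x",
        ncol(x$true_copies), "groups\n")
  }
  if (!is.null(x$effect_ids)) {
    cat("  planted effects:", nrow(x$effect_ids), "proteins\n")
  }
  if (!is.null(x$marker_ids)) {
    cat("  planted markers:",
        sum(lengths(x$marker_ids$strict)), "strict /",
        sum(lengths(x$marker_ids$fisher)), "Fisher-grade\n")
  }
  invisible(x)
}

#' Write a simulated dataset to disk in the package's exchange formats
#'
#' Emits the same files the readers consume — a proteinGroups-style TSV, a
#' sample-metadata CSV — plus the ground truth as TSV and a JSON manifest
#' recording config and seed, so a simulated run is fully reconstructable.
#'
#' @param sim result of [simulate_atlas()] or [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_groups(sim$quant, file.path(dir, "protein_groups.tsv"))
  write_sample_metadata(sim$quant$samples,
                        file.path(dir, "sample_metadata.csv"))
  tr <- sim$truth
  if (!is.null(tr$true_copies)) {
    utils::write.table(
      data.frame(protein_id = rownames(tr$true_copies), tr$true_copies,
                 check.names = FALSE),
      file.path(dir, "truth_copies.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tr$effect_ids)) {
    utils::write.table(tr$effect_ids, file.path(dir, "truth_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tr$marker_ids)) {
    ann <- annotation_set(c(
      stats::setNames(tr$marker_ids$strict,
                      paste0("strict_", names(tr$marker_ids$strict))),
      stats::setNames(tr$marker_ids$fisher,
                      paste0("fisher_", names(tr$marker_ids$fisher)))))
    write_gmt(ann, file.path(dir, "truth_markers.gmt"))
  }
  cfg <- unclass(tr$config)
  cfg$cell_types <- as.list(cfg$cell_types)
  cfg$tissue_groups <- as.list(cfg$tissue_groups)
  cfg$cohort_groups <- as.list(cfg$cohort_groups)
  manifest <- list(generator = class(tr)[1], seed = tr$seed,
                   scale_k = tr$scale_k, mnar_midpoint = tr$mnar_midpoint,
                   config = cfg)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Random annotation set over a protein universe
#'
#' Draws term memberships uniformly from `ids`; useful as a null model for
#' enrichment calibration and for exercising composition analytics on
#' simulated data.
#'
#' @param ids protein-ID universe.
#' @param n_terms number of terms.
#' @param size_range inclusive range of term sizes.
#' @param prefix term-name prefix.
#' @param seed integer seed.
#' @return An [annotation_set()].
#' @export
random_annotation_set <- function(ids, n_terms = 20, size_range = c(10, 50),
                                  prefix = "TERM", seed = 1L) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_terms), function(i) {
      k <- sample(seq(size_range[1], size_range[2]), 1)
      sample(ids, min(k, length(ids)))
    })
    names(sets) <- sprintf("%s%03d", prefix, seq_len(n_terms))
    annotation_set(sets)
  })
}
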