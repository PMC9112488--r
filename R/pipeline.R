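#' Run the analysis stages as one reproducible pipeline
#'
#' Executes the requested stages in dependency order on either a simulated
#' dataset or files on disk, writes every result table as TSV into
#' `out_dir` together with a JSON manifest (stages, config digest, seed),
#' and returns the in-memory results. All randomness (simulation,
#' imputation) flows from the single root `seed`, so re-running with the
#' same config reproduces identical numeric outputs.
#'
#' `config` is a plain named list:
#' \describe{
#'   \item{`simulate`}{`list(kind = "atlas"|"cohort", ...)` with extra
#'     arguments passed to [sim_config()]; or omit and supply}
#'   \item{`input`}{`list(protein_groups = path, metadata = path)` read via
#'     [read_protein_groups()].}
#'   \item{`stages`}{character vector from `simulate`, `filter`, `impute`,
#'     `ruler`, `composition`, `markers`, `anova`, `ancova`, `tukey`,
#'     `cluster`, `enrich`.}
#'   \item{`filter`}{`list(mode =, threshold =)` for [filter_valid()].}
#'   \item{`impute`}{`list(shift =, width =)` for [impute_downshift()].}
#'   \item{`ruler`}{arguments to [ruler_constants()].}
#'   \item{`group_var`, `covariates`, `fdr`, `cluster_k`}{statistics
#'     options.}
#'   \item{`annotations`}{`list(compartments =, classes =, complexes =,
#'     pathways =, terms =)` GMT paths for the composition/enrichment
#'     stages (each optional).}
#' }
#'
#' @param config named list, see above.
#' @param out_dir output directory (created if needed).
#' @param seed root integer seed; overrides `config$seed`.
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  stages <- config$stages
  if (is.null(stages)) stop("config$stages is required")
  known <- c("simulate", "filter", "impute", "ruler", "composition",
             "markers", "anova", "ancova", "tukey", "cluster", "enrich")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  deps <- list(tukey = "ancova", cluster = c("anova", "ancova"),
               impute = character(0))
  if ("tukey" %in% stages && !"ancova" %in% stages) {
    stop("stage 'tukey' requires stage 'ancova'")
  }
  if ("cluster" %in% stages &&
      !any(c("anova", "ancova") %in% stages)) {
    stop("stage 'cluster' requires an omnibus test stage ('anova' or ",
         "'ancova')")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  group_var <- config$group_var %||% "group"
  fdr <- config$fdr %||% 0.05
  res <- list()
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- data acquisition -------------------------------------------------
  if ("simulate" %in% stages || !is.null(config$simulate)) {
    sim_args <- config$simulate %||% list(kind = "atlas")
    kind <- sim_args$kind %||% "atlas"
    sim_args$kind <- NULL
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    sim <- if (kind == "cohort") simulate_cohort(cfg) else
      simulate_atlas(cfg)
    write_simulation(sim, file.path(out_dir, "simulated"))
    res$simulate <- sim
    qm <- sim$quant
  } else if (!is.null(config$input)) {
    samples <- if (!is.null(config$input$metadata)) {
      read_sample_metadata(config$input$metadata)
    } else NULL
    qm <- read_protein_groups(config$input$protein_groups,
                              samples = samples)
  } else {
    stop("config needs either a 'simulate' block or an 'input' block")
  }

  ann <- lapply(config$annotations %||% list(), read_gmt)

  # --- detection-based analyses on the unimputed matrix -----------------
  raw <- qm
  if ("ruler" %in% stages) {
    k <- do.call(ruler_constants, config$ruler %||% list())
    ct <- estimate_copies(raw, k)
    res$ruler <- ct
    tsv(data.frame(protein_id = rownames(ct$copies_per_cell),
                   ct$copies_per_cell, check.names = FALSE),
        "copies_per_cell")
    tsv(ct$totals, "ruler_totals")
    jsonlite::write_json(
      list(constants = unclass(k),
           dna_mass_pg = dna_mass_per_cell(k) * 1e12,
           totals = ct$totals),
      file.path(out_dir, "ruler_summary.json"),
      auto_unbox = TRUE, digits = NA)
    if ("composition" %in% stages) {
      gm <- group_mean_copies(ct, group_var)
      if (!is.null(ann$compartments)) {
        mb <- compartment_mass_fractions(gm, ann$compartments)
        tsv(data.frame(term = rownames(mb$fractions), mb$fractions,
                       check.names = FALSE), "compartment_fractions")
        res$compartments <- mb
      }
      if (!is.null(ann$classes)) {
        cb <- class_mass_fractions(gm, ann$classes)
        tsv(data.frame(term = rownames(cb$fractions), cb$fractions,
                       check.names = FALSE), "class_fractions")
        res$classes <- cb
      }
      if (!is.null(ann$complexes)) {
        st <- complex_stoichiometry(gm, ann$complexes)
        tsv(st$complexes, "complex_totals")
        if (!is.null(st$subunits)) tsv(st$subunits, "complex_subunits")
        res$stoichiometry <- st
      }
      if (!is.null(ann$pathways)) {
        tsv(pathway_copy_sums(gm, ann$pathways), "pathway_copies")
        tsv(pathway_coverage(raw, ann$pathways), "pathway_coverage")
      }
    }
  }
  if ("markers" %in% stages) {
    det_var <- config$marker_group_var %||% group_var
    d <- detection_counts(raw, det_var)
    cand <- candidate_markers(d, min_detected = config$min_detected %||% 2,
                              alpha = config$marker_alpha %||% 0.05)
    strict <- strict_markers(d)
    res$markers <- list(candidates = cand, strict = strict)
    cand_tab <- do.call(rbind, lapply(names(cand), function(g) {
      if (!nrow(cand[[g]])) return(NULL)
      cbind(cell_type = g, cand[[g]])
    }))
    if (!is.null(cand_tab)) tsv(cand_tab, "candidate_markers")
    strict_tab <- do.call(rbind, lapply(names(strict), function(g) {
      if (!length(strict[[g]])) return(NULL)
      data.frame(cell_type = g, protein_id = strict[[g]],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(strict_tab)) tsv(strict_tab, "strict_markers")
  }

  # --- filter / transform / impute --------------------------------------
  if ("filter" %in% stages) {
    fl <- config$filter %||% list(mode = "min_valid_in_any_group",
                                  threshold = 2)
    qm <- filter_valid(qm, mode = fl$mode, threshold = fl$threshold,
                       group_var = fl$group_var %||% group_var)
  }
  if (any(c("impute", "anova", "ancova", "tukey", "cluster") %in% stages)) {
    qm <- log_transform(qm)
    ip <- config$impute %||% list()
    qm <- impute_downshift(qm, shift = ip$shift %||% 1.8,
                           width = ip$width %||% 0.3,
                           seed = seed + 1L)
    res$imputed <- qm
  }

  # --- statistics -------------------------------------------------------
  omnibus <- NULL
  if ("anova" %in% stages) {
    omnibus <- anova_oneway(qm, group_var, fdr = fdr)
    res$anova <- omnibus
    tsv(omnibus, "anova")
  }
  if ("ancova" %in% stages) {
    omnibus <- ancova_group_test(qm, group_var,
                                 covariates = config$covariates %||%
                                   c("age", "sex"),
                                 fdr = fdr)
    res$ancova <- omnibus
    tsv(omnibus, "ancova")
  }
  if ("tukey" %in% stages) {
    sig <- omnibus$protein_id[omnibus$significant]
    if (length(sig)) {
      tk <- tukey_posthoc(qm, group_var, sig,
                          covariates = config$covariates %||%
                            c("age", "sex"))
      res$tukey <- tk
      tsv(tk, "tukey_posthoc")
    }
  }
  if ("cluster" %in% stages) {
    sig <- omnibus$protein_id[omnibus$significant]
    if (length(sig) >= 2) {
      cl <- zscore_cluster(qm, sig, group_var,
                           k = config$cluster_k %||% 4)
      res$cluster <- cl
      tsv(cl$assignment, "clusters")
    }
  }
  if ("enrich" %in% stages && !is.null(ann$terms)) {
    fg <- res$cluster$assignment$protein_id %||%
      omnibus$protein_id[omnibus$significant]
    bg <- qm$proteins$protein_id
    if (length(fg)) {
      er <- fisher_enrich(fg, bg, ann$terms,
                          min_term = config$min_term %||% 10,
                          fdr = config$enrich_fdr %||% 0.01)
      res$enrich <- er
      tsv(er$table, "enrichment")
    }
  }

  manifest <- list(
    package = "protruler",
    version = as.character(utils::packageVersion("protruler")),
    seed = seed,
    stages = stages,
    group_var = group_var,
    fdr = fdr,
    config_digest = digest_config(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable digest of the config: serialized bytes folded into a polynomial
# rolling hash (provenance tag only, no external digest dependency)
digest_config <- function(config) {
  bytes <- as.integer(serialize(config, connection = NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
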