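#' Constants for the histone proteomic ruler
#'
#' The ruler converts relative label-free intensities into absolute copies
#' per cell by anchoring the summed histone intensity to the cellular DNA
#' mass, exploiting the essentially fixed histone:DNA mass ratio of
#' chromatin. The DNA mass per cell is
#' `m_DNA = ploidy * genome_size_bp * bp_molar_mass / avogadro`.
#'
#' The default ploidy is 2; polyploid cells (hepatocytes carry one to four
#' nuclei) should override it, otherwise copy numbers are underestimated.
#'
#' @param genome_size_bp base pairs per haploid genome (human: 3.1e9).
#' @param bp_molar_mass average molar mass of a DNA base pair, g/mol.
#' @param ploidy genome copies per cell.
#' @param avogadro Avogadro constant, 1/mol.
#' @return A list of class `RulerConstants`.
#' @export
ruler_constants <- function(genome_size_bp = 3.1e9,
                            bp_molar_mass = 615.8771,
                            ploidy = 2,
                            avogadro = 6.02214076e23) {
  k <- list(genome_size_bp = genome_size_bp,
            bp_molar_mass = bp_molar_mass,
            ploidy = ploidy, avogadro = avogadro)
  if (any(unlist(k) <= 0)) stop("all ruler constants must be > 0")
  structure(k, class = "RulerConstants")
}

#' DNA mass per cell
#'
#' @param k a [ruler_constants()] object.
#' @return DNA mass per cell in grams (about 6.34 pg for a diploid human
#'   cell).
#' @export
dna_mass_per_cell <- function(k = ruler_constants()) {
  stopifnot(inherits(k, "RulerConstants"))
  k$ploidy * k$genome_size_bp * k$bp_molar_mass / k$avogadro
}

#' Estimate protein copies per cell with the histone proteomic ruler
#'
#' For each sample, with `S_h` the summed raw intensity of the histone
#' proteins and `m_DNA` the DNA mass per cell:
#' \deqn{m_i = I_i \cdot m_{DNA} / S_h \qquad
#'       c_i = (I_i / MW_i) \cdot N_A \cdot m_{DNA} / S_h}
#' so per-protein mass and copy numbers are invariant to any global
#' intensity rescaling, and the total protein mass per sample is exactly
#' `m_DNA * (sum I) / S_h`. The ruler operates on raw (non-log,
#' non-imputed) intensities only; missing intensities yield missing copies.
#'
#' @param m a raw-scale [quant_matrix()] whose `is_histone` column flags at
#'   least one histone with a valid intensity in every sample (see
#'   [flag_histones()]).
#' @param k a [ruler_constants()] object.
#' @return A list of class `CopyTable`: `copies_per_cell` and
#'   `mass_per_cell_pg` (proteins x samples), `totals` (per sample: summed
#'   copies and total protein mass in pg), `samples`, `proteins` and the
#'   `constants` used.
#' @export
estimate_copies <- function(m, k = ruler_constants()) {
  stopifnot(inherits(m, "QuantMatrix"))
  if (m$scale != "raw") {
    stop("the ruler needs raw intensities, got scale '", m$scale, "'")
  }
  hist_rows <- which(m$proteins$is_histone)
  if (!length(hist_rows)) stop("no histone proteins flagged")
  quantified <- rowSums(!is.na(m$intensities)) > 0
  bad_mw <- quantified & (is.na(m$proteins$mw_da) | m$proteins$mw_da <= 0)
  if (any(bad_mw)) {
    stop("missing/invalid molecular weight for quantified protein(s): ",
         paste(utils::head(m$proteins$protein_id[bad_mw], 5),
               collapse = ", "))
  }
  hist_sum <- colSums(m$intensities[hist_rows, , drop = FALSE],
                      na.rm = TRUE)
  if (any(hist_sum <= 0)) {
    stop("zero histone signal in sample(s): ",
         paste(colnames(m$intensities)[hist_sum <= 0], collapse = ", "))
  }
  m_dna <- dna_mass_per_cell(k)
  scale_g <- m_dna / hist_sum                      # grams per intensity unit
  mass_g <- sweep(m$intensities, 2, scale_g, "*")
  copies <- sweep(mass_g, 1, m$proteins$mw_da, "/") * k$avogadro
  totals <- data.frame(
    sample_id = m$samples$sample_id,
    total_copies = colSums(copies, na.rm = TRUE),
    total_mass_pg = colSums(mass_g, na.rm = TRUE) * 1e12,
    stringsAsFactors = FALSE
  )
  structure(list(copies_per_cell = copies,
                 mass_per_cell_pg = mass_g * 1e12,
                 totals = totals,
                 samples = m$samples,
                 proteins = m$proteins,
                 constants = k),
            class = "CopyTable")
}

#' @export
print.CopyTable <- function(x, ...) {
  cat(sprintf("CopyTable: %d proteins x %d samples\n",
              nrow(x$copies_per_cell), ncol(x$copies_per_cell)))
  cat(sprintf("  total mass per cell: %.0f-%.0f pg\n",
              min(x$totals$total_mass_pg), max(x$totals$total_mass_pg)))
  invisible(x)
}

#' Average copies and mass over replicate samples per group
#'
#' Computes per-protein group means of copies and mass, ignoring missing
#' replicates (mean over the valid ones).
#'
#' @param t a [estimate_copies()] result.
#' @param group_var sample-metadata column defining the groups.
#' @return A `CopyTable` whose columns are group means; `samples` carries
#'   one row per group.
#' @export
group_mean_copies <- function(t, group_var = "group") {
  stopifnot(inherits(t, "CopyTable"))
  if (!group_var %in% names(t$samples)) {
    stop("grouping variable '", group_var, "' not found")
  }
  g <- t$samples[[group_var]]
  keep <- !is.na(g)
  lev <- unique(g[keep])
  mean_by <- function(mat) {
    out <- vapply(lev, function(l) {
      rowMeans(mat[, keep & g == l, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(mat)))
    out[is.nan(out)] <- NA_real_
    colnames(out) <- lev
    out
  }
  copies <- mean_by(t$copies_per_cell)
  mass <- mean_by(t$mass_per_cell_pg)
  totals <- data.frame(
    sample_id = lev,
    total_copies = colSums(copies, na.rm = TRUE),
    total_mass_pg = colSums(mass, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(copies_per_cell = copies, mass_per_cell_pg = mass,
                 totals = totals,
                 samples = data.frame(sample_id = lev, group = lev,
                                      stringsAsFactors = FALSE),
                 proteins = t$proteins, constants = t$constants),
            class = "CopyTable")
}

#' Subunit stoichiometry of protein complexes
#'
#' For each annotated complex and each sample (or group-mean) column:
#' the mean subunit copy number, each subunit's ratio to that mean, a flag
#' for whether the ratio lies within `fold`-fold of the mean
#' (`ratio in [1/fold, fold]`), and the complex total copies (sum over
#' quantified members). Complexes with fewer than two quantified members
#' are reported as not evaluable rather than raising an error.
#'
#' @param t a [estimate_copies()] or [group_mean_copies()] result.
#' @param complexes an [annotation_set()] keyed by protein ID.
#' @param fold fold window around the mean (default 2).
#' @param pairwise also return all pairwise subunit copy ratios.
#' @return A list with `subunits` (complex, sample, protein, copies, ratio
#'   to mean, within-fold flag), `complexes` (per complex and sample: n
#'   quantified members, mean and total copies, evaluable flag) and, when
#'   requested, `pairs` (all ordered subunit pairs and their copy ratio).
#' @export
complex_stoichiometry <- function(t, complexes, fold = 2,
                                  pairwise = FALSE) {
  stopifnot(inherits(t, "CopyTable"), inherits(complexes, "AnnotationSet"))
  if (fold < 1) stop("fold must be >= 1")
  cp <- t$copies_per_cell
  sub_rows <- list(); cx_rows <- list(); pair_rows <- list()
  for (term in names(complexes$sets)) {
    members <- intersect(complexes$sets[[term]], rownames(cp))
    for (s in colnames(cp)) {
      v <- cp[members, s]
      v <- v[!is.na(v)]
      evaluable <- length(v) >= 2
      cx_rows[[length(cx_rows) + 1L]] <- data.frame(
        complex = term, sample = s, n_members = length(v),
        mean_copies = if (evaluable) mean(v) else NA_real_,
        total_copies = if (length(v)) sum(v) else NA_real_,
        evaluable = evaluable, stringsAsFactors = FALSE)
      if (!evaluable) next
      ratio <- v / mean(v)
      sub_rows[[length(sub_rows) + 1L]] <- data.frame(
        complex = term, sample = s, protein_id = names(v), copies = v,
        ratio_to_mean = ratio,
        within_fold = ratio >= 1 / fold & ratio <= fold,
        stringsAsFactors = FALSE, row.names = NULL)
      if (pairwise && length(v) >= 2) {
        idx <- utils::combn(seq_along(v), 2)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          complex = term, sample = s,
          protein_a = names(v)[idx[1, ]], protein_b = names(v)[idx[2, ]],
          ratio = v[idx[1, ]] / v[idx[2, ]],
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  out <- list(
    subunits = if (length(sub_rows)) do.call(rbind, sub_rows) else NULL,
    complexes = do.call(rbind, cx_rows)
  )
  if (pairwise) {
    out$pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
  }
  out
}

#' Total protein copies per pathway
#'
#' Sums copies per cell over the quantified members of each pathway, per
#' sample (or group-mean) column. A protein belonging to several pathways
#' counts fully in each (KEGG semantics); an empty or unquantified pathway
#' reports a sum of 0 with `n_members = 0`.
#'
#' @param t a [estimate_copies()] or [group_mean_copies()] result.
#' @param pathways an [annotation_set()] keyed by protein ID.
#' @return data.frame: pathway, sample, n_members (quantified), total
#'   copies.
#' @export
pathway_copy_sums <- function(t, pathways) {
  stopifnot(inherits(t, "CopyTable"), inherits(pathways, "AnnotationSet"))
  cp <- t$copies_per_cell
  rows <- lapply(names(pathways$sets), function(term) {
    members <- intersect(pathways$sets[[term]], rownames(cp))
    sub <- cp[members, , drop = FALSE]
    data.frame(pathway = term, sample = colnames(cp),
               n_members = colSums(!is.na(sub)),
               total_copies = colSums(sub, na.rm = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
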