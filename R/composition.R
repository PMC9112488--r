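#' Protein-class mass fractions
#'
#' Percent of total protein mass carried by each annotated protein class,
#' per sample (or group-mean) column. Classes overlap — a protein counts
#' fully in every class it belongs to — so class percentages need not sum
#' to 100.
#'
#' @param t a [estimate_copies()] or [group_mean_copies()] result (mass per
#'   cell is the mass proxy; under the ruler, mass is proportional to raw
#'   intensity, so the same fractions arise from either).
#' @param classes an [annotation_set()] keyed by protein ID.
#' @return A list of class `MassBudget` with `unit = "class"`, a
#'   `fractions` matrix (term x sample, percent) and the scheme used.
#' @export
class_mass_fractions <- function(t, classes) {
  stopifnot(inherits(t, "CopyTable"), inherits(classes, "AnnotationSet"))
  mass <- t$mass_per_cell_pg
  total <- colSums(mass, na.rm = TRUE)
  fr <- vapply(names(classes$sets), function(term) {
    members <- intersect(classes$sets[[term]], rownames(mass))
    if (!length(members)) return(rep(0, ncol(mass)))
    colSums(mass[members, , drop = FALSE], na.rm = TRUE) / total * 100
  }, numeric(ncol(mass)))
  fr <- matrix(fr, ncol = length(classes$sets),
               dimnames = list(colnames(mass), names(classes$sets)))
  structure(list(unit = "class", fractions = t(fr), unassigned_pct = NULL,
                 scheme = "full_count"),
            class = "MassBudget")
}

#' Subcellular compartment mass fractions
#'
#' Percent of total protein mass per compartment, per sample (or
#' group-mean) column. Because many proteins co-localize to more than one
#' compartment, two schemes are offered:
#' \describe{
#'   \item{`equal_split`}{(default) a protein annotated to `k` compartments
#'     contributes `mass / k` to each; proteins without any annotation go
#'     to `"unassigned"`. Fractions (including unassigned) sum to exactly
#'     100 per column — the normalized whole-cell mass budget.}
#'   \item{`full_count`}{each protein counts fully in every compartment it
#'     belongs to — the unnormalized overlap view; columns need not sum
#'     to 100 (unassigned is still reported).}
#' }
#'
#' @param t a [estimate_copies()] or [group_mean_copies()] result.
#' @param compartments an [annotation_set()] keyed by protein ID.
#' @param scheme `"equal_split"` or `"full_count"`.
#' @return A `MassBudget` with `unit = "compartment"`, a `fractions`
#'   matrix (term x sample, percent) and `unassigned_pct` per sample.
#' @export
compartment_mass_fractions <- function(t, compartments,
                                       scheme = c("equal_split",
                                                  "full_count")) {
  stopifnot(inherits(t, "CopyTable"),
            inherits(compartments, "AnnotationSet"))
  scheme <- match.arg(scheme)
  mass <- t$mass_per_cell_pg
  ids <- rownames(mass)
  total <- colSums(mass, na.rm = TRUE)
  terms <- names(compartments$sets)
  member <- vapply(terms, function(tm) ids %in% compartments$sets[[tm]],
                   logical(length(ids)))
  member <- matrix(member, nrow = length(ids),
                   dimnames = list(ids, terms))
  k <- rowSums(member)
  weight <- member
  if (scheme == "equal_split" && any(k > 0)) {
    weight[k > 0, ] <- member[k > 0, , drop = FALSE] / k[k > 0]
  }
  mass0 <- mass
  mass0[is.na(mass0)] <- 0
  fr <- t(weight) %*% mass0                # term x sample mass
  fr <- sweep(fr, 2, total, "/") * 100
  unassigned <- colSums(mass0[k == 0, , drop = FALSE]) / total * 100
  structure(list(unit = "compartment", fractions = fr,
                 unassigned_pct = unassigned, scheme = scheme),
            class = "MassBudget")
}

#' @export
print.MassBudget <- function(x, ...) {
  cat(sprintf("MassBudget (%s, scheme %s): %d terms x %d columns\n",
              x$unit, x$scheme, nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}

#' Cumulative abundance curve and quantile counts
#'
#' Sorts abundances in decreasing order (ties broken lexicographically by
#' protein ID, for determinism) and reports, for each requested quantile
#' `q`, the smallest number of proteins whose cumulative abundance reaches
#' `q` of the total — e.g. how few proteins make up half the proteome mass.
#'
#' @param values positive per-protein abundances (mass or intensity).
#' @param ids protein IDs (defaults to `names(values)`).
#' @param quantiles cumulative fractions to report.
#' @return A list: `counts` (named, per quantile), `curve` (data.frame of
#'   rank, protein_id, value, cumulative fraction).
#' @export
cumulative_abundance <- function(values, ids = names(values),
                                 quantiles = c(0.25, 0.5, 0.75)) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no abundances supplied")
  if (any(values <= 0)) stop("abundances must be positive")
  if (is.null(ids)) ids <- sprintf("p%06d", seq_along(values))
  ids <- ids[seq_along(values)]
  ord <- order(-values, ids)
  v <- values[ord]
  cum <- cumsum(v) / sum(v)
  counts <- vapply(quantiles, function(q) {
    which(cum >= q - 1e-12)[1]
  }, integer(1))
  names(counts) <- paste0("n", format(100 * quantiles, trim = TRUE), "pct")
  list(counts = counts,
       curve = data.frame(rank = seq_along(v), protein_id = ids[ord],
                          value = v, cum_fraction = cum,
                          stringsAsFactors = FALSE, row.names = NULL))
}

#' Dynamic range in decades
#'
#' @param values positive abundances.
#' @return `log10(max / min)` over the non-missing values.
#' @export
dynamic_range <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values supplied")
  if (any(values <= 0)) stop("values must be positive")
  log10(max(values) / min(values))
}

#' Pathway coverage of the quantified proteome
#'
#' Per pathway, the fraction of member proteins quantified (at least one
#' valid intensity anywhere in the matrix). Pathways without members in
#' the annotation are reported as not evaluable (`NA` coverage).
#'
#' @param m a [quant_matrix()].
#' @param pathways an [annotation_set()] keyed by protein ID.
#' @return data.frame: pathway, n_members, n_quantified, coverage_pct.
#' @export
pathway_coverage <- function(m, pathways) {
  stopifnot(inherits(m, "QuantMatrix"), inherits(pathways, "AnnotationSet"))
  quantified <- m$proteins$protein_id[rowSums(!is.na(m$intensities)) > 0]
  rows <- lapply(names(pathways$sets), function(term) {
    members <- pathways$sets[[term]]
    hits <- sum(members %in% quantified)
    data.frame(pathway = term, n_members = length(members),
               n_quantified = hits,
               coverage_pct = if (length(members)) {
                 100 * hits / length(members)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise Pearson correlation between samples or group means
#'
#' Pearson correlation of (log-scale) abundance profiles between all pairs
#' of columns, over mutually valid entries; also reports the number of
#' complete pairs used per comparison.
#'
#' @param m a log-scale [quant_matrix()].
#' @param level correlate individual `"sample"` columns or per-group mean
#'   profiles (`"group_mean"`).
#' @param group_var grouping column for `level = "group_mean"`.
#' @return A list with `r` (correlation matrix, unit diagonal) and
#'   `n_pairs` (matrix of pairwise-complete counts).
#' @export
pairwise_sample_correlation <- function(m, level = c("sample",
                                                     "group_mean"),
                                        group_var = "group") {
  stopifnot(inherits(m, "QuantMatrix"))
  level <- match.arg(level)
  x <- m$intensities
  if (level == "group_mean") {
    idx <- group_index(m, group_var)
    x <- vapply(idx, function(cols) {
      v <- rowMeans(m$intensities[, cols, drop = FALSE], na.rm = TRUE)
      v[is.nan(v)] <- NA_real_
      v
    }, numeric(nrow(m$intensities)))
  }
  r <- stats::cor(x, use = "pairwise.complete.obs")
  valid <- !is.na(x)
  n_pairs <- t(valid * 1) %*% (valid * 1)
  list(r = r, n_pairs = n_pairs)
}

#' PCA of sample proteome profiles
#'
#' Centered principal component analysis over samples (samples as
#' observations, proteins as variables) on a complete (imputed) matrix,
#' with a deterministic sign convention: each component is oriented so its
#' largest-magnitude loading is positive.
#'
#' @param m a complete [quant_matrix()] (no missing values).
#' @param n_components number of components to return.
#' @return A list: `scores` (samples x components), `loadings`,
#'   `variance_explained` (fraction per component), `samples`.
#' @export
pca_report <- function(m, n_components = 5) {
  stopifnot(inherits(m, "QuantMatrix"))
  if (anyNA(m$intensities)) {
    stop("PCA needs a complete matrix; impute first")
  }
  x <- t(m$intensities)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(nc), drop = FALSE]
  sc <- p$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {                 # deterministic sign
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = sc, loadings = rot,
       variance_explained = ve[seq_len(nc)],
       samples = m$samples)
}
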