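#' Protein quantification matrix with sample and protein metadata
#'
#' The central container of the package: a proteins x samples intensity
#' matrix (with `NA` as the explicit missing state) together with one row of
#' metadata per protein (ID, gene name, molecular weight in Daltons, histone
#' flag) and one row per sample (ID, group label, replicate, and optional
#' design variables such as cell type, tissue, culture day, age and sex).
#'
#' Zero is never used to encode "not quantified"; readers convert zeros to
#' `NA` on import. The `scale` attribute records whether values are raw
#' intensities (`"raw"`) or log-transformed (`"log2"` etc.); operations that
#' only make sense on one scale check it.
#'
#' @param intensities numeric matrix, proteins in rows, samples in columns.
#'   Values must be finite or `NA`; raw-scale values must be non-negative.
#' @param proteins data.frame with columns `protein_id` (unique),
#'   `gene_name`, `mw_da` (molecular weight, Daltons, > 0) and `is_histone`
#'   (logical), one row per matrix row.
#' @param samples data.frame with columns `sample_id` (unique) and `group`,
#'   one row per matrix column. Any further columns (`cell_type`, `tissue`,
#'   `replicate`, `day`, `age`, `sex`, ...) are carried along.
#' @param scale character scalar, `"raw"` or a log scale tag such as
#'   `"log2"`.
#'
#' @return An object of class `QuantMatrix`: a list with elements
#'   `intensities`, `proteins`, `samples` and `scale`.
#' @export
quant_matrix <- function(intensities, proteins, samples, scale = "raw") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  stopifnot(is.data.frame(proteins), is.data.frame(samples))
  req_p <- c("protein_id", "gene_name", "mw_da", "is_histone")
  miss <- setdiff(req_p, names(proteins))
  if (length(miss)) {
    stop("proteins metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  req_s <- c("sample_id", "group")
  miss <- setdiff(req_s, names(samples))
  if (length(miss)) {
    stop("samples metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(proteins) != nrow(intensities)) {
    stop("proteins metadata rows (", nrow(proteins),
         ") do not match intensity rows (", nrow(intensities), ")")
  }
  if (nrow(samples) != ncol(intensities)) {
    stop("samples metadata rows (", nrow(samples),
         ") do not match intensity columns (", ncol(intensities), ")")
  }
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicate protein IDs: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
               collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample IDs")
  if (any(is.na(samples$group))) stop("every sample needs a group label")
  if (any(is.infinite(intensities))) stop("intensities must be finite or NA")
  if (identical(scale, "raw") && any(intensities < 0, na.rm = TRUE)) {
    stop("raw intensities must be non-negative")
  }
  rownames(intensities) <- proteins$protein_id
  colnames(intensities) <- samples$sample_id
  structure(
    list(intensities = intensities,
         proteins = as.data.frame(proteins, stringsAsFactors = FALSE),
         samples = as.data.frame(samples, stringsAsFactors = FALSE),
         scale = scale),
    class = "QuantMatrix"
  )
}

#' @export
print.QuantMatrix <- function(x, ...) {
  nv <- sum(!is.na(x$intensities))
  cat(sprintf(
    "QuantMatrix: %d proteins x %d samples (%s scale), %.1f%% valid values\n",
    nrow(x$intensities), ncol(x$intensities), x$scale,
    100 * nv / length(x$intensities)))
  cat("groups:", paste(unique(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.QuantMatrix <- function(x) dim(x$intensities)

#' Subset a QuantMatrix by proteins and/or samples
#'
#' @param m a [quant_matrix()] object.
#' @param proteins protein IDs, logical mask or integer indices (rows).
#' @param samples sample IDs, logical mask or integer indices (columns).
#' @return A `QuantMatrix` restricted to the selection, order as given.
#' @export
subset_quant <- function(m, proteins = NULL, samples = NULL) {
  stopifnot(inherits(m, "QuantMatrix"))
  ri <- seq_len(nrow(m$intensities))
  ci <- seq_len(ncol(m$intensities))
  if (!is.null(proteins)) {
    ri <- if (is.character(proteins)) {
      match(proteins, m$proteins$protein_id)
    } else if (is.logical(proteins)) which(proteins) else proteins
    if (anyNA(ri)) stop("unknown protein ID(s) in selection")
  }
  if (!is.null(samples)) {
    ci <- if (is.character(samples)) {
      match(samples, m$samples$sample_id)
    } else if (is.logical(samples)) which(samples) else samples
    if (anyNA(ci)) stop("unknown sample ID(s) in selection")
  }
  quant_matrix(m$intensities[ri, ci, drop = FALSE],
               m$proteins[ri, , drop = FALSE],
               m$samples[ci, , drop = FALSE],
               scale = m$scale)
}

#' Flag histone proteins from an explicit identifier list
#'
#' The proteomic ruler needs to know which rows are core histones. To stay
#' reproducible across identifier schemes, histones are flagged from an
#' explicit list (typically the `core_histones` term of a GMT annotation
#' set), never inferred from name patterns.
#'
#' @param m a [quant_matrix()] object.
#' @param ids character vector of protein IDs or gene names to flag.
#' @param by match against `"protein_id"` or `"gene_name"`.
#' @return `m` with its `is_histone` column replaced by the new flags.
#' @export
flag_histones <- function(m, ids, by = c("protein_id", "gene_name")) {
  stopifnot(inherits(m, "QuantMatrix"))
  by <- match.arg(by)
  m$proteins$is_histone <- m$proteins[[by]] %in% ids
  m
}

group_index <- function(m, group_var = "group") {
  if (!group_var %in% names(m$samples)) {
    stop("grouping variable '", group_var, "' not found in sample metadata")
  }
  g <- m$samples[[group_var]]
  keep <- !is.na(g)
  split(which(keep), factor(g[keep], levels = unique(g[keep])))
}
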