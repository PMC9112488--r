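#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated protein-groups dialect: one row per protein
#' group, columns `"Protein IDs"`, `"Gene names"`, `"Mol. weight [kDa]"`
#' (or `[Da]`), one intensity column per sample whose header starts with
#' `sample_prefix` (default the label-free `"LFQ intensity "` columns), and
#' optional `"Reverse"` / `"Potential contaminant"` flags. Rows flagged with
#' `"+"` in either flag column are dropped; intensity zeros become the
#' missing state `NA`; molecular weight is converted to Daltons when the
#' header says kDa.
#'
#' @param path path to the TSV file.
#' @param sample_prefix header prefix identifying intensity columns; the
#'   remainder of the header is the sample ID.
#' @param samples optional sample metadata data.frame with a `sample_id`
#'   column (e.g. from [read_sample_metadata()]); matched to intensity
#'   columns by ID. When absent, minimal metadata with `group = sample_id`
#'   is synthesized.
#' @return A [quant_matrix()] on the raw scale.
#' @export
read_protein_groups <- function(path, sample_prefix = "LFQ intensity ",
                                samples = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (col in c("Protein IDs", "Gene names")) {
    if (!col %in% names(tab)) {
      stop("protein groups file lacks mandatory column '", col, "'")
    }
  }
  mw_kda <- "Mol. weight [kDa]" %in% names(tab)
  mw_da <- "Mol. weight [Da]" %in% names(tab)
  if (!mw_kda && !mw_da) {
    stop("protein groups file lacks mandatory column 'Mol. weight [kDa]'")
  }
  int_cols <- names(tab)[startsWith(names(tab), sample_prefix)]
  if (!length(int_cols)) {
    stop("no intensity column matching prefix '", sample_prefix, "'")
  }
  keep <- rep(TRUE, nrow(tab))
  for (flag in c("Reverse", "Potential contaminant")) {
    if (flag %in% names(tab)) {
      keep <- keep & !(trimws(as.character(tab[[flag]])) == "+")
    }
  }
  tab <- tab[keep, , drop = FALSE]
  if (anyDuplicated(tab[["Protein IDs"]])) {
    stop("duplicate protein IDs in ", path)
  }
  ints <- as.matrix(tab[, int_cols, drop = FALSE])
  storage.mode(ints) <- "double"
  ints[ints == 0] <- NA_real_  # zero means "not quantified" in LFQ output
  sample_ids <- substring(int_cols, nchar(sample_prefix) + 1L)
  colnames(ints) <- sample_ids
  mw <- if (mw_kda) tab[["Mol. weight [kDa]"]] * 1000 else
    tab[["Mol. weight [Da]"]]
  proteins <- data.frame(
    protein_id = tab[["Protein IDs"]],
    gene_name = tab[["Gene names"]],
    mw_da = as.numeric(mw),
    is_histone = if ("Histone" %in% names(tab)) {
      trimws(as.character(tab[["Histone"]])) == "+"
    } else FALSE,
    stringsAsFactors = FALSE
  )
  if (is.null(samples)) {
    samples <- data.frame(sample_id = sample_ids, group = sample_ids,
                          stringsAsFactors = FALSE)
  } else {
    idx <- match(sample_ids, samples$sample_id)
    if (anyNA(idx)) {
      stop("sample metadata lacks sample(s): ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    }
    samples <- samples[idx, , drop = FALSE]
    rownames(samples) <- NULL
  }
  quant_matrix(ints, proteins, samples, scale = "raw")
}

#' Write a QuantMatrix as a proteinGroups-style TSV
#'
#' Inverse of [read_protein_groups()]: missing values become zeros, the
#' histone flag becomes a `"+"` column, molecular weight is written in kDa.
#'
#' @param m a raw-scale [quant_matrix()].
#' @param path output TSV path.
#' @param sample_prefix prefix for intensity column headers.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(m, path, sample_prefix = "LFQ intensity ") {
  stopifnot(inherits(m, "QuantMatrix"))
  ints <- m$intensities
  ints[is.na(ints)] <- 0
  out <- data.frame(
    `Protein IDs` = m$proteins$protein_id,
    `Gene names` = m$proteins$gene_name,
    `Mol. weight [kDa]` = m$proteins$mw_da / 1000,
    Histone = ifelse(m$proteins$is_histone, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  icols <- as.data.frame(ints, check.names = FALSE)
  names(icols) <- paste0(sample_prefix, m$samples$sample_id)
  utils::write.table(cbind(out, icols), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata CSV
#'
#' A plain CSV with one row per sample; must contain `sample_id` and
#' `group`. Optional design columns (`cell_type`, `tissue`, `replicate`,
#' `day`, `age`, `sex`) pass through untouched.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_sample_metadata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "group"), names(tab))
  if (length(miss)) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname read_sample_metadata
#' @param samples sample metadata data.frame.
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter proteins by valid-value pattern
#'
#' Applies the study-style validity filters. Two modes:
#' \describe{
#'   \item{`min_valid_in_any_group`}{keep a protein if it has at least
#'     `threshold` valid (non-missing) values in the replicates of at least
#'     one group — e.g. "two valid values in three biological replicates of
#'     at least one cell type".}
#'   \item{`min_fraction_per_group`}{keep a protein if the fraction of
#'     valid values is at least `threshold` in \emph{every} group — the
#'     strict reading of a cohort-level "70\% valid values at experimental
#'     group level". Set `per_group = FALSE` for the lenient any-group
#'     variant.}
#' }
#' The filter only drops rows; retained values are never altered, so it is
#' idempotent.
#'
#' @param m a [quant_matrix()].
#' @param mode filter mode, see above.
#' @param threshold count (`min_valid_in_any_group`) or fraction in (0, 1]
#'   (`min_fraction_per_group`).
#' @param group_var sample-metadata column defining the groups.
#' @param per_group for the fraction mode: require the fraction in every
#'   group (`TRUE`, default) or in at least one (`FALSE`).
#' @return The filtered `QuantMatrix`, protein order preserved.
#' @export
filter_valid <- function(m,
                         mode = c("min_valid_in_any_group",
                                  "min_fraction_per_group"),
                         threshold,
                         group_var = "group",
                         per_group = TRUE) {
  stopifnot(inherits(m, "QuantMatrix"))
  mode <- match.arg(mode)
  idx <- group_index(m, group_var)
  valid <- !is.na(m$intensities)
  counts <- vapply(idx, function(cols) {
    rowSums(valid[, cols, drop = FALSE])
  }, numeric(nrow(valid)))
  counts <- matrix(counts, nrow = nrow(valid),
                   dimnames = list(NULL, names(idx)))
  sizes <- lengths(idx)
  if (mode == "min_valid_in_any_group") {
    if (threshold < 1 || threshold != round(threshold)) {
      stop("threshold must be a positive integer count")
    }
    if (threshold > max(sizes)) {
      stop("threshold (", threshold, ") exceeds the largest group size (",
           max(sizes), ")")
    }
    keep <- rowSums(counts >= threshold) >= 1
  } else {
    if (threshold <= 0 || threshold > 1) {
      stop("threshold must be a fraction in (0, 1]")
    }
    frac <- sweep(counts, 2, sizes, "/")
    keep <- if (per_group) {
      rowSums(frac >= threshold) == length(idx)
    } else {
      rowSums(frac >= threshold) >= 1
    }
  }
  subset_quant(m, proteins = which(keep))
}

#' Log-transform intensities
#'
#' Elementwise log of valid values; missing entries stay missing. Errors on
#' non-positive valid values (a raw LFQ intensity of zero should already be
#' the missing state).
#'
#' @param m a raw-scale [quant_matrix()].
#' @param base logarithm base (default 2).
#' @return A `QuantMatrix` with scale `"log<base>"`.
#' @export
log_transform <- function(m, base = 2) {
  stopifnot(inherits(m, "QuantMatrix"))
  if (m$scale != "raw") stop("matrix is already on scale '", m$scale, "'")
  x <- m$intensities
  if (any(x <= 0, na.rm = TRUE)) {
    stop("non-positive valid intensities cannot be log-transformed")
  }
  m$intensities <- log(x, base = base)
  m$scale <- paste0("log", format(base))
  m
}

#' Impute missing values from a down-shifted normal distribution
#'
#' For each sample column with observed mean `mu` and standard deviation
#' `sigma` (denominator n-1), every missing entry is replaced by an
#' independent draw from `Normal(mu - shift * sigma, (width * sigma)^2)`.
#' The defaults (shift 1.8 s.d., width 0.3 s.d.) mimic a detection-limit
#' regime: values missing because they are low are filled in from the lower
#' tail of that sample's abundance distribution. Observed values are never
#' touched. Draws follow one seeded RNG stream ordered by (sample index,
#' protein index), so results do not depend on storage order.
#'
#' @param m a log-scale [quant_matrix()].
#' @param shift down-shift in units of the column s.d. (default 1.8).
#' @param width scale factor on the column s.d. (default 0.3).
#' @param seed integer seed for the imputation stream.
#' @return A complete `QuantMatrix`.
#' @export
impute_downshift <- function(m, shift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(inherits(m, "QuantMatrix"))
  if (m$scale == "raw") {
    stop("impute_downshift expects a log-transformed matrix")
  }
  if (shift < 0) stop("shift must be >= 0")
  if (width <= 0) stop("width must be > 0")
  x <- m$intensities
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2)) {
    stop("column(s) with fewer than 2 observed values (s.d. undefined): ",
         paste(colnames(x)[n_obs < 2], collapse = ", "))
  }
  withr::with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      miss <- which(is.na(x[, j]))
      if (!length(miss)) next
      mu <- mean(x[, j], na.rm = TRUE)
      sigma <- stats::sd(x[, j], na.rm = TRUE)
      x[miss, j] <- stats::rnorm(length(miss),
                                 mean = mu - shift * sigma,
                                 sd = width * sigma)
    }
  })
  m$intensities <- x
  m
}
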