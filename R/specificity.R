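#' Detection counts per protein and group
#'
#' "Detected" means a valid (non-missing) raw intensity — imputed values
#' never count as detections, so this must be computed before imputation.
#' Samples whose grouping value is `NA` (e.g. tissue samples when grouping
#' by cell type) are ignored.
#'
#' @param m a [quant_matrix()].
#' @param group_var sample-metadata column defining the groups.
#' @return A list of class `DetectionMatrix`: `n_detected` (proteins x
#'   groups), `n_replicates` (per group), `protein_ids`.
#' @export
detection_counts <- function(m, group_var = "group") {
  stopifnot(inherits(m, "QuantMatrix"))
  idx <- group_index(m, group_var)
  valid <- !is.na(m$intensities)
  det <- vapply(idx, function(cols) {
    rowSums(valid[, cols, drop = FALSE])
  }, numeric(nrow(valid)))
  det <- matrix(det, nrow = nrow(valid),
                dimnames = list(m$proteins$protein_id, names(idx)))
  structure(list(n_detected = det, n_replicates = lengths(idx),
                 protein_ids = m$proteins$protein_id),
            class = "DetectionMatrix")
}

#' One-vs-rest Fisher exact test on detection counts
#'
#' Per protein, a one-sided Fisher exact test of detection enrichment in
#' the target group against all other groups pooled, on the 2x2 table
#' `[[detected_target, undetected_target], [detected_rest,
#' undetected_rest]]` with alternative "greater" (over-detection in the
#' target; a two-sided test would also flag depleted proteins).
#'
#' @param d a [detection_counts()] result.
#' @param target name of the target group.
#' @return Named numeric vector of p-values, one per protein.
#' @export
fisher_one_vs_rest <- function(d, target) {
  stopifnot(inherits(d, "DetectionMatrix"))
  if (!target %in% colnames(d$n_detected)) {
    stop("unknown target group '", target, "'")
  }
  if (ncol(d$n_detected) < 2) stop("need at least 2 groups")
  n_t <- d$n_replicates[[target]]
  if (n_t < 1) stop("target group has zero replicates")
  n_r <- sum(d$n_replicates) - n_t
  det_t <- d$n_detected[, target]
  det_r <- rowSums(d$n_detected) - det_t
  # one-sided Fisher == hypergeometric upper tail on the margins
  p <- stats::phyper(det_t - 1, det_t + det_r,
                     n_t + n_r - det_t - det_r, n_t,
                     lower.tail = FALSE)
  stats::setNames(pmin(p, 1), d$protein_ids)
}

#' Candidate cell-type markers from detection patterns
#'
#' A protein is a candidate marker for group `t` iff it is detected in at
#' least `min_detected` replicates of `t`, detected in zero replicates of
#' every other group, and its one-vs-rest Fisher exact p-value is below
#' `alpha` (strict inequality). The uniqueness clause makes marker lists
#' disjoint across groups by construction. The screen is applied
#' uncorrected, as is conventional for this detection-pattern criterion; a
#' BH-adjusted column is included for reference.
#'
#' @param d a [detection_counts()] result.
#' @param min_detected minimum detections in the target group (default 2).
#' @param alpha Fisher p-value cutoff (default 0.05).
#' @return A list per group of data.frames (protein_id, n_detected,
#'   n_replicates, p, q).
#' @export
candidate_markers <- function(d, min_detected = 2, alpha = 0.05) {
  stopifnot(inherits(d, "DetectionMatrix"))
  if (any(min_detected > d$n_replicates)) {
    stop("min_detected (", min_detected,
         ") exceeds replicate count of group(s): ",
         paste(names(d$n_replicates)[min_detected > d$n_replicates],
               collapse = ", "))
  }
  groups <- colnames(d$n_detected)
  out <- lapply(groups, function(t) {
    det_t <- d$n_detected[, t]
    det_other <- rowSums(d$n_detected) - det_t
    p <- fisher_one_vs_rest(d, t)
    q <- stats::p.adjust(p, method = "BH")
    keep <- det_t >= min_detected & det_other == 0 & p < alpha
    data.frame(protein_id = d$protein_ids[keep],
               n_detected = unname(det_t[keep]),
               n_replicates = rep(d$n_replicates[[t]], sum(keep)),
               p = unname(p[keep]), q = unname(q[keep]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  stats::setNames(out, groups)
}

#' Strict cell-type-unique markers
#'
#' Proteins detected in every replicate of exactly one group and in zero
#' replicates of all others — the stringent "uniquely quantified in all
#' biological replicates" definition. Always a subset of the candidate
#' list whenever `alpha` exceeds the all-vs-none Fisher p-value.
#'
#' @param d a [detection_counts()] result.
#' @return A named list (per group) of protein-ID vectors.
#' @export
strict_markers <- function(d) {
  stopifnot(inherits(d, "DetectionMatrix"))
  groups <- colnames(d$n_detected)
  out <- lapply(groups, function(t) {
    det_t <- d$n_detected[, t]
    det_other <- rowSums(d$n_detected) - det_t
    d$protein_ids[det_t == d$n_replicates[[t]] & det_other == 0]
  })
  stats::setNames(out, groups)
}

#' Best-correlated partner profiles for one protein
#'
#' Pearson correlation of a protein's abundance profile across samples
#' against every other protein (pairwise-complete observations, requiring
#' at least `min_pairs` shared valid samples), ranked by descending r.
#' Used to attach functional context to uncharacterized proteins.
#'
#' @param m a log-scale [quant_matrix()].
#' @param protein_id the query protein.
#' @param min_pairs minimum shared valid samples per comparison.
#' @return data.frame ranked by r: partner protein_id, gene_name, r,
#'   n_pairs.
#' @export
correlation_partner <- function(m, protein_id, min_pairs = 5) {
  stopifnot(inherits(m, "QuantMatrix"))
  i <- match(protein_id, m$proteins$protein_id)
  if (is.na(i)) stop("protein '", protein_id, "' not present")
  x <- m$intensities[i, ]
  others <- setdiff(seq_len(nrow(m$intensities)), i)
  r <- rep(NA_real_, length(others))
  np <- integer(length(others))
  for (j in seq_along(others)) {
    y <- m$intensities[others[j], ]
    ok <- !is.na(x) & !is.na(y)
    np[j] <- sum(ok)
    if (np[j] >= min_pairs && stats::sd(x[ok]) > 0 &&
        stats::sd(y[ok]) > 0) {
      r[j] <- stats::cor(x[ok], y[ok])
    }
  }
  out <- data.frame(protein_id = m$proteins$protein_id[others],
                    gene_name = m$proteins$gene_name[others],
                    r = r, n_pairs = np,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$r), , drop = FALSE]
  out[order(-out$r, out$protein_id), , drop = FALSE]
}
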