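#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_i = min over ranks >= rank_i of
#' min(1, p * m / rank)`, input order preserved. Thin wrapper around
#' [stats::p.adjust()] with input validation.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values, same order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  stats::p.adjust(p, method = "BH")
}

# Partial F tests of nested linear models, vectorized over proteins.
# Y: proteins x samples; both designs share all samples, so one QR each
# suffices for every protein (standard omics row-test computation).
partial_f_tests <- function(Y, X_full, X_red) {
  qf <- qr(X_full)
  qr_ <- qr(X_red)
  if (qf$rank < ncol(X_full)) {
    aliased <- colnames(X_full)[qf$pivot[-seq_len(qf$rank)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  Yt <- t(Y)
  rss_full <- colSums(qr.resid(qf, Yt)^2)
  rss_red <- colSums(qr.resid(qr_, Yt)^2)
  df1 <- qf$rank - qr_$rank
  df2 <- nrow(Yt) - qf$rank
  if (df1 < 1 || df2 < 1) stop("insufficient degrees of freedom")
  scale_tol <- 1e-12 * pmax(colSums(Yt^2), 1)
  degenerate <- rss_full <= scale_tol
  f <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # zero residual variance: p = 0 by convention when the factor explains
  # anything at all, p = 1 for an all-constant response
  delta <- rss_red - rss_full
  p[degenerate] <- ifelse(delta[degenerate] > scale_tol[degenerate], 0, 1)
  f[degenerate & delta <= scale_tol[degenerate]] <- 0
  list(f = f, p = p, df1 = df1, df2 = df2, degenerate = degenerate,
       rss_full = rss_full)
}

diff_result <- function(m, ft, fdr) {
  q <- bh_adjust(ft$p)
  out <- data.frame(protein_id = m$proteins$protein_id,
                    gene_name = m$proteins$gene_name,
                    F = ft$f, df1 = ft$df1, df2 = ft$df2,
                    p = ft$p, q = q,
                    significant = q < fdr,
                    degenerate = ft$degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fdr") <- fdr
  class(out) <- c("DiffResult", "data.frame")
  out
}

check_complete <- function(m) {
  if (m$scale == "raw") {
    stop("tests expect a log-transformed matrix (see log_transform)")
  }
  if (anyNA(m$intensities)) {
    stop("tests expect a complete matrix; impute first (impute_downshift)")
  }
}

#' One-way ANOVA across groups, per protein
#'
#' Per-protein F test of equal group means on a complete log2 matrix, with
#' BH adjustment across all tested proteins and a significance flag at the
#' requested FDR. Proteins with zero residual variance are reported with a
#' `degenerate` flag (p = 0 by convention when group means differ), never
#' silently dropped.
#'
#' @param m a complete log-scale [quant_matrix()].
#' @param group_var grouping column (>= 2 groups with >= 2 samples each).
#' @param fdr BH FDR threshold for the significance flag (default 0.05).
#' @return A `DiffResult` data.frame: protein_id, F, df1, df2, p, q,
#'   significant, degenerate.
#' @export
anova_oneway <- function(m, group_var = "group", fdr = 0.05) {
  stopifnot(inherits(m, "QuantMatrix"))
  check_complete(m)
  idx <- group_index(m, group_var)
  if (length(idx) < 2) stop("need >= 2 groups")
  if (any(lengths(idx) < 2)) stop("every group needs >= 2 samples")
  cols <- unlist(idx, use.names = FALSE)
  g <- factor(rep(names(idx), lengths(idx)), levels = names(idx))
  Y <- m$intensities[, cols, drop = FALSE]
  X_full <- stats::model.matrix(~g)
  X_red <- stats::model.matrix(~1, data = data.frame(row = seq_along(g)))
  diff_result(m, partial_f_tests(Y, X_full, X_red), fdr)
}

#' ANCOVA: group effect adjusted for covariates, per protein
#'
#' Per protein, fits `log2 intensity ~ group + covariates` by least
#' squares and tests the group factor with a partial F test given the
#' covariates (categorical covariates such as sex enter as indicator
#' columns). BH adjustment across proteins; rank-deficient (confounded)
#' designs raise an error naming the aliased terms.
#'
#' @param m a complete log-scale [quant_matrix()].
#' @param group_var grouping column.
#' @param covariates sample-metadata columns to adjust for
#'   (default `c("age", "sex")`).
#' @param fdr BH FDR threshold for the significance flag.
#' @return A `DiffResult` data.frame (see [anova_oneway()]).
#' @export
ancova_group_test <- function(m, group_var = "group",
                              covariates = c("age", "sex"), fdr = 0.05) {
  stopifnot(inherits(m, "QuantMatrix"))
  check_complete(m)
  miss <- setdiff(c(group_var, covariates), names(m$samples))
  if (length(miss)) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  dat <- m$samples[, c(group_var, covariates), drop = FALSE]
  if (anyNA(dat)) stop("covariates must be present for all samples")
  dat[[group_var]] <- factor(dat[[group_var]],
                             levels = unique(dat[[group_var]]))
  for (cv in covariates) {
    if (is.character(dat[[cv]]) || is.logical(dat[[cv]])) {
      dat[[cv]] <- factor(dat[[cv]])
    }
  }
  f_full <- stats::as.formula(paste(
    "~", paste(c(group_var, covariates), collapse = " + ")))
  f_red <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  X_full <- stats::model.matrix(f_full, dat)
  X_red <- stats::model.matrix(f_red, dat)
  diff_result(m, partial_f_tests(m$intensities, X_full, X_red), fdr)
}

#' Tukey post hoc pairwise comparisons on covariate-adjusted group means
#'
#' For each protein in `proteins` (normally the ANCOVA-significant set),
#' compares all group pairs with the studentized-range (Tukey-Kramer)
#' procedure: the difference of covariate-adjusted group means divided by
#' its model-based standard error, referred to the studentized range
#' distribution with the residual degrees of freedom of the per-protein
#' linear model. The family is the `k(k-1)/2` comparisons within each
#' protein; no second adjustment is applied across proteins.
#'
#' @param m a complete log-scale [quant_matrix()].
#' @param group_var grouping column.
#' @param proteins protein IDs to test.
#' @param covariates covariate columns, or `NULL` for the unadjusted case.
#' @return data.frame: protein_id, group_a, group_b, diff (adjusted mean of
#'   b minus a, log2), se, p_tukey.
#' @export
tukey_posthoc <- function(m, group_var = "group", proteins,
                          covariates = NULL) {
  stopifnot(inherits(m, "QuantMatrix"))
  check_complete(m)
  idx <- match(proteins, m$proteins$protein_id)
  if (anyNA(idx)) stop("unknown protein ID(s) in selection")
  dat <- m$samples[, c(group_var, covariates), drop = FALSE]
  dat[[group_var]] <- factor(dat[[group_var]],
                             levels = unique(dat[[group_var]]))
  for (cv in covariates) {
    if (is.character(dat[[cv]]) || is.logical(dat[[cv]])) {
      dat[[cv]] <- factor(dat[[cv]])
    }
  }
  lev <- levels(dat[[group_var]])
  k <- length(lev)
  if (k < 2) stop("need >= 2 groups")
  rhs <- paste(c(group_var, covariates), collapse = " + ")
  pairs <- utils::combn(lev, 2)
  rows <- list()
  for (i in idx) {
    dat$.y <- m$intensities[i, ]
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
    df_res <- fit$df.residual
    cf <- stats::coef(fit)
    V <- stats::vcov(fit)
    # treatment contrasts: group coefficient of the reference level is 0
    cvec <- stats::setNames(numeric(length(cf)), names(cf))
    gcoef <- function(level) {
      nm <- paste0(group_var, level)
      if (nm %in% names(cf)) nm else NA_character_
    }
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      ca <- cvec; cb <- cvec
      if (!is.na(gcoef(a))) ca[gcoef(a)] <- 1
      if (!is.na(gcoef(b))) cb[gcoef(b)] <- 1
      cc <- cb - ca
      diff <- sum(cc * cf)
      se <- sqrt(drop(t(cc) %*% V %*% cc))
      p <- stats::ptukey(sqrt(2) * abs(diff) / se, nmeans = k,
                         df = df_res, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = m$proteins$protein_id[i],
        group_a = a, group_b = b, diff = diff, se = se, p_tukey = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Z-score group-mean profiles and cluster hierarchically
#'
#' Computes per-protein group means, z-scores each protein's profile
#' across groups (mean 0, s.d. 1; flat profiles map to all-zero), then
#' clusters with agglomerative hierarchical clustering on Euclidean
#' distance (average linkage by default) and cuts the tree into `k`
#' clusters. Cluster IDs are relabeled by order of first appearance in the
#' input protein order, so the assignment is deterministic.
#'
#' @param m a complete log-scale [quant_matrix()].
#' @param proteins protein IDs to cluster (normally the significant set).
#' @param group_var grouping column for the mean profiles.
#' @param k number of clusters.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return A list: `assignment` (data.frame protein_id, cluster),
#'   `profiles` (z-scored group-mean matrix), `tree` (`hclust` object).
#' @export
zscore_cluster <- function(m, proteins, group_var = "group", k,
                           linkage = "average") {
  stopifnot(inherits(m, "QuantMatrix"))
  check_complete(m)
  if (!length(proteins)) stop("empty protein set")
  ridx <- match(proteins, m$proteins$protein_id)
  if (anyNA(ridx)) stop("unknown protein ID(s) in selection")
  gidx <- group_index(m, group_var)
  means <- vapply(gidx, function(cols) {
    rowMeans(m$intensities[ridx, cols, drop = FALSE])
  }, numeric(length(ridx)))
  means <- matrix(means, nrow = length(ridx),
                  dimnames = list(proteins, names(gidx)))
  mu <- rowMeans(means)
  sd_ <- apply(means, 1, stats::sd)
  z <- (means - mu) / ifelse(sd_ > 0, sd_, 1)
  z[sd_ == 0, ] <- 0
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = linkage)
  raw <- stats::cutree(tree, k = min(k, length(proteins)))
  cluster <- match(raw, unique(raw))     # relabel by first appearance
  list(assignment = data.frame(protein_id = proteins, cluster = cluster,
                               stringsAsFactors = FALSE),
       profiles = z, tree = tree)
}

#' Per-protein equal-variance and normality screen
#'
#' Reported diagnostic (it does not gate any test): per protein, a
#' Bartlett test of equal variances across groups and a Shapiro-Wilk test
#' on within-group-centered residuals, plus the proportion of proteins
#' passing each screen at the given alpha.
#'
#' @param m a complete log-scale [quant_matrix()].
#' @param group_var grouping column.
#' @param alpha screening level (default 0.05).
#' @return A list: `per_protein` (p_equal_var, p_normal per protein),
#'   `prop_equal_var`, `prop_normal`.
#' @export
variance_normality_screen <- function(m, group_var = "group",
                                      alpha = 0.05) {
  stopifnot(inherits(m, "QuantMatrix"))
  check_complete(m)
  idx <- group_index(m, group_var)
  g <- factor(rep(names(idx), lengths(idx)), levels = names(idx))
  cols <- unlist(idx, use.names = FALSE)
  n <- nrow(m$intensities)
  p_var <- p_norm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- m$intensities[i, cols]
    resid <- unlist(lapply(split(y, g), function(v) v - mean(v)),
                    use.names = FALSE)
    p_var[i] <- tryCatch(stats::bartlett.test(y, g)$p.value,
                         error = function(e) NA_real_)
    p_norm[i] <- tryCatch(stats::shapiro.test(resid)$p.value,
                          error = function(e) NA_real_)
  }
  list(per_protein = data.frame(protein_id = m$proteins$protein_id,
                                p_equal_var = p_var, p_normal = p_norm,
                                stringsAsFactors = FALSE),
       prop_equal_var = mean(p_var > alpha, na.rm = TRUE),
       prop_normal = mean(p_norm > alpha, na.rm = TRUE))
}
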