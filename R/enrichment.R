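#' Fisher-exact term enrichment against an explicit background
#'
#' One-sided hypergeometric over-representation test per annotation term:
#' with `N` background IDs, `K` of them in the term, and a foreground of
#' `n` IDs of which `x` are in the term, `p = P(X >= x)` for
#' `X ~ Hypergeometric(N, K, n)`. The background is always explicit and
#' user-supplied (typically the quantified proteome), never a whole-genome
#' default — detection bias would otherwise inflate every term. Foreground
#' IDs outside the background are dropped (counted in the returned
#' `n_dropped`). Terms with fewer than `min_term` background members are
#' skipped; an optional `min_fraction` filter additionally requires the
#' foreground to cover that fraction of the term. BH adjustment across the
#' tested terms, significance flag at `fdr`.
#'
#' @param foreground character vector of IDs of interest.
#' @param background character vector, the reference universe.
#' @param terms an [annotation_set()].
#' @param min_term minimum background members per term (default 10).
#' @param min_fraction minimum fraction of the term's background members
#'   present in the foreground (default 0, disabled; 0.1 mirrors a
#'   "10 percent of genes per term" floor).
#' @param fdr BH threshold for the significance flag (default 0.01).
#' @return A list of class `EnrichmentResult`: `table` (term, fg_hits,
#'   fg_size, bg_hits, bg_size, odds_ratio, p, q, significant, members)
#'   and `n_dropped`.
#' @export
fisher_enrich <- function(foreground, background, terms, min_term = 10,
                          min_fraction = 0, fdr = 0.01) {
  stopifnot(inherits(terms, "AnnotationSet"))
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (!length(foreground)) stop("empty foreground")
  if (!length(background)) stop("empty background")
  n_dropped <- sum(!foreground %in% background)
  if (n_dropped > 0) {
    warning(n_dropped, " foreground ID(s) outside the background dropped")
    foreground <- intersect(foreground, background)
    if (!length(foreground)) stop("no foreground IDs left in background")
  }
  N <- length(background)
  n <- length(foreground)
  rows <- list()
  for (term in names(terms$sets)) {
    in_bg <- intersect(terms$sets[[term]], background)
    K <- length(in_bg)
    if (K < min_term) next
    hits <- intersect(in_bg, foreground)
    x <- length(hits)
    if (min_fraction > 0 && x / K < min_fraction) next
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    # sample odds ratio of the 2x2 table; 0 when the term misses the
    # foreground entirely
    a <- x; b <- n - x; c_ <- K - x; d <- (N - K) - (n - x)
    or <- if (a == 0) 0 else if (c_ == 0 || b == 0) Inf else
      (a * d) / (b * c_)
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, fg_hits = x, fg_size = n, bg_hits = K, bg_size = N,
      odds_ratio = or, p = min(p, 1),
      members = paste(sort(hits), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), fg_hits = integer(0),
               fg_size = integer(0), bg_hits = integer(0),
               bg_size = integer(0), odds_ratio = numeric(0),
               p = numeric(0), members = character(0),
               stringsAsFactors = FALSE)
  tab$q <- if (nrow(tab)) bh_adjust(tab$p) else numeric(0)
  tab$significant <- tab$q < fdr
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, n_dropped = n_dropped),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: %d terms tested, %d significant\n",
              nrow(x$table), sum(x$table$significant)))
  invisible(x)
}

#' Dominance of a term between two ID sets
#'
#' For each term, the percentage of term-associated proteins contributed
#' by each of two sets (relative to the set's own size), labeling the term
#' dominant in whichever set contributes the larger percentage, or
#' `"shared"` on an exact tie. Used to compare enrichment maps between two
#' related groups.
#'
#' @param set_a,set_b character ID vectors.
#' @param terms an [annotation_set()].
#' @param label_a,label_b labels used in the output.
#' @return data.frame: term, hits_a, hits_b, pct_a, pct_b, dominant.
#' @export
percent_associated <- function(set_a, set_b, terms,
                               label_a = "A", label_b = "B") {
  stopifnot(inherits(terms, "AnnotationSet"))
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!length(set_a) || !length(set_b)) stop("both sets must be nonempty")
  rows <- lapply(names(terms$sets), function(term) {
    mem <- terms$sets[[term]]
    ha <- sum(set_a %in% mem)
    hb <- sum(set_b %in% mem)
    pa <- 100 * ha / length(set_a)
    pb <- 100 * hb / length(set_b)
    dom <- if (pa > pb) label_a else if (pb > pa) label_b else "shared"
    data.frame(term = term, hits_a = ha, hits_b = hb,
               pct_a = pa, pct_b = pb, dominant = dom,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
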