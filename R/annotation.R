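#' Named term -> member sets (GMT-backed annotation)
#'
#' Carrier for protein-class, subcellular-compartment, pathway, complex and
#' histone annotations. Semantically a named list of character sets; term
#' membership is deduplicated, term names are unique.
#'
#' @param sets named list of character vectors (term -> member IDs).
#' @param descriptions optional character vector, one per term (GMT field 2).
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets))) stop("sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate term names")
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(descriptions)) {
    descriptions <- rep("", length(sets))
  }
  stopifnot(length(descriptions) == length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("AnnotationSet: %d terms, member counts %s\n",
              length(x$sets),
              if (length(sizes)) paste0("[", min(sizes), ", ", max(sizes), "]")
              else "[]"))
  invisible(x)
}

#' @export
length.AnnotationSet <- function(x) length(x$sets)

#' Read a GMT file into an AnnotationSet
#'
#' Standard GMT: one term per line, tab-separated fields
#' `term<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a term are stored once. An empty file yields an empty set.
#'
#' @param path path to a GMT file.
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(annotation_set(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(nf < 3), collapse = ", "))
  }
  terms <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(members) <- terms
  annotation_set(members, descriptions = desc)
}

#' Write an AnnotationSet to a GMT file
#'
#' Inverse of [read_gmt()]; a write/read round trip preserves membership.
#'
#' @param set an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(set, path) {
  stopifnot(inherits(set, "AnnotationSet"))
  lines <- vapply(names(set$sets), function(term) {
    paste(c(term, set$descriptions[[term]], set$sets[[term]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Default core-histone gene list
#'
#' Gene names of the replication-dependent core histone families (H2A, H2B,
#' H3, H4) plus common variants, shipped as a GMT file. Used to flag
#' histones for the proteomic ruler when the data carry HGNC-style gene
#' names.
#'
#' @return Character vector of gene names.
#' @export
core_histone_genes <- function() {
  gmt <- read_gmt(system.file("extdata", "core_histones.gmt",
                              package = "protruler", mustWork = TRUE))
  gmt$sets[["core_histones"]]
}
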