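# Constrained gene-set over-representation analysis: one-sided
# hypergeometric tests with a term-size ceiling, Benjamini-Hochberg
# correction, and a minimum-coverage requirement.

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-delimited as
#' `term <tab> description <tab> gene1 <tab> gene2 ...`. Genes duplicated
#' within a term are counted once.
#'
#' @param path GMT file path.
#' @return object of class `cs_genesets`: a named list of character gene
#'   sets, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields")
  }
  terms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(terms)) {
    stop("duplicated term name(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(sets) == 0L)) {
    stop("GMT term(s) with no genes: ",
         paste(terms[lengths(sets) == 0L], collapse = ", "))
  }
  names(sets) <- terms
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, "", 2L),
                                                terms)
  class(sets) <- "cs_genesets"
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection named list of character gene sets.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(length(collection) >= 1, !is.null(names(collection)))
  desc <- descriptions %||% attr(collection, "descriptions") %||%
    stats::setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(tm) {
    paste(c(tm, desc[[tm]] %||% "na", collection[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term for over-representation of the query within the universe
#' with a one-sided (upper-tail) hypergeometric test. Terms are intersected
#' with the universe first, terms whose (intersected) size reaches
#' `max_term_size` are excluded before testing, p-values are BH-adjusted
#' across the tested terms, and a term is significant when its adjusted
#' p-value is below `alpha` and its coverage (overlap / query size) is at
#' least `min_coverage`.
#'
#' @param query character vector of genes (must lie within `universe`).
#' @param universe character vector: the gene universe (genes surviving
#'   preprocessing for the dataset, by default — not the whole genome).
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param max_term_size exclusive upper bound on tested term sizes.
#' @param min_coverage minimum overlap / query-size fraction.
#' @param alpha significance cutoff on the adjusted p-value.
#' @return tibble sorted by raw p: `term`, `overlap`, `term_size`, `p`,
#'   `adj_p`, `coverage`, `significant`.
#' @export
hypergeometric_enrichment <- function(query, universe, collection,
                                      max_term_size = 500,
                                      min_coverage = 0.02, alpha = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) stop("empty query gene list")
  if (!length(universe)) stop("empty gene universe")
  if (length(setdiff(query, universe))) {
    stop("query contains gene(s) outside the universe")
  }
  sets <- lapply(collection, intersect, y = universe)
  size <- lengths(sets)
  keep <- size > 0 & size < max_term_size
  sets <- sets[keep]
  size <- size[keep]
  if (!length(sets)) {
    return(tibble::tibble(term = character(0), overlap = integer(0),
                          term_size = integer(0), p = numeric(0),
                          adj_p = numeric(0), coverage = numeric(0),
                          significant = logical(0)))
  }
  overlap <- unname(vapply(sets, function(s) length(intersect(s, query)), 0L))
  size <- unname(size)
  # upper-tail hypergeometric: P(K >= overlap)
  p <- stats::phyper(overlap - 1L, size, length(universe) - size,
                     length(query), lower.tail = FALSE)
  out <- tibble::tibble(
    term = names(sets),
    overlap = overlap,
    term_size = as.integer(size),
    p = as.numeric(p),
    adj_p = stats::p.adjust(p, method = "BH"),
    coverage = overlap / length(query)
  ) |>
    dplyr::mutate(significant = .data$adj_p < alpha &
                    .data$coverage >= min_coverage) |>
    dplyr::arrange(.data$p, .data$term)
  out
}
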