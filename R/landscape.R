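# Integration of per-dataset interaction calls into a dataset x gene x score
# landscape, with metadata and gene-family annotation, frequency summaries,
# 2D slices, and the context-dependence analysis of a focal stimulus.

#' Build an interaction landscape from per-dataset calls
#'
#' @param calls named list of call tibbles (one per dataset, names are
#'   dataset ids), or a single tibble with a `dataset` column.
#' @param meta tibble of dataset metadata with a `dataset` column matching
#'   the call tables (plus accession, species, cell_type, signal_X,
#'   signal_Y, time_point as available).
#' @param gene_families optional tibble with columns `family`, `gene`.
#' @param taxonomy the `cs_taxonomy` the calls were made against.
#' @return object of class `cs_landscape`.
#' @export
build_landscape <- function(calls, meta, gene_families = NULL,
                            taxonomy = NULL) {
  if (is.data.frame(calls)) {
    stopifnot("dataset" %in% colnames(calls))
    calls <- tibble::as_tibble(calls)
  } else {
    stopifnot(is.list(calls), !is.null(names(calls)))
    calls <- dplyr::bind_rows(
      lapply(calls, tibble::as_tibble), .id = "dataset"
    )
  }
  meta <- tibble::as_tibble(meta)
  stopifnot("dataset" %in% colnames(meta))
  dup <- meta$dataset[duplicated(meta$dataset)]
  if (length(dup)) {
    stop("duplicate dataset id(s) in metadata: ",
         paste(unique(dup), collapse = ", "))
  }
  unknown <- setdiff(unique(calls$dataset), meta$dataset)
  if (length(unknown)) {
    stop("calls reference dataset(s) without metadata: ",
         paste(unknown, collapse = ", "))
  }
  if (!all(is.finite(calls$score))) stop("non-finite interaction score(s)")
  if (!is.null(gene_families)) {
    gene_families <- tibble::as_tibble(gene_families)
    stopifnot(all(c("family", "gene") %in% colnames(gene_families)))
  }
  structure(
    list(calls = calls, meta = meta, families = gene_families,
         taxonomy = taxonomy),
    class = "cs_landscape"
  )
}

#' @export
print.cs_landscape <- function(x, ...) {
  cat("Interaction landscape:", nrow(x$calls), "calls across",
      length(unique(x$calls$dataset)), "datasets (",
      sum(x$calls$sign != "0"), "interacting )\n")
  invisible(x)
}

#' Tidy a landscape into its call table
#' @param x a `cs_landscape`.
#' @param ... unused.
#' @return tibble of calls with dataset metadata joined.
#' @export
tidy.cs_landscape <- function(x, ...) {
  dplyr::left_join(x$calls, x$meta, by = "dataset")
}

#' Category frequencies over the interacting calls
#'
#' Proportion of each interaction category among the calls whose profile has
#' a nonzero interaction sign (additive and constant calls are excluded from
#' the denominator). Categories without calls are reported with proportion 0.
#'
#' @param landscape a `cs_landscape`.
#' @return tibble `category`, `n`, `proportion` (proportions sum to 1).
#' @export
profile_frequencies <- function(landscape) {
  stopifnot(inherits(landscape, "cs_landscape"))
  inter <- landscape$calls[landscape$calls$sign != "0", ]
  if (!nrow(inter)) stop("landscape has no interacting calls")
  cats <- setdiff(.cs_categories, c("additive", "constant"))
  n <- table(factor(inter$category, levels = cats))
  tibble::tibble(
    category = cats,
    n = as.integer(n),
    proportion = as.numeric(n) / nrow(inter)
  )
}

#' Slice the landscape by gene family
#'
#' Projects the landscape onto a gene family: one row per (gene, dataset)
#' call, carrying the score magnitude, the interaction sign and the profile.
#'
#' @param landscape a `cs_landscape` built with gene-family annotations.
#' @param gene_family family name to slice by.
#' @param datasets optional dataset-id filter (default: all datasets).
#' @return tibble of class `cs_landscape_slice`: `gene`, `dataset`,
#'   `profile_id`, `category`, `score`, `abs_score`, `sign`.
#' @export
slice_landscape <- function(landscape, gene_family, datasets = NULL) {
  stopifnot(inherits(landscape, "cs_landscape"))
  if (is.null(landscape$families)) stop("landscape has no gene-family annotations")
  if (!gene_family %in% landscape$families$family) {
    stop("unknown gene family: ", gene_family)
  }
  genes <- landscape$families$gene[landscape$families$family == gene_family]
  keep_ds <- datasets %||% unique(landscape$calls$dataset)
  bad <- setdiff(keep_ds, landscape$meta$dataset)
  if (length(bad)) stop("unknown dataset id(s): ", paste(bad, collapse = ", "))
  out <- landscape$calls |>
    dplyr::filter(.data$gene %in% genes, .data$dataset %in% keep_ds) |>
    dplyr::transmute(
      gene = .data$gene, dataset = .data$dataset,
      profile_id = .data$profile_id, category = .data$category,
      score = .data$score, abs_score = abs(.data$score), sign = .data$sign
    )
  attr(out, "family") <- gene_family
  attr(out, "datasets") <- keep_ds
  class(out) <- c("cs_landscape_slice", class(out))
  out
}

#' Genes whose profile encodes a qualitative change of a focal stimulus
#'
#' For each dataset and each requested change type, lists the genes whose
#' assigned profile encodes that qualitative change (suppression, reversal,
#' or an emergent response) of the focal stimulus's mono-treatment effect.
#' Profile membership is resolved through the taxonomy's `modifies`
#' annotation, with X/Y roles honoured: a profile counts for focal role X
#' when it modifies X (or both stimuli).
#'
#' @param landscape a `cs_landscape` built with a taxonomy.
#' @param focal_role `"X"` or `"Y"`: which stimulus of each dataset is focal.
#' @param change_types subset of `c("suppression", "antagonistic_reversal",
#'   "synergistic_reversal", "emergent")`.
#' @return tibble `dataset`, `change_type`, `gene`, `profile_id`, `score`
#'   (zero rows when nothing matches).
#' @export
qualitative_change_analysis <- function(landscape,
                                        focal_role = c("X", "Y"),
                                        change_types = c("suppression",
                                                         "antagonistic_reversal",
                                                         "synergistic_reversal",
                                                         "emergent")) {
  stopifnot(inherits(landscape, "cs_landscape"))
  focal_role <- match.arg(focal_role)
  allowed <- c("suppression", "antagonistic_reversal",
               "synergistic_reversal", "emergent")
  bad <- setdiff(change_types, allowed)
  if (length(bad)) stop("unsupported change type(s): ", paste(bad, collapse = ", "))
  tax <- landscape$taxonomy
  if (is.null(tax)) stop("landscape was built without a taxonomy")
  signal_col <- paste0("signal_", focal_role)
  if (signal_col %in% colnames(landscape$meta)) {
    miss <- landscape$meta$dataset[is.na(landscape$meta[[signal_col]])]
    if (length(miss)) {
      stop("focal stimulus ", focal_role, " absent from metadata of dataset(s): ",
           paste(miss, collapse = ", "))
    }
  }
  prof <- tax$profiles
  modifies <- prof$modifies[match(landscape$calls$profile_id, prof$id)]
  landscape$calls |>
    dplyr::mutate(modifies = modifies) |>
    dplyr::filter(.data$category %in% change_types,
                  .data$modifies %in% c(focal_role, "both")) |>
    dplyr::transmute(
      dataset = .data$dataset, change_type = .data$category,
      gene = .data$gene, profile_id = .data$profile_id, score = .data$score
    ) |>
    dplyr::arrange(.data$dataset, .data$change_type, .data$gene)
}

#' Functions emerging only under the combination treatment
#'
#' Terms significantly enriched in the combination-responsive gene list and
#' not significantly enriched in the genes regulated by the focal stimulus
#' alone.
#'
#' @param combo_genes genes showing the combination-specific response.
#' @param mono_genes genes regulated by the focal stimulus alone (may be
#'   empty).
#' @param collection gene-set collection (named list).
#' @param universe gene universe containing both lists.
#' @inheritParams hypergeometric_enrichment
#' @return enrichment tibble (as [hypergeometric_enrichment()]) restricted to
#'   terms enriched in the combination list only.
#' @export
emergent_functions <- function(combo_genes, mono_genes, collection, universe,
                               max_term_size = 500, min_coverage = 0.02,
                               alpha = 0.05) {
  combo <- hypergeometric_enrichment(combo_genes, universe, collection,
                                     max_term_size, min_coverage, alpha)
  hit <- combo[combo$significant, , drop = FALSE]
  if (!length(mono_genes)) return(hit)
  mono <- hypergeometric_enrichment(mono_genes, universe, collection,
                                    max_term_size, min_coverage, alpha)
  hit[!hit$term %in% mono$term[mono$significant], , drop = FALSE]
}
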