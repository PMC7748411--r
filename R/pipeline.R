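# Per-dataset analysis: probe collapse, coefficient-of-variation and
# differential-expression gating, signal filtering, classification, and
# Bliss-index interaction scoring.

#' Bundle a combination-treatment dataset
#'
#' @param expression numeric genes (or probes) x samples matrix of normalised
#'   log2 expression, with row and column names.
#' @param design tibble/data frame with columns `sample` and `condition`
#'   (tokens `CTRL`, `X`, `Y`, `COMBO`), one row per sample.
#' @param probe_map optional tibble with columns `probe`, `gene`.
#' @param meta optional named list or one-row tibble of dataset metadata
#'   (accession, species, cell_type, signal_X, signal_Y, time_point).
#' @return object of class `cs_dataset`.
#' @export
new_dataset_bundle <- function(expression, design, probe_map = NULL,
                               meta = NULL) {
  stopifnot(is.matrix(expression), !is.null(colnames(expression)),
            !is.null(rownames(expression)))
  design <- tibble::as_tibble(design)
  stopifnot(all(c("sample", "condition") %in% colnames(design)))
  if (anyDuplicated(design$sample)) {
    stop("duplicated sample name(s): ",
         paste(unique(design$sample[duplicated(design$sample)]), collapse = ", "))
  }
  unknown <- setdiff(unique(design$condition), .cs_conditions)
  if (length(unknown)) {
    stop("unknown condition token(s): ", paste(unknown, collapse = ", "))
  }
  if (!setequal(design$sample, colnames(expression))) {
    stop("sample names differ between expression matrix and design")
  }
  counts <- table(factor(design$condition, levels = .cs_conditions))
  if (any(counts == 0)) {
    stop("missing condition(s): ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  if (any(counts < 2)) {
    stop("fewer than 2 replicates for condition(s): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  expression <- expression[, design$sample, drop = FALSE]
  structure(list(expression = expression, design = design,
                 probe_map = if (!is.null(probe_map)) tibble::as_tibble(probe_map),
                 meta = meta),
            class = "cs_dataset")
}

#' @export
print.cs_dataset <- function(x, ...) {
  cat("Combination-treatment dataset:", nrow(x$expression), "features x",
      ncol(x$expression), "samples\n")
  invisible(x)
}

# Coefficient of variation per row, computed on the linear (2^x) scale to
# avoid sign pathologies of log-scale means.
row_cv <- function(mat) {
  lin <- 2^mat
  m <- rowMeans(lin)
  s <- apply(lin, 1, stats::sd)
  s / m
}

#' Collapse probe-level rows to genes
#'
#' When several probes map to the same gene, the probe with the largest
#' coefficient of variation (linear scale) is kept. Probes absent from the
#' map are dropped with a warning; ties keep the first probe in input order,
#' with a warning.
#'
#' @param mat probes x samples matrix with probe rownames.
#' @param probe_map tibble with columns `probe`, `gene`.
#' @return genes x samples matrix.
#' @export
collapse_probes <- function(mat, probe_map) {
  probe_map <- tibble::as_tibble(probe_map)
  stopifnot(all(c("probe", "gene") %in% colnames(probe_map)))
  if (nrow(probe_map) == 0) stop("empty probe map")
  covered <- rownames(mat) %in% probe_map$probe
  if (!any(covered)) stop("probe map covers no rows of the matrix")
  if (!all(covered)) {
    warning(sum(!covered), " probe(s) absent from the probe map were dropped")
    mat <- mat[covered, , drop = FALSE]
  }
  gene <- probe_map$gene[match(rownames(mat), probe_map$probe)]
  cv <- row_cv(mat)
  keep <- integer(0)
  tie <- FALSE
  for (rows in split(seq_len(nrow(mat)), factor(gene, unique(gene)))) {
    best <- rows[cv[rows] == max(cv[rows])]
    if (length(best) > 1L) tie <- TRUE
    keep <- c(keep, best[1])
  }
  if (tie) warning("coefficient-of-variation tie(s): first probe in input order kept")
  out <- mat[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out
}

#' Filter out low-variation genes
#'
#' Retains genes whose coefficient of variation (linear scale) is at least
#' the median across all genes.
#'
#' @param mat genes x samples matrix.
#' @return the filtered matrix.
#' @export
filter_low_cv <- function(mat) {
  stopifnot(nrow(mat) >= 2)
  cv <- row_cv(mat)
  if (all(apply(mat, 1, stats::sd) == 0)) {
    stop("all-constant expression matrix: coefficient of variation undefined")
  }
  mat[cv >= stats::median(cv), , drop = FALSE]
}

#' Differential expression over the four conditions
#'
#' Omnibus four-group (moderated, for batches of at least 100 genes) F-test
#' per gene, with Benjamini-Hochberg correction; a gene is significant when
#' the adjusted p-value is below `alpha`.
#'
#' @param mat genes x samples matrix.
#' @param design design tibble (`sample`, `condition`).
#' @param alpha significance cutoff on the adjusted p-value.
#' @return tibble with `gene`, `omnibus_p`, `adj_p`, `significant`.
#' @export
differential_genes <- function(mat, design, alpha = 0.05) {
  if (nrow(mat) == 0) stop("empty expression matrix")
  design <- tibble::as_tibble(design)
  f <- features_from_matrix(mat[, design$sample, drop = FALSE],
                            design$condition)
  tibble::tibble(
    gene = rownames(mat),
    omnibus_p = f$omnibus_p,
    adj_p = stats::p.adjust(f$omnibus_p, method = "BH"),
  ) |>
    dplyr::mutate(significant = .data$adj_p < alpha)
}

#' Filter differentially expressed genes by estimated signal
#'
#' Keeps genes whose estimated signal \eqn{\hat\delta} is at least the median
#' \eqn{\hat\delta} across the differentially expressed genes.
#'
#' @param de_features feature tibble (with `gene` and `delta_hat` columns)
#'   restricted to the differentially expressed genes.
#' @return the filtered tibble.
#' @export
filter_by_delta <- function(de_features) {
  stopifnot(nrow(de_features) >= 1, "delta_hat" %in% colnames(de_features))
  de_features[de_features$delta_hat >= stats::median(de_features$delta_hat), ,
              drop = FALSE]
}

#' Bliss interaction index
#'
#' Average deviation from additivity,
#' \eqn{b = \Delta\bar e_{X+Y} - (\Delta\bar e_X + \Delta\bar e_Y)} with
#' \eqn{\Delta\bar e_i = \bar e_i - \bar e_0}; positive for synergistic and
#' negative for antagonistic interactions.
#'
#' @param v length-4 mean vector `(e0, eX, eY, eXY)` or n x 4 matrix.
#' @return numeric vector of Bliss indices.
#' @export
#' @examples
#' bliss_index(c(2.2, 2.2, 2.2, 5.5))  # 3.3
#' bliss_index(c(0, 1, 2, 3))          # 0: additive
bliss_index <- function(v) {
  V <- as_mean_matrix(v)
  as.numeric(V[, 4] - V[, 2] - V[, 3] + V[, 1])
}

#' Interaction score
#'
#' The product \eqn{s = b \cdot p} of the Bliss index and the classifier's
#' probability for the assigned profile: magnitude times robustness.
#'
#' @param b Bliss index (log2 units).
#' @param p class probability in \[0, 1\].
#' @return numeric score with `sign(score) == sign(b)`.
#' @export
interaction_score <- function(b, p) {
  if (any(p < 0 | p > 1)) stop("class probability outside [0, 1]")
  b * p
}

#' Default analysis configuration
#'
#' Collects every tunable of the per-dataset pipeline: admissible range,
#' minimum signal, noise regimes and training sizes for the simulator, the
#' matching tolerance, the DE significance cutoff, filter toggles and the
#' enrichment thresholds.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    range = c(-14, 14),
    min_signal = 0.5,
    regimes = c(4, 2.5, 2),
    instances_per_profile = 400,
    n_reps = 4,
    alpha = 0.05,
    cv_filter = TRUE,
    delta_filter = TRUE,
    tolerance = 0.25,
    moderate_from = 100,
    max_term_size = 500,
    min_coverage = 0.02,
    enrich_alpha = 0.05,
    seed = 1L,
    config_version = "cs-config/1"
  )
}

#' Run the per-dataset interaction analysis
#'
#' Applies, in order: probe collapse (when a probe map is present), the
#' coefficient-of-variation filter, the omnibus differential-expression gate
#' (BH-adjusted p < alpha), the signal filter (\eqn{\hat\delta} at least the
#' DE median), then classifies each surviving gene onto the taxonomy and
#' scores it with the Bliss index: `score = b * p`. Genes assigned
#' non-interacting profiles are retained with sign `"0"`.
#'
#' @param bundle a `cs_dataset` from [new_dataset_bundle()].
#' @param model a `cs_classifier`.
#' @param taxonomy the `cs_taxonomy` the model was trained against.
#' @param config configuration list, see [default_config()].
#' @return tibble of interaction calls (class `cs_calls`): `gene`,
#'   `profile_id`, `category`, `p`, `b`, `score`, `sign`, with a `manifest`
#'   attribute recording the gene count after every stage.
#' @export
run_dataset <- function(bundle, model, taxonomy, config = default_config()) {
  stopifnot(inherits(bundle, "cs_dataset"), inherits(model, "cs_classifier"),
            inherits(taxonomy, "cs_taxonomy"))
  mat <- bundle$expression
  counts <- list(input = nrow(mat))
  if (!is.null(bundle$probe_map)) {
    mat <- collapse_probes(mat, bundle$probe_map)
  }
  counts$genes <- nrow(mat)
  if (isTRUE(config$cv_filter)) {
    mat <- filter_low_cv(mat)
  }
  counts$cv_filter <- nrow(mat)

  feats <- features_from_matrix(mat[, bundle$design$sample, drop = FALSE],
                                bundle$design$condition,
                                moderate_from = config$moderate_from,
                                zero_tol = config$tolerance)
  adj_p <- stats::p.adjust(feats$omnibus_p, method = "BH")
  feats <- feats[adj_p < config$alpha, , drop = FALSE]
  counts$de_filter <- nrow(feats)
  if (isTRUE(config$delta_filter) && nrow(feats) > 0) {
    feats <- filter_by_delta(feats)
  }
  counts$delta_filter <- nrow(feats)

  if (nrow(feats) == 0) {
    calls <- tibble::tibble(
      gene = character(0), profile_id = integer(0), category = character(0),
      p = numeric(0), b = numeric(0), score = numeric(0), sign = character(0)
    )
  } else {
    pred <- stats::predict(model, feats)
    b <- bliss_index(as.matrix(feats[, c("m_e0", "m_eX", "m_eY", "m_eXY")]))
    profile_sign <- interaction_sign_of(taxonomy, pred$profile_id)
    calls <- tibble::tibble(
      gene = feats$gene,
      profile_id = pred$profile_id,
      category = category_of(taxonomy, pred$profile_id),
      p = pred$p,
      b = b,
      score = interaction_score(b, pred$p),
      sign = ifelse(profile_sign == "0", "0", ifelse(b >= 0, "+", "-"))
    )
  }
  counts$calls <- nrow(calls)
  counts$interacting <- sum(calls$sign != "0")
  attr(calls, "manifest") <- list(
    stage_counts = counts,
    alpha = config$alpha,
    tolerance = config$tolerance,
    model_kind = model$model_kind,
    taxonomy_version = taxonomy$version
  )
  class(calls) <- c("cs_calls", class(calls))
  calls
}
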