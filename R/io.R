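# Readers and writers for the package's tab-delimited formats, the YAML
# configuration, and the JSON run manifests that make every artifact
# reproducible (tool version, seed, configuration hash).

cs_version <- function() as.character(utils::packageVersion("comboscape"))

#' Hash of a configuration list
#' @param config configuration list.
#' @return short sha256 prefix identifying the configuration.
#' @export
config_hash <- function(config) {
  substr(digest::digest(config, algo = "sha256"), 1, 16)
}

#' Write a JSON manifest next to an artifact
#'
#' @param target path of the artifact the manifest describes; the manifest is
#'   written to `<target>.manifest.json`.
#' @param ... named fields to record (seed, counts, configuration hash, ...).
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(target, ...) {
  path <- paste0(target, ".manifest.json")
  fields <- c(list(tool = "comboscape", version = cs_version(),
                   artifact = basename(target)), list(...))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample names and one row per gene (first column:
#' gene id). Fails with row/column coordinates on non-numeric or missing
#' cells, and on duplicated gene or sample names.
#'
#' @param path TSV file.
#' @return numeric genes x samples matrix.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression table needs a gene column plus samples")
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicated gene name(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicated sample name(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, samples))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric expression value at row ", bad[1, 1], " (",
         genes[bad[1, 1]], "), column ", bad[1, 2], " (",
         samples[bad[1, 2]], ")")
  }
  vals
}

#' Write an expression matrix to TSV (with manifest)
#' @param mat genes x samples matrix.
#' @param path output path.
#' @param seed optional seed to record in the manifest.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, seed = NULL) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(path, kind = "expression", n_genes = nrow(mat),
                 n_samples = ncol(mat), seed = seed)
  invisible(path)
}

#' Read a design table (sample, condition) from TSV
#'
#' @param path TSV with columns `sample` and `condition`; condition tokens
#'   must be CTRL, X, Y or COMBO.
#' @return tibble with `sample`, `condition`.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "condition") %in% colnames(d))) {
    stop("design table needs columns 'sample' and 'condition'")
  }
  unknown <- setdiff(unique(d$condition), .cs_conditions)
  if (length(unknown)) {
    stop("unknown condition token(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(d$sample)) {
    stop("duplicated sample name(s): ",
         paste(unique(d$sample[duplicated(d$sample)]), collapse = ", "))
  }
  d[, c("sample", "condition")]
}

#' @rdname read_design
#' @param design design tibble.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design[, c("sample", "condition")], path, progress = FALSE)
  invisible(path)
}

#' Read/write interaction call tables
#'
#' Calls are stored as TSV with columns gene, profile_id, category, p, b,
#' score, sign; the writer adds a JSON manifest with the pipeline stage
#' counts.
#'
#' @param calls a `cs_calls` tibble from [run_dataset()].
#' @param path file path.
#' @param seed optional seed recorded in the manifest.
#' @return `write_calls()`: `path` invisibly; `read_calls()`: tibble.
#' @export
write_calls <- function(calls, path, seed = NULL) {
  cols <- c("gene", "profile_id", "category", "p", "b", "score", "sign")
  readr::write_tsv(tibble::as_tibble(calls)[, cols], path, progress = FALSE)
  man <- attr(calls, "manifest")
  write_manifest(path, kind = "calls", seed = seed,
                 stage_counts = man$stage_counts,
                 taxonomy_version = man$taxonomy_version)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(sign = readr::col_character()))
}

#' Write/read a simulated training set
#'
#' The instance table is stored as TSV; simulation parameters (seed, noise
#' regimes, instance counts) travel in the JSON manifest sidecar.
#'
#' @param instances tibble from [build_training_set()].
#' @param path file path.
#' @return `write_training_set()`: `path`, invisibly;
#'   `read_training_set()`: the instance tibble.
#' @export
write_training_set <- function(instances, path) {
  readr::write_tsv(instances, path, progress = FALSE)
  params <- attr(instances, "cs_params")
  do.call(write_manifest, c(list(target = path, kind = "training_set",
                                 n_instances = nrow(instances)), params))
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write/read a feature table
#'
#' Tab-delimited, one row per gene/instance, fixed column order; the feature
#' schema version is embedded in the JSON manifest sidecar.
#'
#' @param features feature tibble.
#' @param path file path.
#' @return `write_features()`: `path`, invisibly; `read_features()`: tibble.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  write_manifest(path, kind = "features",
                 schema = attr(features, "cs_schema") %||% features_schema_version,
                 n = nrow(features))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  man_path <- paste0(path, ".manifest.json")
  if (file.exists(man_path)) {
    attr(out, "cs_schema") <- jsonlite::read_json(man_path)$schema
  }
  out
}

validate_config <- function(config) {
  stopifnot(
    is.list(config),
    length(config$range) == 2, config$range[1] < config$range[2],
    config$min_signal > 0,
    all(config$regimes > 0),
    config$instances_per_profile >= 1,
    config$n_reps >= 2,
    config$alpha > 0, config$alpha < 1,
    config$tolerance >= 0,
    config$max_term_size > 1,
    config$min_coverage >= 0, config$min_coverage <= 1,
    config$enrich_alpha > 0, config$enrich_alpha < 1
  )
  invisible(config)
}

#' Read/write the analysis configuration (YAML)
#'
#' @param path YAML file.
#' @return `read_config()`: validated configuration list (defaults filled
#'   in); `write_config()`: `path`, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  base[names(cfg)] <- cfg
  if (length(base$range) == 2) base$range <- as.numeric(base$range)
  validate_config(base)
  base
}

#' @rdname read_config
#' @param config configuration list (see [default_config()]).
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}
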