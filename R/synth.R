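# Fully synthetic combination-treatment fixtures with known truth, planted
# gene sets, and the packaged compendium metadata table.

compendium_checksum <- "20935059ef2d8349274af0d303f89e45bdbef79a967d5daa803b384ce9153f87"

# Resolve a profile-mix key (profile name, profile id, or category) to the
# candidate profile ids it denotes.
resolve_mix_key <- function(taxonomy, key) {
  prof <- taxonomy$profiles
  if (key %in% prof$name) return(prof$id[prof$name == key])
  if (grepl("^\\d+$", key) && as.integer(key) %in% prof$id) {
    return(as.integer(key))
  }
  if (key %in% prof$category) return(prof$id[prof$category == key])
  stop("invalid profile mix key: '", key,
       "' is neither a profile name, id, nor category")
}

# Deterministic largest-remainder allocation of n items to proportions.
allocate_counts <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Generate a synthetic combination-treatment dataset with known truth
#'
#' Composes the profile simulator into a dataset-shaped fixture: `n_genes`
#' genes drawn from a mixture of taxonomy profiles, each with `n_reps`
#' Gaussian replicates per condition at the requested noise regime, clipped
#' to the admissible range. Gene allocation to mixture components is
#' deterministic (largest remainder), so a 10% component of 100 genes is
#' exactly 10 genes.
#'
#' @inheritParams sample_profile_means
#' @param n_genes number of genes.
#' @param profile_mix named numeric vector of proportions (must sum to 1);
#'   names are profile names (e.g. `"emergent synergy"`), profile ids, or
#'   categories (e.g. `"additive"`, in which case a profile of that category
#'   is drawn uniformly per gene).
#' @param delta_over_sigma noise regime (signal-to-noise ratio).
#' @param n_reps replicates per condition.
#' @param sigma_constant replicate noise s.d. for constant-profile genes
#'   (whose signal, hence \eqn{\sigma = \delta/(\delta/\sigma)}, is
#'   undefined); defaults to `min_signal / delta_over_sigma`, the noise of
#'   the weakest-signal gene at the regime.
#' @return list with `expression` (genes x samples log2 matrix), `design`
#'   (sample/condition tibble) and `truth` (tibble: gene, profile_id,
#'   category, m_e0 ... m_eXY, delta, sigma, regime).
#' @export
generate_synthetic_dataset <- function(taxonomy, n_genes, profile_mix,
                                       delta_over_sigma = 4, n_reps = 4,
                                       seed = NULL, range = c(-14, 14),
                                       min_signal = 0.5,
                                       sigma_constant = NULL) {
  stopifnot(inherits(taxonomy, "cs_taxonomy"), n_genes >= 1,
            length(profile_mix) >= 1, !is.null(names(profile_mix)))
  if (abs(sum(profile_mix) - 1) > 1e-8) {
    stop("profile mix proportions must sum to 1")
  }
  candidates <- lapply(names(profile_mix), resolve_mix_key,
                       taxonomy = taxonomy)
  run <- function() {
    counts <- allocate_counts(as.numeric(profile_mix), n_genes)
    # allocation is deterministic all the way down: category components are
    # spread evenly over the category's member profiles (largest remainder),
    # so the fixture's composition does not vary between realisations
    profile_id <- unlist(lapply(seq_along(counts), function(k) {
      cand <- sort(candidates[[k]])
      rep(cand, allocate_counts(rep(1 / length(cand), length(cand)),
                                counts[k]))
    }))
    truth <- tibble::tibble(
      gene = sprintf("G%06d", seq_len(n_genes)),
      profile_id = profile_id
    )
    M <- matrix(NA_real_, n_genes, 4)
    for (pid in unique(truth$profile_id)) {
      rows <- which(truth$profile_id == pid)
      V <- sample_profile_means(taxonomy, pid, n = length(rows),
                                range = range, min_signal = min_signal)
      M[rows, ] <- as.matrix(V)
    }
    delta <- signal_delta(M)
    sigma <- delta / delta_over_sigma
    const <- is.na(delta)
    # unregulated genes get the replicate noise of the weakest-signal gene
    # at this regime: real null genes show ordinary technical noise, not
    # noise scaled to other genes' signals
    sigma[const] <- sigma_constant %||% (min_signal / delta_over_sigma)
    reps <- matrix(
      stats::rnorm(n_genes * 4L * n_reps,
                   mean = rep(t(M), each = n_reps),
                   sd = rep(sigma, each = 4L * n_reps)),
      nrow = n_genes, byrow = TRUE
    )
    reps <- clip_to_range(reps, range)
    samples <- paste(rep(c("CTRL", "X", "Y", "COMBO"), each = n_reps),
                     seq_len(n_reps), sep = "_")
    dimnames(reps) <- list(truth$gene, samples)
    truth$category <- category_of(taxonomy, truth$profile_id)
    truth$m_e0 <- M[, 1]; truth$m_eX <- M[, 2]
    truth$m_eY <- M[, 3]; truth$m_eXY <- M[, 4]
    truth$delta <- delta
    truth$sigma <- sigma
    truth$regime <- delta_over_sigma
    list(
      expression = reps,
      design = tibble::tibble(sample = samples,
                              condition = rep(c("CTRL", "X", "Y", "COMBO"),
                                              each = n_reps)),
      truth = truth
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a gene-set collection with one planted enriched term
#'
#' Builds `n_terms` random background terms plus one planted term whose
#' overlap with the interacting truth genes exceeds the chance expectation by
#' the requested enrichment factor.
#'
#' @param truth truth tibble from [generate_synthetic_dataset()].
#' @param taxonomy the taxonomy (to identify interacting profiles).
#' @param n_terms number of background terms.
#' @param term_size genes per background term.
#' @param planted_size genes in the planted term.
#' @param enrichment fold enrichment of the planted term's overlap with the
#'   interacting genes over the chance expectation.
#' @param seed optional integer seed.
#' @return list with `collection` (named list of gene sets; the planted term
#'   is `"planted_term"`) and `query` (the interacting truth genes).
#' @export
generate_planted_gmt <- function(truth, taxonomy, n_terms = 50,
                                 term_size = 20, planted_size = 20,
                                 enrichment = 5, seed = NULL) {
  universe <- truth$gene
  interacting <- truth$gene[interaction_sign_of(taxonomy, truth$profile_id) != "0"]
  if (planted_size > length(universe)) {
    stop("planted term size exceeds the available gene pool")
  }
  run <- function() {
    expected <- planted_size * length(interacting) / length(universe)
    k <- min(planted_size, length(interacting), round(enrichment * expected))
    planted <- c(sample(interacting, k),
                 sample(setdiff(universe, interacting),
                        min(planted_size - k,
                            length(universe) - length(interacting))))
    bg <- lapply(seq_len(n_terms), function(i) sample(universe, term_size))
    names(bg) <- sprintf("background_%03d", seq_len(n_terms))
    collection <- c(bg, list(planted_term = planted))
    list(collection = collection, query = interacting)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' The packaged compendium metadata table
#'
#' Returns the packaged transcription of the combination-treatment dataset
#' compendium metadata (accession, species, cell type, the two stimuli and
#' the time point): 32 datasets, 25 human and 7 murine. The installed file's
#' checksum is pinned and verified on every call.
#'
#' @return tibble with 32 rows and columns `accession`, `species`,
#'   `cell_type`, `signal_X`, `signal_Y`, `time_point`.
#' @export
#' @examples
#' nrow(compendium_table())
compendium_table <- function() {
  path <- system.file("extdata", "compendium.tsv", package = "comboscape",
                      mustWork = TRUE)
  actual <- digest::digest(paste(readLines(path), collapse = "\n"),
                           algo = "sha256", serialize = FALSE)
  if (!identical(actual, compendium_checksum)) {
    stop("packaged compendium table fails its checksum")
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
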