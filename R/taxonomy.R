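# Taxonomy of interaction profiles for factorial combination-treatment
# experiments (conditions CTRL, X, Y, COMBO).
#
# A profile is a satisfiable system of sign relations over the four condition
# means. The complete taxonomy is obtained by enumerating the weak orderings
# of five quantities: the four condition means e0, eX, eY, eXY together with
# the additive (Bliss) expectation eA = eX + eY - e0. The position of eXY
# relative to eA encodes the sign of the Bliss index b = eXY - eA. Exactly 123
# of the 541 weak orders on five items are consistent with the linear
# dependence of eA on the other three quantities; these 123 are the taxonomy.

.cs_quants <- c("e0", "eX", "eY", "eXY", "eA")

.cs_basis <- rbind(
  e0  = c(1, 0, 0, 0),
  eX  = c(0, 1, 0, 0),
  eY  = c(0, 0, 1, 0),
  eXY = c(0, 0, 0, 1),
  eA  = c(-1, 1, 1, 0)
)

.cs_categories <- c(
  "emergent", "potentiation", "restoration", "suppression", "inhibition",
  "synergistic_reversal", "antagonistic_reversal", "floor", "ceiling",
  "additive", "constant"
)

taxonomy_format_version <- "1.0"

# All ordered set partitions (weak orders, ascending) of a character vector.
ordered_partitions <- function(items) {
  out <- list()
  rec <- function(blocks, rest) {
    if (!length(rest)) {
      out[[length(out) + 1L]] <<- blocks
      return(invisible(NULL))
    }
    el <- rest[1]
    for (i in seq_along(blocks)) {
      b2 <- blocks
      b2[[i]] <- c(b2[[i]], el)
      rec(b2, rest[-1])
    }
    for (i in 0:length(blocks)) {
      rec(append(blocks, list(el), after = i), rest[-1])
    }
  }
  rec(list(items[1]), items[-1])
  out
}

order_signature <- function(blocks) {
  paste(vapply(blocks, function(b) paste(sort(b), collapse = "="), ""),
        collapse = "<")
}

signature_blocks <- function(signature) {
  lapply(strsplit(signature, "<", fixed = TRUE)[[1]],
         function(s) strsplit(s, "=", fixed = TRUE)[[1]])
}

# Relation rows (over the e0/eX/eY/eXY basis) implied by a weak order:
# within-block equalities and ascending adjacent-block strict inequalities.
order_relations <- function(blocks) {
  eq <- NULL
  gt <- NULL
  for (blk in blocks) {
    if (length(blk) > 1L) {
      for (o in blk[-1]) eq <- rbind(eq, .cs_basis[blk[1], ] - .cs_basis[o, ])
    }
  }
  if (length(blocks) > 1L) {
    for (i in seq_len(length(blocks) - 1L)) {
      gt <- rbind(gt, .cs_basis[blocks[[i + 1L]][1], ] - .cs_basis[blocks[[i]][1], ])
    }
  }
  list(eq = eq, gt = gt)
}

# Qualitative descriptor of a weak order: category, interaction sign, which
# stimulus's mono-treatment effect is qualitatively changed, and a readable
# base name. See the methods vignette for the decision tree.
order_descriptor <- function(blocks) {
  pos <- integer(5)
  names(pos) <- .cs_quants
  for (i in seq_along(blocks)) pos[blocks[[i]]] <- i
  sX <- sign(pos["eX"] - pos["e0"])
  sY <- sign(pos["eY"] - pos["e0"])
  sXY <- sign(pos["eXY"] - pos["e0"])
  sb <- sign(pos["eXY"] - pos["eA"])
  names(sX) <- names(sY) <- names(sXY) <- names(sb) <- NULL

  dirw <- function(s) if (s > 0) "up" else "down"
  mono_desc <- paste0("X ", c("down", "null", "up")[sX + 2], ", Y ",
                      c("down", "null", "up")[sY + 2])
  active <- c(if (sX != 0) "X", if (sY != 0) "Y")
  act_of <- function(who) if (length(who) == 2L) "both" else who

  if (length(blocks) == 1L) {
    category <- "constant"; modifies <- "none"; name <- "constant"
  } else if (sb == 0) {
    category <- "additive"; modifies <- "none"
    name <- paste0("additive (", mono_desc, ")")
  } else if (sX == 0 && sY == 0) {
    category <- "emergent"; modifies <- "both"
    name <- if (sXY > 0) "emergent synergy" else "emergent antagonism"
  } else if (sXY == 0) {
    category <- if (sb < 0) "suppression" else "restoration"
    modifies <- act_of(active)
    verb <- if (sb < 0) "suppresses" else "restores"
    if (length(active) == 1L) {
      other <- setdiff(c("X", "Y"), active)
      d <- if (active == "X") sX else sY
      name <- paste0(other, " ", verb, " ", active, " (", dirw(d), ")")
    } else {
      name <- paste0("mutual ", if (sb < 0) "suppression" else "restoration",
                     " (", mono_desc, ")")
    }
  } else if (length(active) > 0 &&
             all(c(sX, sY)[c(sX, sY) != 0] == -sXY)) {
    category <- if (sb > 0) "synergistic_reversal" else "antagonistic_reversal"
    modifies <- act_of(active)
    name <- paste0(if (sb > 0) "synergistic" else "antagonistic",
                   " reversal (", mono_desc, ")")
  } else if (sXY > 0 && pos["eXY"] == max(pos["eX"], pos["eY"]) &&
             sX >= 0 && sY >= 0) {
    category <- "ceiling"; modifies <- "none"
    name <- paste0("ceiling (", mono_desc, ")")
  } else if (sXY < 0 && pos["eXY"] == min(pos["eX"], pos["eY"]) &&
             sX <= 0 && sY <= 0) {
    category <- "floor"; modifies <- "none"
    name <- paste0("floor (", mono_desc, ")")
  } else {
    category <- if (sb == sXY) "potentiation" else "inhibition"
    verb <- if (sb == sXY) "potentiates" else "inhibits"
    agree <- c(if (sX == sXY) "X", if (sY == sXY) "Y")
    if (length(active) == 1L) {
      other <- setdiff(c("X", "Y"), active)
      name <- paste0(other, " ", verb, " ", active, " (", dirw(sXY), ")")
      modifies <- active
    } else {
      modifies <- "both"
      name <- if (length(agree) == 2L) {
        paste0("mutual ", category, " (", dirw(sXY), ")")
      } else {
        paste0(category, " (", mono_desc, ")")
      }
    }
  }
  sign_chr <- c("-", "0", "+")[sb + 2]
  if (category %in% c("additive", "constant")) sign_chr <- "0"
  list(category = category, sign = sign_chr, modifies = modifies, name = name)
}

swap_xy_signature <- function(signature) {
  blocks <- signature_blocks(signature)
  swapped <- lapply(blocks, function(b) {
    b[b == "eX"] <- ".tmp"; b[b == "eY"] <- "eX"; b[b == ".tmp"] <- "eY"; b
  })
  order_signature(swapped)
}

#' Enumerate the complete taxonomy of interaction profiles
#'
#' Enumerates all weak orderings of the four condition means (`e0`, `eX`,
#' `eY`, `eXY`) together with the additive expectation `eA = eX + eY - e0`,
#' keeps the orderings that are consistent with the linear dependence of `eA`
#' (checked by linear programming inside the admissible expression range), and
#' derives for each a category, interaction sign and readable name. The result
#' is the package's cross-check generator for the shipped taxonomy definition
#' file: exactly 123 profiles.
#'
#' @param range admissible expression range (log2 units) used for the
#'   feasibility check.
#' @return a tibble with one row per profile: `id`, `name`, `category`,
#'   `sign` (`"+"`, `"-"`, `"0"`), `signature` (the weak order, ascending),
#'   `modifies` (which stimulus's mono-treatment effect the profile
#'   qualitatively changes: `"X"`, `"Y"`, `"both"` or `"none"`), `mirror_id`
#'   (the profile with X and Y roles swapped), and a `relations` list-column
#'   of coefficient/relation tibbles.
#' @export
#' @examples
#' prof <- enumerate_interaction_profiles()
#' nrow(prof)
#' prof[prof$name == "emergent synergy", c("id", "category", "sign")]
enumerate_interaction_profiles <- function(range = c(-14, 14)) {
  keep <- list()
  for (blocks in ordered_partitions(.cs_quants)) {
    rel <- order_relations(blocks)
    res <- lp_feasible(rel$gt, rel$eq, range = range)
    if (res$feasible) {
      keep[[length(keep) + 1L]] <- list(blocks = blocks, relations = rel)
    }
  }
  sigs <- vapply(keep, function(k) order_signature(k$blocks), "")
  nblk <- vapply(keep, function(k) length(k$blocks), 0L)
  ord <- order(nblk, sigs, method = "radix")
  keep <- keep[ord]
  sigs <- sigs[ord]

  desc <- lapply(keep, function(k) order_descriptor(k$blocks))
  name <- vapply(desc, `[[`, "", "name")
  # disambiguate repeated base names deterministically, in id order
  name <- stats::ave(name, name, FUN = function(v) {
    if (length(v) == 1L) v else paste0(v, " #", seq_along(v))
  })
  rel_tbl <- lapply(keep, function(k) {
    rows <- rbind(k$relations$gt, k$relations$eq)
    tibble::tibble(
      c_e0 = rows[, 1], c_eX = rows[, 2], c_eY = rows[, 3], c_eXY = rows[, 4],
      rel = rep(c("gt", "eq"),
                c(NROW(k$relations$gt), NROW(k$relations$eq)))
    )
  })
  prof <- tibble::tibble(
    id = seq_along(keep),
    name = name,
    category = vapply(desc, `[[`, "", "category"),
    sign = vapply(desc, `[[`, "", "sign"),
    signature = sigs,
    modifies = vapply(desc, `[[`, "", "modifies"),
    relations = rel_tbl
  )
  prof$mirror_id <- match(vapply(prof$signature, swap_xy_signature, ""),
                          prof$signature)
  prof[, c("id", "name", "category", "sign", "signature", "modifies",
           "mirror_id", "relations")]
}

taxonomy_body_lines <- function(profiles) {
  flat <- tidyr::unnest(profiles[, c("id", "name", "category", "sign",
                                     "signature", "modifies", "mirror_id",
                                     "relations")],
                        "relations")
  header <- paste(colnames(flat), collapse = "\t")
  rows <- do.call(paste, c(lapply(flat, as.character), sep = "\t"))
  c(header, rows)
}

#' Write a taxonomy definition file
#'
#' Serialises a profile table (as produced by
#' [enumerate_interaction_profiles()]) to the package's tab-delimited
#' definition format: one row per relation, a format-version header and a
#' SHA-256 checksum of the body.
#'
#' @param profiles tibble of profiles with a `relations` list-column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(profiles, path) {
  body <- taxonomy_body_lines(profiles)
  checksum <- digest::digest(paste(body, collapse = "\n"), algo = "sha256",
                             serialize = FALSE)
  lines <- c(
    "# comboscape interaction-profile taxonomy (synthetic definition, generated by enumerate_interaction_profiles())",
    paste0("# taxonomy_version: ", taxonomy_format_version),
    paste0("# checksum: sha256:", checksum),
    body
  )
  writeLines(lines, path)
  invisible(path)
}

#' Path to the packaged taxonomy definition file
#' @return file path of the installed definition file.
#' @export
cs_taxonomy_file <- function() {
  system.file("extdata", "taxonomy.tsv", package = "comboscape", mustWork = TRUE)
}

profile_relation_matrices <- function(rel_tbl) {
  m <- as.matrix(rel_tbl[, c("c_e0", "c_eX", "c_eY", "c_eXY")])
  colnames(m) <- NULL
  list(gt = m[rel_tbl$rel == "gt", , drop = FALSE],
       eq = m[rel_tbl$rel == "eq", , drop = FALSE])
}

#' Load and validate a taxonomy of interaction profiles
#'
#' Parses a taxonomy definition file, validates its structure, verifies by
#' linear programming that every profile's relation system is satisfiable
#' inside the admissible range, and certifies pairwise distinguishability: the
#' LP witness point of each profile must satisfy no other profile (candidate
#' duplicates are confirmed by an exact mutual-inclusion check before the load
#' fails).
#'
#' @param definition_file path to the definition file; defaults to the
#'   packaged 123-profile taxonomy.
#' @param tolerance equality tolerance \eqn{\tau \ge 0} (log2 units) used by
#'   [satisfies()] and [match_deterministic()]: deviations of at most
#'   `tolerance` count as equality, strict relations require a margin greater
#'   than `tolerance`.
#' @param range admissible expression range (log2 units).
#' @return an object of class `cs_taxonomy`.
#' @export
#' @examples
#' tax <- load_taxonomy()
#' tax
load_taxonomy <- function(definition_file = cs_taxonomy_file(), tolerance = 0,
                          range = c(-14, 14)) {
  stopifnot(tolerance >= 0)
  lines <- readLines(definition_file)
  comments <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("taxonomy definition file is empty: ", definition_file)

  stored <- sub("^# checksum: sha256:", "",
                grep("^# checksum: sha256:", comments, value = TRUE))
  if (length(stored) == 1L) {
    actual <- digest::digest(paste(body, collapse = "\n"), algo = "sha256",
                             serialize = FALSE)
    if (!identical(stored, actual)) {
      stop("taxonomy definition file checksum mismatch: ", definition_file)
    }
  }
  version <- sub("^# taxonomy_version: ", "",
                 grep("^# taxonomy_version: ", comments, value = TRUE))
  if (!length(version)) version <- NA_character_

  flat <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("id", "name", "category", "sign", "c_e0", "c_eX", "c_eY",
              "c_eXY", "rel")
  missing_cols <- setdiff(needed, colnames(flat))
  if (length(missing_cols)) {
    stop("taxonomy definition file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"signature" %in% colnames(flat)) flat$signature <- NA_character_
  if (!"modifies" %in% colnames(flat)) flat$modifies <- NA_character_
  if (!"mirror_id" %in% colnames(flat)) flat$mirror_id <- NA_integer_

  bad_cat <- setdiff(unique(flat$category), .cs_categories)
  if (length(bad_cat)) {
    stop("unknown profile category: ", paste(bad_cat, collapse = ", "))
  }
  if (!all(flat$sign %in% c("+", "-", "0"))) {
    stop("interaction sign must be one of '+', '-', '0'")
  }
  if (!all(flat$rel %in% c("gt", "eq"))) {
    stop("relation type must be 'gt' (c.x > 0) or 'eq' (c.x = 0)")
  }

  # a profile's relation rows are contiguous; an id recurring in a later
  # block, or shared by entries with different headers, is a duplicate
  entry_key <- paste(flat$id, flat$name, flat$category, flat$sign,
                     sep = "\r")
  runs <- rle(entry_key)
  run_ids <- vapply(strsplit(runs$values, "\r", fixed = TRUE), `[[`, "", 1L)
  dup <- unique(run_ids[duplicated(run_ids)])
  if (length(dup)) {
    stop("duplicate profile id(s): ", paste(dup, collapse = ", "))
  }
  split_rows <- split(seq_len(nrow(flat)), factor(flat$id, unique(flat$id)))
  first <- vapply(split_rows, `[`, 0L, 1L)
  prof <- tibble::as_tibble(flat[first, c("id", "name", "category", "sign",
                                          "signature", "modifies", "mirror_id")])
  prof$relations <- lapply(split_rows, function(i) {
    tibble::as_tibble(flat[i, c("c_e0", "c_eX", "c_eY", "c_eXY", "rel")])
  })
  coefs <- as.matrix(flat[, c("c_e0", "c_eX", "c_eY", "c_eXY")])
  if (any(rowSums(abs(coefs)) == 0)) {
    stop("relation with all-zero coefficient vector")
  }
  csum <- prof$category %in% c("additive", "constant")
  if (any(csum & prof$sign != "0") ||
      any(prof$category == "emergent" & prof$sign == "0")) {
    stop("category and interaction sign are inconsistent")
  }

  mats <- lapply(prof$relations, profile_relation_matrices)
  wit <- matrix(NA_real_, nrow(prof), 4)
  infeasible <- integer(0)
  for (i in seq_len(nrow(prof))) {
    res <- lp_feasible(mats[[i]]$gt, mats[[i]]$eq, range = range)
    if (!res$feasible) infeasible <- c(infeasible, prof$id[i]) else wit[i, ] <- res$point
  }
  if (length(infeasible)) {
    stop("unsatisfiable relation system for profile id(s): ",
         paste(infeasible, collapse = ", "))
  }

  tax <- new_taxonomy(prof, mats, wit, tolerance, range, version)
  check_distinguishable(tax, mats)
  tax
}

new_taxonomy <- function(prof, mats, witnesses, tolerance, range, version) {
  stacked <- do.call(rbind, lapply(seq_along(mats), function(i) {
    rbind(
      if (nrow(mats[[i]]$gt)) cbind(mats[[i]]$gt, i, 1) else NULL,
      if (nrow(mats[[i]]$eq)) cbind(mats[[i]]$eq, i, 0) else NULL
    )
  }))
  prof$witness <- lapply(seq_len(nrow(witnesses)), function(i) witnesses[i, ])
  structure(
    list(
      profiles = prof,
      tolerance = tolerance,
      range = range,
      version = version,
      A = stacked[, 1:4, drop = FALSE],
      row_profile = stacked[, 5],
      row_strict = stacked[, 6] == 1
    ),
    class = "cs_taxonomy"
  )
}

# Pairwise distinguishability: a profile's witness lies strictly inside its
# own cell, so it satisfies another profile only if the two solution sets
# overlap; mutual witness containment triggers an exact inclusion check.
check_distinguishable <- function(tax, mats) {
  n <- nrow(tax$profiles)
  W <- do.call(rbind, tax$profiles$witness)
  sat <- satisfaction_matrix(tax, W, tolerance = 0)  # n vectors x n profiles
  for (i in seq_len(n)) {
    cand <- which(sat[i, ] & seq_len(n) != i)
    for (j in cand) {
      if (sat[j, i] && systems_equivalent(mats[[i]], mats[[j]], tax$range)) {
        stop("profiles ", tax$profiles$id[i], " and ", tax$profiles$id[j],
             " have provably identical solution sets")
      }
    }
  }
  invisible(TRUE)
}

# Is solution set A == solution set B? A <= B iff no interior point of A
# violates any relation of B (checked by LP with a small slack).
systems_equivalent <- function(ma, mb, range) {
  subset_of <- function(a, b) {
    viol_feasible <- function(extra_gt, offset) {
      lp_feasible(rbind(a$gt, extra_gt), a$eq, range = range,
                  offsets = c(rep(1e-4, NROW(a$gt)), offset))$feasible
    }
    if (nrow(b$eq)) {
      for (i in seq_len(nrow(b$eq))) {
        r <- b$eq[i, , drop = FALSE]
        if (viol_feasible(r, 1e-4) || viol_feasible(-r, 1e-4)) return(FALSE)
      }
    }
    if (nrow(b$gt)) {
      for (i in seq_len(nrow(b$gt))) {
        if (viol_feasible(-b$gt[i, , drop = FALSE], -1e-6)) return(FALSE)
      }
    }
    TRUE
  }
  subset_of(ma, mb) && subset_of(mb, ma)
}

# Violation scores for vectors against all profiles.
# V: n x 4 matrix. Returns list(score = n x nprof matrix, ...)
violation_scores <- function(tax, V, tolerance = NULL) {
  if (is.null(tolerance)) tolerance <- tax$tolerance
  tol_eq <- max(tolerance, 1e-9)
  vals <- tax$A %*% t(V)                      # nrow(A) x n
  viol <- vals
  # strict relations need margin > tolerance: a value exactly at the
  # tolerance boundary must not count as satisfied
  viol[tax$row_strict, ] <- tolerance - vals[tax$row_strict, , drop = FALSE] +
    1e-12
  viol[!tax$row_strict, ] <- abs(vals[!tax$row_strict, , drop = FALSE]) - tol_eq
  nprof <- nrow(tax$profiles)
  score <- matrix(-Inf, nrow(V), nprof)
  for (p in seq_len(nprof)) {
    rows <- which(tax$row_profile == p)
    vp <- viol[rows, , drop = FALSE]
    score[, p] <- do.call(pmax, lapply(seq_len(nrow(vp)), function(k) vp[k, ]))
  }
  score
}

satisfaction_matrix <- function(tax, V, tolerance = NULL) {
  violation_scores(tax, V, tolerance) <= 0
}

as_mean_matrix <- function(v) {
  if (is.null(dim(v))) {
    stopifnot(length(v) == 4L)
    v <- matrix(v, nrow = 1)
  }
  stopifnot(ncol(v) == 4L, all(is.finite(v)))
  unname(as.matrix(v))
}

#' Does a mean vector satisfy an interaction profile?
#'
#' A relation `c . x = 0` holds when `|c . x| <= tolerance`; a strict relation
#' `c . x > 0` requires a margin greater than `tolerance`. With
#' `tolerance = 0`, equalities are checked to numerical precision (1e-9).
#'
#' @param taxonomy a `cs_taxonomy`.
#' @param profile a profile id present in the taxonomy.
#' @param v numeric length-4 mean vector `(e0, eX, eY, eXY)` or an n x 4
#'   matrix of such vectors.
#' @param tolerance equality tolerance; defaults to the taxonomy's.
#' @return logical vector, one element per input vector.
#' @export
#' @examples
#' tax <- load_taxonomy()
#' es <- profile_id(tax, "emergent synergy")
#' satisfies(tax, es, c(2.2, 2.2, 2.2, 5.5))
satisfies <- function(taxonomy, profile, v, tolerance = NULL) {
  stopifnot(inherits(taxonomy, "cs_taxonomy"))
  idx <- match(profile, taxonomy$profiles$id)
  if (is.na(idx)) stop("unknown profile id: ", profile)
  V <- as_mean_matrix(v)
  unname(satisfaction_matrix(taxonomy, V, tolerance)[, idx])
}

#' Deterministically match mean vectors to taxonomy profiles
#'
#' Returns, for each mean vector, the profile whose relation system it
#' satisfies under the equality tolerance; deviations of at most `tolerance`
#' are snapped to equality, so the matched profile is unique for vectors in
#' general position. Vectors satisfying no profile exactly (possible after
#' tolerance snapping of noisy means) are assigned the profile with the
#' smallest worst-case relation violation; exact ties are resolved to the
#' lowest profile id with a warning.
#'
#' @inheritParams satisfies
#' @param v numeric length-4 vector or n x 4 matrix of mean vectors.
#' @return integer vector of profile ids.
#' @export
#' @examples
#' tax <- load_taxonomy()
#' match_deterministic(c(0, 0, 0, 0), tax)
match_deterministic <- function(v, taxonomy, tolerance = NULL) {
  stopifnot(inherits(taxonomy, "cs_taxonomy"))
  V <- as_mean_matrix(v)
  out <- integer(nrow(V))
  chunk <- 2000L
  starts <- seq(1L, nrow(V), by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nrow(V))
    score <- violation_scores(taxonomy, V[idx, , drop = FALSE], tolerance)
    nsat <- rowSums(score <= 0)
    if (any(nsat > 1L)) {
      warning(sum(nsat > 1L), " vector(s) satisfied multiple profiles; ",
              "ties resolved to the lowest profile id")
    }
    out[idx] <- taxonomy$profiles$id[max.col(-score, ties.method = "first")]
  }
  out
}

profile_field <- function(taxonomy, profile_id, field) {
  stopifnot(inherits(taxonomy, "cs_taxonomy"))
  idx <- match(profile_id, taxonomy$profiles$id)
  if (anyNA(idx)) {
    stop("unknown profile id: ",
         paste(profile_id[is.na(idx)], collapse = ", "))
  }
  taxonomy$profiles[[field]][idx]
}

#' Profile category and interaction sign lookups
#'
#' @inheritParams satisfies
#' @param profile_id vector of profile ids.
#' @return `category_of()`: character vector of categories;
#'   `interaction_sign_of()`: character vector in `c("+", "-", "0")`.
#' @export
category_of <- function(taxonomy, profile_id) {
  profile_field(taxonomy, profile_id, "category")
}

#' @rdname category_of
#' @export
interaction_sign_of <- function(taxonomy, profile_id) {
  profile_field(taxonomy, profile_id, "sign")
}

#' Look up a profile id by name
#'
#' @inheritParams satisfies
#' @param name exact profile name, e.g. `"emergent synergy"`.
#' @return integer profile id.
#' @export
profile_id <- function(taxonomy, name) {
  stopifnot(inherits(taxonomy, "cs_taxonomy"))
  idx <- match(name, taxonomy$profiles$name)
  if (anyNA(idx)) {
    stop("unknown profile name: ", paste(name[is.na(idx)], collapse = ", "))
  }
  taxonomy$profiles$id[idx]
}

#' @export
print.cs_taxonomy <- function(x, ...) {
  cat("Interaction-profile taxonomy:", nrow(x$profiles), "profiles",
      sprintf("(version %s, tolerance %g, range [%g, %g])\n",
              x$version, x$tolerance, x$range[1], x$range[2]))
  tab <- sort(table(x$profiles$category), decreasing = TRUE)
  cat("Categories:",
      paste(names(tab), as.integer(tab), sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a taxonomy into its profile table
#'
#' @param x a `cs_taxonomy`.
#' @param ... unused.
#' @return tibble of profiles (id, name, category, sign, signature, modifies,
#'   mirror_id).
#' @importFrom generics tidy
#' @export
tidy.cs_taxonomy <- function(x, ...) {
  x$profiles[, c("id", "name", "category", "sign", "signature", "modifies",
                 "mirror_id")]
}
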