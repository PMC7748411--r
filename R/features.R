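# Classifier predictors for one gene/instance: the four condition means, the
# six pairwise-contrast p-values and t-statistics, the estimated signal, the
# omnibus four-group p-value and the (possibly moderated) pooled variance.

features_schema_version <- "cs-features/1"

.cs_conditions <- c("CTRL", "X", "Y", "COMBO")
.cs_pairs <- cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))
.cs_pair_labels <- c("0X", "0Y", "0XY", "XY", "XXY", "YXY")

feature_columns <- function() {
  c("m_e0", "m_eX", "m_eY", "m_eXY",
    paste0("p_", .cs_pair_labels), paste0("t_", .cs_pair_labels),
    "delta_hat", "omnibus_p", "pooled_var")
}

#' Empirical-Bayes shrinkage of per-gene variances
#'
#' Fits a scaled inverse-chi-square prior to an ensemble of per-gene variance
#' estimates by moment matching (via `limma::fitFDist`) and shrinks each
#' variance toward the prior:
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}.
#'
#' @param variances positive per-gene variance estimates (at least 10 genes).
#' @param df residual degrees of freedom of each estimate (scalar).
#' @return list with `prior_variance` (\eqn{s_0^2}), `prior_df` (\eqn{d_0};
#'   `Inf` when the variances are all equal, flagged by `degenerate = TRUE`),
#'   and `moderated` (the shrunken variances).
#' @export
#' @examples
#' set.seed(1)
#' s2 <- 0.5 * rchisq(200, df = 12) / 12
#' shrink_variances(s2, df = 12)[c("prior_variance", "prior_df")]
shrink_variances <- function(variances, df) {
  stopifnot(length(variances) >= 10, all(variances > 0), df > 0)
  if (max(variances) - min(variances) < 1e-12) {
    v <- variances[1]
    return(list(prior_variance = v, prior_df = Inf,
                moderated = rep(v, length(variances)), degenerate = TRUE))
  }
  fit <- limma::fitFDist(variances, df1 = df)
  d0 <- fit$df2
  s02 <- fit$scale
  moderated <- if (is.infinite(d0)) {
    rep(s02, length(variances))
  } else {
    (d0 * s02 + df * variances) / (d0 + df)
  }
  list(prior_variance = s02, prior_df = d0, moderated = moderated,
       degenerate = FALSE)
}

# Core feature computation for a genes x samples matrix. `condition` is a
# vector of CTRL/X/Y/COMBO labels per sample. When `moderate` is TRUE the
# contrasts use limma's moderated statistics (pooled variance shrunk toward
# the ensemble prior); otherwise ordinary pooled-variance contrasts with
# df = 4(n-1).
compute_features <- function(Y, condition, moderate, zero_tol = 0) {
  stopifnot(is.matrix(Y), ncol(Y) == length(condition))
  cond <- factor(condition, levels = .cs_conditions)
  if (anyNA(cond)) stop("unknown condition label(s): ",
                        paste(setdiff(condition, .cs_conditions), collapse = ", "))
  n_per <- table(cond)
  if (any(n_per < 2)) {
    stop("need at least 2 replicates per condition; short: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  }
  if (any(!is.finite(Y))) stop("expression values must be finite")
  ng <- nrow(Y)

  design <- stats::model.matrix(~ 0 + cond)
  colnames(design) <- .cs_conditions
  means <- Y %*% design %*% diag(1 / as.numeric(n_per))
  colnames(means) <- .cs_conditions

  cm <- matrix(0, 4, 6, dimnames = list(.cs_conditions, .cs_pair_labels))
  for (k in 1:6) {
    cm[.cs_pairs[k, 1], k] <- -1
    cm[.cs_pairs[k, 2], k] <- 1
  }
  cm_omni <- cm[, c("0X", "0Y", "0XY")]

  if (moderate) {
    fit <- limma::lmFit(Y, design)
    cfit <- limma::eBayes(limma::contrasts.fit(fit, cm))
    pv <- cfit$p.value
    tv <- cfit$t
    ofit <- limma::eBayes(limma::contrasts.fit(fit, cm_omni))
    omnibus_p <- ofit$F.p.value
    pooled <- cfit$s2.post
    df_thr <- cfit$df.total
  } else {
    df <- sum(n_per - 1)
    resid <- Y - means[, as.integer(cond), drop = FALSE]
    s2 <- rowSums(resid^2) / df
    tv <- matrix(0, ng, 6, dimnames = list(rownames(Y), .cs_pair_labels))
    pv <- tv
    degenerate <- FALSE
    for (k in 1:6) {
      i <- .cs_pairs[k, 1]; j <- .cs_pairs[k, 2]
      se <- as.numeric(sqrt(s2 * (1 / n_per[i] + 1 / n_per[j])))
      dm <- as.numeric(means[, j] - means[, i])
      t_k <- ifelse(se > 0, dm / se, ifelse(abs(dm) > 0, Inf * sign(dm), 0))
      p_k <- 2 * stats::pt(abs(t_k), df = df, lower.tail = FALSE)
      if (any(se == 0 & abs(dm) > 0)) {
        degenerate <- TRUE
        p_k[se == 0 & abs(dm) > 0] <- 0
      }
      tv[, k] <- t_k
      pv[, k] <- p_k
    }
    if (degenerate) {
      warning("zero pooled variance with unequal means: p-value set to 0")
    }
    grand <- rowMeans(Y)
    ssb <- means^2 %*% as.numeric(n_per) - length(cond) * grand^2
    msb <- pmax(as.numeric(ssb), 0) / 3
    fstat <- ifelse(s2 > 0, msb / s2, ifelse(msb > 0, Inf, 0))
    omnibus_p <- stats::pf(fstat, 3, df, lower.tail = FALSE)
    pooled <- s2
    df_thr <- df
  }

  # estimated signal: smallest nonzero difference among the condition means,
  # estimated in two steps. (1) Canonicalize the tie structure: two
  # conditions count as tied unless their difference clears a
  # Bonferroni-guarded two-sided t-test over the six contrasts
  # (alpha = 0.05/6), floored at `zero_tol`; ties are chained into blocks.
  # (2) Average the means within each tie block and take the smallest
  # absolute difference between distinct block means. Averaging first avoids
  # the downward bias of a minimum over several noisy estimates of the same
  # true gap, and the significance guard keeps sub-noise jitter between
  # truly tied conditions from masquerading as signal.
  D <- abs(means[, .cs_pairs[, 2], drop = FALSE] -
             means[, .cs_pairs[, 1], drop = FALSE])
  se_pair <- sqrt(pooled %o% (1 / n_per[.cs_pairs[, 1]] +
                                1 / n_per[.cs_pairs[, 2]]))
  crit <- stats::qt(1 - 0.025 / 6, df_thr)
  tied <- D <= pmax(zero_tol, crit * se_pair)
  lab <- matrix(rep(1:4, each = ng), ng, 4)
  for (pass in 1:3) {
    for (k in 1:6) {
      i <- .cs_pairs[k, 1]; j <- .cs_pairs[k, 2]
      m <- pmin(lab[, i], lab[, j])
      lab[tied[, k], i] <- m[tied[, k]]
      lab[tied[, k], j] <- m[tied[, k]]
    }
  }
  bm <- means[, 1:4, drop = FALSE]
  for (cc in 1:4) {
    same <- lab == lab[, cc]
    bm[, cc] <- rowSums(means[, 1:4, drop = FALSE] * same) / rowSums(same)
  }
  Db <- abs(bm[, .cs_pairs[, 2], drop = FALSE] -
              bm[, .cs_pairs[, 1], drop = FALSE])
  Db[lab[, .cs_pairs[, 2], drop = FALSE] ==
       lab[, .cs_pairs[, 1], drop = FALSE]] <- NA_real_
  delta_hat <- suppressWarnings(apply(Db, 1, min, na.rm = TRUE))
  delta_hat[!is.finite(delta_hat)] <- 0

  out <- tibble::tibble(
    m_e0 = as.numeric(means[, "CTRL"]), m_eX = as.numeric(means[, "X"]),
    m_eY = as.numeric(means[, "Y"]), m_eXY = as.numeric(means[, "COMBO"])
  )
  for (k in 1:6) out[[paste0("p_", .cs_pair_labels[k])]] <- as.numeric(pv[, k])
  for (k in 1:6) out[[paste0("t_", .cs_pair_labels[k])]] <- as.numeric(tv[, k])
  out$delta_hat <- as.numeric(delta_hat)
  out$omnibus_p <- as.numeric(omnibus_p)
  out$pooled_var <- as.numeric(pooled)
  attr(out, "cs_schema") <- features_schema_version
  out
}

#' Extract classifier features from a replicate matrix
#'
#' Converts one gene's 4 x n replicate matrix (rows CTRL, X, Y, COMBO) into
#' the fixed 19-dimensional predictor vector: 4 condition means, 6 pairwise
#' contrast p-values, 6 contrast t-statistics, the estimated signal
#' \eqn{\hat\delta}, the omnibus four-group p-value, and the pooled
#' within-group variance. Contrasts use the pooled variance with
#' df = 4(n - 1); when `ensemble_variances` (from [shrink_variances()]) is
#' supplied, the variance is shrunk toward the ensemble prior and the degrees
#' of freedom augmented accordingly.
#'
#' @param replicates 4 x n numeric matrix (n >= 2), rows in condition order
#'   CTRL, X, Y, COMBO.
#' @param ensemble_variances optional list with `prior_variance` and
#'   `prior_df`.
#' @param zero_tol floor of the nonzero-difference threshold for
#'   \eqn{\hat\delta}; the effective threshold per gene additionally requires
#'   a difference to clear a Bonferroni-guarded t-test over the six contrasts
#'   (alpha = 0.05/6), so mean differences within the noise floor never
#'   masquerade as signal.
#' @return one-row tibble with the 19 feature columns (see
#'   `comboscape:::feature_columns()`).
#' @export
#' @examples
#' set.seed(1)
#' reps <- add_noise(c(0, 0, 0, 3), delta_over_sigma = 4)
#' extract_features(reps)
extract_features <- function(replicates, ensemble_variances = NULL,
                             zero_tol = 0) {
  stopifnot(is.matrix(replicates), nrow(replicates) == 4L)
  n <- ncol(replicates)
  Y <- matrix(as.numeric(t(replicates)), nrow = 1)
  cond <- rep(.cs_conditions, each = n)
  if (is.null(ensemble_variances)) {
    return(compute_features(Y, cond, moderate = FALSE, zero_tol = zero_tol))
  }
  d0 <- ensemble_variances$prior_df
  s02 <- ensemble_variances$prior_variance
  out <- compute_features(Y, cond, moderate = FALSE, zero_tol = zero_tol)
  df <- 4 * (n - 1)
  s2_mod <- if (is.infinite(d0)) s02 else (d0 * s02 + df * out$pooled_var) / (d0 + df)
  df_mod <- df + d0
  scale <- sqrt(out$pooled_var / s2_mod)
  for (k in .cs_pair_labels) {
    tcol <- paste0("t_", k)
    out[[tcol]] <- out[[tcol]] * ifelse(is.finite(scale), scale, 1)
    out[[paste0("p_", k)]] <-
      2 * stats::pt(abs(out[[tcol]]), df = df_mod, lower.tail = FALSE)
  }
  out$pooled_var <- s2_mod
  attr(out, "cs_schema") <- features_schema_version
  out
}

#' Estimate a dataset's signal-to-noise regime
#'
#' Each responding gene carries an estimate of the regime ratio
#' \eqn{\delta/\sigma}: its estimated signal over its replicate standard
#' deviation. The median over genes with nonzero \eqn{\hat\delta} estimates
#' the dataset's regime, which can then be matched to the closest simulated
#' training regime — a classifier trained at the data's own noise level
#' resolves profile boundaries better than the mixed-regime model.
#'
#' @param features a feature tibble (from [features_from_matrix()]),
#'   ideally restricted to differentially expressed genes.
#' @return the estimated \eqn{\delta/\sigma} ratio (scalar).
#' @export
estimate_noise_regime <- function(features) {
  active <- features$delta_hat > 0 & features$pooled_var > 0
  if (!any(active)) stop("no responding genes to estimate the regime from")
  stats::median(features$delta_hat[active] /
                  sqrt(features$pooled_var[active]))
}

#' Extract features for a whole expression matrix
#'
#' Batch version of [extract_features()] for a genes x samples matrix with a
#' condition label per sample. Empirical-Bayes moderation of the contrast
#' variances is enabled automatically for batches of at least
#' `moderate_from` genes (and is what the simulated training set uses, one
#' batch per noise regime), keeping training and application on the same
#' statistical footing.
#'
#' @param Y numeric genes x samples matrix.
#' @param condition character vector of CTRL/X/Y/COMBO labels, one per column
#'   of `Y`.
#' @param moderate logical; defaults to `nrow(Y) >= moderate_from`.
#' @param moderate_from batch size from which moderation turns on.
#' @inheritParams extract_features
#' @return tibble with one row per gene (row order preserved), 19 feature
#'   columns, and a `gene` column when `Y` has rownames.
#' @export
features_from_matrix <- function(Y, condition, moderate = NULL,
                                 moderate_from = 100, zero_tol = 0) {
  if (is.null(moderate)) moderate <- nrow(Y) >= moderate_from
  out <- compute_features(Y, condition, moderate = moderate,
                          zero_tol = zero_tol)
  if (!is.null(rownames(Y))) {
    out <- dplyr::bind_cols(tibble::tibble(gene = rownames(Y)), out)
    attr(out, "cs_schema") <- features_schema_version
  }
  out
}

#' Extract features for a simulated instance table
#'
#' Routes the replicate columns of a [build_training_set()] tibble through
#' the same batch feature computation used for real datasets, one batch per
#' noise regime.
#'
#' @param instances tibble from [build_training_set()].
#' @inheritParams features_from_matrix
#' @return tibble with `instance`, `profile_id`, `regime` and the 19 feature
#'   columns.
#' @export
features_from_instances <- function(instances, moderate = NULL,
                                    moderate_from = 100, zero_tol = 0) {
  rep_cols <- grep("^(CTRL|X|Y|COMBO)_\\d+$", colnames(instances), value = TRUE)
  cond <- sub("_\\d+$", "", rep_cols)
  pieces <- lapply(split(seq_len(nrow(instances)), instances$regime), function(i) {
    Y <- as.matrix(instances[i, rep_cols])
    f <- compute_features(
      Y, cond,
      moderate = if (is.null(moderate)) length(i) >= moderate_from else moderate,
      zero_tol = zero_tol
    )
    dplyr::bind_cols(instances[i, c("instance", "profile_id", "regime")], f)
  })
  out <- dplyr::arrange(dplyr::bind_rows(pieces), .data$instance)
  attr(out, "cs_schema") <- features_schema_version
  out
}
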