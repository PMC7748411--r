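# Simulation of labelled interaction-profile instances: sample each profile's
# solution polytope inside the admissible expression range, then add
# calibrated Gaussian replicate noise at a chosen signal-to-noise regime.

#' Named noise regimes (signal-to-noise ratios delta/sigma)
#'
#' Low noise corresponds to delta/sigma = 4, medium to 2.5, high to 2.
#' @export
noise_regimes <- c(low = 4, medium = 2.5, high = 2)

#' Signal of a mean vector
#'
#' The signal \eqn{\delta} generalises the fold-change to the four-condition
#' design: it is the smallest nonzero absolute difference among the six
#' pairwise contrasts of the condition means.
#'
#' @param v numeric length-4 vector `(e0, eX, eY, eXY)` or n x 4 matrix.
#' @param zero_tol differences with absolute value at most `zero_tol` are
#'   treated as zero (use the matching tolerance for estimated means).
#' @return numeric vector of signals; `NA` for an all-equal (constant) vector,
#'   which has no nonzero contrast — callers must branch on this outcome.
#' @export
#' @examples
#' signal_delta(c(2.2, 2.2, 2.2, 5.5))  # 3.3
#' signal_delta(c(0, 1, 2, 3))          # 1
#' signal_delta(c(5, 5, 5, 5))          # NA: constant
signal_delta <- function(v, zero_tol = 0) {
  V <- as_mean_matrix(v)
  pairs <- utils::combn(4, 2)
  D <- abs(V[, pairs[1, ], drop = FALSE] - V[, pairs[2, ], drop = FALSE])
  D[D <= zero_tol] <- NA_real_
  out <- suppressWarnings(apply(D, 1, min, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Clip expression values to the admissible range
#'
#' Values outside the range are reset to the nearest range limit, emulating
#' the saturation of log2 expression measurements.
#'
#' @param values numeric vector/matrix.
#' @param range length-2 numeric, admissible interval (log2 units).
#' @return clipped values, same shape as the input.
#' @export
#' @examples
#' clip_to_range(-18.5)  # -14
clip_to_range <- function(values, range = c(-14, 14)) {
  pmin(pmax(values, range[1]), range[2])
}

# Tie classes among the four condition coordinates implied by the equality
# rows that are pure pairwise differences (used to make sampled ties exact).
condition_tie_classes <- function(A_eq) {
  parent <- 1:4
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(A_eq) && nrow(A_eq)) {
    for (k in seq_len(nrow(A_eq))) {
      r <- A_eq[k, ]
      if (sum(r != 0) == 2L && sum(r) == 0 && all(abs(r[r != 0]) == 1)) {
        i <- find(which(r == 1)); j <- find(which(r == -1))
        parent[max(i, j)] <- min(i, j)
      }
    }
  }
  vapply(1:4, find, 0L)
}

# Hit-and-run sampler over {x : A_gt x >= offsets, A_eq x = 0, x in range^4}.
# Returns an n x 4 matrix. Assumes the region has been certified non-empty
# and `start` lies strictly inside it.
hit_and_run <- function(n, start, A_gt, A_eq, range, offsets,
                        burn_in = 100, thin = 10) {
  if (!is.null(A_eq) && nrow(A_eq)) {
    sv <- svd(A_eq, nu = 0, nv = 4)
    r <- sum(sv$d > 1e-9)
    if (r >= 4) return(matrix(rep(start, n), n, 4, byrow = TRUE))
    N <- sv$v[, (r + 1):4, drop = FALSE]
  } else {
    N <- diag(4)
  }
  d <- ncol(N)
  G <- if (is.null(A_gt) || !nrow(A_gt)) {
    matrix(0, 0, d)
  } else {
    A_gt %*% N
  }
  off <- if (nrow(G)) offsets - as.vector(A_gt %*% start) else numeric(0)
  # box rows: lo <= start_i + (N t)_i <= hi
  B <- rbind(N, -N)
  boff <- c(range[1] - start, -(range[2] - start))
  C <- rbind(G, B)           # C t >= coff along the chain
  coff <- c(off, boff)
  t_cur <- rep(0, d)
  total <- burn_in + n * thin
  out <- matrix(NA_real_, n, 4)
  kept <- 0L
  U <- matrix(stats::rnorm(total * d), total, d)
  S <- stats::runif(total)
  for (step in seq_len(total)) {
    u <- U[step, ]
    u <- u / sqrt(sum(u^2))
    a <- as.vector(C %*% u)
    rhs <- coff - as.vector(C %*% t_cur)
    # constraint: a * s >= rhs
    lo <- suppressWarnings(max(rhs[a > 1e-12] / a[a > 1e-12], -Inf))
    hi <- suppressWarnings(min(rhs[a < -1e-12] / a[a < -1e-12], Inf))
    if (!is.finite(lo)) lo <- -1e6
    if (!is.finite(hi)) hi <- 1e6
    if (hi > lo) t_cur <- t_cur + (lo + S[step] * (hi - lo)) * u
    if (step > burn_in && (step - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- start + as.vector(N %*% t_cur)
    }
  }
  out
}

#' Sample noiseless mean vectors from a profile's solution polytope
#'
#' Uses hit-and-run sampling over the feasible region of the profile's
#' relation system, intersected with the admissible range. Equality relations
#' are handled by sampling in the affine subspace they define, and every
#' strict relation is enforced with a margin of at least `min_signal`, which
#' makes the signal floor \eqn{\delta \ge} `min_signal` structural for the
#' packaged weak-order profiles. Tied condition coordinates are set exactly
#' identical in the output. A rejection safeguard re-draws the rare vectors
#' (possible only for user-defined, non-weak-order systems) that still fall
#' below the signal floor.
#'
#' @inheritParams satisfies
#' @param profile profile id.
#' @param n number of vectors to draw.
#' @param range admissible expression interval (log2 units).
#' @param min_signal minimum signal \eqn{\delta} (log2 units) for non-constant
#'   profiles.
#' @param seed optional integer seed for reproducibility.
#' @param burn_in,thin hit-and-run burn-in and thinning.
#' @return tibble with `n` rows and columns `e0`, `eX`, `eY`, `eXY`.
#' @export
#' @examples
#' tax <- load_taxonomy()
#' sample_profile_means(tax, profile_id(tax, "emergent synergy"), n = 2,
#'                      seed = 1)
sample_profile_means <- function(taxonomy, profile, n, range = c(-14, 14),
                                 min_signal = 0.5, seed = NULL,
                                 burn_in = 100, thin = 10) {
  stopifnot(inherits(taxonomy, "cs_taxonomy"), n >= 1)
  idx <- match(profile, taxonomy$profiles$id)
  if (is.na(idx)) stop("unknown profile id: ", profile)
  run <- function() {
    mats <- profile_relation_matrices(taxonomy$profiles$relations[[idx]])
    ns <- nrow(mats$gt)
    offsets <- rep(min_signal, ns)
    res <- lp_feasible(mats$gt, mats$eq, range = range, offsets = offsets)
    if (!res$feasible) {
      stop("profile ", profile, " is infeasible within [", range[1], ", ",
           range[2], "] at minimum signal ", min_signal)
    }
    draw <- function(m) {
      hit_and_run(m, res$point, mats$gt, mats$eq, range, offsets,
                  burn_in = burn_in, thin = thin)
    }
    V <- draw(n)
    classes <- condition_tie_classes(mats$eq)
    for (cl in unique(classes)) {
      members <- which(classes == cl)
      if (length(members) > 1L) V[, members] <- V[, members[1]]
    }
    is_constant <- length(unique(classes)) == 1L
    if (!is_constant) {
      for (attempt in 1:100) {
        ok <- satisfies(taxonomy, profile, V, tolerance = 0) &
          !is.na(signal_delta(V)) & signal_delta(V) >= min_signal - 1e-9
        if (all(ok)) break
        V[!ok, ] <- draw(sum(!ok))[seq_len(sum(!ok)), , drop = FALSE]
        for (cl in unique(classes)) {
          members <- which(classes == cl)
          if (length(members) > 1L) V[, members] <- V[, members[1]]
        }
      }
      if (!all(ok)) stop("could not satisfy the signal floor for profile ",
                         profile)
    }
    tibble::as_tibble(as.data.frame(V)) |>
      stats::setNames(c("e0", "eX", "eY", "eXY"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Add Gaussian replicate noise to a mean vector
#'
#' Replicates are drawn as \eqn{e_i \sim N(\bar e_i, \sigma)} with a common
#' standard deviation \eqn{\sigma = \delta / (\delta/\sigma)} across the four
#' conditions, then clipped to the admissible range.
#'
#' @param v numeric length-4 noiseless mean vector.
#' @param delta_over_sigma signal-to-noise ratio (e.g. 4, 2.5 or 2).
#' @param n_reps replicates per condition (at least 2; default 4).
#' @param sigma optional explicit noise standard deviation; required for a
#'   constant vector, whose signal is undefined.
#' @param range admissible range used for clipping.
#' @param seed optional integer seed.
#' @return 4 x `n_reps` numeric matrix with rows `CTRL`, `X`, `Y`, `COMBO`.
#' @export
#' @examples
#' add_noise(c(2.2, 2.2, 2.2, 5.5), delta_over_sigma = 4, seed = 1)
add_noise <- function(v, delta_over_sigma, n_reps = 4, sigma = NULL,
                      range = c(-14, 14), seed = NULL) {
  stopifnot(length(v) == 4L, all(is.finite(v)), delta_over_sigma > 0)
  if (n_reps < 2) stop("n_reps must be at least 2 (replicate variance is undefined otherwise)")
  if (is.null(sigma)) {
    delta <- signal_delta(v)
    if (is.na(delta)) {
      stop("constant mean vector: signal is undefined, supply `sigma`")
    }
    sigma <- delta / delta_over_sigma
  }
  run <- function() {
    m <- matrix(stats::rnorm(4 * n_reps, mean = rep(v, n_reps), sd = sigma),
                nrow = 4)
    rownames(m) <- c("CTRL", "X", "Y", "COMBO")
    clip_to_range(m, range)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Build a labelled training set of simulated profile instances
#'
#' For every profile in the taxonomy and every noise regime, draws
#' `instances_per_profile` noiseless mean vectors from the profile's solution
#' polytope and simulates `n_reps` Gaussian replicates per condition at
#' \eqn{\sigma = \delta / (\delta/\sigma)}. Instances of the constant profile
#' (undefined \eqn{\delta}) receive a \eqn{\sigma} drawn from the empirical
#' \eqn{\sigma} distribution of the non-constant instances at the same regime,
#' so the constant class remains learnable.
#'
#' @inheritParams sample_profile_means
#' @param regimes numeric vector of delta/sigma ratios.
#' @param instances_per_profile instances per (profile, regime) pair.
#' @param n_reps replicates per condition.
#' @param profile_ids optional subset of profile ids (defaults to all).
#' @return tibble with one row per instance: `instance`, `profile_id`,
#'   `regime`, `delta`, `sigma`, the noiseless means `m_e0` ... `m_eXY`, and
#'   the replicate columns `CTRL_1` ... `COMBO_<n_reps>`.
#' @export
build_training_set <- function(taxonomy, regimes = c(4, 2.5, 2),
                               instances_per_profile = 400, n_reps = 4,
                               range = c(-14, 14), min_signal = 0.5,
                               seed = NULL, burn_in = 100, thin = 10,
                               profile_ids = NULL) {
  stopifnot(inherits(taxonomy, "cs_taxonomy"), length(regimes) >= 1,
            instances_per_profile >= 1)
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (is.null(profile_ids)) profile_ids <- taxonomy$profiles$id
  run <- function() {
    n_each <- instances_per_profile * length(regimes)
    per_profile <- lapply(profile_ids, function(pid) {
      V <- sample_profile_means(taxonomy, pid, n = n_each, range = range,
                                min_signal = min_signal,
                                burn_in = burn_in, thin = thin)
      tibble::tibble(
        profile_id = pid,
        regime = rep(regimes, each = instances_per_profile),
        m_e0 = V$e0, m_eX = V$eX, m_eY = V$eY, m_eXY = V$eXY
      )
    })
    inst <- dplyr::bind_rows(per_profile)
    M <- as.matrix(inst[, c("m_e0", "m_eX", "m_eY", "m_eXY")])
    inst$delta <- signal_delta(M)
    inst$sigma <- inst$delta / inst$regime
    # constant-profile instances: sigma resampled from the non-constant
    # sigma distribution at the same regime
    const <- is.na(inst$delta)
    if (any(const)) {
      for (rg in unique(inst$regime[const])) {
        pool <- inst$sigma[!const & inst$regime == rg]
        take <- const & inst$regime == rg
        inst$sigma[take] <- if (length(pool)) {
          sample(pool, sum(take), replace = TRUE)
        } else {
          min_signal / rg
        }
      }
    }
    reps <- matrix(
      stats::rnorm(nrow(inst) * 4L * n_reps,
                   mean = rep(t(M), each = n_reps),
                   sd = rep(inst$sigma, each = 4L * n_reps)),
      nrow = nrow(inst), byrow = TRUE
    )
    reps <- clip_to_range(reps, range)
    colnames(reps) <- paste(rep(c("CTRL", "X", "Y", "COMBO"), each = n_reps),
                            seq_len(n_reps), sep = "_")
    out <- dplyr::bind_cols(
      tibble::tibble(instance = seq_len(nrow(inst))),
      inst[, c("profile_id", "regime", "delta", "sigma",
               "m_e0", "m_eX", "m_eY", "m_eXY")],
      tibble::as_tibble(reps)
    )
    attr(out, "cs_params") <- list(
      regimes = regimes, instances_per_profile = instances_per_profile,
      n_reps = n_reps, range = range, min_signal = min_signal, seed = seed
    )
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Split a training-set row's replicates into a 4 x n matrix
#'
#' @param instances tibble from [build_training_set()].
#' @return list of 4 x n replicate matrices (rows CTRL, X, Y, COMBO).
#' @keywords internal
#' @noRd
replicate_matrix <- function(instances, n_reps) {
  cols <- paste(rep(c("CTRL", "X", "Y", "COMBO"), each = n_reps),
                seq_len(n_reps), sep = "_")
  as.matrix(instances[, cols])
}
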