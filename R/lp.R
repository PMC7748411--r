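# Linear-program feasibility for homogeneous sign-relation systems on the
# four condition means (e0, eX, eY, eXY). All systems handled here are of the
# form  A_gt %*% x > 0  (componentwise),  A_eq %*% x = 0,  x in [-lim, lim]^4.

# Reduce a constraint matrix to a linearly independent subset of its rows.
independent_rows <- function(E, tol = 1e-9) {
  if (is.null(E) || nrow(E) == 0L) return(NULL)
  q <- qr(t(E), tol = tol)
  if (q$rank == 0L) return(NULL)
  E[q$pivot[seq_len(q$rank)], , drop = FALSE]
}

#' Feasibility of a sign-relation system by linear programming
#'
#' Maximises a uniform slack `m` subject to `A_gt %*% x >= offsets + m`,
#' `A_eq %*% x = 0` and box bounds, via the simplex method. The system of
#' strict inequalities is feasible iff the optimum slack is positive.
#'
#' `boot::simplex` rejects rank-deficient equality systems, so equalities are
#' first reduced to a row basis; the returned point is then re-checked against
#' every original row, which also catches inconsistent (rather than merely
#' redundant) dropped rows.
#'
#' @param A_gt numeric matrix (rows are coefficients of strict relations
#'   `c . x > 0`), or `NULL`.
#' @param A_eq numeric matrix of equality relations `c . x = 0`, or `NULL`.
#' @param range admissible interval for each coordinate (log2 units).
#' @param offsets required margin per strict row (scalar or vector); the
#'   optimisation finds a point exceeding these margins uniformly.
#' @param cap upper bound on the slack, to keep the program bounded.
#' @return list with elements `feasible` (logical), and when feasible `point`
#'   (numeric length-4 witness) and `margin` (slack achieved beyond `offsets`).
#' @keywords internal
#' @noRd
lp_feasible <- function(A_gt = NULL, A_eq = NULL, range = c(-14, 14),
                        offsets = 0, cap = 1) {
  lim_lo <- range[1]
  lim_hi <- range[2]
  width <- lim_hi - lim_lo
  if (!is.null(A_gt) && nrow(A_gt) == 0L) A_gt <- NULL
  if (!is.null(A_eq) && nrow(A_eq) == 0L) A_eq <- NULL
  A_eq_full <- A_eq
  A_eq <- independent_rows(A_eq)
  ns <- if (is.null(A_gt)) 0L else nrow(A_gt)
  if (ns > 0L) offsets <- rep_len(offsets, ns)

  # variables: x' = x - lim_lo (4, >= 0), m (>= 0)
  a <- c(0, 0, 0, 0, 1)
  A1 <- rbind(cbind(diag(4), 0), c(0, 0, 0, 0, 1))
  b1 <- c(rep(width, 4), cap)
  A2 <- NULL; b2 <- NULL
  if (ns > 0L) {
    A2 <- cbind(A_gt, -1)
    b2 <- offsets + lim_lo * rowSums(A_gt)
  }
  A3 <- NULL; b3 <- NULL
  if (!is.null(A_eq)) {
    A3 <- cbind(A_eq, 0)
    b3 <- lim_lo * rowSums(A_eq)
  }
  res <- try(
    suppressWarnings(boot::simplex(a = a, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                                   A3 = A3, b3 = b3, maxi = TRUE)),
    silent = TRUE
  )
  if (inherits(res, "try-error") || res$solved != 1) {
    return(list(feasible = FALSE))
  }
  m <- res$value
  if (ns > 0L && m <= 1e-9) return(list(feasible = FALSE))
  x <- unname(res$soln[1:4]) + lim_lo
  # re-check against the full original system (covers dropped equality rows)
  if (!is.null(A_eq_full) && any(abs(A_eq_full %*% x) > 1e-6)) {
    return(list(feasible = FALSE))
  }
  if (ns > 0L && any(A_gt %*% x < offsets + 1e-9)) {
    return(list(feasible = FALSE))
  }
  list(feasible = TRUE, point = x, margin = m)
}
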