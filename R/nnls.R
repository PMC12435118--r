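# unconstrained least squares via rank-revealing (pivoted) QR; coefficients
# of columns dropped for rank deficiency are set to 0, which the active-set
# pruning then removes
ls_coef <- function(Ap, y) {
  z <- qr.coef(qr(Ap), y)
  z[is.na(z)] <- 0
  z
}

#' Lawson-Hanson non-negative least squares
#'
#' Active-set solution of `min ||A x - y||_2` subject to `x >= 0`.  The
#' termination test is on dual feasibility (the Karush-Kuhn-Tucker
#' conditions) in angular form: an atom may enter the passive set while its
#' gradient component `w_j = A_j' r` exceeds `tol_kkt * ||A_j|| * ||r||`,
#' i.e. while the residual r still has a non-negligible positive correlation
#' with some column.  Normalizing by the residual norm makes the test
#' scale-free, so very weak signals are resolved as well as strong ones and
#' near-collinear dictionary columns (neighbouring diffusivities) do not
#' stall the fit at an intermediate residual.  Iteration also stops once the
#' residual norm falls to the rounding floor `30 * eps * ||y||`; `y = 0`
#' returns the zero spectrum immediately.  The algorithm is deterministic:
#' no randomness, ties in the entering-atom selection break to the lowest
#' index.
#'
#' @param A Numeric design matrix (m x n).
#' @param y Numeric right-hand side of length m.
#' @param tol_kkt Relative (angular) dual-feasibility tolerance
#'   (default 1e-11).
#' @param max_outer Cap on outer active-set steps (default 10n); exceeding
#'   it raises a non-convergence error.
#' @return List with `x` (the non-negative solution) and `resid.norm`
#'   (squared Euclidean residual norm, matching the convention of
#'   `pracma::lsqnonneg`).
#' @export
nnls_lawson_hanson <- function(A, y, tol_kkt = 1e-11, max_outer = NULL) {
  stopifnot(is.matrix(A), is.numeric(y), nrow(A) == length(y),
            tol_kkt > 0)
  n <- ncol(A)
  if (is.null(max_outer)) max_outer <- 10L * n
  # column equilibration: unit-norm columns keep the rank-revealing QR from
  # discarding weakly decaying atoms (tiny-norm columns) and make all
  # thresholds scale-free; coefficients are mapped back on exit
  col_norm <- sqrt(colSums(A^2))
  scale <- ifelse(col_norm > 1e-200, 1 / col_norm, 0)
  A <- A * rep(scale, each = nrow(A))
  x <- numeric(n)
  P <- logical(n)
  resid <- y
  w <- drop(crossprod(A, resid))
  r_norm <- sqrt(sum(resid^2))
  r_floor <- 30 * .Machine$double.eps * sqrt(sum(y^2))
  # an entering atom whose refit fails to decrease the residual is reverted
  # and banned until the next genuine improvement; this replaces the
  # textbook unconditional-entry rule, which can cycle in finite precision
  # on near-collinear exponential columns
  ban <- logical(n)
  outer_it <- 0L
  inner_it <- 0L
  while (r_norm > r_floor) {
    outer_it <- outer_it + 1L
    if (outer_it > max_outer)
      stop("NNLS did not converge within ", max_outer, " active-set steps")
    cand <- !P & !ban & (w > tol_kkt * r_norm) & (scale > 0)
    if (!any(cand)) break
    free <- which(cand)
    j <- free[which.max(w[free])]
    old_x <- x; old_P <- P; old_resid <- resid; old_w <- w
    P[j] <- TRUE
    z <- numeric(n)
    z[P] <- ls_coef(A[, P, drop = FALSE], y)
    while (any(z[P] <= 0)) {
      inner_it <- inner_it + 1L
      if (inner_it > max_outer)
        stop("NNLS did not converge within ", max_outer, " inner steps")
      Q <- P & (z <= 0)
      denom <- x[Q] - z[Q]
      alpha <- suppressWarnings(min(x[Q][denom > 0] / denom[denom > 0]))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (z - x)
      P <- P & (x > tol_kkt * max(x))
      z <- numeric(n)
      if (any(P)) z[P] <- ls_coef(A[, P, drop = FALSE], y)
    }
    x <- z
    resid <- y - A[, P, drop = FALSE] %*% x[P]
    new_rnorm <- sqrt(sum(resid^2))
    if (new_rnorm < r_norm * (1 - 1e-12)) {
      w <- drop(crossprod(A, resid))
      r_norm <- new_rnorm
      ban[] <- FALSE
    } else {
      # revert and try the next-best entering atom
      x <- old_x; P <- old_P; resid <- old_resid; w <- old_w
      ban[j] <- TRUE
    }
  }
  list(x = x * scale, resid.norm = sum(resid * resid))
}
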