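# Independent numerical ground truth for the first-order system: direct
# Chebyshev collocation of the coupled complex ODEs, plus brute-force
# quadrature helpers used by the tests.  Nothing here reuses the closed form.

# Chebyshev differentiation matrix and points (Trefethen), x in [1, -1].
#' @keywords internal
cheb <- function(n) {
  if (n == 0) return(list(D = matrix(0, 1, 1), x = 1))
  x <- cos(pi * (0:n) / n)
  c_ <- c(2, rep(1, n - 1), 2) * (-1)^(0:n)
  X <- matrix(rep(x, n + 1), ncol = n + 1)
  dX <- X - t(X)
  D <- outer(c_, 1 / c_) / (dX + diag(n + 1))
  D <- D - diag(rowSums(D))
  list(D = D, x = x)
}

# Default resolution: enough Chebyshev points to resolve both the wall layers
# (width ~ 1/Re(kappa)) and the bulk oscillation (wavenumber ~ Im(kappa)) of
# the stiffest mode.
#' @keywords internal
bvp_default_n <- function(constants) {
  k <- max(Mod(constants$beta), Mod(constants$nu))
  n <- ceiling(1.4 * k + 18 * sqrt(k) + 48)
  min(max(n, 64), 700)
}

#' Collocation solution of the first-order boundary-value problem
#'
#' Solves the first-order traveling-wave system directly as a complex linear
#' boundary-value problem by Chebyshev spectral collocation, independently of
#' the closed form: unknowns \eqn{(U_1, V_1, P_1)} on the Chebyshev grid,
#' continuity imposed at every node, the two momentum equations at interior
#' nodes, and the four wall conditions replacing the boundary momentum rows.
#' Collocation (rather than shooting) is used because the viscous mode makes
#' the system stiff, with wall layers of width \eqn{1/|\beta|}.
#'
#' The reported error estimate compares the solution with one recomputed on a
#' doubled grid (the coarse Chebyshev nodes are a subset of the fine ones).
#'
#' @param params A \code{\link{flow_params}} object.
#' @param n Polynomial degree (number of collocation intervals); defaults to
#'   a resolution chosen from the stiffest mode's wavenumber.
#' @param tol Requested accuracy for the convergence flag, in (0, 1e-4].
#' @param refine If \code{TRUE} (default), solve again on a doubled grid to
#'   estimate the error.
#' @return An object of class \code{"bvp_solution"}: ascending grid \code{y},
#'   complex \code{U1}, \code{V1}, \code{P1}, boundary-condition residual
#'   \code{bc_residual}, error estimate \code{error_estimate} (NA when
#'   \code{refine = FALSE}) and logical \code{converged}.
#' @examples
#' sol <- solve_first_order_bvp(flow_params(0.5, 10, chi = 0.3, lambda1 = 0.5))
#' sol$error_estimate
#' @export
solve_first_order_bvp <- function(params, n = NULL, tol = 1e-10,
                                  refine = TRUE) {
  params <- as_flow_params(params)
  if (!is.numeric(tol) || tol <= 0 || tol > 1e-4)
    stop("'tol' must lie in (0, 1e-4]")
  constants <- mode_constants(params)
  if (is.null(n)) n <- bvp_default_n(constants)
  coarse <- .bvp_solve_grid(params, constants, n)
  err <- NA_real_
  if (refine) {
    fine <- .bvp_solve_grid(params, constants, 2L * n)
    idx <- seq(1L, 2L * n + 1L, by = 2L)   # fine nodes contain the coarse ones
    scl <- max(Mod(fine$U1), Mod(fine$V1), Mod(fine$P1))
    err <- max(Mod(coarse$U1 - fine$U1[idx]),
               Mod(coarse$V1 - fine$V1[idx]),
               Mod(coarse$P1 - fine$P1[idx])) / scl
    if (!is.finite(err) || err > 1e3 * tol)
      ps_error("peristream_convergence_error",
               sprintf(paste0("collocation not converged at alpha=%g, Re=%g, ",
                              "chi=%g, lambda1=%g (n=%d, error estimate %.3e)"),
                       params$alpha, params$reynolds, params$chi,
                       params$lambda1, n, err),
               error_estimate = err, n = n)
    coarse <- fine   # report the more accurate solution
  }
  al <- params$alpha
  iend <- c(1L, length(coarse$y))
  bc <- max(Mod(coarse$U1[iend]),
            Mod(coarse$V1[iend] - c(1i * al / 2, -1i * al / 2)))
  structure(list(y = coarse$y, U1 = coarse$U1, V1 = coarse$V1, P1 = coarse$P1,
                 n = length(coarse$y) - 1L, bc_residual = bc,
                 error_estimate = err,
                 converged = is.na(err) || err < tol,
                 params = params),
            class = "bvp_solution")
}

#' @keywords internal
.bvp_solve_grid <- function(params, constants, n) {
  al <- params$alpha; chi <- params$chi
  gam <- constants$gamma; b2 <- constants$beta2
  ch <- cheb(n)
  m <- n + 1L
  D <- ch$D; D2 <- D %*% D
  I <- diag(m)
  Z <- matrix(0, m, m)
  # unknown vector [U; V; P]; rows: x-momentum (U-block), y-momentum
  # (V-block), continuity (P-block).
  A <- rbind(
    cbind(D2 - b2 * I, Z, -1i * al * gam * I),
    cbind(Z, D2 - b2 * I, -gam * D),
    cbind(1i * al * I, D, -1i * al * chi * I))
  b <- complex(length.out = 3L * m)
  # wall rows: replace boundary momentum rows with the Dirichlet conditions
  for (k in c(1L, m)) {
    A[k, ] <- 0; A[k, k] <- 1; b[k] <- 0                    # U1(+-1) = 0
    A[m + k, ] <- 0; A[m + k, m + k] <- 1
    b[m + k] <- if (ch$x[k] > 0) -1i * al / 2 else 1i * al / 2  # V1(+-1)
  }
  sol <- solve(A, b)
  ord <- order(ch$x)
  list(y = ch$x[ord], U1 = sol[seq_len(m)][ord],
       V1 = sol[m + seq_len(m)][ord], P1 = sol[2L * m + seq_len(m)][ord])
}

#' Brute-force nested double integral on a dense grid
#'
#' Computes \eqn{E(y) = \int_0^y\!\int_0^s f(t)\,dt\,ds} (both lower limits at
#' zero) by two passes of cumulative composite Simpson quadrature on a dense
#' uniform grid.  This is a deliberately independent integrator used by the
#' tests to cross-check the closed-form and adaptive-quadrature paths.
#'
#' @param f Vectorised function of \eqn{y}, or a numeric vector of samples on
#'   \code{y}.
#' @param y Uniform ascending grid containing 0; at least 257 points.
#' @return A list with the grid \code{y}, the inner integral \code{F} and the
#'   nested integral \code{E}.
#' @examples
#' g <- seq(-1, 1, length.out = 513)
#' e <- brute_force_double_integral(function(y) cos(pi * y), g)
#' max(abs(e$E - (1 - cos(pi * g)) / pi^2))
#' @export
brute_force_double_integral <- function(f, y = seq(-1, 1, length.out = 1025)) {
  if (length(y) < 257) stop("grid must have at least 257 points")
  h <- diff(y)
  if (max(abs(h - h[1])) > 1e-10 * h[1]) stop("grid must be uniform")
  i0 <- which.min(abs(y))
  if (abs(y[i0]) > 1e-12) stop("grid must contain y = 0")
  fv <- if (is.function(f)) f(y) else f
  Fcum <- .cumsimp(fv, h[1])
  Fy <- Fcum - Fcum[i0]
  Ecum <- .cumsimp(Fy, h[1])
  list(y = y, F = Fy, E = Ecum - Ecum[i0])
}

# Cumulative composite Simpson integral on a uniform grid (4th order): each
# increment uses the quadratic through three neighbouring samples.
#' @keywords internal
.cumsimp <- function(fv, h) {
  n <- length(fv)
  inc <- numeric(n - 1)
  # integral over [i, i+1] from quadratic through (i-1, i, i+1) or (i, i+1, i+2)
  for (i in seq_len(n - 1)) {
    if (i < n - 1) {
      inc[i] <- h / 12 * (5 * fv[i] + 8 * fv[i + 1] - fv[i + 2])
    } else {
      inc[i] <- h / 12 * (-fv[i - 1] + 8 * fv[i] + 5 * fv[i + 1])
    }
  }
  c(0, cumsum(inc))
}

#' @export
print.bvp_solution <- function(x, ...) {
  cat(sprintf(
    "Collocation first-order solution: n = %d, bc residual = %.2e, error estimate = %s, %s\n",
    x$n, x$bc_residual,
    ifelse(is.na(x$error_estimate), "NA", sprintf("%.2e", x$error_estimate)),
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Export a collocation solution as CSV (same schema as the closed form)
#'
#' @param sol A \code{"bvp_solution"}.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
write_bvp_csv <- function(sol, path) {
  out <- data.frame(y = sol$y,
                    U1_re = Re(sol$U1), U1_im = Im(sol$U1),
                    V1_re = Re(sol$V1), V1_im = Im(sol$V1),
                    P1_re = Re(sol$P1), P1_im = Im(sol$P1))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
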