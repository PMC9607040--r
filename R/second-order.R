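#' Second-order time-averaged mean flow
#'
#' Computes the steady (time-averaged) part of the order-epsilon-squared
#' flow driven by the first-order traveling wave.  With the ansatz
#' \eqn{q = Q(y)e^{i\alpha(x-t)} + c.c.}, conjugate pair products such as
#' \eqn{U_1\bar V_1 + \bar U_1 V_1} are the phase averages of quadratic terms,
#' and the mean axial momentum balance reduces to
#' \deqn{U_{20}''(y) = Re\, f(y), \qquad U_{20}(y) = Re\,E(y) + D_2 y + D_3,}
#' with \eqn{E(y) = \int_0^y\!\int_0^s f\,dt\,ds} (both lower limits at 0, the
#' convention under which the even symmetry of \eqn{f} makes \eqn{E} even and
#' forces \eqn{D_2 = 0}), while the mean transverse balance integrates to
#' \deqn{V_{20}(y) = -\chi\,(P_1\bar V_1 + \bar P_1 V_1) + D_1.}
#'
#' The forcing is
#' \deqn{f = \frac{d}{dy}(U_1\bar V_1 + \bar U_1 V_1) + \lambda_1\,B(y),}
#' where the convected block
#' \deqn{B = 4\alpha^2|U_1|^2 - 2\alpha^2(U_1\bar P_1 + \bar U_1 P_1)
#'   + 2i\alpha(V_1\bar U_1' - \bar V_1 U_1')
#'   + i\alpha(\bar V_1 P_1' - V_1\bar P_1') - (U_1'\bar P_1' + \bar U_1' P_1')}
#' is present only for the upper convected variant; for the linear Maxwell
#' model the convected quadratic terms vanish and \eqn{f} keeps only the
#' Reynolds-stress term (relaxation still enters through \eqn{\gamma} and
#' \eqn{\beta}).
#'
#' Wall conditions are transferred from the displaced wall to the mean
#' position \eqn{y = \pm 1}: averaging the no-slip/no-penetration conditions
#' gives \eqn{U_{20}(\pm 1) \pm \tfrac12(\bar U_1'+U_1')(\pm 1) = 0} and the
#' analogous transverse condition, under which the transverse integration
#' constant \eqn{D_1} vanishes identically (it equals the mean mass flux
#' through the wall); \code{D1} is computed from the wall balance, not
#' assumed.  All mean quantities are built from conjugate pairs and are
#' checked to be real to round-off before their imaginary parts are dropped.
#'
#' Because the first-order fields are finite exponential sums, \eqn{f},
#' \eqn{E} and all integrals are evaluated in closed form (exact integration
#' of the exponential sum), which remains accurate in stiff and highly
#' oscillatory regimes; \code{\link{integrate_E}} provides the adaptive
#' quadrature route for cross-checking and for user-supplied forcings.
#'
#' @param params A \code{\link{flow_params}} object.
#' @param field Optional precomputed \code{\link{first_order}} solution.
#' @return An object of class \code{"second_order"} with vectorised
#'   evaluators \code{f(y)}, \code{E(y)}, \code{V20(y)}, \code{U20(y)},
#'   constants \code{D1}, \code{D2}, \code{D3}, the wall values \code{E1} =
#'   E(1) and \code{dU1_wall} = U1'(1), and \code{intE01} =
#'   \eqn{\int_0^1 E\,dy}.
#' @examples
#' so <- second_order(flow_params(0.5, 10, chi = 0.3, lambda1 = 0.5))
#' c(so$D1, so$D2, so$D3)
#' @export
second_order <- function(params, field = first_order(params)) {
  params <- as_flow_params(params)
  f_es <- .forcing_expsum(field, params)
  pv_es <- .pv_pair_expsum(field)      # P1 conj(V1) + conj(P1) V1
  fb <- es_bound(f_es); Eb <- es_E_bound(f_es); pb <- es_bound(pv_es)
  E1 <- real_part(es_E(f_es, 1), what = "E(1)", floor = Eb)
  Em1 <- real_part(es_E(f_es, -1), what = "E(-1)", floor = Eb)
  intE01 <- real_part(es_int01_E(f_es), what = "int_0^1 E", floor = Eb)
  wall <- first_order_fields(field, c(-1, 1))
  dU_w <- wall$dU1[2]; dV_w <- wall$dV1[2]
  # transverse constant from the mean wall mass balance at y = +1
  pv_w <- real_part(es_eval(pv_es, 1), what = "P1 V1-bar wall pair", floor = pb)
  D1 <- -Re(dV_w) + params$chi * pv_w
  # same balance at y = -1 must give the same constant
  pv_l <- real_part(es_eval(pv_es, -1), what = "P1 V1-bar wall pair", floor = pb)
  D1_low <- Re(wall$dV1[1]) + params$chi * pv_l
  scal <- max(abs(Re(dV_w)), params$chi * abs(pv_w), 1)
  if (abs(D1 - D1_low) > 1e-8 * scal)
    ps_error("peristream_consistency_error",
             sprintf("transverse wall balances disagree: D1 = %.3e vs %.3e",
                     D1, D1_low))
  cst <- solve_wall_constants(field, c(Em1, E1), params)
  force(params); force(field)
  structure(list(
    params = params, field = field,
    f = function(y) real_part(es_eval(f_es, y), what = "forcing f", floor = fb),
    E = function(y) real_part(es_E(f_es, y), what = "E(y)", floor = Eb),
    V20 = function(y)
      -params$chi * real_part(es_eval(pv_es, y), what = "P1 V1 pair",
                              floor = pb) + D1,
    U20 = function(y)
      params$reynolds * real_part(es_E(f_es, y), what = "E(y)", floor = Eb) +
        cst[["D2"]] * y + cst[["D3"]],
    D1 = D1, D2 = cst[["D2"]], D3 = cst[["D3"]],
    E1 = E1, intE01 = intE01, dU1_wall = dU_w,
    f_es = f_es, pv_es = pv_es), class = "second_order")
}

#' @keywords internal
.forcing_expsum <- function(field, params = field$params) {
  al <- params$alpha
  U <- field$U; V <- field$V; P <- field$P
  dU <- field$dU; dP <- field$dP
  Ub <- es_conj(U); Vb <- es_conj(V); Pb <- es_conj(P)
  dUb <- es_conj(dU); dPb <- es_conj(dP)
  fN <- es_deriv(es_add(es_mul(U, Vb), es_mul(Ub, V)))
  if (params$variant == "linear" || params$lambda1 == 0) return(fN)
  blk <- Reduce(es_add, list(
    es_scale(es_mul(U, Ub), 4 * al^2),
    es_scale(es_add(es_mul(U, Pb), es_mul(Ub, P)), -2 * al^2),
    es_scale(es_add(es_mul(V, dUb), es_scale(es_mul(Vb, dU), -1)), 2i * al),
    es_scale(es_add(es_mul(Vb, dP), es_scale(es_mul(V, dPb), -1)), 1i * al),
    es_scale(es_add(es_mul(dU, dPb), es_mul(dUb, dP)), -1)))
  es_add(fN, es_scale(blk, params$lambda1))
}

#' @keywords internal
.pv_pair_expsum <- function(field) {
  es_add(es_mul(field$P, es_conj(field$V)),
         es_mul(es_conj(field$P), field$V))
}

#' Mean-flow forcing f(y)
#'
#' Evaluates the variant-dependent second-order mean forcing at the given
#' points (see \code{\link{second_order}} for the formula).
#'
#' @param field A \code{\link{first_order}} object.
#' @param y Evaluation points in \eqn{[-1, 1]}.
#' @param params Flow parameters; defaults to the field's.
#' @return Real vector of forcing values.
#' @export
mean_forcing <- function(field, y, params = field$params) {
  f_es <- .forcing_expsum(field, params)
  real_part(es_eval(f_es, y), what = "forcing f", floor = es_bound(f_es))
}

#' Nested double integral of a forcing by adaptive quadrature
#'
#' Computes \eqn{E(y) = \int_0^y\!\int_0^s f(t)\,dt\,ds} with both lower
#' limits fixed at \eqn{y = 0}, using the equivalent single-kernel form
#' \eqn{E(y) = \int_0^y (y-s) f(s)\,ds} and adaptive quadrature
#' (\code{stats::integrate}) to absolute tolerance \code{tol}.  The lower
#' limits at 0 are the only convention under which an even forcing yields an
#' even \eqn{E}, consistent with the symmetric channel.
#'
#' A \code{peristream_quadrature_warning} is raised when the quadrature
#' reports an error estimate above \code{tol}.
#'
#' @param f Vectorised real function on \eqn{[-1, 1]}.
#' @param tol Absolute tolerance (default 1e-10).
#' @return A list with the vectorised evaluator \code{E} and scalar \code{E1}
#'   = \eqn{E(1)}.
#' @examples
#' integrate_E(function(y) rep(1, length(y)))$E1   # 1/2
#' @export
integrate_E <- function(f, tol = 1e-10) {
  one <- function(yv) {
    vapply(yv, function(y) {
      if (y == 0) return(0)
      q <- stats::integrate(function(s) (y - s) * f(s), 0, y,
                            abs.tol = tol, rel.tol = tol, subdivisions = 400L,
                            stop.on.error = FALSE)
      if (q$message != "OK" || q$abs.error > max(tol, 1e-8 * abs(q$value)))
        ps_warning("peristream_quadrature_warning",
                   sprintf("quadrature for E(%g): %s (error estimate %.2e)",
                           y, q$message, q$abs.error))
      q$value
    }, numeric(1))
  }
  list(E = one, E1 = one(1))
}

#' Mean transverse velocity V20(y)
#'
#' @param field A \code{\link{first_order}} object.
#' @param y Evaluation points.
#' @param params Flow parameters; defaults to the field's.
#' @return Real vector of mean transverse velocity values.
#' @export
mean_transverse_V20 <- function(field, y, params = field$params) {
  so <- second_order(params, field)
  so$V20(y)
}

#' Axial wall constants D2, D3
#'
#' Solves the two transferred wall conditions
#' \eqn{U_{20}(\pm1) \pm \tfrac12(\bar U_1' + U_1')(\pm1) = 0} for the
#' integration constants of \eqn{U_{20} = Re\,E + D_2 y + D_3}.  With an even
#' forcing (hence even \eqn{E}) and the odd parity of \eqn{U_1'}, the solve
#' returns \eqn{D_2 = 0} to round-off.
#'
#' @param field A \code{\link{first_order}} object.
#' @param E_wall Numeric length-2 vector \eqn{(E(-1), E(+1))}.
#' @param params Flow parameters; defaults to the field's.
#' @return Named numeric vector with elements \code{D2} and \code{D3}.
#' @export
solve_wall_constants <- function(field, E_wall, params = field$params) {
  wall <- first_order_fields(field, c(-1, 1))
  trans <- Re(wall$dU1)                 # (1/2)(U1' + conj(U1)') at the walls
  Re_ <- params$reynolds
  A <- matrix(c(-1, 1, 1, 1), nrow = 2)   # rows y = -1, +1; cols (D2, D3)
  b <- c(-Re_ * E_wall[1] + trans[1],     # U20(-1) - Re U1'(-1)... sign via +-
         -Re_ * E_wall[2] - trans[2])
  d <- solve(A, b)
  c(D2 = d[1], D3 = d[2])
}

#' Mean axial velocity U20(y)
#'
#' @param E Vectorised evaluator of the nested integral \eqn{E(y)} (e.g. from
#'   \code{\link{integrate_E}} or a \code{\link{second_order}} object).
#' @param D2,D3 Wall constants from \code{\link{solve_wall_constants}}.
#' @param params Flow parameters.
#' @param y Evaluation points.
#' @return Real vector \eqn{Re\,E(y) + D_2 y + D_3}.
#' @export
mean_axial_U20 <- function(E, D2, D3, params, y) {
  params$reynolds * E(y) + D2 * y + D3
}

#' @export
print.second_order <- function(x, ...) {
  cat("Second-order mean flow\n")
  print(x$params)
  cat(sprintf("  D1 = %.3e, D2 = %.3e, D3 = %.6g\n", x$D1, x$D2, x$D3))
  cat(sprintf("  E(1) = %.6g, int_0^1 E = %.6g, U20(1) = %.6g\n",
              x$E1, x$intE01, x$U20(1)))
  invisible(x)
}

#' Export mean-flow profiles to CSV
#'
#' @param so A \code{\link{second_order}} object.
#' @param path Output file path.
#' @param y Sampling grid (default 201 uniform points).
#' @return The written data frame, invisibly.
#' @export
write_mean_flow_csv <- function(so, path, y = seq(-1, 1, length.out = 201)) {
  out <- data.frame(y = y, V20 = so$V20(y), U20 = so$U20(y))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
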