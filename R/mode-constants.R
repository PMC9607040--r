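#' Complex constants of the two first-order modes
#'
#' Derives the complex constants that define the two spatial eigen-solutions
#' of the first-order (order-epsilon) traveling-wave system: the viscous
#' (shear) beta-mode and the acoustic (compressible) nu-mode.
#'
#' With the traveling-wave ansatz \eqn{q(x,y,t) = Q(y)e^{i\alpha(x-t)} + c.c.}
#' the linearised governing equations reduce to
#' \deqn{V_1' + i\alpha U_1 = i\alpha\chi P_1,}
#' \deqn{U_1'' - \beta^2 U_1 = i\alpha\gamma P_1,}
#' \deqn{V_1'' - \beta^2 V_1 = \gamma P_1',}
#' with
#' \deqn{\gamma = (1 - i\alpha\lambda_1)Re - i\alpha\chi/3, \qquad
#'       \beta^2 = \alpha^2 - i\alpha(1 - i\alpha\lambda_1)Re.}
#' The pressure-carrying nu-mode (\eqn{\cosh\nu y}/\eqn{\sinh\nu y} profile)
#' is compatible with all three equations only when the dispersion relation
#' \deqn{\gamma(\nu^2 - \alpha^2) = i\alpha\chi(\nu^2 - \beta^2)}
#' holds, which fixes
#' \deqn{\nu^2 = \frac{\gamma\alpha^2 - i\alpha\chi\beta^2}{\gamma - i\alpha\chi}.}
#' As \eqn{\chi \to 0} this deforms continuously to the incompressible value
#' \eqn{\nu = \alpha}.  The pressure normalisation factor is \eqn{\xi = \gamma},
#' entering the closed form as \eqn{P_1 = ((\nu^2-\beta^2)/(\nu\xi)) c_1\cosh\nu y}.
#'
#' Square roots take the principal branch with non-negative real part (purely
#' imaginary results tied toward positive imaginary part); the hyperbolic mode
#' shapes are even/odd, so the fields themselves are branch-independent.
#'
#' @param params A \code{\link{flow_params}} object.
#' @return An object of class \code{"mode_constants"} with fields
#'   \code{gamma}, \code{beta}, \code{beta2}, \code{nu}, \code{nu2},
#'   \code{xi} (all complex) and the originating \code{params}.
#' @seealso \code{\link{dispersion_residual}}, \code{\link{first_order}}
#' @examples
#' mc <- mode_constants(flow_params(0.5, 10, chi = 0.3, lambda1 = 0.5))
#' dispersion_residual(mc)
#' @export
mode_constants <- function(params) {
  params <- as_flow_params(params)
  al <- params$alpha; Re <- params$reynolds
  chi <- params$chi; l1 <- params$lambda1
  m <- (1 - 1i * al * l1) * Re          # modified inertia prefactor
  gamma <- m - 1i * al * chi / 3
  beta2 <- al^2 - 1i * al * m
  denom <- gamma - 1i * al * chi
  if (Mod(denom) < 1e-14 * max(Mod(gamma), al * chi))
    ps_error("peristream_degenerate_mode_error",
             "acoustic mode degenerate: gamma - i*alpha*chi vanishes")
  nu2 <- (gamma * al^2 - 1i * al * chi * beta2) / denom
  beta <- sqrt_principal(beta2)
  nu <- sqrt_principal(nu2)
  check_finite(c(gamma, beta, nu), "mode constants")
  if (Mod(nu - beta) < 1e-8 * Mod(beta))
    ps_error("peristream_degenerate_mode_error",
             sprintf("mode coalescence: |nu - beta| = %.3e < 1e-8 |beta|",
                     Mod(nu - beta)))
  structure(list(gamma = gamma, beta = beta, beta2 = beta2,
                 nu = nu, nu2 = nu2, xi = gamma, params = params),
            class = "mode_constants")
}

#' Residual of the defining relations of the mode constants
#'
#' Returns the maximum relative residual of (i) the beta-squared identity
#' \eqn{\beta^2 = \alpha^2 - i\alpha(1-i\alpha\lambda_1)Re} and (ii) the
#' nu compatibility (dispersion) relation
#' \eqn{\gamma(\nu^2-\alpha^2) - i\alpha\chi(\nu^2-\beta^2) = 0}.
#'
#' @param constants A \code{"mode_constants"} object.
#' @param params Optional \code{\link{flow_params}}; defaults to the ones the
#'   constants were derived from.
#' @return A non-negative scalar (relative residual).
#' @export
dispersion_residual <- function(constants, params = constants$params) {
  al <- params$alpha; Re <- params$reynolds
  chi <- params$chi; l1 <- params$lambda1
  r1 <- Mod(constants$beta^2 - (al^2 - 1i * al * (1 - 1i * al * l1) * Re))
  s1 <- max(Mod(constants$beta^2), al^2, al * Re)
  lhs <- constants$gamma * (constants$nu^2 - al^2)
  rhs <- 1i * al * chi * (constants$nu^2 - constants$beta^2)
  s2 <- max(Mod(lhs), Mod(rhs), Mod(constants$gamma) * al^2, 1e-300)
  max(r1 / s1, Mod(lhs - rhs) / s2)
}

#' @export
print.mode_constants <- function(x, ...) {
  fmt <- function(z) sprintf("%.6g%+.6gi", Re(z), Im(z))
  cat("First-order mode constants:\n",
      "  gamma =", fmt(x$gamma), "\n",
      "  beta  =", fmt(x$beta), "(viscous mode)\n",
      "  nu    =", fmt(x$nu), "(acoustic mode)\n",
      "  xi    =", fmt(x$xi), "\n")
  invisible(x)
}

#' Serialise mode constants to JSON
#'
#' Writes the complex constants with separate real and imaginary fields.
#'
#' @param constants A \code{"mode_constants"} object.
#' @param path Optional file path; if \code{NULL} the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
mode_constants_json <- function(constants, path = NULL) {
  cx <- function(z) list(re = Re(z), im = Im(z))
  obj <- list(gamma = cx(constants$gamma), beta = cx(constants$beta),
              nu = cx(constants$nu), xi = cx(constants$xi))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
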