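#' Dimensionless parameters of the peristaltic flow problem
#'
#' Collects the five dimensionless numbers governing the traveling-wave flow
#' of a compressible Maxwell fluid in a two-dimensional channel of half-width
#' one, together with the constitutive variant.
#'
#' @param alpha Wave number, \eqn{\alpha = 2\pi h/\lambda_{wave}} (channel
#'   half-width over reduced wavelength); must be positive.
#' @param reynolds Reynolds number \eqn{Re = \rho_0 c h/\mu} built on the wave
#'   speed; must be positive.
#' @param chi Compressibility parameter of the exponential equation of state
#'   \eqn{\rho = \exp(\chi(P - P_0))}; non-negative, \code{chi = 0} is the
#'   incompressible limit.
#' @param lambda1 Dimensionless stress relaxation time \eqn{\lambda_1 c/h} of
#'   the Maxwell element; non-negative, \code{lambda1 = 0} is Newtonian.
#' @param epsilon Amplitude ratio (wall wave amplitude over channel
#'   half-width), the perturbation parameter; must lie in (0, 1).
#' @param variant Constitutive variant: \code{"ucm"} (upper convected Maxwell,
#'   frame-invariant convected stress derivative) or \code{"linear"} (linear
#'   Maxwell, partial time derivative).  The two variants share the same
#'   first-order fields; they differ only in the quadratic convected terms
#'   entering the second-order mean-flow forcing, and coincide exactly when
#'   \code{lambda1 = 0}.
#'
#' @return An object of class \code{"flow_params"}.
#' @examples
#' p <- flow_params(alpha = 0.5, reynolds = 10, chi = 0.3, lambda1 = 0.5)
#' p
#' @export
flow_params <- function(alpha, reynolds, chi = 0, lambda1 = 0,
                        epsilon = 0.1, variant = c("ucm", "linear")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(reynolds), length(reynolds) == 1L, is.finite(reynolds),
            is.numeric(chi), length(chi) == 1L, is.finite(chi),
            is.numeric(lambda1), length(lambda1) == 1L, is.finite(lambda1),
            is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (reynolds <= 0) stop("'reynolds' must be > 0")
  if (chi < 0) stop("'chi' must be >= 0")
  if (lambda1 < 0) stop("'lambda1' must be >= 0")
  if (epsilon <= 0 || epsilon >= 1) stop("'epsilon' must lie in (0, 1)")
  structure(list(alpha = alpha, reynolds = reynolds, chi = chi,
                 lambda1 = lambda1, epsilon = epsilon, variant = variant),
            class = "flow_params")
}

#' Build flow parameters from a flat named mapping
#'
#' Accepts a list (e.g. parsed from a YAML or JSON configuration file) with
#' keys \code{alpha}, \code{reynolds}, \code{chi}, \code{lambda1},
#' \code{epsilon} and \code{variant}; missing optional keys take the
#' \code{\link{flow_params}} defaults.
#'
#' @param x A named list or environment of parameter values.
#' @return A \code{"flow_params"} object.
#' @export
as_flow_params <- function(x) {
  if (inherits(x, "flow_params")) return(x)
  x <- as.list(x)
  args <- list(alpha = x$alpha, reynolds = x$reynolds)
  for (k in c("chi", "lambda1", "epsilon", "variant"))
    if (!is.null(x[[k]])) args[[k]] <- x[[k]]
  do.call(flow_params, args)
}

#' @export
print.flow_params <- function(x, ...) {
  cat(sprintf(
    "Flow parameters (%s Maxwell):\n  alpha = %g, Re = %g, chi = %g, lambda1 = %g, epsilon = %g\n",
    if (x$variant == "ucm") "upper convected" else "linear",
    x$alpha, x$reynolds, x$chi, x$lambda1, x$epsilon))
  invisible(x)
}
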