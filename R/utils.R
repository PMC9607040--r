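# Internal numerical helpers and condition constructors.

#' @keywords internal
ps_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "peristream_error")))
}

#' @keywords internal
ps_warning <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "peristream_warning")))
}

# Principal complex square root with Re >= 0; a purely imaginary result
# (negative real argument) is tied toward positive imaginary part.  cosh/sinh
# are even/odd, so the physical fields do not depend on the branch; fixing it
# makes outputs reproducible.
#' @keywords internal
sqrt_principal <- function(z2) {
  z <- sqrt(as.complex(z2))
  if (Re(z) < 0 || (Re(z) == 0 && Im(z) < 0)) z <- -z
  z
}

# tanh for complex z with Re(z) >= 0, stable for large |Re(z)| where the naive
# sinh/cosh ratio overflows.
#' @keywords internal
tanh_stable <- function(z) {
  flip <- Re(z) < 0
  z[flip] <- -z[flip]
  e <- exp(-2 * z)
  out <- (1 - e) / (1 + e)
  out[flip] <- -out[flip]
  out
}

# 1 / (e^z + e^-z) for Re(z) >= 0 without overflow.
#' @keywords internal
sech_half <- function(z) {
  exp(-z) / (1 + exp(-2 * z))
}

#' @keywords internal
check_finite <- function(x, what) {
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(x))))
    ps_error("peristream_nonfinite_error",
             sprintf("non-finite value encountered in %s", what))
  invisible(x)
}

# Drop a numerically negligible imaginary part, erroring if it is not
# negligible.  'floor' is a bound on the magnitudes summed to produce z
# (exponential-sum terms may be much larger than the cancelled result, and
# round-off is relative to them, not to the result).
#' @keywords internal
real_part <- function(z, tol = 1e-11, what = "value", floor = 0) {
  scale <- max(Mod(z), floor / 10, 1e-300)
  bad <- max(abs(Im(z))) / scale
  if (bad > tol)
    ps_error("peristream_consistency_error",
             sprintf("imaginary residue %.3e in %s exceeds tolerance %.1e",
                     bad, what, tol))
  Re(z)
}
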