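# Exponential-sum algebra.
#
# Every first-order field of the perturbation solution is a finite combination
# of exp(+/- nu * y) and exp(+/- beta * y), so every product appearing in the
# second-order mean-flow forcing f(y) is again a finite exponential sum.  The
# nested integral E(y) = int_0^y int_0^s f and the flux integral int_0^1 E are
# therefore available in closed form to machine precision, independent of how
# stiff or oscillatory the modes are (|beta| of order 10^3-10^4 included).
#
# A sum is stored as parallel vectors (cf, mu, a): sum_j cf_j exp(mu_j (y - a_j)).
# The anchor a_j in {-1, 0, 1} is chosen so that Re(mu_j * (y - a_j)) <= 0 on
# [-1, 1]; with that convention no term ever overflows and coefficients of
# products stay bounded by the product of the factors' bounds.

#' @keywords internal
es_new <- function(cf, mu, a = NULL) {
  cf <- as.complex(cf); mu <- as.complex(mu)
  if (is.null(a)) a <- ifelse(Re(mu) >= 0, 1, -1)
  keep <- cf != 0
  structure(list(cf = cf[keep], mu = mu[keep], a = a[keep]), class = "expsum")
}

#' @keywords internal
es_zero <- function() es_new(complex(0), complex(0))

#' @keywords internal
es_add <- function(e1, e2) {
  es_new(c(e1$cf, e2$cf), c(e1$mu, e2$mu), c(e1$a, e2$a))
}

#' @keywords internal
es_scale <- function(e, z) es_new(e$cf * z, e$mu, e$a)

#' @keywords internal
es_conj <- function(e) es_new(Conj(e$cf), Conj(e$mu), e$a)

#' @keywords internal
es_deriv <- function(e) es_new(e$cf * e$mu, e$mu, e$a)

#' @keywords internal
es_mul <- function(e1, e2) {
  n1 <- length(e1$cf); n2 <- length(e2$cf)
  if (n1 == 0L || n2 == 0L) return(es_zero())
  i <- rep(seq_len(n1), times = n2); j <- rep(seq_len(n2), each = n1)
  mu <- e1$mu[i] + e2$mu[j]
  a <- ifelse(Re(mu) >= 0, 1, -1)
  # re-anchor: cf1 cf2 e^{mu1(y-a1)} e^{mu2(y-a2)} = cf' e^{mu (y-a)} with
  # cf' = cf1 cf2 exp(mu a - mu1 a1 - mu2 a2); the exponent has Re <= 0.
  cf <- e1$cf[i] * e2$cf[j] * exp(mu * a - e1$mu[i] * e1$a[i] - e2$mu[j] * e2$a[j])
  es_new(cf, mu, a)
}

# Evaluate the sum at real points y (vectorised).
#' @keywords internal
es_eval <- function(e, y) {
  if (length(e$cf) == 0L) return(complex(real = numeric(length(y))))
  ex <- exp(outer(y, e$mu) - rep(e$mu * e$a, each = length(y)))
  drop(ex %*% e$cf)
}

# E(y) = int_0^y int_0^s e(t) dt ds, both lower limits at 0 (vectorised in y).
# Per term: cf (e^{mu (y-a)} - e^{-mu a}(1 + mu y)) / mu^2, with a series branch
# for small |mu|; the anchored form never overflows.
#' @keywords internal
es_E <- function(e, y) {
  out <- complex(length.out = length(y))
  if (length(e$cf) == 0L) return(out)
  for (j in seq_along(e$cf)) {
    mu <- e$mu[j]; cf <- e$cf[j]; a <- e$a[j]
    if (Mod(mu) >= 0.5) {
      out <- out + (cf * exp(mu * (y - a)) -
                    cf * exp(-mu * a) * (1 + mu * y)) / mu^2
    } else {
      c0 <- cf * exp(-mu * a)
      z <- mu * y
      term <- rep(1 / 2 + 0i, length(y)); acc <- term
      for (k in 3:18) { term <- term * z / k; acc <- acc + term }
      out <- out + c0 * acc * y^2
    }
  }
  out
}

# int_0^1 E(y) dy in closed form:
# per term cf [ e^{mu(1-a)}/mu^3 - e^{-mu a}(1/mu^3 + 1/mu^2 + 1/(2 mu)) ],
# equivalently c0 * sum_{k>=2} mu^(k-2)/(k! (k+1)) for small |mu|.
#' @keywords internal
es_int01_E <- function(e) {
  tot <- 0 + 0i
  if (length(e$cf) == 0L) return(tot)
  for (j in seq_along(e$cf)) {
    mu <- e$mu[j]; cf <- e$cf[j]; a <- e$a[j]
    if (Mod(mu) >= 0.5) {
      tot <- tot + cf * exp(mu * (1 - a)) / mu^3 -
        cf * exp(-mu * a) * (1 / mu^3 + 1 / mu^2 + 1 / (2 * mu))
    } else {
      c0 <- cf * exp(-mu * a)
      v <- 1 / 6 + 0i; fac <- 2; pw <- 1 + 0i
      for (k in 3:18) {
        fac <- fac * k; pw <- pw * mu
        v <- v + pw / (fac * (k + 1))
      }
      tot <- tot + c0 * v
    }
  }
  tot
}

# Bound on the sum of term magnitudes of the sum (anchoring makes each
# |e^{mu(y-a)}| <= 1 on [-1, 1]) and of its nested integral; used as the
# round-off scale when discarding imaginary residues of conjugate pairs.
#' @keywords internal
es_bound <- function(e) sum(Mod(e$cf))

#' @keywords internal
es_E_bound <- function(e) {
  if (length(e$cf) == 0L) return(0)
  m <- Mod(e$mu)
  sum(ifelse(m >= 0.5, Mod(e$cf) * (2 + m) / m^2, Mod(e$cf)))
}
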