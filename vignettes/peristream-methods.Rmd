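---
title: "Peristaltic streaming of a compressible Maxwell fluid: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peristaltic streaming of a compressible Maxwell fluid: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peristream)
```

## The physical problem

A two-dimensional channel of half-width $h$ is filled with a compressible
viscoelastic liquid.  Its flexible walls carry a traveling sinusoidal
deformation $\eta = a\cos\bigl(\tfrac{2\pi}{\lambda}(x - ct)\bigr)$ — the
situation of peristaltic pumping in physiological conduits and of
acoustically actuated transport in microfluidic devices, where an externally
excited surface wave drives a steady net flow even though the wall motion
itself averages to zero.  The liquid obeys a Maxwell stress–strain relation
with relaxation time $\lambda_1$, in one of two variants: the *upper
convected* (UCM) model, whose stress derivative is the frame-invariant
contravariant convected derivative, and the *linear* Maxwell model, which
replaces it with a partial time derivative.  An exponential equation of
state $\rho = \exp(\chi(P - P_0))$ makes the fluid compressible, admitting
an acoustic mode alongside the viscous shear mode.

Five dimensionless groups control the problem (`flow_params()`):

| symbol | meaning | constraint |
|---|---|---|
| $\alpha = 2\pi h/\lambda$ | wave number | $>0$ |
| $Re = \rho_0 c h/\mu$ | Reynolds number on the wave speed | $>0$ |
| $\chi$ | compressibility | $\ge 0$; $0$ = incompressible |
| $\lambda_1$ (scaled by $c/h$) | stress relaxation time | $\ge 0$; $0$ = Newtonian |
| $\epsilon = a/h$ | amplitude ratio | $0<\epsilon<1$, the small parameter |

## Perturbation scheme

All fields are expanded in powers of $\epsilon$.  Writing each first-order
quantity as $q_1 = Q_1(y)e^{i\alpha(x-t)} + \text{c.c.}$ (so the wall
displacement contributes amplitude $\epsilon/2$ per complex exponential — a
convention that must be fixed explicitly because it sets the factor $1/2$ in
the wall condition $V_1(\pm1) = \mp i\alpha/2$), the linearised equations
reduce to

$$V_1' + i\alpha U_1 = i\alpha\chi P_1,\qquad
  U_1'' - \beta^2 U_1 = i\alpha\gamma P_1,\qquad
  V_1'' - \beta^2 V_1 = \gamma P_1',$$

with $\gamma = (1-i\alpha\lambda_1)Re - i\alpha\chi/3$ and
$\beta^2 = \alpha^2 - i\alpha(1-i\alpha\lambda_1)Re$.  Both constitutive
variants linearise to the same factor $(1-i\alpha\lambda_1)$, so **the
first-order field is identical for the linear and upper convected models**;
the variants differ only at second order.  The $\chi$ term in the continuity
relation is what couples pressure into the mass balance ($\rho_1 = \chi
p_1$); it is essential for the mean transverse flow below.

The general bounded solution is a superposition of two modes:

* the **viscous $\beta$-mode**, pressure-free, carrying the wall shear layer
  of thickness $\sim 1/|\mathrm{Re}\,\beta|$;
* the **acoustic $\nu$-mode**, which carries the whole first-order pressure.
  Requiring the $\cosh\nu y$/$\sinh\nu y$ profile to satisfy all three
  equations simultaneously yields the compatibility (dispersion) relation
  $\gamma(\nu^2-\alpha^2) = i\alpha\chi(\nu^2-\beta^2)$, i.e.

$$\nu^2 = \frac{\gamma\alpha^2 - i\alpha\chi\beta^2}{\gamma - i\alpha\chi},$$

which deforms continuously to the incompressible value $\nu = \alpha$ as
$\chi \to 0$.  The closed form is then

$$U_1 = \tfrac{i\alpha}{\nu}c_1\cosh\nu y + \tfrac{i\beta}{\alpha}c_2\cosh\beta y,
\quad V_1 = c_1\sinh\nu y + c_2\sinh\beta y,
\quad P_1 = \tfrac{\nu^2-\beta^2}{\nu\,\gamma}c_1\cosh\nu y,$$

with $(c_1, c_2)$ from the $2\times2$ wall-condition system
(`solve_mode_amplitudes()`).  These formulas were re-derived from the
primitive equations and are accepted only because their residual in the
governing system vanishes to round-off (`first_order_residual()`, checked on
Chebyshev points); the derivation was verified symbolically during
development, and at run time an independent Chebyshev collocation solution
of the same boundary-value problem (`solve_first_order_bvp()`) agrees with
the closed form to better than $10^{-6}$ max-norm across the whole parameter
grid exercised by the tests (typically $10^{-8}$ or better).

**Branch convention.** $\beta$ and $\nu$ take the principal square root with
non-negative real part; a purely imaginary result is tied toward positive
imaginary part.  Since $\cosh$/$\sinh$ are even/odd, the fields are
branch-independent; fixing the branch merely makes stored constants
reproducible.  Mode coalescence $|\nu - \beta| < 10^{-8}|\beta|$ would
invalidate the closed form and raises a classed error; it cannot occur for
admissible parameters ($\nu = \beta$ requires $\beta^2 = \alpha^2$, i.e.
$Re = 0$), but the guard documents the assumption.

## Second-order mean flow

Phase-averaging the $O(\epsilon^2)$ equations gives the steady streaming.
Averages of quadratic terms become conjugate pairs
($\langle ab\rangle = A\bar B + \bar A B$).  The mean transverse balance is
the averaged mass balance,
$$V_{20}(y) = -\chi\,(P_1\bar V_1 + \bar P_1 V_1) + D_1,$$
and the mean axial momentum reduces to $U_{20}'' = Re\,f(y)$ with

$$f = \frac{d}{dy}\bigl(U_1\bar V_1 + \bar U_1 V_1\bigr)
  + \lambda_1\Bigl\{4\alpha^2|U_1|^2 - 2\alpha^2(U_1\bar P_1 + \bar U_1 P_1)
  + 2i\alpha(V_1\bar U_1' - \bar V_1 U_1')
  + i\alpha(\bar V_1 P_1' - V_1\bar P_1')
  - (U_1'\bar P_1' + \bar U_1' P_1')\Bigr\},$$

where the braced block collects the quadratic (convected) parts of the UCM
operator applied to both the inertia and the pressure gradient; for the
linear variant it is absent (the linear operator contributes no mean
quadratic terms), though $\lambda_1$ still shapes the first-order field
through $\gamma$ and $\beta$.  Each brace term is a conjugate-symmetric
combination, so $f$ is real and (by the even/odd parity of the first-order
fields) even in $y$.  The formula was obtained by symbolically expanding the
full governing equations to $O(\epsilon^2)$ and phase-averaging; its residual
against that expansion is identically zero, and the implementation checks it
at run time against finite differences (for the Reynolds-stress term) and
against an independently coded pointwise formula (for the braced block).

**Integration conventions.** $U_{20} = Re\,E(y) + D_2y + D_3$ with
$E(y) = \int_0^y\!\!\int_0^s f$.  Both lower limits sit at $y = 0$: with $f$
even this is the unique choice making $E$ even, so the symmetric-channel
parity survives and $D_2 = 0$ emerges from the wall solve instead of being
assumed.  Any other lower limit would be absorbed by $D_2, D_3$ everywhere
*except* in the perturbation profile $G \propto E(y) - E(1)$, which would
acquire a spurious linear term.

**Wall conditions and $D_1 = 0$.** No-slip/no-penetration hold at the
*displaced* wall $y = \pm(1+\eta)$; Taylor transfer to the mean position
gives
$$U_{20}(\pm1) \pm \tfrac12(\bar U_1' + U_1')(\pm1) = 0,\qquad
  V_{20}(\pm1) = \mp\mathrm{Re}\,V_1'(\pm1).$$
The transverse transfer term is frequently dropped in this family of
problems because it vanishes identically for incompressible flow
($V_1'(\pm1) = i\alpha\chi P_1(\pm1) = 0$ at $\chi=0$); with compressibility
it does not, and keeping it is exactly what makes the integration constant
$D_1$ vanish — $D_1$ equals the mean mass flux through the wall, which must
be zero.  The package computes $D_1$ from this balance at $y=+1$, verifies
the $y=-1$ balance gives the same constant, and reports $\sim10^{-17}$ at
reference parameters.  Imposing the untransferred condition
$V_{20}(\pm1)=0$ literally would instead give $D_1 = -\chi\alpha\,
\mathrm{Im}\,P_1(1)$ ($\approx -0.103$ at $\alpha=0.5$, $Re=10$, $\chi=0.3$,
$\lambda_1=0.5$) and contradict the parity of $V_{20}$.

A structural consequence worth stating: $D_{wall} = U_{20}(1) =
-\mathrm{Re}\,U_1'(1)$ is fixed entirely by the first-order field, which is
variant-independent.  **The wall streaming velocity therefore cannot differ
between the linear and upper convected models**; the variants differ in the
interior profile (through $f$) and hence in $\langle u\rangle$ away from the
wall and in $\langle Q\rangle$, but never at the wall itself.  Claims of
opposite-signed wall streaming for the two variants at equal parameters are
incompatible with these boundary conditions; the acceptance-style trend
checks that encode such claims are retained in the test suite and fail, by
design, as a record of the discrepancy.

## Observables

* $G(y) = -\dfrac{200}{\alpha^2Re^2}\bigl(E(y)-E(1)\bigr)$ — the normalised
  mean velocity perturbation profile, with $G(1)=0$ by construction and no
  $\epsilon$ dependence.  The $200/(\alpha^2Re^2)$ normalisation keeps $G$
  order-one; the alternative reading $-200\,\alpha^2Re^2$ is selectable
  (`perturbation_G(..., scale = "literal")`) for sensitivity checks, and no
  test depends on the absolute scale — only on shape and sign.
* $\langle u\rangle = \epsilon^2U_{20}(y)$, $\quad\langle Q\rangle =
  \epsilon^2\int_0^1U_{20}\,dy$, $\quad D_{wall} = U_{20}(1)$.

Both $\langle u\rangle$ and $\langle Q\rangle$ scale exactly as
$\epsilon^2$ — the expansion is truncated at second order, so $\epsilon$
enters as a pure prefactor; the tests verify the quadratic scaling to
round-off.

## Numerical design

**Closed-form integration via exponential sums.**  Every first-order field
is a four-term exponential sum in $e^{\pm\nu y}, e^{\pm\beta y}$; every
product in $f$ is again a finite exponential sum.  The package therefore
carries $(c_j, \mu_j)$ term lists and computes $f$, $E(y)$, $E(1)$ and
$\int_0^1E$ in closed form: per term, $\iint e^{\mu y} =
(e^{\mu y}-1-\mu y)/\mu^2$, with a Taylor-series branch below $|\mu| = 0.5$
(error $<10^{-20}$ at the switch).  Terms are *anchored*,
$c\,e^{\mu(y-a)}$ with $a = \mathrm{sign}(\mathrm{Re}\,\mu)$, so no factor
ever overflows even for $|\beta|\sim10^4$; products of anchored terms remain
anchored with bounded coefficients.  This is what keeps the strong-elasticity
regime ($\lambda_1 = 10^4$, $Re = 10^4$, where $f$ oscillates with
wavenumber $\sim2\alpha\sqrt{\lambda_1Re}$) exactly integrable — adaptive
quadrature on such integrands is hopeless.  The adaptive-quadrature route
(`integrate_E()`, absolute tolerance $10^{-10}$) and a brute-force nested
Simpson integrator (`brute_force_double_integral()`) are retained and
cross-checked against the closed form in the tests.

**Imaginary residues.**  Mean quantities are assembled from conjugate pairs
in complex arithmetic and must come out real.  Their imaginary parts are
checked before being discarded, against a scale that includes the summed
term magnitudes (cancellation means round-off is relative to the terms, not
the result); a residue above $10^{-11}$ of that scale raises a consistency
error rather than being silently dropped.

**Collocation oracle.**  The first-order system is also solved directly as a
complex linear boundary-value problem: unknowns $(U_1, V_1, P_1)$ on
Chebyshev points, continuity collocated at every node, momentum rows at the
boundary replaced by the four wall conditions.  Collocation was chosen over
shooting because the $\beta$-mode makes the system stiff (wall layers of
width $1/|\beta|$) and shooting overflows.  The default resolution
$n \approx 1.4\kappa + 18\sqrt{\kappa} + 48$ (with $\kappa$ the largest mode
wavenumber) resolves both the wall layers and the bulk oscillation; the
error estimate compares against a doubled grid (whose node set contains the
coarse nodes), and an estimate above $10^3\times$ the requested tolerance
raises a convergence error naming the parameter point.

**Problem sizes.**  Tests run the oracle comparison over the
$3\times3\times3\times3$ grid $\alpha\in\{0.1,0.5,1\}$,
$Re\in\{10,100,10^4\}$, $\chi\in\{0.001,0.3,0.6\}$,
$\lambda_1\in\{0,0.5,5\}$ (81 collocation solves, resolutions up to
$n\approx700$), sweep checks use 40-point $\alpha$ grids for the moderate
regimes and a 400-point grid over $\alpha\in[0.002,0.2]$ for the
strong-elasticity regime, where the flow-rate oscillation scale is
$\Delta\alpha \approx 2\pi/\sqrt{\lambda_1Re} \approx 6\times10^{-4}$.

## Sweep recipes and their limits

`figure_recipe()` ships the parameter sets of the standard parametric
studies (relaxation-time and compressibility sweeps of $G$, $D_{wall}$,
$\langle u\rangle$, $\langle Q\rangle$).  Where a study's legend does not
fix the swept value list, the recipe documents a default chosen once: e.g.
the mean-velocity study uses $\lambda_1\in\{0,1,2,5\}$ because the
near-wall flow reversal of the convected model — a feature those profiles
are known for — first appears around $\lambda_1 = 5$ at $Re=10$,
$\chi=0.05$.

The trend checks in the acceptance tests record which qualitative behaviours
the model actually supports at those recipes:

* supported: $D_{wall}$ growing with $\chi$ (linear model); centerline $G$
  rising with $\lambda_1$ for the UCM; $|G(0)|$ larger for the linear model
  at small $\lambda_1$; flat Newtonian $G$ core at $Re=100$; near-wall UCM
  backflow at large $\lambda_1$; UCM flow rate falling with $\alpha$ beyond
  $\alpha\approx0.75$ at $Re=10^4$; oscillatory flow rate with negative UCM
  excursions at $\lambda_1=10^4$.
* not supported (checks intentionally left failing): any linear-vs-convected
  difference in $D_{wall}$ (see the structural argument above); opposite
  $\lambda_1$-trends of centerline $G$ between the variants (both rise);
  $\langle u\rangle$ rising with $\lambda_1$ at $Re=10$, $\chi=0.05$ (it
  falls for both variants until the large-$\lambda_1$ reversal); near
  variant-independence of $\langle Q\rangle$ at moderate $\lambda_1$ and
  $Re=10^4$ (the linear branch departs strongly — relaxation reshapes its
  first-order field, while the UCM's convected forcing largely compensates);
  strictly positive linear-model flow rate at $\lambda_1=10^4$ (sharp,
  weakly damped acoustic resonances drive excursions of both signs with
  amplitudes of order $10^2$).

## Known limitations

* Sinusoidal, symmetric wall motion only; no asymmetric channels or general
  waveforms.
* Truncation at $O(\epsilon^2)$ means no second-harmonic flow components and
  no amplitude saturation; results are meaningful for $\epsilon^2 \ll 1$.
* The strong-elasticity limit $\lambda_1\to\infty$ is elastically resonant;
  observables there are extremely sensitive to $\alpha$, and profile plots
  need grids finer than $\Delta\alpha\sim10^{-3}$ to be faithful.
* Dimensionless interface only; no SI parameter handling.
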