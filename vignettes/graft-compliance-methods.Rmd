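---
title: "Hyperelastic fitting and graft compliance simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperelastic fitting and graft compliance simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pugraft)
```

## The problem

Synthetic vascular grafts made from stiff polymers (Dacron, PTFE) suffer
from compliance mismatch: the graft dilates far less per unit pressure than
the native artery it replaces, which disturbs wall shear stress and is
implicated in graft failure. Segmented polyurethanes (PUs) built from
polycaprolactone diol, polyethylene glycol and pentaerythritol behave as
nearly incompressible rubber elastomers with moduli close to arterial
tissue, which makes them candidate graft materials — provided their
large-strain mechanics can be characterised and their compliance under
pulsatile pressure predicted from bench tensile data alone.

`pugraft` implements that desk pipeline: fit a hyperelastic constitutive
model to uniaxial tensile curves, derive network-level quantities and
goodness of fit, then drive a cylindrical tube of the fitted material with
a sinusoidal physiological pressure and report its dynamic compliance
across frequency and geometry sweeps.

## Constitutive model

The material model is the three-parameter Mooney–Rivlin strain-energy
density in the first two principal invariants of the right Cauchy–Green
tensor,

$$W = C_{10}(I_1 - 3) + C_{01}(I_2 - 3) + C_{11}(I_1 - 3)(I_2 - 3),$$

with incompressibility assumed ($I_3 = 1$), the conventional idealisation
for rubber-like solids. For uniaxial extension to stretch $\lambda$ the
principal stretches are $\lambda_1 = \lambda$,
$\lambda_2 = \lambda_3 = \lambda^{-1/2}$, so $I_1 = \lambda^2 + 2/\lambda$
and $I_2 = 1/\lambda^2 + 2\lambda$, and the axial Cauchy stress
$\sigma_1 = \lambda\, \partial W/\partial \lambda$ works out to

$$\sigma_1(\lambda) = 2C_{10}\left(\lambda^2 - \tfrac{1}{\lambda}\right)
 + 2C_{01}\left(\lambda - \tfrac{1}{\lambda^2}\right)
 + 6C_{11}\left(\lambda^3 - \lambda^2 - \lambda + \tfrac{1}{\lambda}
 + \tfrac{1}{\lambda^2} - \tfrac{1}{\lambda^3}\right).$$

Every bracket vanishes at $\lambda = 1$, so the undeformed stress is
exactly zero for any coefficients; the small-strain tangent modulus is
$6(C_{10} + C_{01})$. The test suite checks this expression against two
independent formulations — a central-difference evaluation of
$\lambda\,dW/d\lambda$ and the invariant-derivative closed form
$2(\lambda^2 - 1/\lambda)(W_1 + W_2/\lambda)$ — at random coefficients and
stretches.

**Interpretation of the coefficients.** $C_{10}$ carries the
rubber-elasticity meaning of network chain density via
$\nu = C_{10}/(RT)$; $C_{01}$ measures deviation from neo-Hookean
linearity; $C_{11}$ adds inflection to the stress–stretch curve
(stress-stiffening at large stretch). Three-parameter fits to strongly
nonlinear PU curves routinely return negative $C_{10}$ or $C_{01}$; no
sign constraint is imposed. Because a negative $C_{10}$ would give a
meaningless negative chain density, `crosslink_density()` uses
$|C_{10}|/(RT)$ — the magnitude convention reproduces the published
densities of the bundled reference materials at two significant figures
for three of the four compositions (the fourth, 47.5–47.5–5, computes to
0.31 kmol/m³ where 0.32 is printed, consistent with rounding of an
unprinted $C_{10}$ digit in the source table). $R$ is expressed as
8314 J kmol⁻¹ K⁻¹ so that with $C_{10}$ in Pa the density lands in
kmol/m³.

## Engineering → true measures

Instruments record engineering stress and strain. With incompressibility,
$\lambda = 1 + \epsilon_{Eng}$ and $\sigma = \lambda\,\sigma_{Eng}$ — the
cross-section shrinks by $1/\lambda$, so the true stress exceeds the
engineering stress under tension. The alternative reading
$\sigma = \sigma_{Eng}/\lambda$ would contradict volume conservation and
is not offered. Fitting always uses true stress versus stretch.

## Coefficient estimation

Although hyperelastic fitting is conventionally posed as nonlinear
regression, $\sigma_1$ is *linear* in $(C_{10}, C_{01}, C_{11})$. The
least-squares problem therefore has an exact global optimum, solved by QR
factorisation of the three basis functions — no initialisation, no
convergence ambiguity, and noiseless synthetic curves are recovered to
better than eight significant digits. A Levenberg–Marquardt path
(`method = "nonlinear"`, via minpack.lm) is retained purely as a
cross-check and is tested to agree with the linear solution to 1e−8.
Identifiability requires at least three distinct stretches; rank
deficiency raises an error rather than returning an arbitrary solution.

Goodness of fit is reported as RMSE (scale-dependent, MPa) and Lin's
concordance correlation coefficient

$$CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar{x} - \bar{y})^2},$$

with population ($1/n$) moments following Lin's original estimator. CCC
penalises departure from the 45° identity line, not just linear
association, so $|CCC| \le |r|$ always — a property-style test asserts
this on random series.

No Drucker-type stability constraint is applied during fitting: the
admissible fits this package targets can violate $C_{10} > 0$. Instead the
fitted `initial_slope` is reported, and the simulator independently
verifies that the stress–stretch curve is strictly increasing over the
stretch range it needs.

## Replicate averaging

Replicate specimens neither share strain sampling nor break at the same
elongation. Curves are linearly interpolated onto a uniform stretch grid
(default 200 points) spanning $[1, \min_k \max \lambda_k]$ — truncated to
the shortest replicate so no curve is extrapolated — then averaged
pointwise in true stress with a pointwise standard deviation. Averaging is
permutation-invariant and a single replicate returns its own interpolation
with zero sd. No smoothing or toe-region correction is applied.

Models built from averaged curves inherit the usual caveat that an average
curve is not the curve of an average specimen; the package fits whatever
replicate list it is given and the per-replicate path remains available.

## Graft simulation

The pressure waveform is the sinusoidal physiological model

$$P(t) = P_m\left(1 + \epsilon \sin(2\pi f t)\right), \qquad
P_m = \tfrac{1}{3}P_{max} + \tfrac{2}{3}P_{min}, \qquad
\epsilon = P_s / P_m,$$

with defaults $P_{max} = 180$, $P_{min} = 40$, $P_s = 10$ mmHg, giving
$P_m = 86.67$ mmHg. The frequency enters as $\sin(2\pi f t)$ with $f$ in
Hz so that one waveform period is one cardiac cycle; writing the argument
as $f t$ without the $2\pi$ would make a "1 Hz" waveform repeat every
$2\pi$ seconds, which is not a defensible reading of a frequency in hertz.

Wall stress uses the thick-wall circumferential estimate

$$\sigma_{\theta\theta} = P\,\frac{r_0^2}{(r_0+h)^2}
\left(1 + \frac{(r_0+h)^2}{r_0^2}\right)
= P\left(1 + \frac{r_0^2}{(r_0+h)^2}\right),$$

converted from mmHg to MPa with 1 mmHg = 1.33322 × 10⁻⁴ MPa. The stretch
at each time sample solves $\sigma_1(\lambda) = \sigma_{\theta\theta}$,
the radius is $r = r_0\lambda$, and the pointwise compliance between
consecutive samples is

$$C_i = \frac{r_{i+1} - r_i}{r_i\,(P_{i+1} - P_i)} \quad [\mathrm{mmHg}^{-1}].$$

Three consequences follow exactly from these equations and are asserted
by tests rather than merely claimed:

* **Periodicity.** The material law is elastic (time-independent), so the
  compliance series repeats with the pressure period.
* **Geometry invariance.** The bracketed stress factor depends on geometry
  only through $h/r_0$, so scaling $(r_0, h) \to (k r_0, k h)$ leaves
  stretch and compliance unchanged while radii scale by $k$ — the testable
  form of the claim that graft radius and thickness do not affect
  compliance behaviour.
* **Stiffness ordering.** A uniformly stiffer coefficient set inverts to
  smaller stretch excursions, hence pointwise lower compliance; among the
  bundled reference materials 45–45–10 (initial slope 9.7 MPa) lies below
  5–90–5 (1.0 MPa) everywhere.

## Numerical choices

* **Waveform sampling.** Pressure is evaluated at exact sample phases,
  $\sin(2\pi\,(i \bmod N)/N)$ with $N$ samples per cycle, not at
  accumulated floating-point times. The sampled waveform is then exactly
  periodic, cross-cycle samples are bit-identical, and only the $N$ unique
  pressure levels need a stretch inversion per sweep cell.
* **Stretch inversion.** Bracketed bisection on $[1, 3]$ iterated until
  the bracket collapses to adjacent doubles — deterministic, no tolerance
  knob, residual far below the 1e−10 MPa contract at physiological stress
  levels. Monotonicity of $\sigma_1$ on the bracket is checked by sampling
  first; non-monotone (unstable) materials raise a typed error naming the
  range. A target of exactly zero returns $\lambda = 1$ without iteration.
* **Compliance gaps.** The forward difference is undefined at pressure
  turning points; samples with $|\Delta P| < 10^{-6}$ mmHg become explicit
  `NA` gaps, never zeros or infinities, and summaries skip them.
* **Sweep defaults.** $f \in \{1, 1.5, 2\}$ Hz (resting to elevated heart
  rate), $r_0 \in \{1.5, 2, 3\}$ mm (small-calibre grafts), $h \in
  \{0.3, 0.4, 0.5\}$ mm (the cast-film specimen thickness range);
  256 samples/cycle over 3 cycles, with the first cycle excluded from
  summaries as a cheap guard even though an elastic model has no
  transient. All overridable in the run configuration.
* **Fitting.** QR rank tolerance 1e−10; inputs containing NaN raise a
  data error rather than being dropped silently.

## Synthetic data: what it emulates, what it does not

The generator forward-evaluates a known coefficient set on a uniform
stretch grid, converts to engineering stress ($\sigma_1/\lambda$), and
adds three stochastic layers that mirror how tensile replicates actually
vary:

* **Measurement noise** — additive Gaussian on the *engineering* stress
  (the recorded quantity), clipped at zero, default sd 0.02 MPa. No
  instrument noise figure exists for the motivating data; this default is
  an assumed magnitude (~1% of a typical PU ultimate strength) and is
  flagged as such.
* **Replicate jitter** — each replicate's coefficients are multiplied by
  independent unit-mean lognormal factors of a given CV (default 0.05).
  Multiplicative lognormal jitter keeps coefficient signs stable across
  replicates; additive jitter could flip a sign and change the character
  of the material. Unit mean keeps replicate averages centred on the
  truth.
* **Hydration softening** — absorbed water plasticises PU networks,
  shortening and softening tensile curves. Lacking a constitutive model
  for the effect, it is emulated as the minimal mechanism: one factor in
  (0, 1] (default 0.6) scaling all three coefficients in the hydrated
  state. By linearity of $\sigma_1$ in the coefficients this scales the
  whole curve uniformly.

Passing tests on synthetic data therefore demonstrate correctness of the
estimation and simulation machinery under the model's own assumptions.
They do not demonstrate that real PU curves follow a three-parameter
Mooney–Rivlin law (real curves include toe regions, stress-induced
crystallisation upturns beyond the fitted range, and viscoelastic rate
dependence the model ignores), nor that hydration acts as a uniform
scaling. The first point exactly (strain 0, stress 0) is recorded
noise-free, as instruments report the preloaded reference state.

## Problem sizes and determinism

Default study conditions: 5 replicates per material, 100 points per curve
to stretch 2.5; fitting on a 200-point averaged grid; sweeps of
3 × 3 × 3 cells at 256 samples/cycle × 3 cycles. The Monte-Carlo
assertions use 500 replicates (estimator unbiasedness) and 150 seeds
(replicate-average coverage). All randomness flows from a single run seed;
the pipeline derives one substream per material, and reruns with the same
configuration and seed are byte-identical.

## Known limitations

* Uniaxial data only: the coefficient set is not validated against planar
  or biaxial states, and the wall model is isotropic single-layer — no
  vessel anisotropy, no bilayer structure, no axial pre-stretch, no
  fluid–structure interaction.
* The wall response is purely elastic; creep, recovery and the
  strain-dependent dynamic moduli of real PUs are outside the constitutive
  model (the dynamic-moduli utility only converts oscillatory amplitudes
  and phase to storage/loss moduli; it does not predict them).
* Pointwise compliance and per-cycle summaries are both exported; which of
  the two a given published figure used is generally unstated, so absolute
  magnitudes should be compared with care.
* The crosslink-density magnitude convention is a documented choice, not a
  resolution of what sign a negative $C_{10}$ "means" physically.
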