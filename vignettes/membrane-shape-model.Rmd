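---
title: "A contour-dynamics model of protrusive cell shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A contour-dynamics model of protrusive cell shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcontour)
```

## The model

`cellcontour` simulates a one-dimensional cell membrane contour coupled to a
single conserved species of convex, curvature-sensing membrane protein
complexes (BAR/IMD-domain-type complexes that recruit actin nucleation
and/or adhesion).  Two geometries are supported: a closed, counterclockwise
contour representing the outline of a spread cell, and a periodic flat
segment in Monge representation `h(x)` (a piece of the cell edge, pinned by
a harmonic spring that stands in for the adhesion of the rest of the cell).

The free energy per membrane area element `dA = w ds` (with `w` the strip
thickness) contains

* a Helfrich curvature-mismatch term `(kappa/2) (H - Hbar * phi)^2`, where
  `phi` in [0, 1] is the fractional coverage and `Hbar < 0` the convex
  spontaneous curvature of the complexes;
* membrane tension `lam(L)`, reduced locally by adhesion, `- alpha * phi`
  (adhesion energy gain acts as a negative, coverage-proportional tension);
* a harmonic pinning term `(gamma/2) h^2` (flat geometry only);
* the mixing entropy of the complexes at saturation density `n_s`;
* bulk and surface (gradient) aggregation energies with direct binding
  strength `J_bind`; the gradient term uses the protein-scale length
  `l_g^2 = 1/n_s`, so no extra parameter is introduced.

Sign convention, fixed package-wide and testable: a counterclockwise circle
of radius `R` has curvature `H = -1/R`, so outward protrusions have `H < 0`
and match `Hbar < 0`.

**Forces.**  Normal forces are *exact gradients of the discrete free
energy* (hand-derived adjoints, implemented in compiled code).  This is a
deliberate design choice: the test suite checks every conservative force
against a central-difference variation of `free_energy()`, and with exact
discrete gradients that oracle holds to rounding error rather than to
discretization order.  The variational force of the tension term is
`lam_eff * H` with

```
lam_eff(L, phi) = lam * (1 + lam_nl * (exp(((L - L0)/L0) / u0) - 1)) - alpha * phi
```

which reduces to the bare `lam` at the initial length `L0`, is independent
of `L` when `lam_nl = 0`, and hardens on the relative-extension scale `u0`
(default 0.05).  This nonlinear hardening models the finite membrane-area
reservoir; it arrests protrusion growth and prevents the deep coverage
depletion that would otherwise kinetically trap the coarsening dynamics.
Strong adhesion at high coverage makes the local effective tension
negative — the adhesion protrusive force.  Two potential-density metric
forces are deliberately *absent* from the dynamics: the entropic
contour-expansion force (small compared to the others) and the analogous
bulk-aggregation metric force; the adhesion metric force is kept because it
is the adhesion protrusive term itself.  Active terms that cannot be derived
from the free energy are the actin push `A_actin * phi` along the outward
normal (mean-subtracted in the flat geometry to remove drift) and, for the
round geometry, a global area-preserving pressure
`-K_area * (A - A0)/A0` with preferred projected area `A0 = pi R0^2`.
Motion is overdamped with local friction: `v_n = f_total / xi`.

**Transport.**  The conserved coverage field moves along the contour with
four currents: curvature attraction `J_curv = Lambda kappa Hbar phi dH/ds`
(toward protrusive regions), the stabilising dispersion flux
`J_disp = -Lambda kappa Hbar^2 phi dphi/ds` (membrane resistance to
aggregation of curved proteins), the destabilising direct-aggregation flux
`J_agg = Lambda J_bind n_s phi (dphi/ds + l_g^2 d^3 phi/ds^3)`, and thermal
diffusion `J_diff = -D dphi/ds`.  `D` is kept as an independent diffusion
coefficient, as is conventional for this model family, rather than being
derived from `Lambda` by an Einstein relation.

The conservation law on the moving, stretching contour is realised in
finite-volume form: the per-cell mass `m_i = phi_i ds_i` is updated by
edge-current differences and the coverage is recovered on the post-move
metric.  This implements the covariant dilution term exactly and makes total
protein mass conservation a structural identity (observed drift over full
runs is at the 1e-13 level).  The advective currents (`J_curv`, `J_agg`)
carry the donor cell's density (first-order upwinding of the mobility
factor), which preserves positivity of the coverage; around a uniform state
the upwind correction is second order, so the linear stability is untouched.

## Linear stability

Linearising about the uniform state gives a 2x2 problem per wavevector
(flat) or per integer angular mode (round); both eigenvalue branches are
real for this model, one always damped.  The package implements the
continuum linearization of the same discrete functional
(`dispersion_flat()`, `dispersion_round()`), and the test suite
cross-checks the predicted growth rates against seeded-eigenmode runs of
the nonlinear simulator — the guard against transcription errors between
the two codes.  Two details are worth noting:

* the metric coupling of the uniform curvature mismatch contributes an
  extra effective tension `(kappa/2) (Hbar phi_bar)^2` to the flat
  dispersion;
* in the round geometry the `m = 1` mode is a rigid translation and its
  growth rate is zero *exactly* (the linearised curvature perturbation
  `(1 - m^2)/R^2` vanishes), which the tests assert at 1e-6 1/s.

Adhesion destabilises by lowering the mean effective tension
(`lam - alpha phi_bar`) while the curvature coupling between shape and
coverage closes the positive feedback; actin destabilises through its
direct coverage-to-force coupling.  `critical_boundary()` locates the onset
(`alpha_c` or `A_c`) by bisection on the maximal growth rate,
`classify_regime()` distinguishes type-II instability bands (bounded away
from `q = 0`) from type-I bands reaching zero wavevector (reachable here
through strong direct aggregation), and `most_unstable_mode()` returns
`q_max`, `omega_max` and `lambda_max = 2 pi / q_max`.

## Numerical scheme and parameters

Integration is explicit Euler for both shape and coverage, with an
automatic step bound (`stable_dt_bound()`) combining the bending (`ds^4`),
tension (`ds^2`), spring, and second/fourth-order transport stiffness
limits, each with its exact explicit-Euler constant, times a safety factor
(default 0.2 standalone; the run driver uses 0.35, well inside the
stability margin).  If a step would push the coverage outside [0, 1] the
step is retried at halved dt (recursively); with upwinded advection this
guard trips rarely.  The closed contour is re-discretized into
equal-arclength nodes (periodic cubic spline) whenever the edge-length
ratio exceeds 1.5 or after 2000 steps, with conservative piecewise-linear
density transfer; the package uses a 2000-step cadence rather than a very
frequent one to bound interpolation noise.

Units are micrometres, seconds and kBT.  Published values of this model
family fix `phi_bar = 0.1`, `n_s = 10 um^-2`, `kappa = 100 kBT`,
`Hbar = -10 um^-1`, `R0 = 3 um` and `lam_nl` in {0, 0.1, 1}.  The remaining
constants are package defaults chosen once for physical plausibility and so
that the model sits near its instability threshold with onset wavelengths
of one to a few micrometres and growth times of seconds to minutes, the
regime the model describes in cells:

| parameter | default | rationale |
|---|---|---|
| `xi` | 2000 kBT s/um^4 | membrane+cytosol drag; sets minute-scale shape dynamics |
| `D` | 0.02 um^2/s | slow diffusion of large membrane-bound complexes |
| `Lambda` | 0.002 um^4/(kBT s) | mobility of order `D/(kBT n_s)` |
| `lam` | 100 kBT/um^2 (~4e-7 N/m) | soft effective tension of a spread cell edge |
| `gamma` | 10 kBT/um^4 | pins the flat segment without affecting the unstable band |
| `J_bind` | 20 kBT | aggregation aids coarsening but leaves the passive uniform state stable |
| `K_area` | 2000 kBT/um^3 | percent-level area deviations under the active forces |
| `w` | 1 um | free thickness scale of the represented membrane strip |

With these defaults the critical adhesion strength is `alpha_c ~ 1.5e3`
kBT/um^2 (per unit coverage) and the critical actin coefficient is of the
same magnitude; the acceptance script recomputes both at run time.

The initial condition seeds i.i.d. uniform noise of maximal amplitude
`0.01 * phi_bar` on the coverage only (the shape starts exactly uniform),
mean-corrected so the mean coverage is exact; a localized Gaussian coverage
profile is available for polarized initial conditions.  All randomness is
confined to the seeded initial condition, so trajectories are
bit-reproducible given (seed, grid, parameters).

**Problem sizes.**  The simulations in the tests and the acceptance script
use node spacings of ~0.15 um (e.g. N = 128 on a 20 um flat segment, N = 51
on 8 um, N = 128 on the closed cell), about 12-20 nodes per unstable
wavelength — enough to resolve the linear band while keeping the explicit
scheme's `ds^4` step bound workable.  Domains of 5-10 um are used for runs
that must reach the single-protrusion steady state: they hold 3-5 initial
protrusions, so the full coalescence cascade completes in minutes of model
time.  Convergence-sensitive checks (growth rates vs the dispersion
relation, discrete-geometry accuracy) use finer grids (N = 256) over short
horizons.

## What the simulations reproduce

* **Spontaneous protrusions.**  Above onset, seeded noise grows fastest at
  `q_max`; the early protrusion count matches `L / lambda_max` and the
  early-time amplitude grows exponentially at `omega_max`.
* **Coalescence.**  Protrusions merge into progressively fewer features;
  the protrusion count is non-increasing after the growth stage.  The
  coalescence time `tau_c` (last persistent transition to a single feature)
  shortens with the fastest growth rate.  Close to onset (~1.3 x critical)
  it diverges, lying far above the `1/omega_max` law (the stall/dead-lock
  regime); a crossover plateau follows (~1.5-2.4 x critical, where fewer
  protrusions form because the fastest wavelength is long), and from ~2.4 x
  critical upward `tau_c` follows the `1/omega_max` law, which is what the
  scaling fit measures.  At very strong driving the last merge eventually
  becomes transport-limited (deep coverage depletion between features) and
  the law flattens again.
* **Adhesion vs actin morphologies.**  Adhesion-driven steady states are
  sharp tents (droplet-like contours) with the coverage peaked at the shape
  peak and the steady coverage tracking the curvature (`H ~ Hbar phi +
  const`, the balance of the curvature and dispersion currents); the
  net adhesion force does not cancel on a closed contour, so the cell
  drifts.  Actin-driven steady states are broad plateaus (fan shapes)
  punctuated by a single dip whose coverage is depleted, with two coverage
  peaks at the dip shoulders; the net actin force on the closed steady
  contour cancels.  On domains wide enough for the fan (>= 5 um) the dip
  hovers around the 10% counting threshold and the reported count flickers
  between 1 and 2; the monotone-coalescence scenario therefore uses a 4 um
  domain, where the single feature stays compact.
* **Combined forces (not reproduced).**  The published model family reports
  that added actin speeds up the coalescence of an adhesion-dominated
  pattern while added adhesion suppresses the coalescence of an
  actin-dominated one.  With this package's parameter calibration the
  orderings come out inverted or neutral across every admixture strength
  (0.1-0.8 x the secondary force's critical value) and domain we scanned:
  either admixture raises the fastest growth rate and deepens the coverage
  focusing, which in this reconstruction accelerates coarsening.  The
  corresponding acceptance test is implemented faithfully (dominant driver
  at the study strength plus a 0.2 x critical admixture, matched seeds) and
  is expected to fail; reproducing the orderings presumably requires the
  original, unavailable magnitudes of the mobility, diffusion and friction
  constants.
* **Crescent transition.**  With adhesion off and weak tension hardening
  (`lam_nl = 0.1`), increasing the actin coefficient first dents the
  circular steady state and then abruptly produces a crescent with
  essentially complete coverage depletion in the dip.  The crescent branch
  holds up to roughly 3 x the critical actin coefficient; at still stronger
  driving the steady dip broadens and shallows again, so scans probing the
  single abrupt transition stop at 3.2 x critical.

## Design choices and limitations

* The flat geometry keeps the linearised curvature `H = h_xx` in the
  bending term (with the full metric elsewhere), trading asymptotic
  accuracy at large slopes for robustness; forces are reported per unit
  projected area.  The closed contour uses signed Menger (circumscribed
  circle) curvature, exact on circles and second-order on smooth contours.
* The area-pressure normalisation is the dimensionless strain form
  `-K (A - A0)/A0`, making `K_area` independent of cell size.
* The friction `xi`, the mobility `Lambda` and the polymerization
  coefficient `A_actin` are constants: adhesion-dependent (stick-slip)
  friction, crowding-dependent mobility and force-dependent polymerization
  are out of scope, as are myosin contractility, stress fibers,
  microtubules, membrane-area topology changes, and 3-D protein
  reorientation.
* The synthetic initial conditions emulate a quiescent, uniform cell edge
  with molecular-noise-scale coverage fluctuations.  They do not emulate
  spatially correlated noise, persistent stochastic forcing, or protein
  turnover; passing tests therefore demonstrate the deterministic
  shape-feedback mechanism, not agreement with any particular measured
  cell.
* Steady state is declared when the relative change of the maximum
  amplitude over a trailing 5%-of-elapsed-time window falls below 1e-4
  with a constant protrusion count; near-critical runs can stall in
  long-lived multi-peak states (the dead-lock regime), which is reported
  as a flagged, undefined coalescence time rather than forced.
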