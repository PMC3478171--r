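---
title: "Bifurcation analysis of a two-population neocortex model with two delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bifurcation analysis of a two-population neocortex model with two delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`delaypop` analyses a lumped description of two coupled populations of
neocortical pyramidal cells, a continuous-time two-node Hopfield-type
network with two discrete delays:

$$
\dot x_i(t) \;=\; -x_i(t)\;-\;\alpha_1\,S(\beta_1 x_i(t-\tau_1))
\;+\;\alpha_2\,S(\beta_2 x_j(t-\tau_2)), \qquad j \neq i .
$$

Each population inhibits itself through its local interneurons with lag
$\tau_1$ and excites the other population with the longer axonal lag
$\tau_2$ ($\tau_2 > \tau_1 > 0$). Time is non-dimensionalized by the
activity decay rate, so all seven parameters are dimensionless:

| parameter | meaning | default |
|---|---|---|
| `alpha1` | inhibitory coupling gain | 0.069 |
| `alpha2` | excitatory coupling gain (principal bifurcation parameter) | varies; preset 0.55 |
| `beta1`, `beta2` | activation slopes (inhibitory / excitatory) | 2, 1.2 |
| `tau1`, `tau2` | delays (feedback inhibition / feedforward excitation) | 11.6, 20.3 |
| `a` | activation inflection | 1 |

The activation is the shifted tanh
$S(x;a) = (\tanh(x-a)+\tanh(a))\cosh^2(a)$, normalized so $S(0)=0$ and
$S'(0)=1$. It is deliberately *not* odd: synaptic activation saturates
more sharply than deactivation. Its derivatives up to third order are
coded in closed form so that the Hopf normal form below carries no
differentiation noise.

Identical parameters for the two populations make the system
equivariant under the swap $\xi:(x_1,x_2)\mapsto(x_2,x_1)$. That single
symmetry organises everything that follows: equilibria are necessarily
symmetric, the linearization factorizes, and periodic solutions come in
an in-phase family ($x_1\equiv x_2$) and an anti-phase family
($x_1(t)=x_2(t+T/2)$).

The reported default parameter values follow the numerical study this
package reproduces. One of that study's statements of the slopes is
internally inconsistent (it can be read as $\beta_1 = 2\beta_2 = 1.2$);
we use $\beta_1=2$, $\beta_2=1.2$ throughout, the reading under which
the transcritical point of the trivial branch lands at
$(1+\alpha_1\beta_1)/\beta_2 = 0.948$, consistent with the printed
bifurcation table.

The scientific interest of the model is epileptogenesis as
multistability: in a window of coupling parameters, two steady states
(a quiescent and a saturated one) coexist with two large-amplitude
periodic solutions, so a transient perturbation can switch the tissue
into seizure-like oscillation without any parameter change.

## Equilibria and their continuation

Monotonicity of $S$ forces every fixed point onto the diagonal, so
equilibria solve the scalar equation
$g(x) = -x-\alpha_1 S(\beta_1 x)+\alpha_2 S(\beta_2 x)=0$.
`find_equilibria()` brackets sign changes on a grid (default
$[-2,5]$ at resolution 2000, covering every regime reachable with the
shipped presets) and polishes them below $10^{-12}$ residual; the
inverse-activation self-consistency map is kept as an independent
cross-check, not as the solver, because it degenerates at the fold.

For branch continuation in `alpha2` at fixed `alpha1` we do **not** use
pseudo-arclength stepping: since $x\neq 0$ implies
$\alpha_2(x) = (x+\alpha_1 S(\beta_1 x))/S(\beta_2 x)$, the nontrivial
branch admits an exact parameterization by its activity level $x^*$.
Continuation in $x^*$ traverses the fold with no step-size control and
no corrector failures, and event refinement becomes one-dimensional
bisection; we considered the generic arclength machinery strictly
inferior here and use the closed form. The trivial branch is handled
exactly: gains are linear in the couplings and the transcritical point
is $(1+\alpha_1\beta_1)/\beta_2$ in closed form.

## Linear stability: a factorized transcendental problem

At a symmetric equilibrium with gains
$k_1=\alpha_1\beta_1 S'(\beta_1 x^*)$,
$k_2=\alpha_2\beta_2 S'(\beta_2 x^*)$ the characteristic determinant
factorizes,

$$
\Delta_\pm(\lambda)=\lambda+1+k_1e^{-\lambda\tau_1}\pm k_2e^{-\lambda\tau_2},
$$

with minus-factor roots carrying symmetric eigenmodes and plus-factor
roots antisymmetric ones. Three numerical devices share the work:

* **Root location** (`rightmost_roots()`): Chebyshev pseudospectral
  collocation of the scalar delay operator on $[-\tau_2,0]$ (order
  $N=64$) supplies eigenvalue estimates that a damped Newton iteration
  polishes on the exact factor, so reported roots have residuals below
  $10^{-13}$ and no discretization bias.
* **Counting** (`count_unstable_roots()`): an argument-principle
  winding integral over the boundary of a right-half-plane disk. With
  delays near 20 the unstable roots pile up in a strip
  $\operatorname{Re}\lambda \lesssim 0.05$ (the a-priori bound
  $|k_1|+|k_2|\ge e^{\rho\tau_1}\sqrt{(1+\rho)^2+\omega^2}$ forces
  this), where eigenvalue-based location can skip members; the winding
  count cannot, so it is the arbiter of stability along branches and
  the completeness certificate for the root finder. When the two
  disagree, Newton re-seeding along the strip reconciles them; a root
  sitting on the imaginary axis makes both counts ambiguous by its own
  multiplicity and only a residual mismatch raises an error.
* **Analytic tests**: the sufficient square $|k_1|+|k_2|<1$ and the
  frequency cap ($|k_1|+|k_2|<\sqrt{1+\omega_0^2}$ excludes imaginary
  roots at $|\omega|\ge\omega_0$), which bounds every frequency scan.

## The stability chart and its boundary

Purely imaginary roots $\pm i\omega$ of each factor form explicit
curves $h_\pm(\omega)$ in the $(k_1,k_2)$ plane (a $2\times2$ linear
solve; branches are separated by asymptotes at
$\omega = n\pi/(\tau_2-\tau_1)$ and `hopf_curve()` refuses evaluation
within $10^{-10}$ of one). Zero roots live on the lines
$1+k_1\pm k_2=0$; with positive gains only the minus line is
reachable — there are no symmetry-breaking steady-state bifurcations.
The degenerate case $\omega=-\tan\omega\tau_1=-\tan\omega\tau_2$, which
would replace a curve point by a whole line, is scanned for explicitly
and is empty for the delivered delays; near-misses are reported with
residuals.

`stability_region()` assembles the first-quadrant boundary by scanning
the curves below a frequency cap justified by the fast-root exclusion
bound above, then Newton-refining three events: the fold-Hopf vertex ZH where $h_+$
crosses $k_2=1+k_1$, the Hopf-Hopf vertex HH where $h_+$ meets $h_-$,
and the exit of $h_-$ through the $k_1$ axis. For
$\tau_1=11.6,\ \tau_2=20.3$ the boundary is: fold segment to
ZH $(0.008, 1.008)$, a short $h_+$ arc over
$\Omega_S(h_+)\approx(0.148,0.150)$ to HH $(0.056,0.995)$, then the
$h_-$ arc over $\Omega_S(h_-)\approx(0.250,0.294)$ down to the axis.
Every assembled boundary point is spectrally verifiable (neutral root
within $10^{-6}$; interior samples strictly stable) and the test suite
does so. At the trivial equilibrium $S'(0)=1$ makes the chart map
linearly to the coupling plane, $\alpha_i = k_i/\beta_i$, which is how
the Hopf-Hopf and transcritical-Hopf points are reported in
$(\alpha_1,\alpha_2)$.

`count_hopf_crossings()` counts transversal intersections of a branch's
gain-plane image with the *full* $h_\pm$ curve set as changes of the
per-factor unstable-root count (each Hopf passage changes it by two;
steady-state passages, by one, are tallied separately). The headline
count of 18 crossings for the nontrivial branch at $\alpha_1=0.069$ is
obtained on the closed unstable segment, i.e. including the two
boundary crossings at which the branch loses and regains stability.

## Hopf criticality and the generalized Hopf point

For symmetric-factor Hopf bifurcations of the origin the cubic
normal-form coefficient $c_1$ is evaluated in closed form from
$S''(0)$, $S'''(0)$, the normalization scalar
$q_0 = 1/\bigl(2(1-k_1\tau_1e^{-i\omega\tau_1}
+k_2\tau_2e^{-i\omega\tau_2})\bigr)$ and the resonant denominators
$\Delta(0)$ and $\Delta(2i\omega)$ (both guarded against near-vanishing,
which would signal a nearby transcritical point or 1:2 resonance).
Because the pairing convention ($q^T$ versus a conjugate pairing) is a
classic source of sign errors, the same coefficient is implemented a
second time (`method = "multilinear"`) directly from the generic
second- and third-order multilinear forms acting on exponential
histories with numerically inverted characteristic matrices; the two
routes agree to $10^{-8}$ in the tests, which settles the conjugation
question empirically.

The sign rule adopted is: supercritical $\iff \operatorname{Re}c_1<0$.
It is validated dynamically, not typographically: crossing the boundary
radially at $\omega=0.26$ (where $\operatorname{Re}c_1<0$) the
simulated model shows decay below threshold and a small stable orbit
above it whose amplitude scales like the square root of the parameter
excess. Along the symmetric arc `find_generalized_hopf()` bisects
$\operatorname{Re}c_1$ to its zero at $\omega\approx0.281$,
$k\approx(0.491,0.614)$ — the generalized Hopf (Bautin) point at which
the orbits bifurcating from the origin's Hopf change from stable to
unstable at onset.

## Simulation and attractor classification

`integrate_dde()` wraps `deSolve::dede` (method of steps with the
solver's interpolated past) at tolerances `rtol = 1e-8`,
`atol = 1e-10`. Two guards matter in practice: once the state decays
below $10^{-30}$ the derivative is frozen (pure exponential decay to
the origin otherwise underflows the error weights around
$t\sim3000$), and an early solver stop with a tiny final state is
padded as converged-to-equilibrium.

`classify_attractor()` labels the post-transient dynamics as trivial or
nontrivial steady state, symmetric (in-phase) cycle, asymmetric
(anti-phase) cycle, or unclassified. The period comes from the
autocorrelation peak with parabolic refinement; symmetry from the
in-phase residual $\max|x_1-x_2|$ and the anti-phase residual
$\max|x_1(t)-x_2(t+T/2)|$, both relative to orbit amplitude. Defaults
are a 5000-unit horizon with a 4000-unit transient: at the multistable
reference point the transversal contraction onto the in-phase cycle is
only $|\mu|\approx0.96$ per ~21-unit period, so about 180 periods are
needed before the in-phase residual clears the $10^{-3}$ class
threshold — shorter transients misclassify a genuinely symmetric
attractor. For simulated anti-phase orbits the class threshold is 0.02
(the collocation-corrected orbit, not the simulation, carries the
strict $10^{-4}$ anti-phase certificate).

With the four shipped history presets at $\alpha_2=0.55$ the four
coexisting attractors are recovered:

```{r}
library(delaypop)
p <- pop_model_preset()
sapply(c("A", "B", "C", "D"), function(nm)
  classify_attractor(integrate_dde(p, history_preset(nm)))$class)
```

## Periodic orbits: collocation, Floquet multipliers, continuation

Periodic solutions are represented on the unit phase circle by
piecewise Lagrange polynomials (default 40 uniform mesh intervals,
degree 4) collocated at Gauss points, with the period an unknown and
delayed phases $s-\tau/T$ wrapped by as many whole periods as needed
($\tau_2/T$ ranges roughly from 0.5 to 1 on the branches of interest).
An integral phase condition against the previous profile's derivative
removes the translation degeneracy. The Newton corrector uses an
analytic Jacobian in the profile and central differences for the
period and parameter columns. In-phase orbits are corrected inside the
invariant diagonal subspace, where the dynamics reduce to a scalar
delay equation — exact, and half the cost; anti-phase orbits use the
full planar problem.

Floquet multipliers come from the monodromy map of the variational
equation over one period, discretized on the same collocation
structure: the linear solve expresses the solution on $(0,1]$ in terms
of the history segment, and the segment-to-segment map's eigenvalues
are the multipliers. For symmetric orbits the variational problem
decouples into a symmetric and an antisymmetric scalar factor, so each
multiplier carries its symmetry label — an antisymmetric-factor
multiplier leaving through $-1$ spawns anti-phase double-period
orbits. The trivial multiplier is reproduced to ~$10^{-5}$ at the
default mesh (and is monitored as a resolution diagnostic);
double-period planar orbits are corrected at 64 intervals to keep it
below $10^{-4}$.

`continue_cycles()` advances the branch by pseudo-arclength with a
weighted metric (parameter weighted up so parameter folds are resolved),
detects period doubling (a real multiplier crossing $-1$, per factor),
folds of cycles (parameter-tangent reversal) and torus bifurcations
(complex pair crossing the unit circle), and refines each by bisection
in arclength to $5\times10^{-5}$ in `alpha2`. Termination is by
parameter range, amplitude collapse (closure in a Hopf point — also
detected as a steadily shrinking orbit below amplitude 0.1), or a
revisit of a previously computed point (closed loop); the torus event
near the branch start is detected but, being away from any stable
window, not continued. Starting at a Hopf point uses a fixed-amplitude
constraint with the parameter released, which cannot collapse onto the
equilibrium.

On the reference branch born at the origin's Hopf
($\alpha_2 = 0.771$), this machinery recovers the event sequence
(torus point, first period doubling, fold of cycles near 0.462, the
period doubling near 0.465 that opens the stable window, its closing
counterpart near 0.596, a second fold near 0.615 and a further
doubling near 0.522 before closure in the second Hopf), and the stable
window it brackets agrees with the window where direct simulation
finds the in-phase attractor.

## Problem sizes and tolerances

Defaults were chosen once for the delivered study conditions: branch
sampling 600 points for event tables (5000 for the crossing count,
whose events are refined until the tally stabilizes under grid
doubling); collocation mesh $40\times4$ (64 intervals for
double-period planar orbits); pseudospectral order 64, doubled for
verification; Newton/event tolerances as quoted above. The acceptance
script states each size it uses alongside the quantity it reports.

## Known limitations

* Two-parameter continuation of *cycle* bifurcations (period-doubling,
  fold-of-cycle and torus curves, their codimension-two points) and
  homoclinic branches are out of scope; of the codimension-two points
  only the equilibrium-borne ones (Hopf-Hopf, transcritical-Hopf,
  generalized Hopf, fold-Hopf) are located.
* The stability region is certified only as *a* stability region: the
  package verifies the computed boundary spectrally but does not prove
  no disjoint stable island exists elsewhere in the gain plane.
* The branch emerging from the first period doubling (anti-phase
  double-period orbits) is validated through simulation and one-point
  correction rather than continued end to end.
* Event parameters inherit the collocation resolution; at the default
  mesh they are reproducible to about $10^{-4}$ in `alpha2`, which is
  finer than the three decimals at which results are reported.
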