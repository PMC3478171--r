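# delaypop

Bifurcation analysis of a two-population neural mass model of neocortex
with two delays.

## The problem

Epileptic seizures in lumped (neural mass) models appear as
large-amplitude oscillations, and a tissue is epileptogenic when such
oscillations *coexist* with normal steady activity, so that a transient
perturbation — not a parameter change — can trigger a seizure.
`delaypop` is a toolbox for mapping out exactly this structure in a
minimal model of two mutually excitatory populations of neocortical
pyramidal cells with delayed local inhibition:

$$
\dot x_i(t) = -x_i(t) - \alpha_1 S(\beta_1 x_i(t-\tau_1))
              + \alpha_2 S(\beta_2 x_j(t-\tau_2)), \qquad j \neq i,
$$

with the shifted tanh activation
$S(x;a) = (\tanh(x-a)+\tanh(a))\cosh^2 a$ (so $S(0)=0$, $S'(0)=1$),
inhibitory delay $\tau_1$, excitatory delay $\tau_2 > \tau_1$, and
coupling gains $\alpha_1$ (inhibition) and $\alpha_2$ (excitation) as
the bifurcation parameters. The swap symmetry
$(x_1,x_2)\mapsto(x_2,x_1)$ makes all equilibria symmetric and splits
the characteristic equation of any equilibrium into two scalar
transcendental factors
$\Delta_\pm(\lambda)=\lambda+1+k_1e^{-\lambda\tau_1}\pm k_2e^{-\lambda\tau_2}$
in the linearization gains $(k_1,k_2)$.

The package provides, for audiences in computational neuroscience and
delay-equation dynamics:

* equilibria and their continuation with fold / branch-point / Hopf
  detection (`find_equilibria`, `equilibrium_branch`);
* rightmost characteristic roots, argument-principle unstable-root
  counts, and the analytic stability tests (`rightmost_roots`,
  `count_unstable_roots`, `sufficient_stability`, `frequency_bound`);
* the Hopf curves $h_\pm(\omega)$, the assembled stability region in
  the gain plane with its fold-Hopf and Hopf-Hopf vertices, and the
  crossing census of equilibrium branches (`hopf_curve`,
  `stability_region`, `count_hopf_crossings`);
* the first Lyapunov coefficient and generalized Hopf point for Hopf
  bifurcations of the origin, with an independent multilinear
  cross-route (`first_lyapunov`, `find_generalized_hopf`);
* delay-equation simulation and attractor classification
  (`integrate_dde`, `classify_attractor`, `history_preset`);
* collocation-based continuation of periodic orbits with Floquet
  multipliers and period-doubling / fold-of-cycles / torus event
  detection (`correct_cycle`, `floquet_multipliers`,
  `continue_cycles`, `cycle_table`).

## Worked example

The reference configuration (`alpha1 = 0.069`, slopes 2 and 1.2,
delays 11.6 and 20.3, `alpha2 = 0.55`) sits in the multistable window:

```r
library(delaypop)
p <- pop_model_preset()
find_equilibria(p)
#>          x_star          k1        k2 stable
#> 1 -3.998871e-17 0.138000000 0.6600000   TRUE
#> 2  9.849957e-01 0.144398731 1.5206005  FALSE
#> 3  1.768723e+00 0.008115327 0.5444522   TRUE
```

Three symmetric equilibria: the stable origin (quiescence), an unstable
middle state, and a stable high-activity state (saturation). The `k1`,
`k2` columns are the linearization gains, the coordinates of the
stability chart:

```r
stability_region(11.6, 20.3)
#> Stability region of a symmetric equilibrium in the (k1, k2) plane
#>   delays: tau1 = 11.6, tau2 = 20.3
#>   Omega_S(h+) = (0.148, 0.150)
#>   Omega_S(h-) = (0.250, 0.294)
#>   ZH vertex at k = (0.008, 1.008), omega = 0.148
#>   HH vertex at k = (0.056, 0.995), omegas = (0.150, 0.294)
```

The region's boundary is a fold line plus two Hopf arcs; its vertices
are a fold-Hopf (ZH) and a Hopf-Hopf (HH) point, and the frequency
windows say which oscillation frequencies destabilize the tissue.
Raising excitation moves the origin's gains vertically; it leaves the
region — i.e. quiescence is lost through a Hopf bifurcation — at

```r
str(origin_hopf(p))
#> List of 4
#>  $ alpha2: num 0.771
#>  $ omega : num 0.292
#>  $ k1    : num 0.138
#>  $ k2    : num 0.925
```

so for `alpha2` just below 0.771 the quiescent state is still stable
while (as the equilibrium table above shows) the saturated state and —
as simulation confirms — two periodic attractors coexist with it:

```r
classify_attractor(integrate_dde(p, history_preset("C")))$class
#> [1] "symmetric_cycle"
```

The four shipped history presets `"A"`–`"D"` select, at these exact
parameters, the four coexisting attractors: trivial steady state,
nontrivial steady state, in-phase (symmetric) cycle, and anti-phase
(asymmetric) cycle — the multistability that models an epileptogenic
regime.

A command-line wrapper over the same machinery is installed at
`inst/cli/delaypop.R`:

```sh
Rscript inst/cli/delaypop.R region --out-dir out
Rscript inst/cli/delaypop.R simulate --preset C --alpha2 0.55 --out-dir out
Rscript inst/cli/delaypop.R table2-equilibrium --out-dir out
```

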