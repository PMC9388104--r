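---
title: "Bridging scales in mass-conserving membrane-bulk pattern formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging scales in mass-conserving membrane-bulk pattern formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(minscale)
```

## The model and the multiscale question

The reconstituted MinD/MinE system self-organizes into membrane patterns --
traveling waves, standing waves, and spatiotemporal chaos -- whose type is
controlled by the local bulk height and the local total protein densities.
`minscale` implements the skeleton model of that system: three cytosolic
fields (MinD-ATP, MinD-ADP, MinE) diffusing in a bulk of height $H$ with
nucleotide exchange $\lambda$ converting MinD-ADP back to MinD-ATP, and two
membrane fields (MinD, MinDE complexes) with mass-action kinetics

$$r_{D,on} = (k_D + k_{dD}\, m_d)\, c_{DT}, \qquad
  r_{E,on} = k_{dE}\, m_d\, c_E, \qquad
  r_{DE,off} = k_{de}\, m_{de},$$

coupled through reactive boundary fluxes at $z = 0$. Internally the bulk is
described in the transformed variables $(c_D, c_{DD}, c_E)$ with
$c_D = c_{DD} + c_{DT}$, in which the three bulk equations decouple (only
$c_{DD}$ carries the exchange term). In these variables the boundary flux
vector into the bulk is $(r_{DE,off} - r_{D,on},\; r_{DE,off},\;
r_{DE,off} - r_{E,on})$; note the first component, which is forced by mass
conservation at the interface and by the steady state (where only the
MinD-ADP component survives) -- see `?boundary_fluxes` for why a
superficially different sign convention for that component cannot be
consistent. Units are micrometres and seconds throughout; no unit
abstraction is provided.

Total MinD and MinE are conserved. In a wedge-shaped domain, where
$H(x)$ ramps linearly, the conserved densities redistribute slowly between
slices of different height while patterns form quickly within slices. The
package's purpose is to connect those scales: per-slice linear theory
(steady states and dispersion relations), a pattern-type classifier built
on the commensurability of the unstable band, a closed one-dimensional
dynamics for the slow mass redistribution, a two-dimensional nonlinear
simulator for validation, and a second worked instance of the same logic
(a parametrically driven Ginzburg-Landau equation coupled to a conserved
density).

## Homogeneous steady states of a slice

For a slice of height $H$ with totals $(n_D, n_E)$ the stationarity
conditions reduce exactly to one scalar equation. Given the membrane MinD
density $m_d$: the MinE balance gives $m_{de}$ in closed form, the two mass
constraints give the contact values $c_{D0}$ and $c_{E0}$, and the
steady-flux relation $\phi = \sqrt{D_c \lambda}\,
\tanh\!\big(\sqrt{\lambda/D_c}\, H\big)\, c_{DD0}$ gives $c_{DD0}$. The
remaining condition (MinD attachment balance) is a smooth scalar function
of $m_d$ that is positive at $m_d = 0$ and negative at the admissible upper
bound, so `solve_hss()` brackets every root with a dense scan and refines
with `uniroot()` to machine precision. This replaces a five-dimensional
Newton iteration by construction rather than by convergence luck; branch
counts of one or three arise naturally, and the analytic corners (no MinD:
everything cytosolic; no MinE: no detachment pathway, all MinD on the
membrane) are handled exactly. `hss_continuation()` tracks branch
identities along parameter paths and brackets saddle-node folds.

## Dispersion relations

Lateral perturbations $\propto e^{\sigma t + i q y}$ of a slice steady
state decay vertically as $\cosh(k_j (z - H))$ with $k_j^2 = q^2 +
(\sigma + \lambda_j)/D_c$. Substituting this ansatz into the linearized
membrane equations and reactive boundary conditions yields a $5\times 5$
characteristic matrix whose determinant root condition is the exact
dispersion relation; the matrix depends on $k_j$ only through
$k_j \tanh(k_j H)$, which is even in $k_j$, so the square-root branch
cancels (asserted by construction through a series-stabilized
implementation of $k\tanh(kH)$ near $k = 0$).

Transcendental determinants have spurious stationary points, so root
finding is seeded physically: the same linear operator is discretized in
$z$ by Chebyshev collocation (boundary conditions eliminated exactly), and
its leading eigenvalues seed a damped complex Newton iteration on the
row-scaled determinant. At coarse resolution the collocation operator is
the seed generator; at fine resolution it is an independent cross-check,
and the suite requires agreement to $10^{-4}$ relative across parameter
draws (collocation converges spectrally, so a few dozen nodes already sit
near machine precision; uniform second-order finite differences at the
same node count would not reach that tolerance for deep slices).
`dispersion_curve()` then traces $\sigma(q)$ by continuation in $q$,
refines the fastest-growing mode $q^*$ parabolically, brackets the right
band edge $q_{\max}$ by bisection, and reports the mode ratio
$q_{\max}/q^*$. At $q = 0$ the two conserved masses force a double root at
$\sigma = 0$; the suite checks it by a rank test.

Two structural features of this model family are worth knowing when
interpreting results. First, at the canonical densities the lateral
instability exists only for bulk heights above roughly $25\,\mu m$;
thinner slices destabilize only once mass redistribution raises their
local MinE share. The often-quoted picture of patterns at low height
therefore refers to dynamically shifted local densities, not to the global
averages. Second, for deep slices the leading mode remains unstable as
$q \to 0$ (a local oscillatory mode, distinct from the neutral mass
modes), so there the unstable band extends from zero to $q_{\max}$.

## The commensurability classifier

The empirical commensurability criterion maps the mode ratio to the fully
developed pattern: no unstable band $\to$ locally stable; ratio below 2
$\to$ spatiotemporal chaos; above 2 $\to$ ordered waves, standing close to
the threshold and traveling beyond it. There is no sharp standing/traveling
boundary, so the default `r_TW = 2.5` is an explicit design choice exposed
in `classify_ratio()`, and the continuous ratio always travels alongside
the class. `regional_kymograph()` applies the chain
slice totals $\to$ steady state $\to$ dispersion relation $\to$ class to
every cell of an $(x, t)$ grid, interpolates the critical front
$x_{crit}(t)$ where the ratio crosses 2 (all crossings are reported; the
primary one separates the largest contiguous sub- and super-threshold
regions), and caches slice solutions keyed by rounded $(H, n_D, n_E)$.

## Reduced large-scale dynamics

Averaging over slices closes the slow dynamics of the totals,
$$\partial_t n_i = \frac{1}{H(x)} \partial_x\!\big(H(x)\, D_c\,
  \partial_x c_i\big),$$
with the cytosol concentrations slaved to the local slice equilibria
$c_i^*(H, n_D, n_E)$ (at a steady state $c_D$ and $c_E$ are vertically
uniform, so the contact value is used). Membrane diffusion is three
orders of magnitude slower than bulk diffusion and is neglected. Because
slice equilibria fold, $c_i^*$ can jump; the dynamics are regularized by
auxiliary cytosol fields that relax toward $c_i^*$ at rate $\kappa$
(default $1\,s^{-1}$: fast against the $10^3$--$10^4\,s$ redistribution
timescale, slow against nothing it needs to resolve) *and diffuse with the
same height-weighted operator*. The diffusion term in the auxiliary
dynamics is a deliberate reading of the regularization with a
well-posedness rationale: wherever slices are laterally unstable the slope
matrix $\partial c^*/\partial n$ has an eigenvalue with negative real part
-- this is precisely the physical mass-redistribution instability -- and
pointwise relaxation alone would let grid-scale perturbations grow at a
rate $\sim \sqrt{\kappa D_c |S|}\, q$, unbounded in wavenumber. With the
diffusion term the growth saturates at $\kappa |S|$ while the large-scale
limit (effective diffusivity $D_c\, \partial c^*/\partial n$) is
unchanged. The suite verifies that doubling $\kappa$ changes the final
wedge profiles by well under one percent.

Branch selection on folds is continuation in time: each cell tracks its
membrane density with a warm-started Newton iteration, frozen across the
stages of a step, and re-scans all branches (adopting the one nearest its
relaxed cytosol state) only when its branch disappears. This is
deliberately hysteretic, matching the subcritical character of the
underlying patterns. A pure state-based selection (nearest branch at every
evaluation) was tried and rejected: cells near a fold then rattle between
branches and the right-hand side becomes effectively discontinuous.

The spatial scheme is a cell-centered finite volume with face-evaluated
heights (200 cells for the 500-um wedge by default) whose flux form makes
the two wedge masses linear invariants; time stepping is a fixed-step
third-order strong-stability-preserving Runge-Kutta in increment form
(one small increment added to the state per step keeps the conservation
drift at the random-walk round-off level, about $10^{-15}$ relative over
$10^6$ steps, where repeated convex recombinations of the state would
accumulate a biased drift two orders larger). The default step
$0.02\,s$ sits a third below the diffusive stability limit of the default
grid. Error-controlled adaptive integrators (two were tried) stall in the
laterally unstable regions, where the closure generates bounded
grid-scale structure that is physically meaningful only in aggregate; a
fixed step marches through it robustly. In those regions the reduced
model should be read as a transport model for the slowly varying totals,
not as a resolved simulation of the local patterns.

The canonical initial state is uniform totals (proteins uniformly
distributed), with the auxiliary fields on the steady-state branch
continued along the wedge axis.

## The slice simulator

`simulate_slice()` integrates the full nonlinear model in a rectangular
$(y, z)$ slice: finite volumes on a sinh-stretched vertical grid (refined
toward the membrane boundary layer $\sqrt{D_c/\lambda} \approx 3.2\,\mu
m$), backward-Euler diffusion split by direction, and the interface
kinetics solved *monolithically with the vertical diffusion* each step: a
five-variable Newton per column couples the membrane update to the
column's unit-flux response. Two details matter quantitatively:

* splitting the interface kinetics from vertical diffusion is not an
  option, because the bottom cell equilibrates with its neighbour on a
  timescale $h_1^2/D_c$ far below any reasonable step -- the split scheme
  misrepresents the exchange and was measured to bias growth rates by a
  factor of several;
* the kinetics act on the contact concentrations $c(z=0)$, not on the
  bottom-cell averages. Substituting the flux boundary condition
  eliminates the contact values in closed form and appears as
  exchange-resistance denominators $(1 + \text{rate}\cdot z_{c1}/D_c)$ in
  the rates; without this correction the effective attachment rates carry
  an $O(z_{c1})$ bias that converges away only slowly with grid
  refinement.

Because both the membrane update and the boundary flux use the same rate
evaluations, the two conserved totals drift only at round-off; the
stationary initial state is constructed against the discrete vertical
operator (its flux coefficient replaces the $\tanh$ closed form), so an
unperturbed run is a fixed point of the scheme to $10^{-12}$. The
default time step $0.01\,s$ is an accuracy choice; the suite carries a
refinement test showing measured growth rates move by under one percent
when both grid spacings are halved.

Measured growth of a seeded lateral mode matches the dispersion
prediction at the fraction-of-a-percent level -- but only at very small
seed amplitudes ($10^{-5}$ relative). The patterns are subcritical:
already at a fraction of a percent relative amplitude the measured growth
accelerates beyond the linear rate, which is a property of the system,
not of the numerics. Validation runs therefore seed at $10^{-5}$.

Lateral boundaries are closed (no flux) by default, matching the
conserved-mass setting; periodic boundaries are available and are used for
classifier validation, where a single traveling direction can win the
whole domain. The random initial perturbation defaults to $10^{-3}$
relative amplitude, seeded and reproducible.

## The space-time pattern classifier

`classify_field()` replaces visual/learned classification with a
transparent spectral rule, applied locally: fully developed wave fields
organize into domains of left- and right-movers separated by persistent
sources, so the kymograph is cut into overlapping windows a few dominant
wavelengths wide (Hann-tapered). Each window is scored by the
directionality $D$ of its dominant spectral ridge and by its normalized
spectral entropy; the field is chaotic if the median window entropy
exceeds 0.45, else traveling if the median $|D|$ exceeds 0.5, else
standing. The thresholds were calibrated once against the synthetic
generator (`generate_synthetic_field()`: waves, noisy waves, and a
band-limited Ornstein-Uhlenbeck surrogate with analytically known
spectra): noisy coherent waves stay below entropy 0.40 while surrogate and
simulated turbulence sit above 0.53, and pure standing/traveling waves
give $D = 0$ and $|D| = 1$ exactly. What passing these tests shows is
that the classifier separates its design categories and agrees with the
commensurability prediction on saturated slice simulations; it does not
certify performance on experimental imagery with illumination artifacts,
which is outside the package's scope.

## The conserved-density Ginzburg-Landau instance

The same regional-stability logic is exercised on a parametrically driven
complex Ginzburg-Landau equation coupled to a conserved density (the
standard phenomenological model of vibrated granular layers). The closed
form for the two growth-rate branches,
$\sigma_\pm = -(1 + \rho + q^2) \pm \sqrt{\gamma^2 - (\omega - b q^2)^2}$,
is derived by eliminating the conjugate field and is cross-checked against
the real $2\times2$ linearization at $10^4$ random points; the critical
drive $\gamma_c = (\omega + b(1 + \rho_0))/\sqrt{1 + b^2}$ and critical
density $\rho_c = \gamma\sqrt{1+b^2}/b - \omega/b - 1$ follow. The
pseudo-spectral simulator advances the full linearization -- including the
parametric pairing of $\psi_k$ with $\overline{\psi_{-k}}$ -- with its
exact per-mode matrix exponential. That choice is forced by the physics:
at $\gamma = 1.001\,\gamma_c$ the growth margin is a fraction of a percent
of the individual linear terms, and any scheme that splits the linear part
shifts the effective threshold by more than the margin (the first
implementation decayed everything). The density flux is evaluated in
spectral divergence form, so the mean density is conserved exactly. The
Gaussian filter of the regional stability map interprets its standard
deviation in grid cells (documented, configurable), and long runs show
localized stripe patches confined to the regions where the filtered
density is below $\rho_c$ -- with the expelled density accumulating
between the patches and locally stabilizing them.

## Problem sizes used by the validation suite

The suite runs the full pipeline at desk scale: slices of 10-20
wavelengths with $10^2$-scale lateral grids, the 500-um wedge at 200
finite-volume cells to $2\times10^4\,s$, dispersion checks over 20
parameter draws against the 200-node collocation oracle, and three seeds
for every stochastic claim (slice turbulence, localized Ginzburg-Landau
patches). These sizes are the package's validation choices: large enough
that every qualitative regime of the wedge story appears, small enough
that the whole suite runs on a laptop core in well under an hour.

## Known limitations

* The wedge is never simulated in full 3D; the two-dimensional slice
  simulator plus the reduced one-dimensional dynamics *are* the
  wedge-scale story, and cross-slice structure (fronts aligned along the
  height gradient) is only represented through the regional
  classification.
* The reduced dynamics predicts mass transport and pattern types, not
  phases or wave speeds; in laterally unstable regions its grid-scale
  structure is meaningful only in aggregate.
* The standing/traveling boundary of the classifier is a calibrated
  convention, as is the entropy threshold; both are exposed in the
  configuration surface.
* Membrane-membrane cross-talk (a second membrane at the top surface) is
  not modeled, and with it the homogeneous oscillations it is known to
  produce.
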