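---
title: "Capsid assembly in implicit condensates: models, theory and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsid assembly in implicit condensates: models, theory and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condcap)
```

## The scientific problem

Many viruses assemble their protein shells inside biomolecular
condensates -- liquid-like droplets formed by liquid-liquid phase
separation (LLPS) -- rather than in the dilute cytoplasm.  `condcap`
models the simplest physical picture of that situation: rigid,
patchy capsid subunits diffusing in a periodic box that contains one
spherical condensate, represented *implicitly* as an attractive
potential well.  The package provides the simulation engine, two
equilibrium theories that predict how partitioning and crowding shape
assembly yields, closed-form kinetic estimates, and the trajectory
analytics needed to measure yields and partition coefficients.

All quantities are in reduced units: the thermal energy $k_BT$ is the
unit of energy, the subunit mass $m$ the unit of mass, the subunit
length scale ($l_0$ for the pentagonal model, $\sigma$ for the
triangular model) the unit of length, and $t_0 = l_0\sqrt{m/k_BT}$ the
unit of time.

## Subunit models

Two coarse-grained models are implemented.

**Dodecahedron model.** A pentagonal subunit of circumradius $l_0$
carries five attractor ('A') pseudoatoms at its vertices, a top ('T')
pseudoatom at height $h_T = 0.5\,l_0$ above the pentagon plane, and a
bottom ('B') pseudoatom at depth $h_B = 0.25\,l_0$.  A-A pairs
attract through a Morse well of depth $\epsilon_{ss}$ with range
parameter $\alpha_M = 5/l_0$ and cutoff $r_{\rm eq} + 2.5/\alpha_M$;
T-T and B-T pairs are purely repulsive (WCA).  Twelve subunits tile a
dodecahedral shell with 30 edge bonds (five per subunit).

Two geometric choices deserve comment because the pentagon model's
fine structure admits more than one consistent construction:

* *Attractor equilibrium separation.* The Morse equilibrium distance
  is set to zero, so that bonded subunits' vertex attractors
  coincide.  In the closed shell the subunit vertices are exactly the
  dodecahedron's vertices, where three subunits meet; any positive
  equilibrium separation would make the closed shell a frustrated,
  high-energy state.  With $r_{\rm eq}=0$ the reference capsid sits
  exactly at the potential minimum: its attraction energy is
  $30 \times 2$ contacts at the full (cut-and-shifted) well depth and
  the net force on every subunit vanishes, which the test suite
  asserts to $10^{-9}$.
* *Dihedral calibration.* The T and B repulsive diameters are
  computed, not tuned: they are chosen so that both the T-T and the
  B-T WCA contacts of a bonded pair are exactly tangent (zero energy
  and force) at the regular dodecahedron dihedral angle of
  116.57 degrees.  Flattening a hinge then engages the T-T repulsion
  and over-closing engages B-T, so the two repulsions lock the bond
  angle at the value that propagates to a closed shell, while the
  B-T asymmetry penalizes upside-down binding.

**Icosahedron model.**  A triangular subunit of circumscribed
diameter $3\sigma$ is a plate of 45 excluder pseudoatoms (diameter
$\sigma$, a 9-row triangular grid) with two attractor pseudoatoms per
edge at 1/3 and 2/3 of the edge length.  Attractors carry
complementarity tags: only the 1/3-position atoms bind the
2/3-position atoms of a partner edge (lock-and-key), through a
Lennard-Jones well of depth $\epsilon_{ss}$.  Two subunits therefore
bind edge-to-edge in antiparallel registry with both attractor pairs
at the LJ minimum $2^{1/6}\sigma \approx 1.12\sigma$ -- consistent
with the bond-detection criterion (attractor pairs within
$1.3\sigma$).  The reference icosahedral shell is inflated radially
by $\delta = 2^{1/6}\sigma / (2\sin\beta)$ (with $\beta$ half the
exterior hinge angle), which simultaneously puts all 60 attractor
contacts at their minimum and the excluder plates exactly at WCA
tangency across each hinge.  The LJ cutoff is $1.75\sigma$, chosen
between the bonded contact (1.12$\sigma$) and the nearest
non-bonded complementary pair in the closed shell (1.82$\sigma$), so
that only the intended contacts contribute -- this keeps the closed
shell's attraction energy exactly 30 bonds times the per-bond
minimum.  The pentagonal model is the package's production model;
the triangular model's single-layer excluder plate gives it limited
bending rigidity, so its dynamical assembly pathways should be
treated as qualitative.

## The implicit condensate

The condensate is a spherical well at the box center:
$$u_c(r) = \begin{cases} -\epsilon_c, & r < R_c\\
-\epsilon_c\,(2e^{-\alpha_C (r-R_c)} - e^{-2\alpha_C (r-R_c)}), & r \ge R_c
\end{cases}$$
with $\alpha_C = 10$ per unit length, thin compared with $R_c$ but
bounding the boundary force by $\alpha_C \epsilon_c/2$.  The field
couples once per subunit at its center of mass, so an $n$-subunit
cluster gains $n\epsilon_c$ by entering the condensate -- assembly
amplifies partitioning.  The condensate is pinned (never wrapped
periodically); runs validate $R_c + \text{interaction range} < L/2$.
The geometry bookkeeping uses $V_c = \tfrac43\pi R_c^3$,
$V_{bg} = L^3 - V_c$ and the volume ratio $V_r = V_c/V_{bg}$.  When a
configuration fixes $V_r$ rather than $R_c$, the radius is derived
from the box length, so density scans at fixed $V_r$ rescale
$R_c \propto L$.

## Dynamics

Rigid-body Langevin dynamics: BAOAB splitting for translation and,
for rotation, body-frame angular momenta with a symplectic free-rotor
axis-permutation update (half-z, half-y, full-x, half-y, half-z per
drift) and an Ornstein-Uhlenbeck kick per principal axis.  With
friction zero the integrator reduces to velocity Verlet plus the
symplectic free rotor; a two-subunit bound dimer at $dt = 10^{-3}$
drifts less than $10^{-3}\,k_BT$ over $10^4$ steps.  Defaults:
$dt = 5\times10^{-3}$, $\gamma = 1$ (so the Einstein diffusion
constant is $D = 1$), isotropic rotational friction
$\gamma_r = \gamma\,c^2$ with $c$ the subunit circumradius.
Quaternions are renormalized every step.  Pair interactions use a
Verlet neighbor list over pseudoatoms (skin 0.8, rebuilt when any
body's center displacement plus rotation-angle-times-radius exceeds
half the skin).  The thermostat noise stream is an internal
xoshiro256++ generator seeded from the run configuration, so
identical seeds give bit-identical trajectories on one platform.

## Equilibrium theory

The two-state approximation allows only free monomers and complete
capsids of $N_{\rm cap}$ subunits.  In each phase the law of mass
action holds, $\mu_{\rm cap} = N_{\rm cap}\,\mu_1$, and each species'
chemical potential is equal across phases.  Excluded volume enters by
mapping monomers and capsids onto effective hard spheres and using
the Carnahan-Starling equation of state and its BMCSL binary-mixture
extension; chemical potentials are the analytic density derivatives
of the BMCSL free energy, and the one-component reduction to
$\mu^{ex} = (8\eta - 9\eta^2 + 3\eta^3)/(1-\eta)^3$ is asserted to
$10^{-10}$ in the tests.  In the ideal-solution limit the monomer
partition coefficient is $K_c = e^{\epsilon_c}$; with excluded volume
$K_c$ falls below that, by more than an order of magnitude once
condensate packing fractions grow.

Numerics: the solver reduces the coupled equations to nested
bracketed one-dimensional root finds (monomer density inside a phase,
then capsid density, then the common chemical potential from total
mass conservation), each bracketed in log-density with relative
tolerance $10^{-12}$; hard-sphere solutions with a phase packing
fraction at or above 0.74 are rejected as saturated, and packing
fractions above 0.5 are flagged because the Carnahan-Starling form
degrades there.

Two calibration constants connect the theory to the particle model:

* *Effective monomer diameter* $\sigma_{\rm sub}$: rather than the
  circumscribing sphere (which overestimates a soft, anisotropic
  repulsion carried only by the T and B pseudoatoms), the default
  matches the orientation-averaged second virial coefficient of the
  subunit's repulsive interactions to a hard sphere,
  $B_2 = \tfrac{2\pi}{3}\sigma_{\rm eff}^3$, by Monte Carlo with a
  fixed internal seed.  For the pentagon model this gives
  $\sigma_{\rm sub} \approx 1.84\,l_0$.
* *Capsid formation free energy*
  $\Delta G_{\rm cap} = -30(\epsilon_b - \Delta s_b)$, with
  $\epsilon_b$ the per-bond well depth measured from the pair
  potential (two attractor contacts per bond) and $\Delta s_b$ a
  single per-bond entropic penalty.  The default
  $\Delta s_b = 7.153\,k_BT$ is fixed once by requiring the bulk
  (no-condensate) two-state critical subunit concentration at
  $\epsilon_{ss} = 6$ to be $5\times10^{-4}$, the density scale at
  which weak bulk assembly first appears in simulations of this
  model class.  Both constants are exposed as arguments of
  `theory_params()`.

The capsid effective diameter defaults to $\sigma_{\rm cap} = 5.1$
for the dodecahedron model.  The close-packing concentration is
$\rho_{CP} = \sqrt2/\sigma_{\rm cap}^3$; note that
$\sqrt2/5.1^3 = 1.066\times10^{-2}$, whereas the commonly quoted
rounded value $1.28\times10^{-2}$ corresponds to a slightly smaller
effective diameter ($\approx 4.80$).  `threshold_volume_ratio()`
therefore accepts $\rho_{CP}$ directly so either convention can be
used; the packing-threshold results below use $1.28\times10^{-2}$.

With these defaults the hard-sphere theory reproduces the
qualitative structure of condensate-coupled assembly: yield versus
total density is non-monotone with an interior optimum near
$\rho_T \approx 3\times10^{-4}$ at $\epsilon_c = 7$,
$V_r = 5\times10^{-3}$ (the ideal-solution theory is monotone on the
same grid), the condensate capsid density saturates beyond the
optimum, and shrinking $\sigma_{\rm cap}$ raises high-density yields.

## Kinetics

Three closed-form scaling estimates:
$$\tau_D = \frac{V_c/(V_r + 1/K_c) + f_c V_{\rm tot}}{4\pi R_c D},
\qquad
s_{\rm nuc} = \frac{V_r}{(V_r + 1/K_c)^{n_{\rm nuc}}},
\qquad
\tau_{1/2} = \tau_{1/2}^0/s_{\rm nuc} + \tau_D/2 .$$
$\tau_D$ is the Smoluchowski time to supply the condensate with the
subunits it will absorb; $s_{\rm nuc}$ is the nucleation speedup from
concentrating monomers (the exponent grouping is the only one that
*accelerates* nucleation for strong partitioning,
$s_{\rm nuc} \to V_r^{1-n_{\rm nuc}} \gg 1$ as $K_c \to \infty$; the
typeset form of the published scaling is ambiguous and this reading
is adopted deliberately); and the median assembly time is bounded
below by $\tau_D/2$ -- diffusion into the condensate is the speed
limit of LLPS-accelerated assembly.  The critical nucleus size
defaults to $n_{\rm nuc} = 5$ and is treated as a constant input.
$K_c$ may be the equilibrium value or a measured
$K_c^{\rm meas}(t)$ from a trajectory.

## Trajectory analytics

Bonds: two pentagon subunits are bonded when any pair of edge
midpoints lies within $0.3$ (minimum image); triangles when both
complementary attractor pairs of an edge pair are within $1.3$.  Each
subunit edge joins at most one bond (nearest partner wins, preventing
degree overflow in malformed regimes).  Connected components are
computed with `igraph`.  A cluster is *complete* when it has
$N_{\rm cap}$ subunits all at maximal degree; a *dangler* has
$N_{\rm cap}$ subunits but missing bonds (e.g. 12 subunits, 26 of 30
bonds, from a misoriented final subunit); *malformed* covers
danglers, oversized clusters and over-bonded subunits.  Yields are
$f_c = N_{\rm cap}\rho_{\rm cap}/\rho_T$ with the
condensate/background split assigned by cluster centroid
(minimum-image consistent), so $f_c = f_c^c + f_c^{bg}$ holds to
machine precision.  The measured partition coefficient is
$K_c^{\rm meas} = \rho_1^c/\rho_1^{bg}$ over monomers; an empty
background returns a flagged sentinel rather than an error.  Median
assembly times interpolate the half-yield crossing linearly between
snapshots (snapshot cadence contributes about one interval of
uncertainty); maximum assembly rates convolve $f_c(t)$ with a
reflect-padded first-derivative-of-Gaussian kernel (width: ten
snapshot intervals by default).

## Synthetic fixtures: what they emulate and what they do not

`generate_fixture()` builds deterministic configurations for testing
the analytics without running dynamics: monomer gases (no pair within
three circumradii), planted reference capsids, danglers (one subunit
hinged outward about a bonded edge so exactly four of its five bonds
break), and condensate-packed capsid arrays (complete capsids on an
FCC lattice clipped to the condensate sphere, realizing a requested
packing fraction within 2% by construction).  These fixtures carry
planted ground truth, so analyzer tests are exact; they do not
emulate thermal disorder, partial intermediates, or the malformed
aggregates of strong-binding regimes, so passing them validates the
bookkeeping, not the dynamics.

## Scaled-down study conditions

The packaged tests run desk-scale analogs of cluster-scale
simulations, with sizes chosen once: Boltzmann-sampling validation
uses one subunit for $4\times10^4\,t_0$ in a condensate with
$R_c = 5$; partition-coefficient validation uses $N = 150$ subunits
at $\rho_T = 4\times10^{-4}$, $V_r = 5.03\times10^{-3}$,
$\epsilon_c \in \{1,2,3\}$, four replicates of $4800\,t_0$ each with
the first $1200\,t_0$ discarded -- the condensate monomer count
relaxes over roughly $400\,t_0$ (slower than the bare diffusion
estimate, because escape from the well is also rate limiting), so
shorter windows carry a shared filling transient that biases
$K_c^{\rm meas}$ low, and the window must span many relaxation times
for the replicate scatter to be a faithful error estimate; the
LLPS-enhancement comparison uses $N = 120$ at $\epsilon_{ss} = 6$,
$\rho_T = 4\times10^{-4}$, five replicates of $3000\,t_0$ per
condition ($\epsilon_c = 0$ vs $7$), about $\tau_D$ at the measured
partitioning strength.  At these sizes a condensate holds a
handful of capsids, so replicate-to-replicate scatter is substantial
and all quantitative comparisons are made against twice the standard
error of the mean over replicates, the convention used throughout
the package.  Full-scale behavior (e.g. $N = 1200$,
$t_F = 10^6$) is configurable but not exercised by the tests.

## Known limitations

* Subunits are rigid; no intrasubunit flexibility, so annealing of
  malformed intermediates is slower than for flexible models.
* Empty capsids only: no nucleic-acid cargo, no condensate
  constituents, growth, surface tension or droplet motion.
* The icosahedron model's excluded-volume plate is a single layer;
  its assembly dynamics are qualitative (see above).
* The two-state theory ignores intermediates; near close packing
  ($\eta \gtrsim 0.5$) the Carnahan-Starling mapping is only
  semi-quantitative.
* $\Delta s_b$ and $\sigma_{\rm sub}$ are calibration constants; all
  theory-simulation comparisons inherit their uncertainty.
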