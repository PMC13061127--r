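---
title: "Methods: inertial raft transport, Markov-chain reduction, and bloom-origin inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inertial raft transport, Markov-chain reduction, and bloom-origin inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomtrace)
```

# The problem

Pelagic *Sargassum* blooms are observed by satellite only once they are
dense; the biomass that seeded them may have drifted for months from a
remote region where concentrations were too low to detect.  bloomtrace
implements a pipeline for turning near-surface ocean currents and winds
into a probabilistic answer to "where did this bloom come from?": a
physical transport model for buoyant algal rafts, a reduction of its
trajectories to a time-inhomogeneous Markov chain on a box partition,
and two independent inference layers on that chain — Bayesian inversion
of first-hitting times, and nonautonomous transition path theory (TPT).
Because real reanalysis forcing is far too large for routine testing,
the package ships a synthetic-data module that generates analytic flow
fields and full scenarios with a seeded, known source region, so the
whole inferential chain can be validated by recovery.

# The raft transport model

A *clump* is a small group of algae idealized as a buoyant sphere; a
*raft* is a network of clumps coupled by nonlinear elastic links.  On a
planar beta-plane (x east, y north, meters; Coriolis parameter
$f = f_0 + \beta y$), with ocean velocity $v(x,t)$ and 10-m wind
$w(x,t)$, each clump moves according to

$$\dot x_m = u|_m + \tau\, u_\tau|_m + \tau F_m, \qquad
  u = (1-\alpha)\, v + \alpha\, w,$$

where $\alpha \in [0,1)$ is the windage fraction, $\tau \ge 0$ the
inertial (Stokes) response time, and the finite-size correction is

$$u_\tau = R\,\frac{Dv}{Dt} + R\Big(f + \tfrac{\omega}{3}\Big)v^\perp
          - \frac{Du}{Dt} - \Big(f + \tfrac{R\omega}{3}\Big)u^\perp,$$

with $R \in [0,1]$ the clump's exposure to air, $\omega = \partial_x v_y
- \partial_y v_x$ the vertical vorticity of the ocean field,
$a^\perp = (-a_y, a_x)$, and $D/Dt$ the material derivative following
the respective field.  Setting $\tau = 0$ recovers the passive "leeway"
model; the $u_\tau$ and spring terms are what distinguish an inertial,
mechanically coupled raft from independent tracers.

The pairwise force between linked clumps at separation
$x_{mm'} = |x_m - x_{m'}|$ is

$$F_m = -\sum_{m' \in \mathrm{neighbor}(m)}
        \kappa(x_{mm'})\Big(1 - \frac{\ell}{x_{mm'}}\Big)\,\mathbf
        x_{mm'},\qquad
  \kappa(x) = \frac{\kappa_0}{e^{(x - 2\ell)/d} + 1},$$

a spring of natural length $\ell$ whose stiffness switches off
logistically beyond twice its natural length over the cutoff scale
$d \ll \ell$.  Because $\tau F_m$ enters a velocity, $F_m$ carries
units of m/s$^2$ and $\kappa_0$ of s$^{-2}$.  Links stretched beyond
`cutoff_radius` (default $2\ell + 10d$, where the stiffness has decayed
to $\sim 5\times10^{-5}\kappa_0$) are removed permanently: rafts
disaggregate and never re-link.  Coincident linked clumps contribute
zero force (the unit vector is singular there) with a warning.

**Network initialization.** Rafts are seeded on a hexagonal (or square)
lattice of pitch $\ell$ with links between all pairs closer than
$1.5\ell$.  This is the simplest rule consistent with a natural length
$\ell$; the original raft model leaves the network construction to its
own reference and we do not attempt to reproduce it more finely.

**Integration.** The coupled $2M$-dimensional system is advanced by
fixed-step classical RK4 — chosen over adaptive stepping so runs are
bit-reproducible — with the link set re-evaluated after every step.
Clumps that enter a land cell are frozen in place ("beached") and keep
counting in their box; clumps that leave the field bounding box are
frozen with their exit step recorded and count as exterior thereafter.
Freezing rather than deleting beached clumps is deliberate: deletion
would leak probability before the chain closure gets to account for it.
Field queries during the final partial step of an exiting clump are
clamped to the bounding box inside the compiled integrator; the
user-facing sampler instead raises a hard error on out-of-bounds
queries, so domain-exit handling stays at the Markov level where it
belongs.

**Forcing and differentiation.** Gridded fields (the stand-in for
reanalysis products) are interpolated bilinearly in space and linearly
in time — the lowest-order scheme that reproduces nodal values exactly
— and differentiated by central differences of the interpolant with a
one-grid-cell step (one-sided within a boundary cell).  The carrying
field's derivatives are the same linear combination of the per-field
stencils, so the R reference implementation and the compiled integrator
agree to rounding.  A piecewise-linear interpolant is only $C^0$; its
kinks dominate the time-stepping error, and step-halving experiments on
gridded forcing show an effective convergence order near 2 no matter
how fine the grid.  For accuracy studies the package therefore also
provides *analytic* forcing (`analytic_double_gyre()`,
`analytic_uniform_wind()`), evaluated exactly at every RK4 stage point;
under smooth forcing the integrator exhibits its nominal fourth order
(error ratios $\approx 16$ per step halving).  The reference scenario
keeps gridded forcing, since exercising the interpolation path is part
of what the synthetic experiments are for.

# Markov-chain reduction

The domain is tiled by square boxes of side $h$ (half-open, row-major
from the south-west corner).  Sampling every trajectory at the chain
times $t_k = t_0 + k\Delta t$ and counting box-to-box transitions gives
the Ulam estimate $\hat P_{ij}(k)$: the fraction of clumps in box $i$
at $t_k$ found in box $j$ at $t_{k+1}$.  The open domain loses mass
(exits, and anything else unaccounted), so each $\hat P(k)$ is closed
into an $(N{+}1)\times(N{+}1)$ stochastic matrix by a two-way *nirvana*
state $\omega$: a final column absorbs each row's probability
imbalance, and the $\omega$ row re-injects it through an inflow
distribution — uniform $1/N$ by default, emulating a diffuse background
concentration of algae too sparse for satellites to see.  Rows of boxes
with no occupants at $t_k$ are routed wholly to $\omega$ and re-enter
through the inflow: stochasticity is preserved without inventing local
dynamics, and the affected rows are visible in the stored counts.
Beached clumps keep counting in their frozen box (the alternative,
sending them to $\omega$, is a one-line change in the counting rule but
is not the default).  $\Delta t$ should be long enough for memory loss
between steps; the synthetic default is $T_{\rm flow}/20$ (3 days for
the 60-day flow period), standing in for the weekly increment a
real-data application would use on a 1.5-degree grid.

Densities evolve by $\lambda(k{+}1) = \lambda(k) P(k)$; every matrix is
row-stochastic to $10^{-12}$ by construction and pushforward conserves
mass to the same tolerance.

# Bayesian origin inversion

A bloom observation is a box set $B$ and a time index $k_B \ge 1$.  For
each candidate origin box $\bar b$ the likelihood is the probability
that the chain, started at $\bar b$ at $t_0$, *first* hits $B$ exactly
at $t_{k_B}$.  With $B$ made absorbing (rows of $B$ replaced by unit
self-loops), the cumulative occupation probability equals the
first-hitting-time distribution function, and the pmf follows by
differencing; the cumulative curves for all candidates are obtained in
one pass by accumulating the matrix product over the candidate rows.
(A single backward recursion cannot produce the whole cumulative curve
for a time-inhomogeneous chain — it yields occupation at the final
horizon only — which is why the implementation accumulates forward.)
The posterior is proportional to likelihood times prior (uniform by
default), normalized over the candidate set; the maximum likelihood
estimate $\hat b$ is the argmax with deterministic lowest-index
tie-breaking and the full tie set reported.

Three guard rails are deliberate design choices rather than paper-given
mechanics: candidates are restricted to boxes with at least one clump
occupancy over the horizon (others are reported unvisited with zero
posterior), the nirvana state is never a candidate (a bloom cannot
originate in a virtual background state), and an all-zero likelihood
vector yields an explicit `no_path` flag instead of a silently uniform
posterior.

# Nonautonomous transition path theory

TPT characterizes *transition paths* — stretches of trajectory that run
from a source set $A$ to a target set $B$ without revisiting $A$ or
passing through $B$ in between — on the finite-time, time-inhomogeneous
chain.  The forward committor $q^+_i(k)$ (probability of reaching $B$
before $A$ within the horizon) solves a backward iteration with final
condition $\mathbf 1_B$; the backward committor $q^-_i(k)$ (probability
of having last left $A$ rather than $B$) solves a forward iteration on
the time-reversed chain
$P^-_{ij}(k) = \lambda_j(k{-}1) P_{ji}(k{-}1) / \lambda_i(k)$.  States
with $\lambda_i(k) = 0$ cannot be visited; their reversed rows are
masked to self-loops and their $q^-$ set to zero, which is harmless
because every current term carries the $\lambda_i(k)$ factor.  The
reactive current
$f^{AB}_{ij}(k) = q^-_i(k)\lambda_i(k)P_{ij}(k)q^+_j(k{+}1)$ is
conserved at interior states; the effective current is its positive net
part $f^+_{ij} = \max\{f^{AB}_{ij} - f^{AB}_{ji}, 0\}$ — we read the
bare "max" of the source formulation as the positive part, matching the
autonomous definition — and satisfies $f^+_{ij} f^+_{ji} = 0$ exactly.
For display, each box gets the vector $\sum_{j\neq i} f^+_{ij} e_{ij}$
with $e_{ij}$ the unit vector between box centers; $\omega$ has no
geometric position, so flux exchanged with it is reported as per-box
injection/ejection scalars instead.  The initial density for TPT runs
defaults to all mass on $\omega$ (background mass entering the domain);
it is an explicit argument because no canonical choice exists.  Root
transforms in the plotting helpers are display-only.

# The synthetic scenario and what it validates

`make_scenario()` builds the study conditions end to end: a
double-gyre basin of 2000 km by 1000 km (stream function amplitude
$8\times10^4$ m$^2$/s, peak current about 0.25 m/s, separatrix
perturbation $\varepsilon = 0.1$ with a 60-day period), a steady 4 m/s
westward wind with a 2 m/s meridional oscillation of the same period,
and windage $\alpha = 0.01$ — windage-driven drift of about 4 cm/s
weak enough that the gyres dominate locally but strong enough to bleed
the seeded population out of its gyre.  Inertial parameters are
$R = 0.5$, $\tau = 1800$ s, $f_0 = 5\times10^{-5}$ s$^{-1}$,
$\beta = 2\times10^{-11}$ m$^{-1}$s$^{-1}$: plausible magnitudes for
decimeter-scale buoyant clumps at subtropical latitude, used as direct
configuration inputs (the closed-form dependence of $(\alpha, R, \tau)$
on buoyancy and clump radius is out of scope).  Sixty 5x5 hexagonal
rafts ($\ell = 5$ km, $\kappa_0 = 10^{-8}$ s$^{-2}$, $d = 500$ m — the
spring length is scaled up from physical raft dimensions so that raft
cohesion is visible at basin scale) are seeded in a 120-km disc at the
eastern gyre center, plus 300 isolated background clumps spread
uniformly: about 1800 clumps in all.  The chain uses 20x10 boxes of
100 km, $\Delta t = 3$ days, $K = 40$ steps, and the RK4 substep is
$\Delta t / 56$ (the analog of 3-hour substeps under a weekly
increment; the spring relaxation rate $\tau\kappa_0$ times the substep
is about 0.08, comfortably stable).

Ground truth is defined by the generator itself.  The *source region*
is the set of boxes the seeded population occupies during its early
residence phase — at least 5 cluster clumps in some step $k \le 4$ —
about 13 boxes (6–7% of the domain).  This footprint definition,
rather than the $t_0$ boxes alone, includes the exit gate the
population funnels through in its first days, which is part of the
origin region in any physical reading.  The *bloom observation* is the
set of 3 boxes holding the densest detached (non-source) concentration
of seeded clumps; with `k_bloom = "auto"` (the default) the
observation time is the step in steps 20–32 at which that
concentration peaks — a bloom is observed when it blooms — and a fixed
integer `k_bloom` is honoured when given.  Source and bloom sets are
disjoint by construction, and a pilot pushforward verifies positive
source-to-bloom transport before a scenario is accepted; otherwise a
`scenario_infeasible` error with diagnostics is raised.  A decoy
region of the same size in the opposite (western) gyre supports
source-contrast experiments.  Everything is a pure function of
`(seed, config)`: regeneration is bit-identical.

What the generator emulates: seasonal-scale time dependence, a
basin-like gyre circulation with a retentive core, windage-driven
inter-gyre leakage, raft cohesion and disaggregation, beaching against
an optional land barrier with a strait, a sparse baseline population,
and domain-open boundaries.  What it does not emulate: mesoscale
eddies and realistic spectral content of reanalysis currents,
spatially structured winds, Stokes drift, biological growth and decay,
spherical geometry, and observation noise in the bloom footprint.
Passing the recovery experiments therefore demonstrates that the
machinery — transport, reduction, closure, inversion, TPT — is
internally consistent and identifies a designed-identifiable source;
it does not by itself establish skill on real reanalysis forcing.

# Validation layout and problem sizes

The test suite checks every closed form against hand-derived values,
and each probabilistic computation against an independent oracle:
first-hitting pmfs against exhaustive path enumeration on chains with
up to 6 states and 6 steps (50 random chains) and against a
Monte-Carlo histogram of $10^5$ sampled paths on an 8-state, 12-step
chain; committors and reactive currents against enumeration on 50
random chains; interior current conservation to $10^{-12}$; the Ulam
estimator against a directly simulated 2-state time-varying process
with $10^4$ samples (error below $3/\sqrt M$).  The headline recovery
experiments run ten reference scenarios (a few minutes in total): the
Bayesian MLE must fall inside the source region in at least 8 of 10,
the box of maximal outgoing effective current over the first quarter
of the horizon likewise, and the time-integrated reactive current into
the bloom from the true source must exceed the decoy's at least
tenfold (observed contrast is two orders of magnitude — the scaled-down
analog of a much larger contrast expected over multi-year basin-scale
runs).  `scripts/acceptance.R` recomputes these quantities from
scratch under a caller-supplied master seed.

Numerical conventions worth knowing: probability tolerances are
$10^{-12}$ absolute for stochasticity and conservation; position
comparisons against closed forms are relative to the trajectory scale
(coordinates are order $10^6$ m, so absolute float accumulation is
proportional to that scale); negative first-hit pmf entries within
$-10^{-12}$ are clipped as rounding, anything larger is an error;
argmax ties break to the lowest box index; currents are stored sparse
with no flushing of tiny values, since source-contrast experiments
span many orders of magnitude.

# Limitations

The beta-plane formulation ignores spherical geometry, which matters
at basin scale for real applications.  The interpolation order caps
trajectory accuracy under gridded forcing (see above); a smoother
interpolant would raise it at the cost of nodal exactness.  The
uniform-inflow closure is one of several defensible re-entry models —
drifter-derived re-entry statistics would be the natural alternative
with real data.  Chains are stored as dense-ish sparse matrices per
step; at the reference size (201 states, 39 steps) this is trivial,
and the design has headroom for the $10^4$-box partitions a real-data
mode would need, but no out-of-core support is attempted.  Finally,
the scenario's identifiability is by design: a real bloom's origin may
sit in a region with no retention signature, where the posterior will
be correspondingly diffuse — exactly the situation the `no_path` flag
and the posterior's full reporting (rather than just $\hat b$) are
meant to expose.
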