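---
title: "Wave gaits from foot-contact phase resetting: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave gaits from foot-contact phase resetting: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexagait)
```

## The scientific question

Slow-walking insects coordinate six legs into metachronal and tripod gaits,
and shift smoothly between them with speed, even though there is little
evidence of strong direct neural coupling between the ipsilateral leg
oscillators.  One candidate explanation is *embodied sensorimotor
interaction*: each leg's rhythm generator only senses its own foot contact,
and the body's mechanics couple the legs by deciding *when* each foot meets
the ground.  `hexagait` implements a minimal closed-loop model of that
hypothesis and the machinery needed to analyse it: an event-driven
simulator, Poincaré-map fixed points and stability, basins of attraction,
footprint diagrams, and closed-form first-order solutions that serve as
analytic cross-checks.

## The model

**Controller.**  Each leg $i$ carries a phase oscillator $\phi_i \in
[0, 2\pi)$ with

$$\dot\phi_i = \omega + g_i + y_i, \qquad
  \tau \dot y_i = k^f_i - y_i,$$

where $\omega = 2(1-\beta)\pi/T_{sw}$ keeps the swing duration $T_{sw}$
constant while the duty factor $\beta$ sets the speed.  During stance
($0 \le \phi_i < 2\beta\pi$) the foot tracks a line of length $s$ from the
anterior to the posterior extreme position; during swing it returns along
an arc of height $d$.  The only inter-oscillator coupling $g_i$ pins
contralateral pairs in antiphase; ipsilateral oscillators are not coupled
at all.  The sensory feedback $k^f_i$ is *phase resetting*: when foot $i$
touches down during its swing phase, $\phi_i$ is reset to stance onset,
an advance of $2\pi - \phi_i^{td}$, injected through a first-order lag
($\tau = 1$ s by default; $\tau = 0$ gives an instantaneous jump).
`step_network()`/`simulate_network()` integrate this six-oscillator system
with fixed-step RK4 (default $dt = 10^{-3}$ s), applying contact events
between steps; one isolated reset adds exactly its amount of phase once the
lag has decayed, which the test suite verifies against the closed-form
impulse response.

**Body.**  The body is a rigid plate (half length $a^*$, half width $b^*$,
normalized by the neutral leg length) on six massless vertical springs of
relative stiffness $K^* = KL/Mg$.  The oscillator phases command each
spring's root offset $\Delta x_i^*(\phi_i)$ and neutral length
$L_i^*(\phi_i)$.  Because the gait is slow, the body is assumed to be in
static equilibrium at every instant: vertical force balance
$\sum_{i \in S} K^* \Delta l_i^* = 1$ and pitch/roll moment balance about
the centre of mass, linearized with the small-angle body rotation, where
$S$ is the stance set and the compressions $\Delta l_i^*$ follow from the
rigid-plate ground constraint.  `solve_equilibrium()` solves the resulting
$3\times 3$ system for pitch, roll and hip height, and reports hypothetical
compressions for all six legs; a negative value for a swing leg means the
foot is above the ground, and its upward zero crossing defines touchdown.

**Reduction.**  With contralateral pairs locked ($\phi_{i+3} = \phi_i +
\pi$) and the feedback lag neglected on the gait timescale, the closed loop
reduces to three oscillator phases that advance uniformly between contact
events, each touchdown contributing *half* of its reset to the shared
reduced oscillator.  This makes the system autonomous in cumulative phase
advance, so the simulator needs no wall clock and no ODE stepping between
events.

## The event engine

`simulate_gait()` drives a compiled event loop:

* **Integration variable.**  All phases advance at unit rate; events are
  located by bracketing zero crossings of the six compression/gap functions
  on a grid (spacing 0.04 rad, window capped at 0.35 rad and at the next
  stance-branch exit) followed by bisection/secant refinement to
  $10^{-13}$.  Event handling uses a tolerance of $10^{-10}$ rad.
* **Touchdown** is the upward zero crossing of a swing leg's gap function.
  On touchdown during the swing branch the reduced oscillator jumps by
  $(2\pi - \phi^{td})/2$; contact during the stance branch is ignored by
  the feedback (the reset is zero), as the resetting rule prescribes.
* **Liftoff at the neutral length.**  A stance leg stays on the ground past
  $\phi = 2\beta\pi$ while its commanded neutral length shrinks, and leaves
  when its compression crosses zero — i.e. when the spring force vanishes.
  This is a deliberate design decision.  The alternative reading, liftoff
  exactly at the phase boundary $2\beta\pi$, looks equivalent (the
  unloading tail lasts only $O(1/K^*)$) but is not: it changes the stance
  sets present at the touchdown instants and with them the entire
  first-order structure of the gait fixed points.  Only force-zero liftoff
  reproduces the closed-form coefficients $2(1-\beta)$ and
  $\tfrac{9}{10}(1-\beta)$ of the wave-gait fixed points; the
  phase-boundary variant yields $(1-\beta)$ and $0.45(1-\beta)$ instead.
  The quasi-static idealization is mildly inconsistent here (at the phase
  boundary the spring still carries $O(1/K^*)$ force), and resolving the
  inconsistency in favour of the force condition is what makes the analytic
  limit work.
* **Degenerate support.**  Pure complementarity can chatter at states where
  removing one foot makes the support polygon collinear (fewer than three
  non-collinear stance feet cannot balance the moments).  The engine
  resolves each event instant atomically: stretched springs are released
  most-negative-first, feet pushed onto the ground are added, each leg may
  toggle a bounded number of times per instant, and a liftoff that would
  leave the body unsupportable is deferred — the foot *adheres* until the
  support set becomes solvable again.  Insect feet do adhere, so this
  regularization is not unphysical, but it only ever activates far from
  the wave gaits; on the gait branch the support alternates between three
  and four non-collinear feet and the guard never triggers (verified by the
  fixed points being bit-identical with and without it).
* **Poincaré section.**  The state *immediately before* each leg-2
  touchdown is recorded: relative phases $\psi_1 = \phi_2 - \phi_1$,
  $\psi_2 = \phi_3 - \phi_2$ and the touchdown phase.  To start a run
  *on* the section from bare $(\psi_1, \psi_2)$, the engine scans the swing
  branch for the last upward crossing of leg 2's gap, assigns stance flags
  by a guarded complementarity cleanup from five-leg support, and backs the
  state off by 0.02 rad along the flow so that no flag is assigned at a
  branch boundary; the first recorded sample is then the true section
  crossing.  One caveat is inherent to the reduction: $(\psi_1, \psi_2)$
  determines the full hybrid state only where the contact configuration is
  phase-determined.  Near the wave gaits this holds and the half-cycle map
  composed with itself equals the full-cycle map to $10^{-10}$; far from
  the attractors the contact set carries memory and the "map" on the
  relative-phase plane is only an approximate description (the basin scan
  is still well defined because every lattice point is integrated as a full
  hybrid state after initialization).

## Fixed points, stability, basins, footprints

`find_fixed_point()` runs a torus-aware Newton iteration on $P(\psi) -
\psi$ with a central-difference Jacobian (step $10^{-6}$ rad, two orders
above the event tolerance), initialized at the closed-form values;
residuals reach $10^{-10}$ and typically machine precision.
`numerical_jacobian()` exposes the same Jacobian; its eigenvalue moduli
are the gait's stability multipliers.

`basin_scan()` follows the lattice protocol: $n \times n$ initial
conditions on $[0, 2\pi)^2$ (offset by half a cell so no point sits on the
singular in-phase lines), each iterated until it has stayed within 0.1 rad
of a known fixed point for three consecutive samples.  Two numerical facts
matter for interpreting the counts.  First, some phase combinations have no
solvable leg-2 section state (nearly in-phase clusters leave only collinear
support); these are labelled `invalid` and excluded.  Second, away from the
attractors the map moves points by only $O(1/K^*)$ per cycle — the resets
are the only thing that changes relative phases — so convergence from a
distant initial condition takes hundreds of cycles at $d^*K^* = 50$.  A
200-step scan therefore reports a sizeable `unconverged` class, and counts
restricted to early converged points measure convergence *speed*, not basin
*size*; where basin sizes are compared across duty factors the package runs
the scan to convergence (1000 steps).  Both protocols give two and only two
attractor labels: the direct and retrograde wave gaits.

`footprint_diagram()` reconstructs per-leg stance intervals over the last
cycle(s) in cycle-normalized units, together with the minimum number of
simultaneous stance legs.  Phase resetting starts stance early and the
force-zero liftoff ends it late, so every leg's stance fraction is at least
$\beta$.  At $\beta = 1/2$ the direct gait is an alternating tripod
($\{1,3,5\}$ / $\{2,4,6\}$, each about half the cycle).  At $\beta = 0.65$
mean support is $6\beta \approx 3.9$ legs: the gait keeps at least four
feet down for most of the cycle but necessarily passes through brief
three-leg windows (about 9% of the cycle); a claim of "always at least
four" can only hold when ground contact outlasts the commanded duty factor,
as it does on compliant robot hardware.

## Closed forms and what they do (and do not) reproduce

`analytic_fixed_point()`, `halfcycle_multipliers()` and
`evolution_matrix()` implement the first-order analytical results.  For the
direct wave gait,

$$\psi_1 = 2(1-\beta)\pi - \frac{2(1-\beta)}{d^*K^*}
         + c_1(\beta)\,\frac{s^*/a^*}{d^*K^*}, \qquad
  \psi_2 = 2(1-\beta)\pi - \frac{9(1-\beta)}{10\,d^*K^*}
         + c_2(\beta)\,\frac{s^*/a^*}{d^*K^*},$$

with the retrograde gait given exactly by the fore-aft mirror
($s^* \to -s^*$, legs 1 and 3 swapped, $\psi_1 \leftrightarrow \psi_2$),
and half-cycle perturbation multipliers whose squares are the Poincaré-map
eigenvalues; at $s^* = 0$ both gaits share $\lambda_{\max} = (5/6)^2 =
25/36$.  The evolution matrix of relative-phase perturbations over a full
cycle is the square of a lower-triangular half-cycle matrix built from the
*unsquared* multipliers — the only self-consistent reading, confirmed here
by the numerical Jacobian.

Everything above that does not involve $s^*$ is reproduced by the
simulator to second order: the fixed-point discrepancy shrinks fourfold per
doubling of $K^*$, and the numerical eigenvalues match $25/36$ and
$(13/18)^2$ to 0.2% at $d^*K^* = 200$.  The *propulsive* terms are where
the two routes part ways.  The package ships two coefficient sets:

* `variant = "published"`: $c_1 = \tfrac{2}{5}\tfrac{1-\beta}{\beta}$,
  $c_2 = \tfrac{1}{25}(11\beta - 30)(1-\beta)$, and eigenvalue slopes
  $\mp\tfrac{4}{45}\beta$, $\pm\tfrac{4}{81}\beta$ on $m_1, m_2$.
* `variant = "rederived"`: $c_1 = (1-\beta)(45\beta-28)/(10\beta)$,
  $c_2 = (1-\beta)(75\beta-86)/(100\beta)$, obtained by solving the three
  touchdown conditions of the periodic solution (with the stance sets and
  reset bookkeeping described above) to first order in $s^*$ and $1/K^*$.

The two sets agree exactly at $s^* = 0$ and disagree in sign and magnitude
for $s^* \ne 0$.  Three independent routes — hand perturbation algebra, an
exact symbolic solve of the touchdown conditions, and the event-driven
simulator with Richardson extrapolation in $s^*$ and $K^*$ — agree on the
rederived values to the order retained, and the disagreement with the
published coefficients is robust to every modelling convention we tested
(swing-branch versus extrapolated stance-line root positions for the
unloading leg, ground-fixed versus commanded foot positions, alternative
reset bookkeeping).  The published propulsive terms therefore appear to
rest on an additional approximation or slip in their derivation that the
stated equilibrium equations do not contain; `compare_with_numeric()`
tabulates both variants against the simulator so the reader can judge.
Two caveats on the rederived set itself: the derivation evaluates the
stance feet's line positions at the leading-order event phases, neglecting
$O(1/K^*)$ phase corrections that enter the same order with a relative
weight of roughly $10^{-3}$; and the formulas are linear in $s^*$, while
the model has a genuine quadratic remainder, so at $s^*/a^* = 0.3$ the
fixed-point residual is dominated by $\sim 0.13\,(s^*/a^*)^2/K^*$ (about
$1.3\times 10^{-4}$ rad at $d^*K^* = 200$, still five times smaller than
the published-variant residual).

The *qualitative* propulsive predictions are unambiguous and reproduced by
both routes: the two gaits are equally stable when marching in place,
propulsion stabilizes the direct wave and destabilizes the retrograde wave
($\lambda^{Dw} < \lambda^{Rw}$ for $s^* > 0$), reversing the walking
direction swaps the two gaits exactly, both gaits remain stable across
$\beta \in [0.52, 0.65]$ and $s^*/a^* \le 0.3$, and the direct gait owns
the larger basin of attraction.

## Defaults, tunable parameters, problem sizes

| parameter | default | meaning |
|---|---|---|
| `beta` | — (required) | duty factor; wave-gait analysis assumes $1/2 < \beta < 2/3$ |
| `T_sw` | 10 s | swing duration (constant across speeds) |
| `s`, `d` | 6 cm, 6 cm | stance line length and swing arc height |
| `k_c` | 10 s$^{-1}$ | contralateral coupling gain (large = hard antiphase lock) |
| `tau` | 1 s | feedback lag; 0 = instantaneous resets |
| `a_star, b_star, d_star` | 1 | body geometry in units of leg length |
| `K_star` | 50 | relative stiffness; $d^*K^* = 50$ is the stiff study setting |
| `s_star` | 0.3 | propulsive ratio $s^*/a^*$ (0 = marching in place) |
| event tolerance | $10^{-10}$ rad | simultaneity and zero-crossing tolerance |
| Newton tolerance | $10^{-10}$ rad | fixed-point residual |
| Jacobian step | $10^{-6}$ rad | two scales above the event tolerance |
| classification radius | 0.5 rad | anchors deviate from gaits by $O(1/K^*) \ll 0.5$ |
| basin convergence | 0.1 rad, 3 samples | see the creep discussion above |

Ties between simultaneous events (within $10^{-10}$) are resolved
deterministically: liftoffs before touchdowns, then ascending leg index —
relevant exactly at $\beta = 1/2$, where the tripod makes whole triples of
events coincide.  At $\beta = 1/2$ the two gait anchors also coincide, and
`classify_gait()` falls back on the touchdown order: $(2,6,1,5,3,4)$
cyclically is the direct wave, its fore-aft mirror $(2,4,3,5,1,6)$ the
retrograde wave.

The shipped tests and the acceptance script use: 20×20 basin lattices with
200 steps (the lattice protocol) plus convergence-resolved scans (16×16,
1000 steps) for cross-$\beta$ basin-size comparisons; 30-cycle runs for
footprints; stiffness sweeps over $K^* \in \{50, 100, 200\}$; and the
eigenvalue grid $\beta \in \{0.52, 0.55, 0.6, 0.65\} \times s^*/a^* \in
\{0, 0.15, 0.3\}$ at $d^*K^* = 200$.  All of it runs in well under a
minute on one core; sizes were chosen so that every reported digit is
converged, not by runtime pressure.

## What this model is, and is not

The simulator reproduces the *closed-loop phase dynamics* of a slow,
quasi-static walker with ideal force control: massless springy legs,
no inertia, no horizontal ground friction, no yaw, instantaneous posture
equilibration, and a hard antiphase constraint between body sides.  Passing
its tests says the reduced model and its analysis are mutually consistent;
it does not certify behaviour of a physical robot (motor bandwidth, joint
compliance and inertial dynamics all shift the fixed points at low
feedback gain) nor of real insects, which show no strong contralateral
coupling and can coordinate even with the body held fixed.  The adhesion
regularization and the `invalid` basin labels mark, honestly, where the
quasi-static idealization stops being able to say anything at all.

```{r example, eval = FALSE}
g <- body_geometry(beta = 0.55, K_star = 50, s_star = 0.3)
fp <- find_fixed_point("direct", g)
tidy(fp)
b <- basin_scan(g)          # 20 x 20 lattice, 200 steps
autoplot(b)
cmp <- compare_with_numeric(beta = seq(0.52, 0.65, by = 0.01))
plot_gait_sweep(cmp)
```
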