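# hexagait

Hexapod wave gaits from decoupled oscillators with foot-contact phase
resetting.

## The problem

Slow-walking insects such as stick insects coordinate six legs into
metachronal and tripod gaits and shift between them smoothly with speed,
yet their ipsilateral leg rhythm generators show little direct neural
coupling.  `hexagait` implements and analyses a minimal model of the
alternative hypothesis — that the coordination *emerges* from the closed
loop of rhythm generation, body mechanics and local touch sensing:

* one phase oscillator per leg, `dphi_i/dt = omega + g_i + y_i`, with
  contralateral pairs locked in antiphase and **no** ipsilateral coupling;
* **phase resetting**: when foot *i* touches down during swing
  (`2*beta*pi <= phi_i < 2*pi`), its oscillator is reset to stance onset,
  an advance of `2*pi - phi_i^td`, fed through a first-order lag `tau`;
* a rigid body on six massless vertical spring legs (relative stiffness
  `K* = KL/Mg`), solved quasi-statically: force balance
  `sum_S K* dl*_i = 1` plus pitch/roll moment balance picks the posture,
  and the posture decides when each swing foot meets the ground.

Closing this loop produces exactly two attracting gaits: the **direct
wave gait** (swing propagating hind-to-front, the insect pattern, relative
phases `psi_1 ~ psi_2 ~ 2(1-beta)pi`) and the **retrograde wave gait**
(`psi_1 ~ psi_2 ~ 2 beta pi`).  Both collapse to the tripod at duty factor
`beta = 1/2`.  The package provides the six-oscillator controller, the
quasi-static mechanics, an event-driven simulator with Poincaré-map
analysis (fixed points, eigenvalues, basins of attraction, footprint
diagrams), and the closed-form first-order fixed points
(e.g. `psi_1 = 2(1-beta)pi - 2(1-beta)/(d*K*) + ...`) and stability
multipliers (`lambda_max = (5/6 -+ (4/45) beta s*/a*)^2`) as analytic
cross-checks.  It is aimed at researchers in computational neuromechanics
and bioinspired robotics who want a fully analysable testbed for
sensory-feedback-driven interlimb coordination.

## Worked example

```r
library(hexagait)

# study conditions: swing time 10 s, 6 cm stride line, 40 cm body
p <- gait_params(beta = 0.55, body_length = 40)
derived_timing(p)
#>     T_p omega frequency   S_l     v   v_bl
#> 1  22.2 0.283     0.045  10.9 0.491 0.0123

# dimensionless body: d*K* = 50 (stiff legs), s*/a* = 0.3 (propulsion)
g  <- body_geometry(beta = 0.55, K_star = 50, s_star = 0.3)
fp <- find_fixed_point("direct", g)
fp
#> <gait_fixed_point> direct wave gait (beta = 0.55)
#>   psi1 = 2.80733191, psi2 = 2.81675730, phi_td = 6.27304492
#>   |eigenvalues| = 0.65926, 0.55416; residual 7.1e-15 (3 iterations)

glance(find_fixed_point("retrograde", g))
#> # A tibble: 1 x 5
#>   gait       lambda_max stable residual iterations
#>   <chr>           <dbl> <lgl>     <dbl>      <int>
#> 1 retrograde      0.742 TRUE   7.86e-14          3
```

Reading the numbers: at `beta = 0.55` the direct wave gait sits a little
below its anchor `2(1-beta)pi = 2.827` rad, by the predicted `O(1/(d*K*))`
correction; its largest Poincaré-map eigenvalue 0.659 is smaller than the
retrograde gait's 0.742, so perturbations of the insect-like gait die out
faster — propulsion stabilizes the direct wave and penalizes the
retrograde one, while at `s* = 0` both share `lambda = 25/36`.  A basin
scan (`basin_scan(g)`, the 20 x 20 lattice / 200 map-step protocol) labels
144 starting conditions direct versus 130 retrograde, with the remainder
still creeping toward an attractor; `autoplot()` draws the basin map, and
`footprint_diagram(simulate_gait(fp$psi1, fp$psi2, g))` shows the stance
pattern.

A command-line front end is installed with the package:

```sh
$(Rscript -e 'cat(system.file("exec/hexagait", package = "hexagait"))') \
    fixed-point --beta 0.55 --dkstar 50 --s-over-a 0.3 -o out/
```

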