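---
title: "Modelling freezing of gait as a forced hybrid pendulum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling freezing of gait as a forced hybrid pendulum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(fogait)
```

## The model

Walking, in this package, is the stance phase of an inverted pendulum. The
body's centre of mass (CoM) sits at the top of a rigid, massless leg of
length $l$ pivoting about the stance foot; the stance angle $\theta$ is
measured from the vertical, counterclockwise positive, and forward walking
has $\omega = \dot\theta < 0$. A step runs from $\theta = +|\theta_{reset}|$
down through vertical to $\theta = \theta_{reset} < 0$, where the swing heel
meets the ground. The heel strike is an instantaneous, inelastic collision:
angular momentum about the new contact point is conserved across the
inter-leg (hip) angle $\theta_h$, giving the reset

$$\theta^+ = -\theta^-, \qquad \omega^+ = \omega^-\cos\theta_h .$$

Between collisions the stance leg obeys, in the small-angle regime
($|\theta| < 0.5$ rad),

$$\ddot\theta \;=\; \frac{g}{l}\,\theta \;+\; \Gamma(t), \qquad
  \Gamma(t) = \frac{\zeta_2(t) - \zeta_1(t)}{m_1 l^2},$$

where the two plantar-flexor inputs are sinusoidal envelopes of the calf
muscles' activity:

* $\zeta_1(t) = \tau_r\, l \sin\theta_h\,(\sin 2\pi f_{r2} t + 1)$ — the
  trailing leg's **ankle push-off** force $F(t) = \tau_r(\sin 2\pi f_{r2} t + 1)$
  acting through the moment arm $l\sin\theta_h$; it propels the CoM.
* $\zeta_2(t) = \tau_l(\sin(2\pi f_{r1} t + \phi) + 1)$ — the stance leg's
  own plantar-flexor torque, which **opposes** progression. Its premature
  activation (the phase offset $\phi$) is the pathological ingredient.

Both frequencies default to 1 Hz. A **freeze** is the absence of forward
progression: the first time $\omega$ crosses zero from below while
$\theta > \theta_{reset}$, the leg has stalled mid-stance and gravity then
pulls it backward. The companion biped model adds a swing leg
($\ddot\theta_2 = -(g - l\omega_1^2)\theta_2/l$, reset to a constant rate
$\omega_2^0$ at each strike, guard $\theta_1 + \theta_2 = 0$ with
$\theta_1 < 0$); its stance dynamics are identical, which is the rationale
for analysing the reduced pendulum. The unforced full two-link field
(`biped_field()`) is also provided and is checked in the test suite against
an independently derived Lagrangian formulation; there $\theta_2$ is the
swing angle relative to the stance leg while $\omega_2$ is the swing leg's
absolute spin rate.

## Parameters that matter

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `tau_l` | N m | 0 | opposing stance-leg plantar-flexor amplitude |
| `tau_r` | N | 0 | ankle push-off amplitude |
| `phi` | rad | 0 | phase of the opposing torque (premature activation) |
| `theta_reset` | rad | −0.1 | heel-strike angle; step length is $|\theta_{reset}|$ |
| `theta_h` | rad | `2*abs(theta_reset)` | hip angle; collision dissipation |
| `l` | m | 0.6 | leg length |
| `m1 * l^2` | N m s² | 1 | inertia scale dividing the muscle torques |
| `fr1`, `fr2` | Hz | 1 | forcing frequencies |
| `clock` | — | `"step"` | forcing clock restarts at each heel strike |

Three of these deserve comment.

**The hip angle.** No closed formula ties $\theta_h$ to the rest of the
geometry, so the default uses the isosceles-triangle picture of two
equal-length legs at heel strike: $\theta_h = 2|\theta_{reset}|$. With
$l = 0.6$ m and $\theta_{reset} = -0.1$ rad this makes the peak push-off
torque $2 l \sin\theta_h = 0.238$ N m per unit $\tau_r$ — the factor of
roughly $0.23\,\tau_r$ (against exactly $2\,\tau_l$ in the opposing
direction) that fixes the relative strength of the two muscle groups. The
default is configurable and is deliberately decoupled as soon as the user
sets `theta_h` explicitly.

**The forcing clock.** The push-off is assumed in phase with the heel
strike, so by default the forcing time restarts at every strike. This is
what makes successive stance phases iterates of a single autonomous
one-dimensional map (below); a global-clock mode is kept for sensitivity
checks.

**The inertia scale.** Torques enter the dynamics only through
$\Gamma = (\zeta_2 - \zeta_1)/(m_1 l^2)$, so the body mass is a single
multiplicative knob. The default normalisation $m_1 l^2 = 1$ makes torques
and angular accelerations numerically equal, which is convenient for
reasoning but leaves absolute timing (freeze onset times, bifurcation
locations) uncalibrated. `calibration_sweep()` resolves the scale by
grid-searching $m_1 l^2$ (optionally jointly with $l$) against a known
outcome, reporting every candidate and its residual. Its default grid,
`seq(15, 40, by = 2.5)` N m s², spans the physiological range — body masses
of roughly 40–110 kg at leg lengths near 0.6 m. Calibrating against the
period-doubling accumulation point of the canonical bifurcation experiment
(`gait_fixture("fig9")`) selects $m_1 l^2 = 25$ at $l = 0.6$ m, i.e. a
body mass of about 70 kg — a reassuringly human number, and the scale used
throughout the examples below.

## The stride return map

Because the stance ODE is linear with sinusoidal-plus-constant forcing, the
flow is available in closed form (`flow_theta()`, `flow_omega()`): a
$\cosh/\sinh$ homogeneous part with $k = \sqrt{g/l}$ plus one particular
sinusoid per forcing term, amplitude $-a/(\nu^2 + k^2)$, and a constant
offset $-C/k^2$. The coefficients are re-derived from the forcing
definitions and validated against numeric integration to $10^{-8}$; the
resonance denominator $\nu^2 + k^2$ is strictly positive, so the particular
form never degenerates. The analytic flow matters because the bifurcation
structure of the map depends on event times located far more precisely than
a discretised trajectory would allow.

At fixed step length ($\theta_n = |\theta_{reset}|$ for all $n$) one step is
summarised by the **stride return map**

$$\omega_{n+1} = \tilde f_\omega(\omega_n) =
  f_\omega\!\big(\tilde T(\omega_n)\big)\cos\theta_h,$$

where the reset time $\tilde T$ is the first positive root of
$f_\theta(t) = \theta_{reset}$. `stride_step()` scans the flow forward in
~2.4 ms chunks for the first event — either that crossing or an upward zero
crossing of $\omega$ (freeze) — brackets it, and refines with Newton's
method seeded from the bracket midpoint (the analytic $\omega$ is the exact
derivative), falling back to bisection; the accepted root satisfies
$|f_\theta(\tilde T) - \theta_{reset}| \le 10^{-10}$. The first positive
root is the physical choice: it is the moment the swing heel actually meets
the ground. FREEZE is an explicit map value (`NA`), not an error, so
iteration, tabulation and plotting handle it uniformly.

Without forcing the map is exactly $\omega \mapsto \omega\cos\theta_h$ for
$|\omega| > k\theta_0$ and FREEZE otherwise — the package's sharpest
internal oracle: energy $E = \omega^2 - k^2\theta^2$ is conserved along the
flow, and a step completes iff $E > 0$. The test suite checks the map
against this identity to $10^{-9}$, and checks ten-step map iterates
against the full event-located hybrid simulation to $10^{-7}$ — two
independent routes (closed form + Newton vs `lsodar` root finding) to the
same trajectory.

## Orbits, bifurcations, chaos

`find_periodic_orbits()` locates period-$p$ orbits as roots of
$\tilde f_\omega^{\,p}(\omega) - \omega$ on a dense scan grid (2000 points
by default) with bisection refinement. Dense bracketing is essential: the
map is piecewise-smooth with genuine discontinuities where the first reset
crossing jumps between branches, and a sign change across a discontinuity
is not a root — refined candidates are accepted only if the residual is
below $10^{-8}$. Roots whose minimal period divides $p$ are filtered out,
orbit points are grouped, and each orbit is labelled with its multiplier
$\big|\mathrm d\tilde f_\omega^{\,p}/\mathrm d\omega\big|$ (central
difference, $h = 10^{-5}$): stable below 1, unstable above.

`bifurcation_diagram()` follows the published procedure: 500 iterations per
grid point from a fixed initial velocity (no continuation warm start), the
last 50 retained, the attractor classified by minimal recurrence within
$10^{-5}$. A point with no recurring period up to 64 is labelled *chaotic*
only when the map-iterate Lyapunov estimate (mean $\log|\tilde f_\omega'|$
over the kept iterates) is positive — this makes the visual label testable —
and *aperiodic* otherwise.

`feigenbaum_estimate()` turns the period-doubling cascade into a number: it
marches the parameter through the window, brackets each onset where the
detected period doubles by bisection, and extrapolates the geometric
accumulation $\phi_\infty = \phi_m + (\phi_m - \phi_{m-1})/(\hat\delta - 1)$
with $\hat\delta$ estimated from the last onset spacings (the universal
4.669 when only two onsets resolve). The estimator is validated on the
logistic map, where it recovers the accumulation at $r_\infty = 3.5699$ to
better than $10^{-2}$, before being applied to the stride map:

```{r feigenbaum, eval = FALSE}
p9 <- set_inertia(gait_params(tau_l = 5, tau_r = 35), 25)
feigenbaum_point(p9, omega0 = -0.433)
#> $onsets
#> [1] -0.8124 -1.2437 -1.3442 -1.3603
#> $accumulation
#> [1] -1.3634
```

The cascade sits in $\phi \in (-5\pi/8, -\pi/4)$, wedged between the
periodic walking regime and the freezing regime, with the accumulation near
$\phi = -1.36$ rad at the calibrated scale. Past it, the low-velocity
dynamics are chaotic; a stable period-3 window (the package's implemented
chaos indicator, via `find_periodic_orbits(p, 3, ...)` and
`fixed_point_contour(..., period = 3)`) certifies orbits of all periods.
No formal horseshoe or symbolic-dynamics construction is attempted.

## Simulation, freezing, and the walk-time map

`simulate_gait()` integrates the hybrid system with `deSolve::lsodar`,
whose internal root finding locates the guard surface independently of the
output sampling grid (default 1 ms). Tolerances are $10^{-9}$ relative and
$10^{-11}$ absolute. Freeze detection is primary on the
$\omega = 0$ upcrossing; a per-step timeout of 5 s — more than three times
the longest physiological stance — is a backstop for non-progression
without a crossing. The biped applies the same criterion to
$(\theta_1, \omega_1)$. Guard roots are accepted for the biped only when
$\theta_1 < 0$ (the reset maps the guard surface onto itself, so every
stance phase starts on it; spurious crossings with $\theta_1 \ge 0$ are
stepped past).

`walk_time_before_freeze()` reports the time of the last heel strike before
the freezing event within an observation window (10 s in the canonical
heatmaps); runs that never freeze report the full window, and 9 s or more
of walking marks a non-freezing parameter combination.
`freeze_time_heatmap()` tabulates this over a $\tau_l \times \tau_r$ grid:
sustained walking requires enough push-off to balance both collision
dissipation and the opposing torque, so the walkable region climbs to
higher $\tau_r$ as $\tau_l$ grows.

The boundary-value module asks the complementary question: fixing
$\theta(0) = 0$ and $\theta(0.5\,\mathrm s) = -0.1$ rad, what initial speed
is needed, and how much speed does the step add? For the pendulum,
$\theta(t_{end})$ is affine in $\omega(0)$, so two closed-form evaluations
solve the BVP exactly; the biped uses secant shooting on integrated
trajectories (boundary residual $\le 10^{-8}$, verified by
re-integration). Trajectories that would cross the reset angle inside the
window are flagged invalid rather than silently continued through a
collision. The reported `gain` is $|\omega(0)| - |\omega(t_{end})|$;
unforced it is negative (gravity adds speed), and the speed *added*,
its negative, falls with $\tau_l$ and rises with $\tau_r$ — the energetic
reading of the freezing map.

## What the canonical experiments do and do not show

The preset registry (`gait_fixture()`) pins the parameter sets of the
published demonstration experiments: the biped freeze
(`fig5`: $\tau_l = 2.3$ N m, $\tau_r = 15.74$ N, $\phi = -\pi/2$), the
pendulum freeze (`fig7`: $\tau_l = 2$, $\tau_r = 11$, $\omega_0 = -1$),
the walk-time heatmaps, the BVP contours, and the $\phi$ bifurcation
diagram (`fig9`: $\tau_l = 5$, $\tau_r = 35$, $\omega_0 = -0.433$). Where a
preset has a printed outcome (the accumulation at $-1.37$ rad; freezing
after 18 s) it is stored as `known` and doubles as the calibration
reference.

Two honest caveats. First, the inertia scale and leg length behind the
published demonstrations are not recoverable from the model structure, so
absolute-time outcomes are reproduced *after* calibration, with the chosen
scale and residual always reported: the bifurcation experiment calibrates
to $m_1 l^2 = 25$ at $l = 0.6$ (accumulation $-1.363$, residual
$0.007$ rad), while the pendulum freeze-time experiment is best matched in
the same physiological box at $l = 0.45$–$0.5$ m (onset 17.4–18.8 s against
the printed 18 s); no single $(l, m_1 l^2)$ pair reproduces both absolute
times at once, which is itself informative about how strongly the freeze
clock depends on geometry. Second, these are deterministic, small-angle,
sagittal-plane models with prescribed muscle envelopes: no neural feedback,
no noise, no double-support dynamics, no ground-reaction forces, and a
constant step length in the reduced model. Passing tests certify the
mathematics of this idealisation — the hybrid integration, the map algebra,
the bifurcation structure — not fidelity to any individual patient's gait.
The model's claim is qualitative: opposing plantar-flexor drives suffice to
produce slowing, shortening steps, variability via a period-doubling route
to chaos, and freezing, in the configurations where patients show them.

## Numerical choices, in one place

* Integration: `lsodar`, rtol $10^{-9}$, atol $10^{-11}$; event location
  independent of the 1 ms output grid.
* Map events: chunked scan at ~2.4 ms, Newton refinement to
  $|f_\theta - \theta_{reset}| \le 10^{-10}$, bisection fallback.
* Orbit scans: 2000-point bracketing grid; discontinuity roots rejected at
  residual $> 10^{-8}$; multipliers by central difference, $h = 10^{-5}$.
* Period classification: 500 iterations, last 50 kept, recurrence
  tolerance $10^{-5}$, periods up to 64; chaos requires a positive
  Lyapunov estimate.
* Per-step timeout 5 s; heatmap window 10 s; heatmap simulations may use a
  coarser 10 ms output grid (event location is unaffected).
* Problem sizes in the shipped tests and acceptance script: 50 random
  parameter sets for flow validation, 20 for map/simulation consistency,
  11 calibration candidates for the bifurcation experiment and 44 for the
  freeze-time experiment, 400-point $\phi$ grids for full diagrams —
  sizes at which every result here reproduces in a few minutes on one core.
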