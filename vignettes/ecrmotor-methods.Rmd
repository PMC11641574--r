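---
title: "Methods: mesoscale simulation of enzyme-cascade-powered Janus nanomotors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mesoscale simulation of enzyme-cascade-powered Janus nanomotors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrmotor)
```

## The model

`ecrmotor` simulates a chemically powered Janus colloid in a coarse-grained,
momentum-conserving solvent. The colloid carries two enzymes arranged in a
cascade: the inner sphere (radius $R_1$) has an inert hemisphere of E0 beads
and a catalytic hemisphere of E1 beads, and an outer hemispherical shell
(radius $R_2$) over the E1 side carries beads of a second enzyme E2 at an
adjustable area coverage $\phi$. The solvent is a bath of point particles of
three interconvertible species: fuel A, intermediate I and product B.

Three coupled pieces of physics drive the motor:

* **Surface cascade.** A fuel particle colliding with the catalytic
  hemisphere converts, $A + E1 \to I + E1$; an intermediate colliding with
  the outer shell converts again, $I + E2 \to B + E2$. Far from the motor,
  I and B regenerate into A with first-order rates $k_{bI}$, $k_{bB}$,
  which maintains the nonequilibrium steady state that propulsion requires.
* **Unequal surface interactions.** Solvent species $\alpha$ interacts with
  bead species $\beta$ through a purely repulsive shifted-truncated
  Lennard-Jones (WCA) potential
  $V_{\alpha\beta}(r) = 4\epsilon_{\alpha\beta}\left[(\sigma/r)^{12} -
  (\sigma/r)^6 + \tfrac14\right]\Theta(r_c - r)$, $r_c = 2^{1/6}\sigma$,
  with $\sigma$ the bead-class size parameter ($\sigma_1$ for E0/E1,
  $\sigma_2$ for E2). The default well depths satisfy
  $\epsilon_{I\beta} = \epsilon_{BE0} = \epsilon_{BE1} = \epsilon_{AE2} = 5.0
  > \epsilon_{AE0} = \epsilon_{AE1} = 0.2 > \epsilon_{BE2} = 0.1$: the
  species a surface produces is repelled from it more strongly than the
  species it consumes. The reaction-generated concentration gradients then
  exert a net force — self-diffusiophoresis. With all well depths equal, the
  mean axial velocity is statistically zero (the package's null control).
* **Mesoscale hydrodynamics.** Between collisions with the motor, solvent
  particles stream ballistically; every $t_{\mathrm{MPC}}$ they undergo
  multi-particle collision dynamics (stochastic rotation dynamics): particles
  are binned into a cubic lattice of cell size $a_0$, randomly shifted each
  step to restore Galilean invariance, and their velocities relative to the
  cell centre of mass are rotated by a fixed angle $\varphi$ about an
  independent random axis per cell. The rule conserves mass, momentum and
  kinetic energy per cell exactly, so hydrodynamic interactions and thermal
  fluctuations emerge correctly without a thermostat; the whole MD--MPC
  dynamics is microcanonical.

The observables mirror what one measures on such a motor: the axial velocity
$V_u = \mathbf{V}(t)\cdot\hat{u}$ (with $\hat{u}$ the unit vector from the
E1-hemisphere centre of mass to the E0-hemisphere centre of mass — positive
$V_u$ means the inert side leads), radial and angular concentration profiles
of A/I/B in the co-moving frame, azimuthally averaged flow fields, and the
coverage power law $V_u = A(R_2)\,\phi^4 + V_{u0}$ with
$A(R_2) = a - b\,R_2$ fitted across sweeps.

## Parameters

All quantities are in reduced units (energy $\epsilon$, mass $m_s$, length
$a_0$, $k_B = 1$). Reference defaults, all overridable through
`simulation_config()`:

| parameter | default | meaning |
|---|---|---|
| $L_x = L_y = L_z$ | 30 | periodic box edge |
| $n_s$ | 20 | solvent number density ($5.4\times10^5$ particles) |
| $T$ | 1/6 | temperature |
| $a_0$, $t_{\mathrm{MPC}}$, $\varphi$ | 1, 0.5, $\pi/2$ | MPC cell, interval, rotation angle |
| $t_{\mathrm{MD}}$ | 0.005 | MD step (100 per MPC collision) |
| $k_s$ | 60 | spring constant |
| $R_1$, $\sigma_1$, $N_{E0} = N_{E1}$ | 2.9, 0.3, 500 | inner shell |
| $N_{in}$, $m_{in}$, $m_{out}$, $m_2$ | 2681, 0.44, 1.50, 0.64 | masses |
| $R_2$, $\sigma_2$ | 4.2, 0.2 | outer shell |
| $\phi$ | 0--1 | E2 coverage, $N_{E2} = \phi\,2R_2^2/(2^{1/6}\sigma_2)^2$ (700 at $\phi=1$) |
| $k_{bI} = k_{bB}$ | 0.001 | bulk regeneration rates |

A note on the temperature: the closed-form MPC self-diffusion relation
$D = \frac{k_B T\, t_{\mathrm{MPC}}}{2 m_s}\left[\frac{3 n_s}{(n_s - 1 +
e^{-n_s})(1 - \cos\varphi)} - 1\right]$ evaluates to $D = 0.0899$ at these
solvent parameters only for $T = 1/6$; that value is therefore the package
default, and the package's first acceptance check certifies it.

The total motor mass follows from the printed per-particle masses
($M = 2679.64$ at $\phi = 0$). As a diagnostic, this is within 2.5% of the
neutral-buoyancy mass $\frac43 n_s \pi R^3$ evaluated at the effective
hydrodynamic radius $R \approx R_1 + \sigma_1$; the printed masses are used
verbatim rather than enforcing the buoyancy formula.

## Numerical design choices

**Bead placement.** Shell beads sit on deterministic Fibonacci (golden-angle)
lattices — reproducible geometry independent of the seed, near-uniform area
coverage. A fresh lattice of exactly $N_{E2}$ points is generated for each
coverage, so every $\phi$ yields a uniform shell (an index-ordered prefix of
one master lattice would concentrate near the pole and is deliberately not
used). `open_polar_cap()` instead carves an aperture at the shell pole from
an existing motor, for studying how an opening vents the confined
intermediates.

**Spring topology.** The motor must behave as a nearly rigid body at
$k_s = 60$. A purely local network (each particle bonded to a few nearest
neighbours) turns out to have floppy collective modes: in a thermalised
vacuum test the shell crumpled from $\langle r\rangle = R_1$ toward
$0.55\,R_1$ with total energy perfectly conserved. The package therefore
bonds each particle to its 10 nearest neighbours *and* to the 12 particles
nearest its reflection through the centre. These near-diametral struts act
as distributed spokes: they are the bonds whose axis projects onto the
radial direction, and stacking ~12 of them per particle raises the radial
stiffness to $\sim 700$, giving a per-bead radial RMS fluctuation of about
$0.007 \approx 2\%\,\sigma_1$ on the solvated desk-scale fixture (measured;
the package's rigidity test). Each E2 bead is additionally strutted to its 3
nearest inner beads so the outer shell co-moves, and the graph is repaired
to a single component if ever disconnected. Rest lengths equal build-time
separations, so the build geometry is the mechanical equilibrium.

**Reactions at exactly zero potential.** In continuous time a species flip
"on collision" happens at the cutoff, where the WCA potential is zero for
both old and new species, so the cascade is energy-neutral. With a finite
time step, crossing detection lands the particle slightly *inside* the
cutoff, where the old and new potentials differ by up to
$\mathcal{O}(10^{-2})$ per event — enough to heat the system measurably.
The engine therefore latches the reaction at the first inward crossing
(counting and any sub-unit reaction probability apply at that moment) and
materialises the species flip at the first instant the particle is outside
*every* bead cutoff, where the pair potential is exactly zero for both
species. Reactions then conserve energy and momentum to machine precision;
the measured drift with reactions on is indistinguishable from the
reactions-off drift. A particle inside a cutoff cannot re-react until it
leaves and re-enters, and a newly minted I can only convert at E2 through a
genuine subsequent crossing.

**Bulk regeneration** applies $p = 1 - e^{-k\,\Delta t}$ per MPC interval,
but only beyond an exclusion radius ($R_2 + \sigma_2 + r_c$ from the motor
centre by default), so regeneration flips also happen at exactly zero pair
potential.

**RNG streams.** One master seed derives four named substreams (geometry,
solvent initialisation, MPC shifts/axes, reactions), so toggling one
stochastic component leaves the others' draws untouched. Runs are
bit-reproducible from the seed, including across checkpoint/restart.

**Integrator resolution.** The stiffest motion is a WCA collision between
solvent and an E2 bead at $\epsilon = 5$: curvature at the cutoff gives
$\omega\,t_{\mathrm{MD}} \approx 0.7$ at the reference step. The consequence
is a slow $\mathrm{d}t^2$-convergent energy drift that grows with E2
coverage: at $\phi = 0$ the drift is $\sim 10^{-5}$ relative per $10^4$
steps, at $\phi = 0.8$ on the desk-scale fixture $\sim 4\times10^{-4}$. The
conservation acceptance test runs at the fixture default $\phi = 0$; a
separate regression test guards the $\phi = 0.8$ value at a $10^{-3}$
bound. Reducing $t_{\mathrm{MD}}$ tightens both quadratically.

**Field binning.** Angular bins are uniform in $\cos\theta$ (equal solid
angle), so a uniform gas is flat by construction; $\theta$ is measured from
$-\hat{u}$, the outer-shell pole. Radial bins are uniform in $r$ with
shell-volume normalisation; bins overlapping the motor body are flagged,
not dropped. Profiles are accumulated from minimum-image displacements
about the instantaneous motor centre. Flow fields subtract the motor
centre-of-mass velocity and azimuthally average into the
(axial, cylindrical-radial) plane; empty cells are reported as missing
rather than zero.

**Velocity statistics.** The first 20% of every run is discarded as burn-in.
Consecutive $V_u$ samples are autocorrelated over roughly the motor's
momentum relaxation time, so standard errors come from ~20 contiguous block
means rather than raw samples; sweeps pool block means across independent
seeds.

## Desk-scale fixtures

The reference box ($30^3$, $5.4\times10^5$ solvent particles, 20
realisations per data point) is a cluster-scale workload. The packaged
fixtures scale every *size* down while keeping every physical constant
(temperature, masses, time steps, interaction matrix, spring constant, MPC
parameters) at its reference value:

* `tiny` — box $12^3$, $n_s = 5$ (8640 solvent particles), motor
  $R_1 = 1.1$, $R_2 = 1.7$, $N_{E0} = N_{E1} = 80$, $N_{in} = 200$;
  the full loop runs in seconds per hundred cycles.
* `small` — box $16^3$, $n_s = 10$ (40960 particles), $R_1 = 2.0$,
  $R_2 = 2.9$, $N_{E0} = N_{E1} = 240$, $N_{in} = 880$.

The motor is shrunk with the box because the minimum-image convention
requires box $\geq 4(R_2 + \sigma_2)$; bead counts keep the areal bead
density of the shells near the reference. The test suite runs its
propulsion checks on the tiny fixture with runs of 150 time units and 2--3
seeds per condition — sizes chosen so the whole suite stays interactive.

What the fixtures do and do not show: they exercise every mechanism
(cascade, confinement by the E2 shell, diffusiophoretic propulsion,
hydrodynamic feedback) and reproduce the qualitative structure — near-zero
bare-Janus velocity at this scale, strongly increasing $V_u$ with coverage,
sign along $+\hat{u}$. They do not reproduce the reference-scale *numbers*:
the gap between shells is only ~2 bead diameters, periodic-image
hydrodynamic self-interaction is strong in a small box, and the thermal
velocity of the light motor is an order of magnitude above its drift, so
quantitative velocities, amplitudes and exponents at full scale are outside
what passing desk-scale tests demonstrate.

## Known limitations

* Surface reactions are probability-1 on crossing (exposed as
  `react_prob`), with no Michaelis--Menten saturation, reversibility or
  enzyme deactivation.
* Solvent particles are ideal between MPC collisions (no solvent--solvent
  excluded volume), the standard MPC trade-off; transport coefficients are
  those of the MPC fluid, not of water.
* Internal mass particles carry inertia only; solvent cannot reach them
  behind the dense bead shell, and no interaction is computed for them.
* The bead-spring body is nearly rigid but not exactly rigid; at
  temperatures or spring constants far from the defaults the network's
  fluctuation scale $\sqrt{T/k_{\mathrm{eff}}}$ should be rechecked against
  the bead size.
* The printed reference time step under-resolves the stiffest (A--E2)
  collisions; see the integrator note above.
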