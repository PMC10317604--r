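---
title: "Modelling passive capillary blood-plasma separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling passive capillary blood-plasma separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capilsep)
```

## The device and the modelling problem

A drop of whole blood (10 µl) is metered into a surface-patterned PDMS
chip: a shallow horizontal inlet channel (180 µm deep), a vertical
cylindrical well of 4 mm height whose upper 1 mm is left hydrophobic while
the rest is surfactant-coated, and a shallower outlet channel (100 µm) at
the top. Capillary pull and gravity drive the sample through the well; the
cells pile up at the hydrophobic band and act as their own filter, while
plasma continues to the outlet, where it is collected in a pipette tip.
The measurements available are a collected-volume time series (1, 2.3,
2.8, 3.5 µl at 3, 7, 9, 12 min) and pre/post cell-counter readings, from
which purity and recovery follow.

`capilsep` is a reduced-order, fully testable re-implementation of this
system: a quasi-one-dimensional capillary-network flow solver, a
finite-volume advection–diffusion solver for the plasma mass fraction on
the moving filled domain, a cell-retaining junction operator,
least-squares calibration of the model's free parameters against the
measured series, and the purity/recovery/goodness-of-fit metrics.

## Flow: quasi-steady Lucas–Washburn dynamics in a segment chain

The full problem is incompressible creeping flow with a moving meniscus.
Under the assumptions the device itself justifies — steady (quasi-static)
flow, constant density and surface tension, isothermal operation — the
momentum balance reduces to the lubrication (Poiseuille) limit in each
segment. The meniscus at arc position $x$ advances according to

$$\frac{dx}{dt} = \frac{Q}{A(x)}, \qquad
  Q = \max\!\left(0, \frac{\Delta P(x,t)}{R(x,t)}\right),$$

with driving pressure
$\Delta P = P_\mathrm{cap}(x) - \rho_l g\, \Delta h(x)$, where
$P_\mathrm{cap}$ is the Young–Laplace entry pressure of the segment the
meniscus occupies ($2\sigma\cos\theta/R$ for a cylindrical bore,
$2\sigma\cos\theta(1/w + 1/d)$ for a rectangular channel) and $\Delta h$
the vertical rise of the filled column. The wetted resistance $R$ sums
$8\mu L/(\pi R^4)$ and $12 \mu L / (w d^3(1 - 0.63\,d/w))$ over the filled
path. A hydrophobic segment contributes a negative entry pressure: passive
flow stops there, permanently, because nothing in the model raises the
driving pressure later. The metering pump is a displacement source; while
it runs, it caps the rate at its set point and forces the meniscus through
a stopped barrier (recorded as a stop event followed by a burst event).

The integrator is an adaptive explicit Heun scheme with an absolute
per-step position tolerance of $10^{-7}$ m, exact clamping at segment
boundaries (where entry conditions change discontinuously), and a 1 µm
minimum wetted length regularising the $t = 0$ Washburn singularity. The
test suite checks the solver against the closed-form parallel-plate
Washburn law $x(t) = \sqrt{\sigma \cos\theta\, d\, t/(3\mu)}$ to within
1%, volume–flux continuity to $10^{-6}$, step-halving convergence to
0.1%, and the monotone approach to the Jurin equilibrium height in a
vertical capillary.

## Effective viscosity: the creeping-flow rheology choice

Two viscosity decisions matter and both are deliberately visible in the
configuration objects.

First, the *base* viscosity. At the flow rates this chip sustains
(< 1 µl/min), shear rates are far below 1 s⁻¹. Whole blood in that regime
is not a 3–4 mPa·s fluid: rouleaux formation and incipient coagulation
raise its apparent viscosity by two to three orders of magnitude. With the
handbook high-shear value the model fills the chip in seconds and passes
hundreds of µl per minute — three orders of magnitude off the measured
12-minute timescale, which no coagulation time constant can repair because
the supply cap then dominates and the predicted collection curve becomes
linear. The package therefore defaults to an effective low-shear viscosity
$\mu_l = 0.35$ Pa·s. It is a config-overridable scalar, flagged as a
rheological modelling choice, not a measured property.

Second, the *slowdown*. The observed collection rate decays over the run;
the device's authors attribute this to progressive coagulation. The
package models it as a single-exponential growth of the effective
viscosity, $\mu(t) = \mu_l e^{t/\tau_c}$, the simplest monotone law with
one interpretable parameter, the coagulation time constant $\tau_c$
(seconds; `Inf` disables it). The functional form is a package decision;
$\tau_c$ is a calibration parameter, not an assumed constant.

## Transport: binary advection–diffusion on the moving domain

The multicomponent Fickian flux model reduces exactly, for two species at
constant temperature (the isothermal assumption removes the thermal-
diffusion term) and a single effective diffusivity, to a binary
advection–diffusion equation for the plasma mass fraction
$\omega$:

$$\frac{\partial(\rho_l \omega)}{\partial t}
  + \nabla\!\cdot j + \rho_l (v \cdot \nabla)\,\omega = 0,
  \qquad j = -\rho_l D^f \nabla \omega .$$

The moving filled domain $[0, x_\mathrm{front}(t)]$ is mapped onto a fixed
reference grid by a uniform stretch — the one-dimensional reduction of the
Laplace mesh-motion equation with a pinned inlet and a meniscus-following
outlet, so every node moves at a velocity proportional to its reference
coordinate. The discretisation is finite-volume with implicit (backward)
time stepping, first-order upwind advection, central diffusion, and the
arbitrary Lagrangian–Eulerian flux correction computed from *exact* face
sweep volumes, which makes uniform fields invariant under pure mesh motion
even across changes of cross-section. Implicitness and upwinding give
unconditional stability and a discrete maximum principle; species are
carried as per-cell masses, so conservation is exact up to the tridiagonal
solve (verified to $10^{-8}$ and better). The meniscus face carries zero
relative and zero diffusive flux; an open inlet feeds sample at the feed
composition through a ghost cell.

Cells are treated as a dissolved species. The hydrophobic junction is a
flux partition: the advective and diffusive flux of species $s$ across the
junction face is multiplied by its transmission $\varepsilon_s$ (plasma
passes freely, $\varepsilon = 1$); blocked mass simply stays in the cell
against the barrier. Two consequences are worth stating plainly. The
retained mass concentrates into a cake whose concentration grows until
$\varepsilon\,c_\mathrm{cake}$ balances the feed flux, after which cells
break through — the steady transmitted-to-upstream concentration ratio
equals $\varepsilon$ only while the upstream composition is held fixed
(the well-mixed condition under which that property is tested). And
because the partition acts on species mass while the volumetric flux is
common, plasma partial density is never *enriched* anywhere: collected
plasma flux is the feed plasma fraction times the volumetric rate. Purity
replication therefore uses the measured count table directly, which is
also what the headline purity figure is defined on.

## Time origin, priming, and collection accounting

Collected plasma is the cumulative plasma mass that has crossed the entry
face of the outlet segment, divided by the liquid density — the model
equivalent of the pipette-tip collection point. The replication runs start
from a *primed* device (fully wetted chip; time zero is the moment
separated liquid first stands at the collection point), because the
measured series already shows 1 µl collected at 3 min: a dry chip fed at
the 0.8 µl/min metering rate cannot deliver that through the chip dead
volume, so the loading phase must precede the reported clock. The dry
(filling) mode remains a first-class simulation path and carries the
stop/burst event physics; it is exercised by the solver tests.

The inlet is idealised as a continuously wetted reservoir: no receding
rear meniscus or drainage phase is modelled. This is valid while the
cumulative draw stays below the injected 10 µl; the calibrated model draws
≈ 10 µl as $t \to \infty$, so the idealisation holds over the whole
simulated range and the collected-volume asymptote equals the plasma
content of the injected sample to within a fraction of a percent.

## Geometry defaults

Channel depths (180/100 µm), the well height (4 mm), the hydrophobic band
(1 mm), the injected volume, pump rate, and hematocrit are the device's
stated values. The planar widths, channel lengths and well bore are not
stated anywhere; `default_chip()` fixes them once at fabrication-typical
values (inlet 1 mm × 5 mm, well radius 0.25 mm, outlet 0.5 mm × 8.5 mm)
chosen so that the filled chip's nominal hydraulic conductance reproduces
the measured early-time collection rate (≈ 0.43 µl/min) — a standard
conductance-matching design step, done once, using only the printed
series. Contact angles default to 40° on coated zones, 110° on the band,
100° on native PDMS; they are calibration parameters with these starting
values.

## Calibration and extrapolation

`calibrate()` minimises the mean squared error between modelled and
observed collected volumes (monotone piecewise-linear interpolation to the
observation times) by bounded derivative-free local search from a fixed
documented start: Nelder–Mead on a logistic box transform (log-scaled for
$\tau_c$ and $D^f$), or Brent line search when one parameter is free.
Everything is deterministic. Goodness of fit is reported as both the
coefficient of determination
$R^2 = \left[\sum_i (x_{i,\mathrm{exp}} - \bar x)^2 - \sum_i
(x_{i,\mathrm{exp}} - x_{i,\mathrm{model}})^2\right] / \sum_i
(x_{i,\mathrm{exp}} - \bar x)^2$ and the mean squared error
$\sum_i (x_{i,\mathrm{exp}} - x_{i,\mathrm{model}})^2 / N$.

In replication mode the free pair is $\{\tau_c, D^f\}$. One identifiability
fact falls out of the transport closure and is stated rather than hidden:
because the junction never enriches plasma partial density, the
collected-volume curve is insensitive to $D^f$, so the objective is flat
along that direction and only $\tau_c$ is effectively identified from a
volume series. The parameter-recovery properties are therefore
demonstrated on an identifiable pair ($\tau_c$ plus the hydrophilic
contact angle); the replication keeps the $\{\tau_c, D^f\}$ convention,
and the cell transmission $\varepsilon$ is fitted analytically from the
red-cell counts ($\varepsilon = \mathrm{output}/\mathrm{input}$), which
constrains it independently of the time series.

`extrapolate_completion()` runs the calibrated model forward and reports
the first time the collected volume reaches a stated fraction of the
available plasma (injected volume × plasma fraction; the rounded-
hematocrit convention, 0.399 → 0.40, is the default as in the headline
recovery figure). Crossing times are located by linear interpolation
between steps. Non-attainment within the 500-minute cap returns an
explicit `NA` sentinel, never a fabricated time. Note a near-degeneracy
that any user of this number should know: the measured series itself
extrapolates to almost exactly the available plasma volume, so the
99.9%-completion time sits on a flat part of the curve and is sensitive at
the tens-of-minutes level to sub-percent changes in the calibrated
asymptote. The package reports ≈ 108 min for the default calibration; the
device's own full-CFD study quoted 88 min from an unpublished
configuration, and only the order of magnitude is comparable.

## Numerical resolutions and runtimes

Reporting resolution defaults to 200 cells and 0.1 s steps; the
calibration objective uses 120 cells and 1 s steps, which passes the 1%
grid- and step-halving convergence checks for the reference chip and keeps
a full calibration in the seconds-to-minutes range on one core. The
quasi-steady rate inside the coupled driver is evaluated at mid-step
(midpoint rule); with the exponential viscosity law this matters — the
collected-volume asymptote is first-order sensitive to the quadrature —
and it is what makes the closed-form crossing-time oracle hold to within
one step.

## The synthetic-data generator

`generate_series()` runs the forward model at ground-truth parameters,
samples the observation times, adds zero-truncated Gaussian measurement
noise (default SD 0.1 µl, the reading precision of a 0.1–10 µl
micropipette), and restores monotonicity by isotonic projection.
`generate_counts()` Poisson-samples input and transmitted counts on a
counted aliquot. Both are driven by a single integer seed stamped into the
outputs. The generator emulates the *statistical shape* of the two
measured tables — a saturating recovery curve with additive noise, and
counter shot noise — and nothing else: it inherits every idealisation of
the forward model (primed start, unlimited-reservoir feed, dissolved-
species cells, single-exponential slowdown), so tests that pass on
synthetic data validate the pipeline's internal consistency, not the
model's fidelity to real blood.

## Known limitations

Velocity profiles, meniscus shape, contact-angle hysteresis and 2-D
concentration fields are out of scope by design. Cell sedimentation,
deformability, hemolysis and clot microstructure are not modelled; the
cake consequently saturates instead of clogging. The effective low-shear
viscosity and the exponential slowdown are phenomenological stand-ins for
blood's actual thixotropic rheology. The purity computed for HGB and HCT
rows is flagged unit-ambiguous (those table rows are not particle counts).
All of these are visible in the configuration surface rather than baked
in, so each can be tightened independently.
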