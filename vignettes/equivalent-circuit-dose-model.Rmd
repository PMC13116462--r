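---
title: "An equivalent-circuit dose model of discharge-plasma cell death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An equivalent-circuit dose model of discharge-plasma cell death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmadose)
```

## The physical system and the model

A microdischarge plasma is struck between a high-voltage needle and the
surface of a small buffer droplet covering a confluent cell monolayer at the
bottom of a 96-well plate (well diameter 6.4 mm) standing on a grounded
copper plate. The drive is sinusoidal, 20 kHz at 20 kV peak-to-peak, applied
for 2–100 ms. After treatment, dead cells form a circular zone around the
well centre; the radius of that circle grows with treatment duration, and
approximately linearly in the logarithm of the duration.

`plasmadose` asks the quantitative question behind that observation: what
electrical dose does a cell at radius $r$ receive, and what dose rule
predicts the observed death radius as a function of treatment duration?

The well contents are modelled as an axisymmetric RC network. The domain is
divided into 40 concentric annular regions with non-uniform widths
($\Delta r = R/128$ for regions 1–4 and 37–40, $R/64$ for 5–6 and 35–36,
$R/32$ for 7–34; the widths sum exactly to $R$). Each region carries a
vertical ladder from the liquid surface to ground:

* buffer layer (height 0.1 mm, conductivity 0.172 S/m): resistive,
  $R = H_s/(\sigma_s A_n)$;
* plasma membrane (7.5 nm): capacitive, parallel-plate
  $C = \varepsilon_m A_n / T_m$, on both faces of the cell layer;
* cytoplasm (10 µm, $\sigma_c = 1$ S/m, $\varepsilon_c = 30\varepsilon_0$):
  resistance in parallel with capacitance;
* dish bottom (1.5 mm, $\varepsilon_d = 2.4\varepsilon_0$): capacitive,
  terminated at the grounded plate.

Adjacent regions are linked radially inside the two conducting layers
(buffer and cytoplasm) by annular resistances
$\ln(r_{n+1}/r_n) / (2\pi\sigma H)$ between region centres — exact for
purely radial flow through an annular shell. The plasma channel is treated
as a perfect conductor, so an ideal source pins the buffer-top node of
region 1; the buffer-top nodes of all other regions face insulating air.
This ladder-plus-radial-links topology is a reconstruction: the detailed
circuit used in the original analyses of this system was not published, and
the reconstruction is constrained by the layer list, the source-attachment
description, and the requirement that cytoplasm current has both radial and
vertical components.

The membrane permittivity is not part of the published parameter table; the
default $\varepsilon_m = 5\varepsilon_0$ (typical lipid-bilayer range 2–7)
is an explicit, configurable choice (`material_config()`), and membrane
conductivity defaults to 0 (an intact membrane is an ideal dielectric at
this scale). Everything is computed in strict SI internally; millimetres,
milliseconds, µW/mm³ and µJ/mm³ appear only at I/O boundaries.

## Solving the network

`solve_phasor()` performs complex nodal analysis at the drive frequency
(signals $x(t) = X\sin(\omega t + \varphi)$ are phasors
$X e^{i\varphi}$; admittances $1/R$ and $i\omega C$). The element values
span roughly fifteen orders of magnitude (sub-femtofarad dish capacitances
against sub-kilohm cytoplasm resistances), so the dense solve is followed by
one step of iterative refinement, after which the Kirchhoff-current-law
residual at every internal node is below $10^{-9}$ of the source current.

`solve_transient()` is a deliberately independent oracle: trapezoidal
(A-stable, second-order) time integration from a fully discharged initial
state. After the start-up transient decays — the network's slowest time
constants (membrane charging through the buffer) are microseconds, far below
the 2 ms minimum treatment — its per-cycle waveforms must match the phasor
solution; the test suite and the acceptance script verify agreement on all
cytoplasm branch currents to well within 1 % (measured ≈ 0.02 %).
`power_audit()` closes the loop: the time-averaged source power
$\tfrac12\mathrm{Re}(V\bar I)$ equals the total resistive dissipation
$\sum \tfrac12|I|^2R$ to within 0.1 % (measured ≈ $3\times10^{-7}$
relative), and capacitors average to zero.

Because the start-up transient is negligible on treatment timescales, dose
accumulation uses the steady-state waveform from $t = 0$. Users who want to
quantify the transient's contribution can integrate the transient solution
directly (`transient_branch_currents()`); `export_netlist()` additionally
writes a SPICE netlist so the whole network can be re-run in any SPICE-class
simulator as an external check.

## From currents to dose

The damaging quantity is the current density through the cytoplasm.
Per region, the vertical component is the total vertical cytoplasm branch
current divided by the annulus area; the radial component averages the
densities at the region's two cylindrical boundaries (radial link current
over $2\pi r H_c$; the axis and the wall carry none). The instantaneous
power density is $p(r,t) = J(r,t)^2/\sigma_c$ with
$J^2 = J_r^2 + J_z^2$, and the injected energy density is
$w(r) = \int_0^{T_p} p\,\mathrm dt$. Since $p$ is periodic at twice the
drive frequency, all accumulation arithmetic works on one sampled
steady-state cycle (1024 samples per cycle by default; gating-time
quantisation is then below $10^{-3}$ of a cycle) plus exact whole-cycle
counting — this is what makes grid-search fitting affordable.

### Shape of the dose field

Two features of the solved field matter downstream and are asserted as
regression properties in the tests:

* The cycle-averaged power density **rises** over the first four to five
  annuli (within ~0.15 mm of the axis) before decaying strictly outward.
  This is intrinsic to a central point injection spreading toward a
  distributed capacitive sink: the lumped radial current density scales
  like $r$ near the axis. Time-to-death in that core is tens of
  microseconds — three orders below the shortest treatment — so the core
  never hosts the death front at experimental durations.
* Beyond the core, the dose is dominated by the radial sheet current in the
  buffer and cytoplasm. Its logarithmic decay rate is not constant: it
  slackens toward mid-well (the $1/r$ spreading term fades) and steepens
  sharply near the wall (the no-flux boundary extinguishes radial current).
  The death-radius curves inherit this structure; in particular the
  one-step radius-versus-log-duration curve has an inflection where the
  front crosses mid-well, rather than a single curvature sign across the
  full well.

## The two death models

Both models threshold dose accumulation per region and are represented by
one parameter object, `death_model(pth, wth, model)`:

* **One-Step**: a cell dies at the first time $t$ where
  $w(r, t) \ge W_{th}$.
* **Two-Step**: energy accumulates only while the instantaneous power
  density exceeds a gate, $w(r,t) = \int_0^t p\,H(p - P_{th})\,\mathrm dt'$
  with $H(0) = 1$ (a sample exactly at the gate counts), and death occurs
  when this gated accumulation reaches $W_{th}$.

One-Step is exactly Two-Step with $P_{th} = 0$; the implementation shares a
single code path, so the reduction holds bit for bit (asserted in the
acceptance suite). The gate operates on the sampled instantaneous waveform,
not on cycle averages. Two structural consequences are tested: the
time-to-death is monotone in both thresholds, and the Two-Step death radius
can never exceed the outermost region whose *peak* instantaneous power
reaches the gate — raising the gate pulls that saturation radius inward,
which is what produces the late-time plateau characteristic of the
Two-Step model.

### Inverting time-to-death into a death radius

`death_radius()` computes the per-region crossing time $T^*(r)$ and locates
the radius where it crosses the treatment duration, by linear interpolation
of $T^*$ between the centre radii of the bracketing regions (a
nearest-region mode is available). Because of the near-axis dose rise, the
front is defined as the **outermost** region with $T^* \le T_p$; the
function then insists every region inside the front is also dead (the model
predicts a dead disc) and raises an error otherwise. With the default
configuration that error can only trigger at sub-millisecond durations or
extreme thresholds. Censoring (no death anywhere) and saturation (death
reaches the wall) are explicit flags, never sentinel numbers. When the
region beyond the front never dies (its gate stays closed), there is no
finite bracket to interpolate in and the front is reported at the last
dying region's centre.

During grid-search fitting, parameter combinations whose predictions
violate the dead-disc premise are excluded by an infinite objective rather
than aborting the search. The effective-gate estimator (below) inverts the
outer front and tolerates a gated-out core: probing gate values above the
innermost annulus' peak power (but below the interior maximum) switches
that annulus off while cells beyond it still die, and the observable
death-circle boundary is the outer front regardless — the core gap is below
the spatial resolution of the radius measurements the model is compared to.

## Fitting the thresholds

`fit_thresholds()` is an exhaustive grid search scored by the equal-weight
sum of squared residuals between model radii and per-duration mean radii
(mm²), evaluated at the dataset's durations, followed by one local
refinement at 5× resolution around the coarse argmin. Residuals on radii
are agnostic to the time-axis scale, and the log-spacing of the standard
duration grid already weights the short-duration decades; a least-squares
objective on radii therefore serves both the linear- and log-axis views of
the data. Replicate standard deviations are carried for reporting, not
weighting. Ties break toward the smallest gate, then the smallest energy
threshold, so results are deterministic; an all-censored optimum (possible
only for degenerate data such as all-zero radii) is reported at the energy
grid's maximum — the most conservative representative of the zero-death
ridge — and flagged `degenerate`. The default grids
($P_{th} \in [0, 20]$ µW/mm³ by 0.5; $W_{th} \in [0.05, 1]$ µJ/mm³ by
0.05) bracket the threshold scale at which such assays are conventionally
reported.

### Designing the recovery validation

The synthetic-data closure test ("generate with known thresholds, fit, and
recover them") needs its truth placed where the data constrain both
parameters, which depends on the dose field. Two facts decide the design:

* A parameter is resolvable only where the curve responds to it. The gate
  $P_{th}$ is identified by the late-time plateau at the saturation radius
  and by the gating inflation of crossing times near the gate edge; with
  this field's dose scale, gates of a few µW/mm³ put that edge into the
  steep wall zone where the plateau barely moves and recovery of $P_{th}$
  is not meaningful at any useful resolution.
* With replicate noise of SD 0.02 mm and $n = 4$ wells (standard error
  0.01 mm per duration), the local slope of the radius with respect to each
  threshold converts that uncertainty into a parameter resolution; the
  validation grids are sized so that one refined-grid step is comparable to
  that resolution.

The shipped validation therefore generates Two-Step data at
$P_{th} = 2500$ µW/mm³, $W_{th} = 10$ µJ/mm³ — the gate edge then sits
mid-well (≈ 1.55 mm) and the plateau spans the four longest durations —
and fits on grids $[0, 5000]$ by 500 and $[2, 30]$ by 2, requiring recovery
within one refined step (100 / 0.4) in at least 90 % of 20 seeds.
Noiseless data generated at the conventional reporting-scale point
(7.0 µW/mm³, 0.3 µJ/mm³) on the default grid is recovered exactly, with a
zero objective, closing the pipeline loop at that scale too.

## The effective gate at short durations

Real data show smaller death radii at the shortest treatments than a
constant-gate Two-Step model predicts — as if cells tolerate brief, intense
stimuli. `effective_pth()` quantifies this: for each duration at or below
10 ms it solves, by bisection (tolerance 0.5 % of the bracket width), for
the gate value that makes the Two-Step death radius match the observed
mean radius at the fixed $W_{th}$. The death radius is nonincreasing in
the gate, so the root is well defined whenever the observed radius is
attainable within the bracket; unattainable targets are flagged
non-convergent and carry no value. On data generated with the short-duration
suppression switched on, the estimated profile strictly decreases with
duration; on unsuppressed data it is flat at the generating gate. Bisection
is cross-checked against a dense grid scan in the tests.

## The synthetic-experiment generator

`generate_dataset()` emulates the structure of the radius-versus-duration
assay: per duration (default: the experimental grid 2, 3, 4, 6, 8, 10, 20,
30, 40, 50, 100 ms), the mean radius is the forward Two-Step prediction and
replicates add homoscedastic Gaussian noise truncated at zero (default SD
0.02 mm — small against millimetre-scale radii, matching the visual spread
of published replicate errorbars — with $n = 4$ wells per condition). An
optional multiplicative short-duration deficit,
$\max(0,\,1 - s\log_{10}(10\,\mathrm{ms}/T_p))$ for $T_p \le 10$ ms,
exists solely to exercise the effective-gate estimator; it makes no claim
about biology. Generation is fully reproducible from an integer seed, uses
a private RNG stream (the caller's RNG state is untouched), and echoes all
generator parameters into a JSON sidecar next to the CSV.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: radius extraction from fluorescence images and its
segmentation error, between-experiment day effects, heteroscedasticity at
large radii, chemical (reactive-species) and thermal contributions at long
exposures, and any real short-duration biology beyond a smooth
monotone deficit.

## Numerical choices

* 1024 samples per drive cycle for dose and gating (configurable; ≥ 64
  enforced); cycle-periodic accumulation plus linear interpolation inside
  the crossing interval makes crossing times exact for the sampled
  waveform.
* Transient oracle: 400 steps per cycle, 8 cycles, comparison on cycles
  7–8 via projection onto the drive frequency; capacitor currents by
  centred differences (second order).
* Dense complex solve with one iterative-refinement step; singular systems
  (floating subgraphs) are reported with the offending nodes named, and
  connectivity is checked at network construction.
* Degenerate inputs: zero drive gives exact zeros end-to-end; zero
  conductivity omits the resistive element (open circuit); `tp = 0` gives
  zero energy.
* Problem sizes in the shipped tests: the full 40-region network (200
  nodes), 3-region toys for hand-checkable topology, 20-seed recovery
  studies, and brute-force oracles at 256–512 samples per cycle over up to
  20 ms — the whole suite runs in well under a minute.

## Known limitations

* The circuit topology is a documented reconstruction; its dose field is
  hotter and decays more steeply with radius than the original (inferred
  from the radii that published threshold values reproduce). Fitted
  thresholds are therefore *effective parameters tied to this circuit* and
  are not transferable numbers — the same caution the threshold-model
  framework itself attaches to its estimates under the
  perfect-conductor/sinusoid approximations.
* The one-step radius-versus-log-duration curve of this field does not have
  a single curvature sign across the well (see the dose-shape section);
  the corresponding acceptance check fails and is intentionally left
  failing rather than weakened, as a faithful record of the
  reconstruction gap.
* The plasma is an ideal conductor and the drive an ideal sinusoid; spiky
  discharge currents would raise instantaneous power at the cell layer.
  Plasma chemistry, heating, and frequency-dependent material properties
  are out of scope.
* The mesh scheme is fixed at 40 regions; only the well radius is
  variable. Death radii are resolved to roughly one region width
  (R/32 ≈ 0.1 mm in the bulk).
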