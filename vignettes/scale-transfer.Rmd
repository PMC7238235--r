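---
title: "Scaling tableting processes between rotary presses and compaction simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling tableting processes between rotary presses and compaction simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabscale)
```

## The scaling problem

Single-station compaction simulators (CS) replay the punch kinematics of a
target rotary tablet press from a programmed displacement profile, so that
formulation and process development can run at gram scale. Two sub-processes
limit how faithfully CS results transfer back to the rotary press:

1. **The compression phase itself.** The simulator executes the programmed
   profile imperfectly: the stress-time curve is slightly prolonged, and the
   punches keep creeping together during the nominal dwell phase. For
   strain-rate-sensitive (visco-plastic) materials this shifts tensile
   strength systematically.
2. **Feeding and filling.** A paddle feed frame shears the powder before it
   enters the die. Lubricated blends — in particular ductile excipients with
   magnesium stearate — lose tensile strength as the lubricant is dispersed
   over particle surfaces ("overlubrication"). Because a CS has a single die
   position under its feeder and only actuates the paddle during filling,
   running it at intuitively convenient feeder settings exposes the powder
   to a shear history orders of magnitude harsher than the rotary press it
   simulates.

`tabscale` implements the quantitative machinery for both: exact punch
kinematics from machine geometry, profile metrics that expose the simulator's
execution deviations, and a shear-number algebra that equates powder shear
histories across machines.

## Punch kinematics from machine geometry

A punch head travelling on the turret pitch circle (diameter $D_{pc}$) at
turret frequency $n_t$ moves horizontally at $v = \pi D_{pc} n_t / 60$. While
the curved head rim (radius $r_h$) is under the compression roller (radius
$R$), the vertical displacement toward minimum separation follows the
circular-arc contact

$$z(x) = (R + r_h) - \sqrt{(R + r_h)^2 - (|x| - l_f/2)^2},
  \qquad |x| > l_f/2,$$

capped at the penetration depth, and $z = 0$ while the head flat (length
$l_f$) passes under the roller's lowest point. That flat portion is the dwell
phase, of duration $t_{dwell} = l_f / v$. `simulate_displacement()` samples
this construction on a uniform grid (default 0.1 ms, which resolves the
shortest production-scale dwells of about 12.5 ms with more than 100 points);
upper and lower punches are assumed to move symmetrically, each contributing
half the penetration, and pre-compression rollers are not modelled — one
main-compression event per profile. Profiles at different turret speeds are
exact time-rescalings of one another, which the test suite uses as an
invariant.

The profile container bottoms out at a configurable `min_separation`
(default 2 mm), standing in for the in-die tablet thickness at peak stress,
so that simulator-style residual punch approach never drives the separation
negative.

## Profile metrics

`detect_dwell_window()` finds the maximal contiguous interval where the punch
separation stays within a tolerance of its minimum. The default tolerance of
10 µm is of the order of punch-position sensor resolution. Because the head
arc is *tangent* to the flat, any positive tolerance widens the detected
window beyond the geometric flat; oracle comparisons against the closed-form
dwell time therefore use a near-zero tolerance, and the reported `width`
attribute extends half a sampling step beyond the bounding samples on each
side so its quantisation error is at most one sampling step.

`residual_dwell_velocity()` is the unweighted least-squares slope of
separation versus time over the dwell window (reported in mm/s with its
standard error and confidence interval); negative values mean the punches are
still approaching. An optional centred moving average (default off) is
available for noisy high-speed profiles before fitting.

The prolongation of a simulator profile against its press reference is not
uniquely defined by eye; `tabscale` defines it operationally as the ratio of
times spent at or above a common fraction of peak stress (default 10%, robust
to baseline noise), minus one, with crossing times linearly interpolated
between samples. The threshold is exposed rather than hard-coded because
total contact time, threshold time and dwell time all "prolong" by similar
but not identical amounts.

## The shear-number algebra

For a rotary press, the cumulative shear exposure of the powder in the feed
frame is indexed by

$$SN = \frac{\pi d_p k_s}{c}\left(\frac{m}{w\,k_d}\right)^2
       \left(\frac{n_p}{n_t}\right)^2,$$

the product of a shear intensity (paddle diameter $d_p$ times spokes $k_s$
over clearance $c$), the squared residence time (feed-frame hold-up $m$ over
tablet weight $w$ times die count $k_d$ and turret speed), and the squared
paddle-to-turret frequency ratio. `tabscale` evaluates it with lengths and
masses in SI units and frequencies in min⁻¹; the absolute magnitude
(typically 1E6–1E9 at practical settings) depends on that convention,
comparisons and ratios do not.

A CS run differs in two structural ways: its paddle only turns during the
filling time corresponding to the simulated press's fill angle
$\varphi_{fill}$, and its single die receives powder that the paddle has
sheared as many times as the multiple dies under a rotary feed frame would
have withdrawn it, which introduces the die-spacing angle $\varphi_{dies}$.
Both corrections act on the paddle frequency, giving the CS-adapted index

$$SN_C = \frac{\pi d_p k_s}{c}\left(\frac{m}{w\,k_d}\right)^2
         \left(\frac{n_p}{n_t}\,
         \frac{\varphi_{fill}^2}{360°\,\varphi_{dies}}\right)^2 .$$

Here $k_d$, $\varphi_{fill}$ and $\varphi_{dies}$ are taken from the
*simulated* press and $d_p, k_s, c, m$ from the simulator's own feeder.
Equating $SN_C$ to the rotary $SN$ and solving for the CS paddle frequency
gives the closed form implemented in `match_paddle_frequency()`; tablet
weight and turret frequency cancel exactly, which the tests assert. The
result is rounded to a machine step, default 4 min⁻¹ — an inference about
feeder-drive granularity, exposed as a parameter.

```{r}
xl100 <- load_fixture("XL100")
cs <- load_fixture("StylOne")
op <- operating_point(turret_frequency = 20, paddle_frequency = 60,
                      target_stress = 150, tablet_weight = 7.25e-4)
match_paddle_frequency(xl100$press, xl100$feeder, cs$feeder, op)
```

## Fixtures and their provenance

Feeder geometry, pitch-circle and roller diameters, and fill/die angles of
the packaged XL100, XL400 and StylOne fixtures are editable placeholders, not
vendor data; each file says so in its `provenance` field. They are
calibrated so that two documented anchors hold: the XL400 theoretical dwell
time at 60 min⁻¹ is 12.5 ms, and the XL100→CS paddle-frequency transfer maps
60 min⁻¹ to 128 min⁻¹ (hence 24 min⁻¹ to 51.2, rounding to 52). The single
calibrated degree of freedom for the transfer is the XL100 feeder hold-up
mass; all other values are round numbers of plausible magnitude. For an
under-tooled turret (the XL100 run with 4 punch pairs) the die-spacing angle
is defined as 360°/k_d of the *installed* set, since the shear-number
residence term counts installed dies. Users with real machine drawings
should replace the placeholders via `save_fixture()`/`load_fixture()`.

## The synthetic-data generator

No measured profile or tablet datasets ship with the package; the generator
produces inputs with the documented qualitative structure so that every
analysis path can be exercised and property-tested.

**Profile deviations** (`cs_deviation_model()`): the simulator's time-stretch
factor is $s = \max(1,\, 1 + a\sigma + b\,n_t)$ with defaults
$a = 7\times10^{-4}$ per MPa and $b = -5\times10^{-4}$ per min⁻¹ — exactly
1.20 at (300 MPa, 20 min⁻¹), growing with stress, shrinking with speed, and
at least 1.005 over the supported 50–300 MPa × 20–60 min⁻¹ grid. The
residual punch approach during dwell has velocity $-\kappa/t_{dwell}$ with
$\kappa = 25$ mm·ms/s, i.e. a fixed 25 µm of extra closing per dwell —
−0.5 mm/s at a 50 ms dwell and −2 mm/s at 12.5 ms, reproducing the
observation that shorter dwells show faster residual closing and hence
stress *rising* over the dwell. Separation noise (default off) scales with
simulated speed, mimicking machine vibration.

**Stress synthesis**: the displacement→stress law of real measured profiles
is material-dependent and not modelled mechanistically; a configurable
power law `stress_material_law()` (default exponent 3) paints stress onto
displacement, and the simulator profile is rescaled to the press profile's
peak, mirroring force-calibrated replay ("same maximum compaction stress").
The residual approach therefore appears as rising dwell stress rather than a
higher peak. In reality stress *falls* slightly during dwell at low stress
as the material relaxes; the generator's profiles rise at all stresses, a
known simplification that does not affect the duration-based metrics.

**Shear response** (`material_response()`): the equilibrium tensile strength
under shear exposure is a log-logistic decay
$\sigma(SN) = \sigma_{floor} + (\sigma_{ref} - \sigma_{floor}) /
(1 + (SN/SN_{50})^h)$ — the minimal monotone sigmoid on a log-SN axis. The
approach to equilibrium over process runtime is exponential with the feed
system's ideal filling time $t_f = V_R \rho_b / \dot m$ as time constant,
because the strength plateau is observed in the range of $t_f$; the exact
kinetics are not known, so the simplest one-parameter relaxation is used.
The presets are calibrated jointly against the packaged fixtures: the
ductile (MCC-like) preset loses 70% of its stress-normalised strength
between paddle frequencies 10 and 272 min⁻¹ and retains 35% of the rotary
strength at uncorrected convenient-filling settings
($\sigma_{floor}/\sigma_{ref} = 0.10$, $SN_{50} = 3.0\times10^6$,
$h = 0.462$); the intermediate (lactose-like) preset loses 30%
($\varphi = 0.5$, $h = 1$, $SN_{50} = 6.79\times10^7$, the upper of the two
admissible roots, i.e. the less shear-sensitive one); the brittle (DCP-like)
preset is flat because fracture during compaction creates lubricant-free
surfaces; the visco-plastic (starch-like) preset is shear-flat but carries a
dwell-time sensitivity $\sigma \cdot (1 + 0.08 \ln(t_{dwell}/40\,\text{ms}))$
— direction known, functional form a modelling choice. Batch noise is
multiplicative log-normal (strengths stay positive), mean-corrected so the
expectation equals the model mean.

What the generator does **not** emulate: die-fill efficiency differences
between paddle speeds (the starting strength is a free parameter instead),
punch elasticity and frame deflection, ejection, overfilling/dosing-out
shear, and the punch-size residual anomaly (smaller punches losing more
strength at nominally equal shear number). Passing tests therefore
demonstrate internal consistency of the methodology and correct algebra, not
predictive accuracy on real powders.

## Numerical choices

* Sampling default 0.1 ms; plateau-width quantisation at most one step via
  the edge-midpoint width estimate.
* Threshold crossings in `compression_time()` are linearly interpolated.
* Dwell detection on a monotone ramp returns a degenerate single-sample
  window with a warning rather than an error; a tolerance wider than the
  profile amplitude returns the whole profile.
* Paddle-frequency rounding uses round-half-even on the machine-step grid.
* Porosity is computed out-of-die from measured dimensions (in-die porosity
  would need punch-tip separation under load); apparent density exceeding
  true density flags inconsistent inputs with a warning, not an error.
* Reproducibility: every stochastic generator takes an integer seed and
  restores the caller's RNG state.

## Problem sizes

The test suite and the reproduction script run the full operating grid
(3 stresses × 3 turret speeds) at 0.1–0.2 ms sampling, 50-tablet batches per
feeder condition, and 500 replicates of the residual-velocity coverage
study; together they complete in a few seconds on one core, and all results
quoted in the documentation are produced by those runs.
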