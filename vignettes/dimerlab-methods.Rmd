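---
title: "Models and methods behind dimerlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dimerlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerlab)
```

dimerlab implements the quantitative workflow used to characterize an
adhesive protein trans-homodimer — the kind formed by the two outermost
extracellular (EC) repeats of cadherin-23 — across six solution and
single-molecule techniques. Each analysis stage is paired with a
synthetic-data generator that produces data with exactly the statistical
structure the stage assumes, so the entire pipeline is validated by
parameter recovery rather than against deposited instrument files (none
exist for this system). This vignette records the models, the defaults,
and the judgment calls.

## Dynamic force spectroscopy

### The model chain

A single receptor-ligand bond pulled at constant velocity `v` through a
polymer tether ruptures stochastically. Three models stack:

1. **Tether elasticity.** The PEG spacers behave as a freely-jointed
   chain (FJC): extension
   $l(F) = L_c\,[\coth(Fa/k_BT) - k_BT/(Fa)]$ with contour length $L_c$
   and Kuhn length $a$. Defaults: $L_c = 58.7$ nm (two 5-kDa PEGs in
   series, the value recovered per-curve by the fit), $a = 0.7$ nm. The
   Kuhn length of PEG is not reported for this system; 0.7 nm is a
   literature-typical value and is exposed as a parameter.
2. **Loading-rate correction.** The cantilever (stiffness $k_c$) and the
   tether act as springs in series, so the force ramp at rupture is
   slower than $k_c v$:
   $v_F = k_c v / \{1 + k_c (L_c a / k_BT)[(k_BT/Fa)^2 -
   \mathrm{csch}^2(Fa/k_BT)]\}$.
   It is evaluated once at the fitted most probable force of each state
   (no self-consistent iteration at analysis time): the most probable
   force is the force whose loading rate enters the force-vs-rate fit.
3. **Bell-Evans kinetics.** Force lowers the unbinding barrier, giving
   $F(v_F) = (k_BT/x_\beta)\,\ln(v_F\, x_\beta \tau_0 / k_BT)$ with
   intrinsic lifetime $\tau_0 = 1/k_\mathrm{off}$ and transition distance
   $x_\beta$. The fit is a weighted linear model in $\ln v_F$ — an exact
   re-parameterization that makes error propagation transparent. The two
   bound states of the EC1-2 trans-dimer serve as reference parameter
   sets: a weak single-interface state ($\tau_0 = 1.86$ s,
   $x_\beta = 0.55$ nm) and a strong fully-engaged state
   ($\tau_0 = 1224.2$ s, $x_\beta = 0.31$ nm).

$k_BT$ defaults to 4.11 pN nm (298 K) and is configurable; the
force-spectroscopy temperature is not stated in the source protocols.

### The generator

`sample_rupture_forces()` draws from the closed-form first-passage
distribution of the constant-rate Bell-Evans model by inverse-transform
sampling. Within one simulated curve the loading rate is taken as locally
constant at the rupture force; the constant used is the fixed point
$r = v_F(F_\mathrm{mode}(r))$ of the compliance correction
(`self_consistent_loading_rate()`), so that the correction applied at
analysis time is consistent with generation. `make_force_curve()` shares
the tip displacement $vt$ between tether extension and cantilever
deflection, records tip-sample separation, truncates the trace with a
sharp drop at the drawn rupture force, and adds Gaussian force noise.
The rupture is placed at a sampled instant, so the last above-baseline
sample carries exactly the drawn force — without this convention a 6 kHz
trace pulled at 15000 nm/s under-reads every rupture by up to one
sample's force step (tens of pN), which is a property of instrument
discretization, not of the kinetics being recovered.

Study conditions emulated by default: seven pulling speeds (500, 750,
2000, 5000, 7500, 10000, 15000 nm/s), 6 kHz sampling, $k_c$ = 20 pN/nm
(the nominal stiffness of the soft silicon-nitride lever used; with the
compliance correction this reproduces the reported 13841 pN/s loading
rate near 2000 nm/s), and 5 pN Gaussian force noise, a realistic force
precision for a soft lever at this bandwidth.

### Event selection and its thresholds

A rupture is a drop of more than 5 times the noise floor within at most
3 samples of the median-filtered trace. The rupture index is refined to
the last raw sample above half the filtered peak (the 50% crossing of
the drop), and the rupture force is that single raw sample. This choice
is deliberate: a maximum over a window carries the expected-maximum bias
of Gaussian noise at slow speeds, and a local linear extrapolation
carries a curvature bias at fast speeds; both are speed-dependent and
therefore tilt the $F_{mp}$-vs-$\ln v_F$ slope, which $\tau_0$
amplifies exponentially. A single-sample read is unbiased at every
speed.

Single-molecule criteria: exactly one drop, fitted contour length within
20-120 nm, and an RMS force residual below 2.5 times the curve's noise
floor. A force-space $R^2$ threshold is available but defaults to a
loose 0.5 evaluated over the whole pre-rupture trace: a strict $R^2$
cut over the stretch segment alone punishes the *force range* of the
segment rather than the fit quality, and silently discards genuine
low-force events — which truncates the weak state's distribution and
biases its kinetics. The residual criterion measures what the selection
is meant to measure.

The FJC fit itself profiles $L_c$ (linear given $a$) and optimizes $a$
in one dimension, with weights $1/(\partial l/\partial F)^2$ that make
the extension-space objective equivalent to force-space least squares —
appropriate because the noise lives in the force channel.

### Force distributions

Histograms use Scott's rule ($h = 3.49\,\mathrm{sd}\,n^{-1/3}$)
throughout; one or two Gaussians are fitted to the bin counts by least
squares, matching the original analysis chain. Two caveats are inherited
knowingly: the first-passage density is left-skewed, so the fitted
Gaussian mean sits a couple of piconewtons below the analytic mode (an
offset that is nearly constant in $\ln v_F$, hence mostly absorbed by
the intercept, i.e. $\tau_0$, and visible in its recovery tolerance);
and a two-component fit on unimodal data is refused — if the two means
come out closer than one combined standard deviation the fit falls back
to a single component with a warning.

## Single-molecule FRET

Traces are donor/acceptor intensity pairs with single-step acceptor
photobleaching at a geometric random frame (mean 150 of 400 frames) —
after the bleach the donor rises to the full intensity, the
anticorrelation that validates a genuine pair. Shot noise is
approximated as Gaussian with variance equal to the mean count
(defaults: 500 signal photons/frame, 50 background per channel). Donor
blinking and direct acceptor excitation are not modeled, and no
donor-leakage correction chain is implemented; only the
$\gamma$-corrected ratio
$E = (I_A - b_A)/[(I_A - b_A) + \gamma (I_D - b_D)]$ with $\gamma = 1$
by default. The bleach step is located as the largest single-step drop
of the median-filtered acceptor trace; traces whose acceptor starts at
background are excluded (the median over the first frames is used for
that check, so a trace that bleaches on frame one is not mistaken for a
FRET pair). The most probable efficiency is the mean of a Gaussian
fitted to the Scott-binned efficiency histogram; with 25 traces the
histogram can be too coarse for a stable three-parameter fit, in which
case the sample mean is used. Distances come from inverting
$E = 1/(1 + (R/R_0)^6)$; $R_0$ must be supplied, since the dye-pair
Forster radii live in supplementary material not reproduced here, and
distance outputs are validated by round-trip identities instead.

## Time-resolved anisotropy

The generator builds $r(t) = r_0[A_1 e^{-t/\phi_1} + A_2 e^{-t/\phi_2}]$
and emits polarized intensities $I_\parallel = S(1+2r)/3$,
$I_\perp = S(1-r)/3$ for a monoexponential total decay $S(t)$ (lifetime
5 ns, tryptophan-like), with fractional Gaussian noise per channel. The
anisotropy is computed with the standard convention
$r = (I_\parallel - G I_\perp)/(I_\parallel + 2G I_\perp)$; the
perpendicular-minus-parallel variant that sometimes appears in print is
available as `convention = "as-printed"` but yields negative anisotropy
for polarized emission and is not used by default. The G factor
defaults to 1 (none is reported); no IRF reconvolution is performed
(tail fitting). The biexponential fit enforces $A_1 + A_2 = 1$, orders
the correlation times fast-first (local wobble vs whole-molecule
tumbling), falls back to a monoexponential when the two times are
within a factor of 3 (ill-conditioned separation), and flags — without
clamping — a fitted $r(0)$ above the fundamental limit of 0.4.

## Sedimentation equilibrium

At equilibrium a species of buoyant molar mass $M(1-\bar v \rho)$
distributes as $\exp[\sigma (r^2 - r_0^2)/2]$ with
$\sigma = M(1-\bar v\rho)\omega^2/RT$. The monomer-dimer profile is

$$A(r) = \epsilon l\, c_m e^{\sigma_m \xi} + 2\epsilon l
\frac{c_m^2}{K_D} e^{2\sigma_m \xi} + b, \qquad
\xi = (r^2 - r_\mathrm{men}^2)/2,$$

with the dimer's signal coefficient $2\epsilon l$ (two chromophores) and
its exponent exactly twice the monomer's, so mass action
$c_d(r) = c_m(r)^2/K_D$ holds at every radius by construction. The
generator solves the meniscus concentration from conservation of the
loaded material in the sector-shaped cell, which also guarantees that
scans at different speeds share one ground truth. The global fit floats
one $\log K_D$ plus a per-scan meniscus concentration and baseline;
meniscus and bottom are fixed geometry (floating them is ill-posed on
synthetic data with known geometry). Confidence intervals are profile
likelihood on $\log K_D$. A fit running to the $K_D$ bound is reported
as a no-association outcome. Reference experiments: the two-domain
fragment (26 kDa monomer, 36 uM load, 24/28/32 krpm, planted
$K_D = 18$ uM) and the single-domain fragment (15 kDa, 45 uM,
18/20/25 krpm, $K_D = 52$ uM). Assumed, because unreported:
$\bar v = 0.73$ mL/g, $\rho = 1.0$ g/mL, $\epsilon l = 36000$ AU/M
(eps280 of 30000 /M/cm over a 1.2 cm path), 293.15 K, a 6.00-6.15 cm
solution column, 0.005 AU optical noise. Rotor speed is accepted in rpm
or rad/s, never as a g-value. Sedimentation-velocity analysis (Lamm
equation, c(s) distributions) is out of scope.

## SAXS shape parameters

- **Guinier:** weighted regression of $\ln I$ on $q^2$, iterated until
  $q_{max} R_g \le 1.3$ (the standard globular window; configurable for
  rods). A non-negative slope is reported as an aggregation error.
- **Normalized Kratky:** $(qR_g)^2 I/I_0$ vs $qR_g$; a Gaussian
  (globular) profile peaks at exactly $\sqrt 3 \approx 1.73$ with height
  $3/e$; a peak shifted beyond that by more than 5% raises the rod-like
  flag.
- **P(r):** the indirect Fourier transform solves
  $I(q) = 4\pi \sum_j p(r_j)\,\mathrm{sinc}(q r_j)\,\Delta r$ with zero
  endpoints, non-negativity (a hand-written Lawson-Hanson active-set
  NNLS; no installed package provides one) and a second-difference
  smoothness penalty; the weight is chosen at the corner of a discrete
  L-curve unless given. The effective maximum dimension is the
  interpolated radius beyond which $p$ stays below 0.5% of its peak — a
  compromise threshold: much tighter and noise-induced tails inflate
  $D_{max}$, much looser and the smooth approach of $p(r)$ to zero
  truncates it. `scan_dmax()` picks the smallest candidate whose
  chi-squared is within 5% of the large-$D_{max}$ plateau and whose
  $p(r)$ decays naturally before the endpoint.
- **Vc:** the volume of correlation $I_0/\int q I\,dq$ and the protein
  mass calibration $MW = QR/0.1231$ (QR in cubic Angstrom) with the
  calibration constants exposed as arguments; a 20%-truncation
  sensitivity is always reported. The lysozyme-standard route is a
  plain $I_0$ ratio helper and requires a user-supplied standard.
- **Model scoring:** per-parameter z-tests of model-derived $R_g$,
  $D_{max}$ and FRET end-to-end distances against experimental values,
  two-sided normal p-values, worst parameter and a 0.05 flag.

The synthetic oracle is the solid sphere (analytic form factor, $R_g =
R\sqrt{3/5}$, $D_{max} = 2R$, closed-form $p(r)$) with shot-noise-like
Gaussian errors ($\sigma \propto \sqrt{I I_0}$ plus a 1%-of-$I_0$
detector floor — a pure relative-error model gives unrealistically
informative deep minima). Desmearing of slit-collimated data and ab
initio bead modeling are out of scope; q is nm$^{-1}$ internally with
Angstrom input converted on read.

## SEC calibration

$K_{av} = (V_e - V_0)/(V_c - V_0)$ with the 8/24 mL column geometry,
fitted linearly against $\log_{10} MW$ — the phrase "linear plot against
molecular weight" is interpreted as the standard semi-log relationship,
since a literally linear-in-MW calibration cannot reproduce SEC
behavior; the literal variant remains available via `form = "linear"`.
Standards: cytochrome c (12 kDa), carbonic anhydrase (29 kDa), albumin
(66 kDa), alcohol dehydrogenase (76 kDa). Standard elution volumes are
not printed anywhere, so the calibration is validated by planted-line
recovery and round-trip identities, and elution volumes are always user
inputs (no peak detection).

## What the synthetic tests do and do not show

The generators reproduce the *statistical models the analyses assume* —
Bell-Evans first-passage statistics on an ideal FJC, exact two-species
Boltzmann gradients, single-step bleaching with Gaussian shot noise,
ideal biexponential decays, noiseless-geometry sphere scattering.
Passing recovery tests therefore demonstrates that the estimator chain
is consistent and unbiased at realistic noise, not that real instrument
data are free of the effects deliberately not modeled: baseline drift
and hydrodynamic lag in AFM, donor blinking and spectral cross-talk in
TIRF, time-varying backgrounds, non-ideality and pressure effects in
the ultracentrifuge, interparticle structure factors and smearing in
SAXS. Those require the instrument-vendor corrections upstream of this
package.

## Problem sizes and determinism

The recovery studies use 1000 events per speed at 7 speeds for the
kinetics, 500 curves for the contour-length distribution, 3 scans of
60-80 points for each equilibrium fit (100 replicates for interval
coverage), 25 FRET traces, and ~300-point scattering profiles — the
sizes of the corresponding real experiments, which also keep the whole
validation suite in the minutes range on one core. Every generator takes
a `seed` and is bit-identical under it; `run_study()` derives all stage
seeds from one master seed and reports planted vs recovered values with
pass/fail flags per stage.
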