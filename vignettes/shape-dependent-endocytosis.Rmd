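---
title: "Models and methods: shape-dependent nanoparticle endocytosis"
author: "ndwrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: shape-dependent nanoparticle endocytosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndwrap)
```

Endocytosis of a nanoparticle proceeds in two distinguishable stages:
*anchoring*, the attachment of the particle to the plasma membrane, and
*internalization*, the energy-dependent engulfment that follows.  Particle
shape plays into both stages differently.  A particle with sharp edges and
corners ("prickly") presents a larger flat contact patch to the membrane and
anchors readily, but its sharp tips are costly to wrap; an etched, rounded
particle anchors less but internalizes more easily.  `ndwrap` implements the
four computational models that make this picture quantitative, plus the
synthetic-data generators needed to validate each of them end to end.

This vignette records the modelling assumptions, parameter conventions,
numerical choices, and the design decisions that were genuinely open.

## 1. Contact-area model: random polygons with rounded corners

The membrane contact patch of a faceted particle is abstracted as a random
simple polygon; chemical etching is abstracted as replacing each corner with
a circular fillet of rounding radius $R_r$.  The quantity of interest is the
ensemble mean of the *relative* area $A(R_r)/A(0)$ as a function of $R_r$,
for polygons of 4, 6, 8 and 10 vertices.

**Generation.**  Vertex $i$ of an $n$-gon sits at angle
$\varphi_i = \tfrac{2\pi}{n}(i + u_i\,d_\alpha)$, $u_i \sim U(-1,1)$, with
the angles sorted ascending, and radius
$\rho_i = r_0(1 + v_i\,d_r)$, $v_i \sim U(-1,1)$.  The two dimensionless
irregularity amplitudes default to $d_r = d_\alpha = 0.3$.  This radial
star-shaped construction is the standard way to generate random simple
polygons with independent radial and angular disorder; angle sorting
guarantees simplicity and counter-clockwise orientation by construction.
The construction is a design choice of this package — the two amplitudes are
the model's only irregularity knobs, and the reference ensemble size is
100,000 polygons per vertex count.

**Rounding.**  A corner with wedge angle $\beta$ (the interior angle for a
convex corner, its explement for a reflex corner) is replaced by an arc of
radius $R_r$ tangent to both adjacent edges at offset
$t = R_r/\tan(\beta/2)$ from the vertex.  At $d_r = d_\alpha = 0.3$ the
generator occasionally emits mildly non-convex polygons; reflex corners are
filleted with the same tangent construction, the arc bulging outward, and
the signed Green's-theorem boundary integral handles both cases uniformly
(rounding a reflex corner *adds* area).  The exact rounded area reduces, for
each polygon, to

$$A(R_r) = A(0) - R_r^2 \sum_i s_i\left[\cot\tfrac{\beta_i}{2}
  - \tfrac{\pi - \beta_i}{2}\right], \qquad s_i = \pm 1,$$

which the ensemble sweep uses directly; `round_corners()`/`rounded_area()`
build the explicit segment-and-arc outline and integrate it, and the test
suite holds the two routes to machine-precision agreement, with a dense
chord-discretization oracle as a third, independent check.

**Infeasibility.**  When the tangent offset at any vertex exceeds half of an
adjacent edge, neighbouring fillets would overlap.  Such polygons are
*rejected at that radius* — excluded from the mean and counted in
`rejection_fraction` — rather than having their radius clamped, because
clamping silently changes the geometry being averaged.  `area_curve()`
therefore reports a conditional mean over feasible polygons together with
the rejection rate, and errors only if an entire ensemble is infeasible.

$R_r$ is expressed in units of the base circumradius; since outputs are
relative areas, the base radius cancels.

## 2. Adhesion strength from umbrella sampling via WHAM

The free energy of membrane adhesion per unit contact area, the *unit
adhesion strength* $k_{ad}$, is obtained from the potential of mean force
(PMF) of a slab pulled off a lipid bilayer along the distance coordinate
$z$: $k_{ad} = \Delta F / A_{slab}$, where $\Delta F$ is the PMF depth.  The
reference protocol uses a ladder of harmonic umbrella windows, spacing
0.15 nm, force constant 400 kcal/mol/nm².

**WHAM.**  `wham_solve()` combines the biased window histograms
self-consistently:

$$p_b \propto \frac{\sum_w n_{wb}}{\sum_w N_w\, e^{-\beta(U_w(z_b) - f_w)}},
\qquad f_w = -k_BT \ln \sum_b p_b\, e^{-\beta U_w(z_b)},$$

iterated until the largest change in any window free energy $f_w$ falls
below $10^{-6}$ kcal/mol (cap $10^5$ iterations; exceeding the cap is an
error, never a silently unconverged profile).  Bins are uniform over
$[\min z_0 - 3\sigma,\ \max z_0 + 3\sigma]$ with
$\sigma = \sqrt{k_BT/k}$, clipped to the observed sample range (the clip
matters only in the weak-bias limit, where the rule span would diverge);
default 200 bins.  Adjacent windows must share at least one populated bin,
otherwise the solver names the gap and stops.  The output profile is
$F(z_b) = -k_BT\ln p_b$, min-referenced.  $k_B = 0.0019872041$ kcal/mol/K
throughout.

**Depth.**  A PMF is defined up to a constant, so the depth is measured as
the mean free energy over the populated bins in the top 10% of the $z$
range (a plateau average, robust to per-bin noise; `bulk_fraction`
configurable) minus the profile minimum.  Uncertainty, when requested, is a
declared bootstrap over window samples (`pmf_depth_boot()`, 200 resamples
by default); it is an estimator choice of this package, not a reproduction
of any particular published error bar.

**Validation truth.**  The synthetic generator samples each window *exactly*
from its biased Boltzmann density
$p_w(z) \propto e^{-\beta(F_{true}(z) + \frac{k}{2}(z - z_{0,w})^2)}$ by
inverse-CDF on a fine grid (≥ 10⁴ points) — the statistical model of a
perfectly equilibrated, uncorrelated window, with no molecular dynamics and
no Markov chain.  The default truth is a Morse-like well,
$F(z) = \Delta F[(1 - e^{-(z - z_{min})/w})^2 - 1]$, with depth
9.93 kcal/mol, minimum at 0.5 nm and width 0.3 nm, sampled by 13 windows
from 0.45 nm at 0.15 nm spacing — the published window protocol around a
well whose depth equals the published 2 nm × 2 nm slab value.  What this
validates is the estimator: recovered profiles match the truth to
RMSE < 0.1 kcal/mol and depths to within 5% at 10⁴ samples/window.  What it
does not validate is anything about real force fields, sampling
autocorrelation, or slow membrane relaxation — the published depths
(9.93, 37.39 kcal/mol) come from cluster-scale MD and enter this package
only as printed inputs to the $k_{ad}$ arithmetic.

Comparisons of a recovered profile against a truth function remove the mean
offset over populated bins first (both are defined up to a constant); the
depth itself needs no alignment.

## 3. Continuum wrapping energetics

For the initial stage of internalization, the membrane wraps the particle
*tip*, modelled as a sphere of radius $R$ wrapped to angle $\theta$ on an
infinite tension-free membrane:

$$G_{tot}(\theta) = G_{bend} + G_{ad}
 = 4\pi k_b (1 - \cos\theta) + 2\pi R^2 k_{ad} (1 - \cos\theta).$$

Because both terms share the factor $(1-\cos\theta)$, the sign of the
prefactor decides everything: wrapping is favorable iff
$4\pi k_b + 2\pi R^2 k_{ad} < 0$, equivalently $R > R_c = \sqrt{2k_b/|k_{ad}|}$.
Sharper tips (smaller $R$) are harder to wrap — the mechanistic link between
shape and internalization.

Conventions worth stating explicitly:

* **Sign of $k_{ad}$.**  Adhesion strengths are usually *reported* as
  positive magnitudes but enter the model negative (favorable).  The model
  stores signed values; `kad_signed()` converts a magnitude.
* **Units of $k_b$.**  Accepted in $k_BT$ (typical lipid bilayer value
  20 $k_BT$) or kcal/mol, converted at a configurable temperature,
  default 298.15 K ($k_BT = 0.5925$ kcal/mol); classification is invariant
  to the unit round-trip.  The experiments ran at 4 °C and 37 °C, and no
  single conversion temperature is canonical — 298.15 K is the package's
  default, and the phase boundary moves by only ~±6% in $k_b$ across
  277–310 K.
* **Boundary points.**  $G_{tot} = 0$ is classified *no-wrap* (strict
  inequality), with a $10^{-9}$ relative guard so analytic boundary points
  computed in floating point land on the declared side.
* **Tip radius.**  The phase diagram over $(k_b, k_{ad})$ depends on $R$,
  which must be supplied; the reference marker ($k_b = 20\,k_BT$,
  $k_{ad} = -2$ kcal/mol/nm², giving $R_c \approx 3.44$ nm) is an input
  point, not a fitted result.
* Membrane tension is zero by assumption; the model covers only the onset
  of wrapping, not full engulfment.

## 4. Uptake quantification from temperature-split plate assays

The experimental trick for separating the two stages: at 4 °C anchoring
proceeds but energy-dependent internalization is suppressed, so 4 °C wells
measure anchored particles only, while 37 °C wells measure anchored plus
internalized.  Per particle type and time point,

$$\widehat{I} = \overline{X}_{37} - \overline{X}_{4},$$

with uncertainty $\sqrt{s_{37}^2 + s_4^2}$ by quadrature, because the two
conditions are measured on *separate, unpaired* plates (the protocol runs
them independently, so per-well pairing does not exist).  Negative
internalized estimates are reported with a QC flag, never truncated:
truncation at zero would bias downstream ratio estimates upward.

**Normalization.**  The two particle types differ in brightness per unit
mass.  A photoluminescence calibration series (0, 5, 10, 15, 20 µg/mL) is
fitted by OLS per type; well intensities are divided by the type's slope.
The 0 µg/mL point blanks the calibration series itself, but is *not*
subtracted from cell wells: a water-based calibration blank is not a
cell-plate background, and subtracting it drives low-signal early-time
wells negative.  All downstream ratios and p-values are invariant to a
common intensity rescaling.

**Tests.**  Cross-type comparisons default to the pooled two-sided Student
t-test ($df = n_1 + n_2 - 2$), which reproduces the reported zeta-potential
comparison ($p = 0.937$ from group summaries with $n = 3$); Welch is
available by argument.  Summary-statistic input (mean, sd, n) is accepted
alongside raw replicate values.  P-values are reported per time point
without multiple-testing correction, matching how such assays are
conventionally reported.

## 5. Synthetic plate assays and what passing tests mean

`simulate_assay()` draws well intensities
$[A(t) + I(t)\,\mathbf{1}\{37°\mathrm{C}\}](1 + \varepsilon)$,
$\varepsilon \sim N(0, CV^2)$, truncated at zero.  Kinetics are saturating
exponentials $A(t) = A_{max}(1 - e^{-t/\tau_A})$ (and likewise $I(t)$),
chosen because observed anchoring and uptake rise gradually and level off;
the functional form is a modelling stand-in, not an empirical claim.

The `"reference"` preset fixes the study conditions: two types, $n = 4$
replicate wells, $CV = 0.15$, and kinetics

| type    | $A_{max}$ | $\tau_A$ | $I_{max}$ | $\tau_I$ |
|---------|-----------|----------|-----------|----------|
| prickly | 100       | 2 hr     | 150       | 4 hr     |
| round   | 50        | 2 hr     | 600       | 4 hr     |

so that prickly anchoring is exactly twice round anchoring (hence at the
6-hr comparison point) and round internalization exactly four times prickly
(hence at 10 hr).  The intensity magnitudes are arbitrary units chosen once
so that the prickly type remains substantially surface-anchored at 10 hr
(~42% of its total) while the round type is majority-internalized —
the qualitative picture the assay is meant to detect.  Shared time grid
{10 min, 30 min, 1, 3, 6, 10 hr} for both conditions: the subtraction at
10 hr requires a 4 °C measurement at 10 hr, so the design extends the 4 °C
series to the full grid rather than stopping at 6 hr.

The generator is deterministic given its seed (per-window and per-plate
substreams), returns the generative truth alongside the data, and
emulates: the condition/time/replicate structure, type-specific kinetics,
and multiplicative plate noise.  It does **not** emulate cell-to-cell
heterogeneity, plate-position effects, autocorrelated readings, or
background drift — so recovery tests certify the estimator pipeline, not
robustness to every artifact of real plates.

## 6. Problem sizes used in the shipped tests

The test suite runs the geometry oracle on 1,000 random feasible polygons
at 10⁴ chords/arc, ensemble curves at 2,000 polygons per radius (the
package default remains 100,000), WHAM recovery at 13 windows × 10⁴
samples, and uptake recovery over 500 simulated plates — sizes at which
every stochastic assertion has comfortable margin while the whole suite
runs in well under a minute.

## 7. Known limitations

* The polygon model is the 2-D contact-patch abstraction only; no 3-D
  meshes, no shapes derived from micrographs, and no attempt to fit $R_r$
  to real etched particles.
* WHAM here assumes uncorrelated samples; applying it to correlated MD
  time series requires the user to subsample or to treat error bars with
  care.
* The wrapping model is the two-term bending-plus-adhesion balance at zero
  tension; stretching, tension, curvature-sensing proteins and full-particle
  engulfment are out of scope.
* The uptake pipeline assumes the 4 °C condition fully suppresses
  internalization; any residual uptake at 4 °C biases the anchored estimate
  upward and the internalized estimate downward.
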