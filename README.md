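# ndwrap

Shape-dependent nanoparticle endocytosis: contact geometry, adhesion
energetics and uptake quantification.

## The problem

Cellular uptake of a nanoparticle happens in two stages: **anchoring** to
the plasma membrane, then energy-dependent **internalization**.  Particle
shape pulls these stages in opposite directions — a faceted particle with
sharp edges presents a larger flat contact patch and anchors readily, but
its sharp tips are expensive for the membrane to wrap; an etched, rounded
particle anchors less but internalizes more.  `ndwrap` provides the four
computational models that make this trade-off quantitative, for anyone
analysing faceted-vs-rounded nanoparticle uptake (fluorescent nanodiamonds
being the motivating system):

1. **Contact-area model** — Monte-Carlo ensembles of random irregular
   polygons whose corners are replaced by tangent circular fillets of
   radius $R_r$; exact rounded areas via the Green's-theorem boundary
   integral, and mean relative-area curves $\langle A(R_r)/A(0)\rangle$.
2. **Adhesion energetics** — a weighted-histogram (WHAM) solver that
   reconstructs a 1-D potential of mean force $F(z)$ from harmonic
   umbrella-sampling windows,
   $p_b \propto \sum_w n_{wb} \big/ \sum_w N_w e^{-\beta(U_w(z_b)-f_w)}$,
   its well depth $\Delta F$, and the unit adhesion strength
   $k_{ad} = \Delta F / A_{slab}$ (kcal/mol/nm²).
3. **Wrapping energetics** — the continuum tip-wrapping energy
   $G_{tot}(\theta) = [4\pi k_b + 2\pi R^2 k_{ad}](1-\cos\theta)$ on a
   tension-free membrane, the critical tip radius
   $R_c = \sqrt{2 k_b/|k_{ad}|}$, and wrapping/no-wrapping phase diagrams
   over $(k_b, k_{ad})$.
4. **Uptake quantification** — the 4 °C / 37 °C temperature-split method
   for plate-reader fluorescence: anchored = 4 °C signal, internalized =
   37 °C minus 4 °C, with photoluminescence-slope normalization across
   particle types, error propagation over unpaired wells, and pooled/Welch
   two-sample tests.

A fifth module generates synthetic inputs for everything — umbrella-window
samples drawn exactly from the biased Boltzmann density of a known profile,
and plate assays with configurable anchoring/internalization effect sizes —
so the whole pipeline is testable without external data.  See the vignette
`vignettes/shape-dependent-endocytosis.Rmd` for models, assumptions and
design decisions.

## Worked example

```r
library(ndwrap)

## 1. How much contact area does corner rounding cost a 4-gon patch?
spec <- polygon_ensemble_spec(4, dr = 0.3, dalpha = 0.3,
                              n_samples = 2000, seed = 1)
as.data.frame(area_curve(spec, seq(0, 0.25, by = 0.05)))
#>   n_vertices   rr mean_relative_area sd_relative_area rejection_fraction n_effective
#> 1          4 0.00              1.000         0.000000             0.0000        2000
#> 2          4 0.05              0.999         0.000365             0.0000        2000
#> 3          4 0.10              0.994         0.001461             0.0000        2000
#> 4          4 0.15              0.987         0.003287             0.0000        2000
#> 5          4 0.20              0.977         0.005819             0.0005        1999
#> 6          4 0.25              0.964         0.008864             0.0110        1978
```

The mean relative area falls monotonically with the rounding radius
(in units of the mean circumradius): rounding a prickly patch at
$R_r = 0.25$ removes ~3.6% of its membrane contact area, which lowers its
anchoring free energy proportionally.

```r
## 2. Unit adhesion strength from synthetic umbrella sampling
pmf <- true_pmf_spec("well", depth = 9.93, z_min = 0.5, width = 0.3,
                     z_range = c(0.2, 2.6))
w <- sample_umbrella_windows(pmf, centers = 0.45 + 0.15 * (0:12),
                             force_constant = 400, n_per_window = 10000,
                             seed = 1)
prof <- wham_solve(w)
k_ad_from_depth(pmf_depth(prof), slab_spec(2, 2))
#> Adhesion estimate: depth 9.972 kcal/mol over a 2 x 2 nm slab -> k_ad = 2.493 kcal/mol/nm^2
```

WHAM recovers the 9.93 kcal/mol ground-truth depth to 0.4% from 13 windows
of exact biased samples, giving $k_{ad} \approx 2.49$ kcal/mol/nm² on the
2 nm × 2 nm slab.

```r
## 3. Which tips get wrapped at that adhesion strength?
critical_radius(20, kad_signed(2.34), k_b_units = "kBT")
#> [1] 3.182444
```

With a typical bilayer bending modulus of 20 k_BT and adhesion strength
2.34 kcal/mol/nm², tips sharper than ~3.2 nm are not wrapped — sharp
corners stall internalization right at its first step.

```r
## 4. Recover anchored/internalized amounts from a simulated plate
sim <- simulate_assay(assay_design(), seed = 1)   # reference preset
res <- quantify_uptake(sim$assay)
uptake_ratio(res, "internalized", numerator = "round",
             denominator = "prickly", time_hr = 10)
#> $ratio
#> [1] 4.78471
#> $se
#> [1] 0.7858416
```

On this single simulated plate the 37 °C-minus-4 °C pipeline estimates the
round particles internalize 4.8× (± 0.8) as much as the prickly ones at
10 hr; the generative truth is 4×, and averaging over many plates recovers
it to within ~1%.

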