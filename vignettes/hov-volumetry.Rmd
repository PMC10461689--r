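---
title: "Hill-of-vision volumetry: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hill-of-vision volumetry: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hovmp)
```

This vignette is the package's account of the science it implements: the
surface model and its assumptions, the volume quadrature, the statistical
machinery downstream, what the synthetic cohort generator does and does not
emulate, and the choices made where the design was genuinely open.

## The measurement and the grid

Fundus-controlled perimetry (microperimetry) maps light-sensitivity
thresholds, in dB on a 0–36 dB dynamic range, to retinal locations tracked
in visual-field coordinates. The 24-point standard grid places stimuli on
the ±1°, ±3°, ±5° positions of both axes with `|x| + |y| ≤ 6°`:

```{r grid}
g <- pinnacle_grid()
nrow(g$points)
convex_hull_area(g$points)
```

The hull is an octagon of exactly 68 deg² (the four corner triangles of the
10°×10° square are cut off by the diagonal `|x| + |y| = 6` edges). Two
geometric facts matter downstream: the hull has only 8 extreme points — the
(±3°, ±3°) locations sit *on* its diagonal edges — and the point set is
symmetric under sign flips and axis swap, so odd (affine) surface terms
integrate to zero over it.

Coordinates are visual-field cartesian degrees with fixation at the origin,
as recorded by the device; no automatic left-eye mirroring is applied. The
grid and both summary metrics are mirror-symmetric, so volumes and MS are
unaffected; users needing retinal (nasal/temporal) coordinates can mirror x
for left eyes themselves before plotting.

## The thin-plate-spline surface

`fit_tps()` solves the classical scattered-data thin-plate-spline system:
kernel `φ(r) = r² log r` (with `φ(0) = 0`), an affine part
`a₀ + a₁u + a₂v`, and the side conditions `Σw = Σwu = Σwv = 0` that make
the kernel part orthogonal to affine trends. With smoothing `λ = 0`
(default) the surface passes through every threshold exactly; `λ > 0` adds
a ridge term on the kernel block. Exact interpolation is the default
because it is the only parameter-free, fully reproducible choice;
smoothing-parameter selection (e.g. by cross-validation) is left to the
user via `lambda`.

Assumptions worth stating: the spline is a minimal-bending-energy
interpolant, so between test points it can *overshoot* — a deep focal
defect surrounded by normal points produces surface values below 0 dB
(below the measurable floor) near the defect. By default this overshoot is
integrated as-is, because clamping silently hides a property of the
interpolant; `clamp_floor = TRUE` clamps at 0 dB for users who prefer the
physically-bounded reading. Degenerate inputs (duplicate nodes, collinear
layouts at n = 3) make the system singular and are refused with the
offending points named.

## Two volume engines, one fit space

The total volume beneath the surface is reported in two parameterizations:

- **cartesian**: `∬ f(x, y) dx dy`, in dB·deg²;
- **polar**: `∬ f(θ, φ) sinθ dθ dφ`, in dB·sr (solid-angle element).

Both engines fit the spline in the same planar coordinates; the polar
engine's fit space is azimuthal-equidistant `(θ cosφ, θ sinφ)`, which is
numerically identical to cartesian degrees at macular eccentricities. The
engines therefore differ only in the area element and the unit of the
result. This is a deliberate minimal reading of "polar coordinates with
dB·sr output": it isolates the one mathematically forced difference (the
`sinθ/θ ≤ 1` weighting) without speculating about any particular vendor
implementation. Within the 5.1° grid, `sinθ/θ ≥ 0.9974`, so the two
engines must agree within ~0.26% after unit conversion — a property the
test suite asserts, and a useful calibration check for any other pair of
volume implementations. Published comparisons of real cartesian- and
polar-engine software report method differences of either sign and larger
magnitude; those arise from unshared implementation details (integration
domain, smoothing, basis), which is why both the domain and λ are exposed
as configuration here rather than fixed assumptions.

Units convert exactly: `1 sr = (180/π)² ≈ 3282.8 deg²`; MS (dB) converts
to dB·deg² by multiplying by the 68 deg² grid area.

## Quadrature

`integrate_hov()` uses a midpoint-rule raster (default cell 0.05°) over the
convex integration domain. One refinement over a plain
center-in-polygon mask: cells straddling the boundary are clipped exactly
against the domain polygon (Sutherland–Hodgman) and contribute their true
overlap area. The plain mask is biased here — the hull's diagonal edges are
commensurate with any raster anchored at the grid bounding box, so many
cell centers fall exactly on an edge and the tie-breaking error accumulates
systematically (~0.5% for constant fields at 0.05°). With exact-overlap
weights, constant fields integrate exactly at any resolution, and the
remaining error for smooth fields is the midpoint error of interior cells.
Every integration can report a convergence estimate (relative difference
against a half-resolution pass); the default resolution keeps it below
10⁻³ for exam-like surfaces.

The default domain is the convex hull of the test points — no extrapolation
beyond tested retina, and `MS × area` equals cartesian VTOT exactly for
constant exams. A disc domain (any radius, represented as a fine regular
polygon, 1440 vertices by default) is available for sensitivity analyses;
for a constant surface over a disc of angular radius α the polar engine
recovers the spherical-cap solid angle `2π(1 − cos α)` as resolution
shrinks, which the tests use as a closed-form oracle.

## Classical metrics

`mean_sensitivity()` is the plain average of the 24 thresholds. `bcea()`
implements the bivariate contour ellipse area as the probability ellipse of
a fitted bivariate normal: `BCEA_P = π χ²₂(P) σx σy √(1−ρ²)` with sample
(n−1) standard deviations and `χ²₂(0.95) = −2 ln 0.05 ≈ 5.9915`. This is
the standard definition in the fixation-stability literature, stated
prominently because legacy conventions with fixed multipliers (e.g. 1.14
per axis) circulate in device firmware; the `coverage` argument exposes the
quantile. `log10(BCEA95)` is the analysis variable — fixation areas span
orders of magnitude and are strongly right-skewed.

Device "not seen" responses (code −1) are stored as 0 dB — the floor of the
stated dynamic range — with a per-point flag, so sensitivity analyses can
exclude flagged points. This is a convention, not a device specification;
it is the one fact the exam I/O layer invents, and it round-trips through
the CSV dialect.

## Method comparison

`bland_altman()` computes bias (mean of paired differences) and 95% limits
of agreement `bias ± 1.96 × SD`. The multiplier is fixed at 1.96 — the
classic presentation — rather than a t quantile; at the cohort sizes this
package targets (hundreds of eyes) the difference is cosmetic, and the
fixed multiplier keeps the arithmetic identity `LoA = bias ± 1.96·SD` exact
for testing. Unit harmonization (dB·sr → dB·deg²) is the caller's
responsibility in the core function and automatic in the `run_compare()`
stage, keyed on column naming.

`paired_comparison()` gates the paired test on normality of the
differences: D'Agostino–Pearson omnibus test (implemented in-package from
the standard transformed-skewness and transformed-kurtosis statistics,
n ≥ 8; Shapiro–Wilk fills in below that), then paired t-test if normal at
α = 0.05, else Wilcoxon signed rank. All-zero differences are reported as
a degenerate comparison with p = 1 rather than an error.

## Mixed-effects association

`fit_lmm()` regresses a sensitivity metric on per-eye covariates with eyes
nested in patients. With one exam per eye — the cross-sectional design this
package targets — the eye-within-patient variance is not statistically
separable from the residual: both act at the eye level exactly once. The
model therefore carries a random intercept per patient, and the fit object
flags the eye variance as merged into the residual (`eye_merged`). When
eyes have replicate rows (repeated visits), an explicit
`(1 | patient:eye)` intercept is added. Slope estimates, Satterthwaite
t-statistics, and the Nakagawa R² decomposition are unaffected by the
merge, since eye and residual variance enter every denominator as a sum.

Marginal R² is `var(Xβ)` over the total variance; conditional R² adds the
random-effect variances to the numerator. Both are recomputed by
independent arithmetic in the tests from the stored variance components.

Variable selection follows the two-track design: backward elimination by
per-term Satterthwaite F-tests (drop the largest p above 0.05, ties broken
by name order), validated by greedy forward selection on ML-fit BIC. The
treatment coding uses clinically conventional reference levels (phakic,
never-smoked, female). A condition-number guard (κ > 10⁶ on the full fixed
design, intercept included so affine dependences register) refuses
collinear multivariable fits with an actionable message; forward selection
treats such candidates as unavailable. This mirrors the practical failure
mode of entering two strongly correlated acuity measures (BCVA and LLVA)
into one model. Covariates are not standardized before modeling — slopes
are reported per logMAR and per log₁₀(deg²), the scales on which they are
interpreted.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so every stage is testable end-to-end with known ground
truth. Per eye, the true surface is

```
S(x, y) = base + patient + eye − s·(x² + y²) − Σ depth·exp(−‖(x,y)−c‖²/(2r²)),
```

a plateau with nested Gaussian offsets, a quadratic eccentricity falloff,
and Poisson-many Gaussian scotomata. Thresholds add test-retest noise, are
rounded to integer dB (staircase output) and clamped to [0, 36], with
sub-floor responses emitted as the device's "not seen" code.

Default calibration, chosen once as a realistic intermediate-AMD profile:
189 patients with a 0.31 probability of contributing the second eye
(≈ 250 eyes); base 26 dB; eccentricity falloff 0.06 dB/deg² (≈ 0.9 dB mean
depression over the grid); patient/eye/test SDs 2/1/1.5 dB; scotoma rate
0.5 per eye with depth 5–20 dB and radius 0.8–2°. The acuity link
`LLVA = 0.95 − 0.025·(mean S) + N(0, 0.15²)` logMAR and BCVA correlated at
0.8 put the acuity medians, spreads, and the emergent sensitivity–LLVA
slope on the scale reported for real iAMD cohorts; fixation dispersions
uniform on 0.02–0.17° per axis put median log₁₀(BCEA95) near −0.8.
Categorical covariates are drawn at published iAMD cohort frequencies
(35.2% pseudophakic; 42.1/49.8/8.1% never/ex/current smoker; 64% female).
R's default Mersenne-Twister generator is used throughout; the seed fully
determines the cohort.

Two things the generator deliberately does *not* emulate: spatial
correlation of test-retest noise between neighboring points, and any
structural (OCT-coupled) drivers of sensitivity loss. Passing tests
therefore validate the *pipeline* — geometry, interpolation, integration,
unit bookkeeping, model identification — under a plausible data-generating
process; they are not evidence about real-device noise characteristics.
Likewise `simulate_lmm_table()` plants regression coefficients directly at
the table level (the forward model's acuity slope is emergent, not
planted), which is what coverage and selection-frequency simulations
require.

`oracle_vtot()` integrates the *true* surface — not the spline — at 0.01°
resolution, giving an independent reference for the TPS volume estimate;
its constant and quadratic terms are additionally cross-checked against
exact polygon moments (Green's theorem), a second independent route.

## Problem sizes and tolerances

The validation suite runs exams at 0.05° quadrature (convergence checked
against 0.025°), TPS node-exactness at 10⁻⁸ dB over 100 random integer
exams, engine agreement at 0.2%, Monte-Carlo BCEA at n = 10⁵ within 2%,
and the mixed-model simulations at 200 cohorts of 190 patients (CI
coverage) plus 25 replicates for selection frequency — sizes at which the
binomial noise of the checked proportions is comfortably inside the
asserted bands.

## Known limitations

- Convex integration domains only (hull or polygonal disc).
- The polar engine is a parameterization of the same planar fit, not an
  emulation of any specific commercial implementation.
- One grid geometry ships built-in; other layouts work through the same
  API (`mp_exam` accepts any `mp_grid`), but validation tolerances were
  chosen with 2° point spacing in mind.
- Cross-sectional only; no longitudinal/ability-to-detect-change analysis.
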