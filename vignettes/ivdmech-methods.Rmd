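---
title: "Models and methods in ivdmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ivdmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivdmech)
```

ivdmech quantifies two complementary aspects of soft embryonic spine
tissue: its time-dependent micromechanics, from spherical ramp-hold
nanoindentation, and the organisation of its collagen network, from
grayscale fluorescence images. This vignette explains the models, the
tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## The viscoelastic indentation model

A rigid sphere of radius $R$ pressed a depth $h$ into an incompressible
elastic half-space carries the Hertzian force

$$P = \frac{4\sqrt{R}}{3(1-\nu^2)}\,E\,h^{3/2},$$

with Young's modulus $E$ and Poisson's ratio $\nu$ (0.5 throughout,
assuming incompressibility). For a viscoelastic material,
elastic–viscoelastic correspondence replaces $E$ by a Boltzmann
hereditary integral over the relaxation function $G(t)$:

$$P(t) = \frac{4\sqrt{R}}{3(1-\nu^2)} \int_0^t G(t-u)\,
  \frac{\mathrm{d}\,h(u)^{3/2}}{\mathrm{d}u}\,\mathrm{d}u .$$

We use the standard linear solid (SLS): a spring $E_0$ in parallel with a
Maxwell arm (spring $E_1$, relaxation time $\tau_1$), so
$G(t) = E_0 + E_1 e^{-t/\tau_1}$. Three derived quantities summarise a
fit:

* instantaneous modulus $E_{ins} = G(0) = E_0 + E_1$,
* equilibrium modulus $E_{eq} = G(\infty) = E_0$,
* elastic fraction $f = E_{eq}/E_{ins} \in [0, 1]$, where $f = 1$ is a
  purely elastic and $f = 0$ a purely viscous material.

The displacement command is a trapezoid: a ramp at $v$ = 2 um/s to
$h_{max}$ = 2 um, a 10 s hold, and an unload at 2 um/s. The hereditary
integral is solved separately on the ramp ($h = vt$) and the hold
($h = h_{max}$); the unload is outside the model and never fitted. On the
ramp the Maxwell term reduces to
$e^{-t/\tau_1}\int_0^t e^{u/\tau_1}\sqrt{u}\,\mathrm{d}u
 = \tau_1^{3/2}\,(x - D(x))$ with $x = \sqrt{t/\tau_1}$ and $D$ the Dawson
function. This form is evaluated without overflow for any $t/\tau_1$; the
package's Dawson implementation uses the scaled imaginary error function
below $x = 6$ and a 14-term asymptotic series above, accurate to about
1e-11. An adaptive-quadrature evaluation of the same integral is kept as
an independent route and the two agree to better than 1e-8 relative
(tested over $\tau_1/t_{ramp} \in \{0.1, 1, 10\}$).

Units are um, s, kPa and uN end to end. In (um, kPa) the Hertz prefactor
produces nN, so a single factor of 1/1000 sits at the model boundary;
this avoids the double conversions of a mixed SI scheme and is pinned by
an arithmetic test ($E^* = 40$ kPa, $R = 42$ um, $h = 2$ um gives
0.978 uN).

## Contact detection and fitting

Soft, hydrated samples give force curves whose contact point is not
sharp. `detect_contact()` estimates the pre-contact baseline level and
linear drift from the early record (only a 60 % prefix of the samples
before the force first reaches 20 % of its excursion, so the rise onset
stays out of the fit), then finds the threshold crossing
$\delta = \max(0.003\ \mathrm{uN},\ 0.5\%\ \mathrm{of}\ P_{max})$. Both
thresholds are parameters; the defaults reflect an instrument whose
noise floor sits well below 0.003 uN, which is what makes that rise a
*significant* change. Two robustness rules matter in practice:

* the exceedance run that must persist is the one connected to the force
  peak, so short noise excursions in the baseline cannot fire detection;
* the detected index is backtracked along the raw residual to the start
  of the rise, and a curve that opens significantly above its own
  baseline (judged against a successive-difference noise estimate) is
  rejected as having no visible pre-contact segment.

`fit_sls()` performs bounded nonlinear least squares
(Levenberg–Marquardt via minpack.lm) of the forward model against the
measured force over ramp and hold. Bounds are $E_0, E_1 \ge 0$ and
$\tau_1 \in [\Delta t, 10\,t_{hold}]$; starting values come from the
hold plateau ($E_0$), the force at ramp end ($E_0 + E_1$) and a
log-linear fit of the hold decay ($\tau_1$), with a small multi-start
grid over $\tau_1$ as fallback. One design choice deserves emphasis: the
contact time is refined as a fourth bounded parameter (within 20 samples
of the detected index), with the ramp speed and hold window taken from
the clean displacement command. At 100 Hz a one-sample contact error
biases $E_{ins}$ by about 1.5 %, more than the fit's own noise floor;
joint contact refinement removes that bias and is common practice in
indentation analysis. Fits with $f$ or $\tau_1$ pinned at a bound are
flagged but retained; exclusion is the caller's choice.

Measurement validity follows two rules: representative contact strain
$0.2\,a/R$ with $a = \sqrt{R\,h_{max}}$ (the Tabor convention — chosen
because it reproduces the "below 5 %" property of a 2 um indent with a
42 um tip, which depth-over-radius definitions do not), and indentation
depth below 10 % of the section thickness (25 um sections give a ratio
of 0.08).

```{r}
check_validity(h_max_um = 2, tip_radius_um = 42, section_thickness_um = 25)
```

## Synthetic indentation data

`generate_indent_curve()` forward-simulates the full trapezoid: an
approach segment at the ramp speed (displacement below contact, force
zero), the modelled ramp and hold, and a linear force taper over the
unload (plumbing only — the fit never sees it). Additive i.i.d. Gaussian
force noise (default 0.001 uN for cohorts, consistent with a 0.003 uN
threshold being a ~3-sigma event) and optional linear drift complete the
noise model; the paper-facing analyses need nothing richer, and the
generator's ground truth (true parameters and contact index) travels
with every record.

`generate_cohort()` adds the nested structure the group statistics
assume: specimen-level $E_{ins}$ and $f$ drawn from a between-specimen
normal, indent-level values from a within-specimen normal around them,
by default 3 specimens per group and 6 indents per structure.
`cervical_cohort_spec()` carries the built-in cell means and SDs for
vertebral bodies C5/C6 and the C5–C6 annulus fibrosus of control and
muscular-dysgenesis (mdg) groups at Theiler stage 24. Published tables
report one total SD per cell; the generator splits it into equal
between- and within-specimen variance shares (each total/sqrt(2)) —
with only three specimens per group the split is not identifiable from
the table, and equal shares keep both variance components active in the
mixed-model tests. Draws use an exact inverse-CDF truncated normal
($E_{ins} \ge 1$ kPa, $f \in [0.02, 0.98]$): embryonic tissue softer
than ~1 kPa is not measurable with this probe, and clamping (rather than
truncating) would create a point mass of degenerate curves. No summary
table constrains $\tau_1$; the default 2 s makes the hold decay fully
resolved within the 10 s hold ($\tau_1 \ll t_{hold}$), so $E_{eq}$ is
identifiable. Sampling is 100 Hz, giving 100 points on the 1 s ramp.

What the generator does *not* emulate: cantilever compliance (commanded
displacement is treated as indentation depth — the instrument class
reports displacement control only, and the 0.48 N/m spring constant is
carried as metadata), adhesion, poroelastic drainage, spatial
heterogeneity within an indent, and thermal drift nonlinearity. Passing
round trips therefore demonstrate correctness of the analysis chain, not
robustness to every instrument artifact.

## Orientation analysis

Collagen orientation is computed per pixel from the structure tensor:
image gradients $g_x, g_y$ (derivatives of a separable natural cubic
spline interpolant; a central-difference fallback is available and
agrees within 2 degrees on phantoms), tensor components
$\langle g_x^2\rangle, \langle g_x g_y\rangle, \langle g_y^2\rangle$
averaged under a Gaussian window ($\sigma$ = 10 px, truncated at
3 sigma, reflective boundaries), orientation
$\theta = \tfrac12\,\mathrm{atan2}(2J_{xy},\,J_{xx}-J_{yy}) + 90^\circ$
folded to $[0, 180)$ — the direction *along* structures, measured
counter-clockwise from the image x-axis (the dorsoventral axis) — and
coherency $(\lambda_{max}-\lambda_{min})/(\lambda_{max}+\lambda_{min})$,
defined as 0 where the tensor trace vanishes. Pixels enter the
statistics only if their intensity exceeds 5 % of the image maximum and
their coherency exceeds 0.05 (both strict), matching common practice for
fluorescence images of fibrous tissue.

The region of interest is split at the midpoints into four quadrants
(cranial/caudal x dorsal/ventral; with odd dimensions the extra pixel
goes to the caudal/ventral half; axis polarity is configurable and
flipping it relabels, never recomputes). Angles are axial — defined
modulo 180 degrees — so all statistics double the angles first: the
circular mean is $\tfrac12\,\mathrm{atan2}(\bar S, \bar C)$ of the
doubled angles, dispersion is $\tfrac12\sqrt{-2\ln\bar R}$ (degrees),
histograms use 36 five-degree bins, and a region with mean resultant
length $\bar R < 0.1$ is flagged as having no predominant orientation.
Across samples, the group table reports the axial circular mean of the
per-sample means and the root-mean-square axial deviation from it, so
means straddling the 0/180 wrap (5, 175, 0 degrees) aggregate correctly.

```{r}
circular_summary(c(10, 170))$circular_mean_deg  # 0, not 90
```

`generate_fiber_image()` renders straight fibres with a Gaussian
cross-section (profile SD of half the nominal fibre width) at angles
drawn from a wrapped normal on doubled angles, optionally with distinct
distributions per quadrant, plus flat background and pixel noise. A
noise-free background has exactly zero coherency everywhere; note that
for an i.i.d.-noise background the windowed coherency distribution
straddles the 0.05 threshold (median about 0.04 at sigma 10), and the
few surviving pixels cluster into blobs at the window scale, so their
resultant length is dominated by small-sample variation — the
predominance flag is meaningful only when many independent coherent
regions exist. Phantoms do not emulate confocal optics, fibre curvature,
crossing-density effects or depth attenuation.

## Group statistics

Observations are per-indent $E_{ins}$ or $f$ values nested in specimens.
Outliers are removed in one pass per cell (structure x stage x group,
pooled over specimens): an observation is excluded when it deviates from
the cell mean by more than three cell SDs, where mean and SD are
computed leaving that observation out. The leave-one-out form matters at
these cell sizes: with the candidate included, no point of an $n$-point
sample can deviate more than $(n-1)/\sqrt{n}$ SDs, so the rule would be
vacuous for $n \lesssim 10$.

The group comparison fits
$y = \mu + \mathrm{group} + \mathrm{specimen(random)} + \varepsilon$ and
tests the fixed group effect with containment degrees of freedom: the
denominator df is the number of specimens minus the number of groups, so
3 + 3 specimens give F(1, 4) regardless of how many indents each
specimen contributes. Operationally the test is one-way ANOVA on the
specimen means with specimens weighted equally — exactly the mixed-model
F-test for balanced data (verified against REML via lmerTest in the test
suite) and the package's normative definition for unbalanced data.
Significance is fixed at 0.05 with no multiple-testing correction across
structures, mirroring the small-cohort practice this package supports;
that is a limitation, not a recommendation.

## Pipeline, problem sizes and reproducibility

`run_pipeline()` chains both arms (simulate/read curves, detect, fit,
validity-filter, exclude, compare; generate phantoms, orient, mask,
quadrant summaries, group table), writes tidy CSVs plus a manifest (seed,
config hash, package version, failure count), and continues over
per-item failures while counting them. Everything is regenerable from
config + seed. The bundled demo config uses an annulus-only cohort (2
groups x 3 specimens x 6 indents) and two 128 px phantom images per
group; the test suite exercises the same sizes, with 512 px phantoms and
a 50-seed noise study where the statistical claims require them, chosen
so the whole suite runs in a couple of minutes on one CPU. Orientation
accuracy improves with image size through the ratio of image extent to
the 10 px window; 512 px phantoms recover a 5-degree-SD fibre field's
mean within a fraction of a degree.

Known limitations: the SLS is the simplest relaxation model that
separates instantaneous and equilibrium stiffness — tissues with broad
relaxation spectra will show systematic hold-phase residuals; contact
refinement assumes the displacement command is clean; the orientation
pipeline assumes approximately straight fibres at the window scale; and
the containment-df comparison is conservative when indent counts are
very unbalanced across specimens.
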