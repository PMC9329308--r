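---
title: "DOCI analysis: model, phantom design and statistical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DOCI analysis: model, phantom design and statistical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dociR)
```

## The DOCI measurement model

Dynamic optical contrast imaging estimates a *relative* fluorescence
lifetime per pixel without per-pixel exponential fitting. A square
excitation pulse drives the tissue's endogenous fluorophores; during the
pulse the fluorescence of a component with amplitude $a$ and lifetime
$\tau$ rises as $a\,(1 - e^{-(t - t_\mathrm{on})/\tau})$, and after
turn-off it decays as
$a\,(1 - e^{-T/\tau})\,e^{-(t - t_\mathrm{off})/\tau}$ with $T$ the pulse
width. The DOCI value is the ratio of two gated integrals of the detected
intensity,

$$\mathrm{DOCI} =
\frac{\int_{\mathrm{decay\ gate}} I(t)\,dt}
     {\int_{\mathrm{steady\ gate}} I(t)\,dt}
\;\xrightarrow{\ \text{saturated pulse, long decay gate}\ }\;
\frac{\sum_i a_i \tau_i}{W_\mathrm{ss} \sum_i a_i},$$

the amplitude-weighted mean lifetime divided by the steady-gate width
$W_\mathrm{ss}$. Two properties make this a robust imaging statistic: it is
invariant to overall intensity (illumination, concentration, collection
efficiency cancel in the ratio), and it is strictly increasing in the
lifetime of any mono-exponential pixel. `dociClosedForm()` evaluates the
exact integrals — including the pulse-saturation factor, the residual rise
term inside the steady gate and the decay-gate offset — rather than the
idealised limit; at the default timing the two differ by less than
$10^{-5}$ relative, but the exact form is what gated trapezoidal
integration of `decayTrace()` converges to, which keeps the dual-route
tests honest.

### Timing defaults

No gate timings are dictated by the measurement principle itself, so the
package declares its own: pulse $[0, 100)$ ns, steady-state gate
$[50, 100]$ ns, decay gate $[100, 200]$ ns, sampling step $0.5$ ns. For
nanosecond-scale endogenous fluorophores (NADH $\sim$0.4–2.5 ns bound/free,
FAD and collagen single-digit ns) a 100 ns pulse saturates the rise to
better than $10^{-6}$ and a 100 ns decay gate captures essentially the
whole tail, so the measured ratio sits in the clean
$\sum a\tau / (W_\mathrm{ss}\sum a)$ regime. All timings are user-settable
through `PulseTiming()` and the YAML configuration.

Gates are treated as closed integration windows on the sample grid: the
trapezoid spans the full gate width, and the sample at the
steady-gate/decay-gate boundary is shared between the two integrals with
half weight each — the natural behaviour of the trapezoid rule, and the
convention under which a constant unit signal over a 50 ns gate aggregates
to exactly 50.

### Numerical behaviour

Trapezoidal integration of a sampled exponential carries a relative bias of
about $(\Delta t/\tau)^2/12$. At the default $\Delta t = 0.5$ ns this is
$\sim 0.9\%$ for the shortest default lifetime (tumor, 1.5 ns) and
$< 0.1\%$ for lifetimes $\ge 5$ ns. The bias cancels almost entirely in
*comparisons* (it scales all tissues alike to first order), which is why the
default step is kept coarse for speed; tests that compare a rendered pixel
against the analytic value to sub-percent accuracy use $\Delta t = 0.1$ ns,
where the bias is $\le 0.04\%$ over the whole default lifetime range.

## What the phantom emulates — and what it does not

The generator composes labelled scenes (rectangles, ellipses, axis-aligned
nerve bands; 0-based row-major pixel geometry) over seven tissue classes
and renders one time-resolved stack per emission channel. Detected counts
follow the standard CMOS camera model: Poisson shot noise on
$\text{photonScale} \times \text{trace}$ plus additive Gaussian read noise,
clipped at zero. Channels draw from independent RNG substreams derived from
the scene seed, so a channel subset renders bit-identically to the full
render.

Default lifetimes (ns, channel-uniform): tumor 1.5, PNI+ nerve 1.8, muscle
2.5, nerve 4.0, dermal adipose tissue 5.0, adipose 6.0. These are invented
values constrained only by the orderings the analysis depends on — invaded
nerve strictly below healthy nerve in every channel, tumor distinct from
every healthy class — which `defaultTissues()` enforces as invariants.
Per-channel amplitude overrides exist so spectral contrast between channels
can be configured, but the defaults are deliberately channel-uniform: with
them, all channels are equally informative and the contrast-score ranking
ties. Consequently the package's channel ranking is a configuration-driven
mechanism, not a claim about which physical wavelength separates real
tissues best.

The phantom does **not** model optical blur, spectral bleed-through between
band-pass filters, tissue curvature or motion, instrument response
deconvolution, or dark-frame structure. Passing tests therefore demonstrate
that the *analysis chain* is correct under its stated noise model — they do
not certify performance on real surgical fields, where contrast is smaller
and artefacts abound.

Default scene sizes are chosen to keep a full test run cheap while
preserving the statistical design: the margin scene packs 15 instances per
tissue of 15×15 px blocks (~104×172 px), and the nerve scene is 32×64 px
with 8 px-wide bands and the invasion transition at column 32.

## Statistical design

**Sampling unit.** One connected ROI region is one sample — mirroring one
animal/tumor (15 tumor instances, 6 nerves). Treating pixels as samples
would inflate $n$ by orders of magnitude and make every comparison
spuriously significant; instance means are the honest unit.

**Normalisation.** Per channel, every tissue's instance means are divided
by the grand mean of the reference tissue (tumor for margins, PNI+ nerve
for the invasion sweep), so the reference normalises to exactly 1 and other
tissues become relative lifetimes. Normalisation is global per channel, not
per-animal, and is idempotent.

**Test.** Each non-reference tissue is tested with a one-sample t-test of
its normalised means against 1, two-sided, independently per channel (the
Manhattan-plot presentation). Raw p-values are compared against
$\alpha = 0.05$; Benjamini–Hochberg q-values are emitted as an additional
column but do not drive the significance flag, matching the per-channel
reporting convention.

**A calibration caveat.** Dividing by an *estimated* reference mean couples
the samples: with $n$ test and $n_\mathrm{ref}$ reference instances of equal
variance, the t statistic is inflated by roughly
$\sqrt{1 + n/n_\mathrm{ref}}$ under the null, because the shared divisor
shifts all normalised samples together while leaving their spread unchanged.
With $n = n_\mathrm{ref} = 15$ the nominal 5% test rejects a true null
~17% of the time. The package's type-I calibration checks therefore run in
the well-estimated-reference regime (200 reference instances against 15
test instances), where the inflation is below $\sqrt{1.075} - 1 \approx 4\%$
of the statistic and the empirical rejection rate sits within $0.05 \pm
0.02$. In the headline use the reference is far from the null (tumor vs
healthy separations of 65–300%), so the inflation is irrelevant to the
reported significances; it matters only if the method is pointed at
near-null contrasts with a small reference sample, and the vignette flags
it for that reason.

**Low-signal masking.** A pixel enters no statistic unless its steady-state
aggregate exceeds `minSteady`, by default five read-noise standard
deviations of the steady integral ($5\sigma_r\sqrt{W_\mathrm{ss}\Delta t}$).
Masked pixels carry value 0 and mask `FALSE` rather than a sentinel; ROI
means, profiles and renderings all honour the mask. Dark handling is folded
into this threshold: no separate dark-frame subtraction is modelled.

## The PNI decision rule

The caller quantifies the qualitative reading "invaded segments show lower
relative lifetime than control nerve":

1. extract the along-axis profile of each nerve band (mean unmasked DOCI
   across the band width per axial position);
2. calibrate a threshold on control nerves: pooled mean $- k \cdot$ sd,
   default $k = 3$;
3. call a nerve `pni` iff at least `min_run = 5` consecutive positions fall
   below threshold — the run-length persistence suppresses isolated noise
   dips — and report the first position of the first qualifying run as the
   transition point;
4. score each nerve by its whole-band mean (the way an intact nerve would
   be interrogated), and accompany the accuracy with a one-sample t-test of
   control-normalised PNI scores against 1.

The rule is a declared quantitative surrogate for a reader's visual call;
$k$ and `min_run` trade sensitivity against false calls and are exposed in
the configuration. Raising $k$ only ever moves calls toward `control`
(threshold consistency), and at the default effect size (nerve 4.0 ns vs
invaded 1.8 ns) the control and invaded value distributions separate with
no overlap at photon scales $\ge 10^3$, which is what makes the 100%
batch accuracy reproducible. Curved-nerve centerline tracing and
minimum-detectable-lesion analysis are out of scope.

## Degenerate inputs and tie-breaks

* Zero-lifetime components are admitted as the instant-decay limit (they
  contribute plateau intensity but no tail), making the zero-DOCI limit
  testable.
* Zero-variance samples (noiseless phantoms) report an *absent* p-value
  rather than erroring, so noiseless pipelines stay runnable end to end.
* Zero control variance degrades the PNI threshold to the control mean with
  a warning; strict inequality (`values < threshold`) then keeps an
  identical-valued healthy band classified as control.
* Contrast-score ties (the default, with channel-uniform spectra) resolve
  to the first channel in the configured order; the PNI calling channel
  defaults to 465 nm and is configurable.
* Negative integration results from read noise are clipped to zero before
  the ratio; masked pixels never produce `NaN`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate every phantom they
measure: 20 margin scenes (15 instances × 4 tissues × 9 channels) for the
significance re-creation, 10 batches × 12 nerve scenes for the accuracy
re-creation, 100 random mixtures for the closed-form/trapezoid agreement,
1000 instance-level replicates for the type-I calibration, and 100 noisy
scenes for transition recovery (±2 px at photon scale $10^3$). These sizes
were chosen as the smallest that exercise each claim at its stated
tolerance; all are set in code and scale up by changing one argument.

## Known limitations

* DOCI is a *relative* lifetime: absolute lifetimes, fluorophore unmixing
  and multi-exponential fitting are explicitly out of scope.
* The phantom's tissue parameters are plausible inventions, not fitted to
  measured autofluorescence spectra; quantitative agreement with any real
  instrument's per-channel curves is not claimed.
* The classified pseudo-color rendering assigns nearest-class in DOCI space
  at a single calling channel; composing all nine channels into one color
  image is left open.
* The shared-divisor inflation described above means tissue-vs-reference
  p-values near the null should be interpreted with the reference sample
  size in mind.
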