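---
title: "Methods: variance angiography, mask subtraction, and paired CNR comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance angiography, mask subtraction, and paired CNR comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varangio)
```

## The two imaging engines

An unsubtracted angiographic acquisition is a time-ordered stack of detector
intensities $I_t(x) > 0$. Both engines work in the attenuation (log) domain,
where the Beer–Lambert model makes contrast additive:
$a_t(x) = -\ln I_t(x) / I_{\mathrm{ref}}$.

**Digital subtraction angiography (DSA)** picks a pre-contrast mask frame $m$
and forms $d_t(x) = \ln I_m(x) - \ln I_t(x)$, positive where iodine
accumulates. For single-image comparison the package summarizes the run by
the frame maximizing $\sum_x \max(d_t(x), 0)$ (peak opacification; a
pixel-wise maximum-opacity projection is available as an alternative). The
log domain is the physically standard choice: subtraction in raw intensity
would leave anatomy-dependent residuals.

**Digital variance angiography (DVA)** uses no mask. Each pixel maps to the
sample standard deviation (denominator $N-1$) of its log intensity across
all $N$ frames,
$$\mathrm{DVA}(x) = \sqrt{\tfrac{1}{N-1}\sum_t \bigl(\ln I_t(x) - \overline{\ln I(x)}\bigr)^2},$$
which equals the SD of $a_t(x)$ for any constant reference — both engines
are exactly invariant to a global intensity gain. Flowing contrast makes a
pixel's attenuation vary in time, so vessels are bright; a motionless
background contributes only noise. For $N$ frames of i.i.d. Gaussian
attenuation noise $\sigma$, the expected background DVA level is
$\sigma \, c_4(N)$ with $c_4$ the finite-sample SD bias constant
(`c4_constant()`), and its spatial spread shrinks like
$\sigma/\sqrt{2(N-1)}$ — this is the mechanism by which DVA buys
contrast-to-noise: the per-frame DSA noise floor is $\sigma\sqrt{2}$ and
does not shrink with $N$. Both laws are verified by the test suite against
simulated all-background series.

The sample ($N-1$) rather than population denominator is a deliberate,
documented choice; the step-signal closed form
$\mathrm{DVA} = A\sqrt{k(N-k)/(N(N-1))}$ for an amplitude-$A$ signal present
in $k$ of $N$ frames pins it down, and the tests include a
denominator-mutation check.

## Contrast-to-noise ratio and its comparison

For a vascular region of interest paired with an adjacent background region
on the same image,
$$\mathrm{CNR} = \frac{\mathrm{Mean}_v - \mathrm{Mean}_b}{\mathrm{SD}_b},$$
with arithmetic means and the sample SD of background pixels. CNR is signed;
it is invariant to adding a constant to the image and flips sign only with
the sign of a multiplicative gain. CNR is always computed on raw engine
output: display windowing (`window_image()`) marks an image as windowed, and
`compute_cnr()` refuses such images, because a clipped linear rescale does
not preserve CNR.

Each ROI pair yields a CNR on the DSA image and on the DVA image formed from
the same frames; the per-pair ratio $\mathrm{CNR_{DVA}}/\mathrm{CNR_{DSA}}$
is the quantity of interest. Pairs with non-positive DSA CNR make the ratio
unstable or undefined; they are flagged and excluded from ratio summaries
but counted and reported, never silently dropped. Summaries are medians with
interquartile ranges (linear-interpolation percentiles), compared by the
Wilcoxon signed-rank test on paired CNR differences.

## The synthetic phantom

Patient angiograms are not distributable, so the package ships a generator
whose output has the statistical structure the measurement chain cares
about, with known ground truth:

* **Geometry** — large vessels (8–20 px wide), small vessels (3–4 px), a
  draining vein, and a diffuse tissue-blush patch, as mutually exclusive
  label classes on rasters of at least 64×64 (default 512×512).
* **Kinetics** — a gamma-variate time–attenuation curve per structure class,
  $a(t) = A\,\tau^{\alpha} e^{\alpha(1-\tau)}$ with
  $\tau = (t - t_0)/t_p$, peaking at exactly $A$; the venous curve is the
  arterial curve delayed and scaled. Arrival, time-to-peak and venous delay
  default to fractions of the series length (≈20%, 25%, 30%): clinically a
  run is filmed until the venous phase completes, so acquisition length
  tracks the lesion's transit time. This coupling also means longer series
  genuinely contain more temporal signal, not just more noise averaging.
* **Static anatomy** — a two-scale Gaussian random attenuation field
  (soft-tissue component, SD 0.25 at ~30 px; bone-detail component, SD 0.2
  at ~5 px). This field is load-bearing twice over: patient motion is only
  visible because static anatomy moves (a featureless background translates
  into itself), and sub-pixel shift estimation needs the fine component's
  gradient energy, exactly as clinical pixel-shift correction keys on bone
  edges. With the field disabled, pre-contrast frames are uniformly $I_0$.
* **Detector** — expected intensity $I_0 e^{-a}$, Poisson photon noise plus
  Gaussian read noise, clamped at one count so logarithms stay finite
  (clamp events are counted). Defaults $I_0 = 2000$ counts and read noise 2
  give a background attenuation noise of ≈0.022, placing DSA CNR of large
  vessels near the values angiographic studies report.
* **Motion** — rigid whole-field translation only, matching what pixel-shift
  correction can undo. Region profiles set the regime: upper limb none,
  lower limb occasional small jitter, head/neck intermittent jitter
  (≤1.5 px), chest a respiratory sinusoid (2.5 px, ~4 s period) plus jitter.
  The first frame is never displaced, so the canonical mask frame has zero
  true shift. Out-of-field pixels are filled with $I_0$.

Everything is a pure function of (configuration, seed); seeds for substages
derive from the master seed by an arithmetic hash (`derive_seed()`), so any
acquisition of a larger experiment reproduces in isolation.

What the phantom does **not** emulate: real AVM angioarchitecture, scatter
and beam hardening, deformable (non-rigid) motion, vendor display
processing, and human readers. Passing tests therefore demonstrate the
correctness and internal consistency of the measurement chain — not that
any particular patient-derived number would be reproduced.

## Motion correction

Shifts are estimated per frame against a reference by FFT cross-correlation
with two numerical safeguards, then refined to sub-pixel precision on a
locally upsampled DFT grid (10× by default; evaluated by matrix-multiply
DFT, so no full-size upsampled FFT is formed):

* A Hann taper is applied after mean subtraction. Without it, the constant
  border bands that rigid motion leaves at frame edges correlate with each
  other and bias the correlation peak toward zero shift.
* The reference defaults to the most structured frame (largest spatial SD of
  log intensity) rather than the mask frame, since a featureless frame
  carries no registration signal. Frames with numerically zero variance get
  shift (0,0) and a warning flag.

Wrap-around ambiguity resolves toward the smaller shift magnitude.
Alignment translates each frame by the negative shift with bilinear
interpolation and edge replication, which preserves positivity. ROI sets
defined in ground-truth coordinates are carried onto aligned images by
translating centers with the reference frame's true shift (`align_rois()`),
mirroring how ROIs are re-aligned between modality images after pixel shift.

## ROI placement policy

ROIs are circles whose pixel set is every raster pixel center within the
radius. Defaults are per class — large vessel and blush 4 px, vein 3 px,
small vessel 1.5 px — because a radius-4 disc cannot lie inside a 3–4 px
vessel; the background partner uses the same radius and its center must
fall 2–8 radii away ("adjacent"). Vascular discs must lie entirely on their
class, background discs entirely on background, and pairs never overlap.
When geometry cannot satisfy a request the placement returns fewer pairs
with an explicit per-class shortfall attribute and a warning.

## Statistical battery

* **Wilcoxon signed-rank** — zeros dropped, midranks on $|d|$; exact
  two-sided p by dynamic-programming enumeration of all $2^n$ sign
  assignments when $n \le 20$ and $|d|$ is untied, otherwise the normal
  approximation with tie correction and continuity correction. The exact
  path is tested against a literal $2^n$ enumeration oracle and against
  `stats::wilcox.test`.
* **One-sample t** — $t = (\bar{x} - \mu_0)/(s/\sqrt{n})$, two-sided; the
  result carries mean ± SEM for score reporting.
* **Kolmogorov–Smirnov normality** — parameters estimated from the sample,
  so the null is calibrated by Monte Carlo (Lilliefors-style, seeded,
  default 10,000 replicates) rather than the parameter-free KS tables.
* **Kendall's W** — midranks within rater, tie-corrected denominator,
  $\chi^2 = m(k-1)W$ p-value for $k \ge 3$ items; agreement bands at the
  conventional 0 / 0.1 / 0.3 / 0.6 / 1 thresholds. Under rater
  independence $E[W] \approx 1/m$, which is why the "no agreement" limit is
  only observable with many raters.
* **Power** — simulation-based: differences drawn from
  $\mathcal{N}(d, 1)$, the chosen two-sided test applied at level
  $\alpha$, rejection fraction reported with its binomial Monte-Carlo
  standard error. Correlation-type effects convert via
  $d = 2r/\sqrt{1 - r^2}$, so a medium $r = 0.3$ maps to $d \approx 0.629$.

No multiple-testing correction is applied anywhere, mirroring standard
practice in paired image-quality comparisons of this design.

**Synthetic raters.** To exercise the concordance and t-test machinery end
to end, `likert_rater_sim()` produces signed Likert scores in $[-3, 3]$ as
$\mathrm{clamp}(\mathrm{round}(g_i \Delta q + \varepsilon), -3, 3)$ with
rater noise $\varepsilon \sim \mathcal{N}(0, \sigma_r)$. The experiment
pipeline feeds it the standardized log median CNR ratio per acquisition and
class, with default noise $\sigma_r = 1.5$, which lands concordance in the
moderate band. These raters exercise the statistics; they are not a model
of human readers, and no claim about reader studies follows from them.

## Experiment pipeline and problem sizes

`run_experiment()` composes the full chain per acquisition: phantom →
motion → noise → (optional) pixel-shift correction → DSA + DVA → ROI pairs
→ paired CNR, then summarizes by region and overall, tests paired CNR
differences, and builds the rater-concordance table. The default
configuration simulates 132 acquisitions split 14/56/23/39 across upper
limb, lower limb, head/neck and chest, 25 ROI pairs each, frame counts
drawn from a shifted negative-binomial on 5–53 frames with mean ≈15 at 2 or
4 frames/s. The pipeline default raster is 256×256 — a desk-scale choice
that preserves every qualitative property of the 512×512 phantom while
keeping the full experiment around a minute of CPU; the test suite uses
128–256 px rasters and a quarter-scale experiment (~850 ROI pairs) for the
same reason.

Reports are pure summaries: every number is recomputable from the persisted
per-pair table, and the whole experiment is byte-identical under a fixed
master seed.

## Known limitations

* Rigid translation only; deformable motion (swallowing, peristalsis) is
  out of scope, so head/neck degradation is approximated by jitter.
* The phantom's vessels are straight segments, not realistic
  angioarchitecture; structure classes matter only through their width,
  area and kinetics.
* The Monte-Carlo KS test is exchangeable-seed deterministic but its p-value
  has Monte-Carlo granularity $\approx 1/\mathrm{reps}$.
* Only linear display windowing is modeled; vendor tools may apply
  nonlinear display maps before reader evaluation.
* CNR is measured on raw engine output. Whether published reader studies
  measured on raw or display-windowed pixels is generally unstated; the
  package records this decision in provenance.
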