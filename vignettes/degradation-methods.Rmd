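---
title: "Spatial-frequency degradation and observer comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-frequency degradation and observer comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenedegrade)
```

## Overview

`scenedegrade` implements a workflow common in visual psychophysics
and in human–machine comparison studies: natural-scene pictures are
degraded in the spatial-frequency domain, two observers (for example,
human participants and a convolutional network) categorize the
degraded pictures, a Weibull psychometric function is fitted to
accuracy as a function of degradation level, and the two observers are
compared through an accuracy ratio and an image-level agreement ratio.
Because the original stimulus sets, participants and fine-tuned
networks of such studies cannot be redistributed, the package includes
a synthetic-data module that emulates the statistical structure the
analysis relies on, so every stage is testable end to end.

## Frequency conventions

All operators work on the 2-D discrete Fourier transform with a fixed
normalization: unnormalized forward transform, `1/(H*W)` inverse.
Under this convention the DC amplitude equals `H*W` times the mean
pixel value, and Parseval's identity reads
`sum((x - mean(x))^2) = sum(amp[-DC]^2)/(H*W)`.

Radial frequency is expressed in **cycles per image (cpi)**. Per-axis
frequencies are first computed in cycles per pixel (`u/W`, `v/H`),
combined isotropically in pixel space, and scaled by the image height:

$$f(u,v) = H\sqrt{(u/W)^2 + (v/H)^2}.$$

Two consequences motivate this choice. First, the Nyquist frequency is
`H/2` along both axes, so one number characterizes the band limit of a
non-square frame. Second, cycles per degree of visual angle is then
simply `cpi / vertical_extent_deg`; with the 11.6° display extent used
in this line of work, the conversion reproduces the conventional
printed cutoffs to two decimals (e.g. 120.68 cpi → 10.40 cpd, 64 cpi →
5.52 cpd), which pins the convention down uniquely. The same reasoning
applies to color images: the channel policy (identical operator per
channel, one shared noise field, luminance statistics on the per-pixel
channel mean) is not dictated by the method itself, so it is fixed
here and documented rather than asserted.

## Degradation operators

**Band filters.** A filter is parameterized by its full-attenuation
frequency `F1`; the passband edge `F0` sits exactly three octaves away
(`F0 = F1/8` for lowpass, `F0 = 8 F1` for highpass). Between the edges
the gain falls as a parabola in octaves,

$$g(f) = 1 - \left(\frac{x}{3}\right)^2, \qquad
  x = \lvert\log_2(f/F_0)\rvert \in (0, 3),$$

which is 1 at `F0` and reaches 0 exactly at `F1`. The falloff shape is
named "parabolic" in the psychophysics literature but its exact
parameterization varies; the octave-domain parabola above is this
package's choice and is asserted in tests (for example the gain is
exactly 0.75 at 1.5 octaves past the edge). The DC bin is exempt from
high-pass attenuation: every degraded stimulus is renormalized
afterwards, and a zeroed mean would only destabilize that rescale. A
filter level beyond the corner frequency of a small grid removes every
non-DC component; the output is then rendered as a uniform mid-gray
field rather than treated as an error, since a fully degraded stimulus
is a legitimate endpoint of the design.

**Phase scrambling** uses the weighted mean phase construction: the
new phase is the argument of
$(1-w)e^{i\phi_{\mathrm{orig}}} + w e^{i\phi_{\mathrm{noise}}}$, and
is recombined with the *original* amplitude spectrum, which is
preserved bin by bin — the central property of this manipulation, and
an invariant in the test suite. The noise phase is the phase of the
DFT of white Gaussian noise, hence uniform and Hermitian-symmetric.
One numerical subtlety: where the two unit phasors nearly cancel
(`w ≈ 0.5` and phases ≈ π apart), the argument of the mixture
amplifies the rounding asymmetry between the two phase grids, so
Hermitian antisymmetry is re-imposed by construction (each bin's phase
is mirrored, negated, onto its frequency-negated partner, and
self-conjugate bins are snapped to 0 or π). Without this step the
inverse transform can acquire a macroscopic imaginary part.

**Whitening** multiplies the amplitude spectrum by a gain that rises
with frequency up to Nyquist,

$$W(f) = \frac{f}{f_N}\exp\!\left(1 - (f/f_N)^p\right), \quad p = 4,$$

cancelling the characteristic `1/f` amplitude falloff of natural
scenes while rolling off near Nyquist so as not to amplify
high-frequency noise. The analytic form of the gain is a package
choice (only its qualitative shape — increasing toward Nyquist,
guarded at the top end — is fixed by the method); the guard exponent
`p` is therefore exposed as an argument. With `p = 4`, a `1/f` input
comes out with a radial log–log amplitude slope of about −0.06 over
0.1–0.6 Nyquist, comfortably inside the ±0.15 flatness band the tests
enforce.

**Luminance renormalizations.** Base stimulus sets are standardized to
pixel mean 128 and SD 72.11 (`normalize_mean_sd()`); each degraded
stimulus is stretched to span the full 0–255 range
(`stretch_full_range()`). Degradation happens in float; quantization
to 8 bits happens only on write, so analyses can run on
pre-quantization pixels.

## Psychometric fitting

Accuracy is modeled by the Weibull psychometric function

$$\psi(x) = \gamma + (1-\gamma-\lambda)\,(1 - e^{-(x/\alpha)^\beta}),$$

with the guess rate fixed at γ = 0.5 (two-alternative task) and the
lapse rate λ estimated but capped at 0.05, following the standard
argument that a small free lapse parameter protects the threshold and
slope estimates from occasional stimulus-independent errors. Each
degradation kind is mapped onto a **clarity axis** along which
accuracy increases: the F1 cutoff itself for lowpass, `1/F1` for
highpass, and `1 - w` for phase scrambling. Fitting maximizes the
Bernoulli likelihood over `(α, β, λ)` on the linear clarity axis from
a multistart grid (scale starts at four quantiles of the tested
levels, shape starts at 0.5/1.5/3/8). We fit on linear rather than
log clarity for all kinds: the Weibull already acts on
`log(x/α)` through `(x/α)^β`, so a second log transform would change
the family (to a Gumbel) rather than merely reparameterize it, and a
single family keeps thresholds comparable across kinds. The axis used
is recorded in the fit object.

The 80% threshold is solved analytically from the fitted parameters
and mapped back to original stimulus units (so a highpass threshold is
again an F1 cutoff). Degenerate data — all correct everywhere, or at
chance everywhere — push the scale (or shape) to a box bound; such
fits are returned flagged `converged = FALSE` with a threshold outside
the tested range, not as errors.

Confidence intervals come from a **parametric bootstrap**: each of
2000 replicates redraws per-level binomial correct counts from the
fitted curve at the original per-level `n`, refits (started from the
point estimate), and records the threshold; the 2.5th–97.5th
percentiles form the interval. Replicates that fail to converge are
dropped and counted, and the interval is flagged when more than 10%
fail. At the simulation scale used in the tests (8 levels spanning the
rise, 100 trials per level, 500 replicates, 200 datasets) the
intervals cover the true threshold at or slightly above the nominal
95%, i.e. the procedure is mildly conservative.

## Comparison statistics

For a matched degradation level, with correct counts `k` out of `n`
trials for the artificial classifier (`c`) and the pooled human
observers (`h`):

- the **accuracy ratio** is $(k_c/n_c)/(k_h/n_h)$, with the Katz log
  method giving $SE(\ln R) = \sqrt{1/k_c - 1/n_c + 1/k_h - 1/n_h}$, a
  95% interval $\exp(\ln R \pm 1.96\,SE)$, and a two-sided p-value
  from the normal deviate. A zero cell (no correct, or no wrong,
  responses on either side) triggers the Haldane–Anscombe correction
  (+0.5 to all four counts). p-values are Bonferroni-corrected, by
  default over the four matched levels per degradation type.
- the **expected agreement** is the chance image-level match rate
  implied by the accuracies alone,
  $E = \frac{k_c}{n_c}\frac{k_h}{n_h} + \frac{w_c}{n_c}\frac{w_h}{n_h}$
  (it equals 0.5 whenever either side is at chance and tends to 1 at
  joint ceiling);
- the **agreement ratio** divides the observed image-level match rate
  by `E`. Values above 1 indicate shared successes and failures on the
  same images beyond what accuracy predicts. Inference reuses the log
  machinery: the observed agreement is a binomial proportion over the
  number of aligned images; the expected agreement's variance is
  propagated from the two accuracy proportions by the delta method
  ($\partial E/\partial p_c = 2p_h - 1$, symmetrically for `h`); and
  the two log-variances are summed. Treating the observed and expected
  components as independent ignores their positive coupling through
  the same trials, which makes the interval conservative — in the null
  simulations (independent observers, 2000 images) the 95% interval
  contains 1 in essentially all runs, while a shared per-image
  difficulty of 1 SD on the log-clarity axis is detected with
  corrected p-values far below 0.05.

Per-run classifier scores in `[0, 1]` are rounded half-up to binary
decisions; the group accuracy is the mean of per-run accuracies, and
the group image-level decision is the majority vote across runs, with
ties broken by the rounded mean score.

## Synthetic data: what it emulates, and what it does not

`gen_pink_image()` builds images with amplitude `f^(-slope)` (slope 1
by default, the `1/f` regime of natural scenes), uniform random phase,
and standardized luminance; the measured radial log–log slope is −1.0
within ±0.15. `gen_two_class_set()` adds class geometry on top:
"blob" images (smooth Gaussian clusters, low-frequency energy —
loosely the animal category) versus "grid" images (rectilinear
line/edge structure, higher-frequency cardinal energy — loosely the
vehicle category). The two classes are separable both by amplitude
statistics and by phase-dependent geometry, so filters and phase
scrambling both have bite. The default frame is 323×431 pixels; the
test suite and demo configurations use 64×64 frames, which preserve
every property under test at a fraction of the cost.

Simulated observers draw per-trial correctness from a Weibull on the
clarity axis. Default human-observer scales in the pipeline place the
80% thresholds near values typical of human performance on this task
(lowpass ≈ 3.4 clarity units, highpass ≈ 1/6.0, phase ≈ 0.42).
`simulate_paired_observers()` adds a per-image latent difficulty
`d_i ~ N(0, sd)` multiplying both observers' effective clarity by
`exp(d_i)` — the generative mechanism for image-level error
correlation; `sd = 0` is the agreement-ratio null.

The stand-in classifier is a ridge-regularized logistic model on ten
spectral features (log band-energy *proportions* in eight log-spaced
radial annuli, plus cardinal- and horizontal/vertical-orientation
energy ratios). Two deliberate properties: (1) it is amplitude-driven,
so unlike deep networks it remains above chance under full phase
scrambling of the synthetic classes — a documented difference, not a
bug; (2) a linear probe has none of the robustness a pretrained
network brings, so its training can be augmented with degraded copies
of the training images (random kind × level from the test grids).
Without augmentation the probe collapses to chance under band
filtering it never saw even though the filtered classes remain
perfectly separable; with it, the degradation sweeps rise from chance
to ceiling with clarity, reproducing the qualitative psychometric
shape. Passing tests on this synthetic material therefore validates
the operators and the statistical machinery — not any claim about real
scenes, real observers, or real networks.

## Numerical choices and degenerate inputs

- Transform round trips are asserted at 1e−8 relative tolerance;
  amplitude preservation under scrambling at 1e−6.
- A recomposed spectrum whose imaginary residue exceeds 1e−6 of the
  image dynamic range signals a malformed (non-Hermitian) phase grid
  and errors.
- Constant images error in both renormalizations (SD and range are
  degenerate); fully filtered stimuli are rendered mid-gray by
  `degrade_image()` as described above.
- All stochastic operators route randomness through namespaced
  substreams derived from a master seed (`derive_seed()`), so a
  stimulus manifest, a trial table, or an entire pipeline run is a
  pure function of (config, seed), and an identical integer seed never
  reuses another operator's random field.
- Scores of exactly 0.5 round up; a tied majority vote falls back to
  the rounded mean score.

## Problem sizes

The shipped configurations use study-scale defaults (288 images per
class, 14 observers, 10 classifier runs, 2000 bootstrap replicates);
`demo_config()` scales the same design to 64 images per class at
64×64 pixels, 4 observers, 2 runs and 200 replicates, which completes
in minutes on one CPU. Simulation-based checks use 200 datasets × 500
bootstrap replicates for interval coverage, 1000 pairs for the type-I
rate, 100 runs × 2000 images for the agreement null, and 15-level
sweeps over 48 test images for the end-to-end shape; these sizes were
chosen as the smallest at which the binomial noise bands in the
assertions are meaningfully tight.

## Known limitations

- The synthetic classes are far cleaner than photographs; absolute
  accuracies and thresholds on them say nothing about real scenes.
- The agreement-ratio interval is conservative by construction (see
  above); its coverage under the null is above, not at, 95%.
- The Koopman score interval, sometimes used alongside the Katz log
  method for ratios of proportions, is not implemented; the log
  method is the single inferential route.
- Whitening's gain shape near Nyquist is a modeling choice; different
  guard exponents change high-frequency content and should be treated
  as part of the experimental specification.
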