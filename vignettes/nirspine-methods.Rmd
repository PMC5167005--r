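---
title: "Methods: an event-related fNIRS pipeline for lumbar mechanosensory stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an event-related fNIRS pipeline for lumbar mechanosensory stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the model

`nirspine` implements a complete analysis chain for continuous-wave fNIRS
recordings acquired while three mechanosensory stimuli — painful
posterior-to-anterior vertebral pressure (PAPain), nonpainful 30 N pressure
(PA30), and tactile brushing (Brush) — are applied to the lower back. The
probe spans two regions of interest, the supplementary motor area (SMA,
channels 1–6) and the primary somatosensory cortex (S1, channels 7–18),
with 8 sources and 8 detectors forming 18 channels sampled at 7.81 Hz at
760 and 850 nm. Channels 2 and 10 are short-separation channels (~11 mm):
at that source–detector distance the photon path stays almost entirely in
the scalp, so they measure the superficial circulation that contaminates
every long channel.

Optical density changes relate to chromophore concentration changes through
the modified Beer–Lambert law,

$$\Delta OD(\lambda) = \big[\varepsilon_{O_2Hb}(\lambda)\,\Delta[O_2Hb] +
  \varepsilon_{HHb}(\lambda)\,\Delta[HHb]\big]\; d \cdot DPF(\lambda),$$

a 2×2 linear system per channel and sample that `mbll_invert()` solves
exactly. The differential pathlength factor is the published general
equation, a cubic polynomial in wavelength plus a power law in age, one DPF
per wavelength per subject. Extinction coefficients are the standard
Gratzer/Kollias compilation values, shipped as package data with a
provenance header.

## The signal chain and its conventions

The preprocessing stages run in this order, each behind its own exported
function and together behind `preprocess_subject()`:

1. **Band-pass** (`sg_bandpass()`): the difference of two third-degree
   Savitzky–Golay smoothers with 4 s and 80 s windows (31 and 625 samples;
   seconds are rounded to odd sample counts). Edges are handled by
   evaluating the terminal in-window polynomial fit — no reflection
   padding. The measured frequency response passes 0.08–0.2 Hz at ≥ 85%
   amplitude, attenuates 0.01 Hz by ~89% and the ~1.1 Hz cardiac band by
   ~97%. Two consequences of this choice are worth knowing. First, the
   trend filter's pass-band ends near 0.015 Hz, so a 0.05 Hz component —
   the stimulation cycle frequency (20 s per trial) — is passed nearly
   unchanged, not removed. Second, the small fraction of the 0.05 Hz train
   that the trend estimate does absorb is phase-locked to the events; its
   subtraction imprints a bias of roughly 5% of the mean evoked amplitude
   on every condition's response scalar, including null conditions. This
   is an inherent property of trend removal at 80 s against a 20 s trial
   cycle, and it is visible in the simulations as a small positive offset
   of the Brush scalars.
2. **Segmentation** (`segment()`): one 99-sample window per event — 3.9 s
   pre-stimulus (30 samples), 5 s stimulus (39), 3.9 s post-stimulus (30);
   onsets are mapped to the nearest sample.
3. **Detrend and baseline** (`detrend_and_baseline()`): per segment, the
   ordinary least-squares line over all 99 samples is subtracted, then the
   median of the 30 pre-stimulus samples; the pre-stimulus median is zero
   to machine precision afterwards. Because the line is fitted over the
   full segment, any signal occupying most of the segment is partly
   absorbed: a step occupying the final 70% of a segment keeps only ~56%
   of its height, and a hemodynamic response peaking *after* the stimulus
   window retains a mid-stimulus median near zero. The summary statistic
   downstream (the median over the middle 2.5 s of the stimulus) therefore
   presumes responses that rise within the stimulus — which is also the
   premise of the study design this package emulates.
4. **Short-separation regression** (`apply_ssr()`): each long channel is
   corrected with the short channel of its ROI (1, 3–6 against 2; 7–9,
   11–18 against 10), separately per chromophore, by subtracting an
   ordinary-least-squares-scaled copy of the short-channel signal,
   $\alpha = \langle \ell, s\rangle / \langle s, s\rangle$. The default
   estimates one α per channel and chromophore over all concatenated
   processed segments. A per-segment α (`ssr_scope = "segment"`) is
   available, but with 99-sample segments and a temporally smooth
   superficial signal the regressor spans only a few effective degrees of
   freedom, and per-segment least squares also projects out roughly a
   third of the true evoked cerebral amplitude in simulations with ground
   truth — the recording-wide estimate matches the original formulation of
   the method and preserves the evoked signal.

## Statistics

The per-trial and per-subject summary is always the same scalar: the median
over the middle 2.5 s of the stimulus window (samples onset + 1.25 s to
onset + 3.75 s). Block averages are per-sample medians over the 15 trials;
grand averages are across-subject medians, with the standard error of the
median from a seeded bootstrap over subjects (1000 resamples by default; a
Gaussian approximation `1.2533·SD/√n` is available).

Single-subject responder status per (channel, condition, chromophore) is a
two-sided Wilcoxon signed-rank test of the 15 per-trial scalars against
zero at uncorrected p < 0.05. The signed-rank test uses the exact null
distribution for n ≤ 25 without ties (zeros dropped) and the tie-corrected
normal approximation otherwise; the exact path is verified against a full
2ⁿ sign enumeration in the tests.

Group analysis runs in two tracks. *All* uses every subject everywhere;
*Responders* restricts each channel × condition cell to the subjects
classified as responders there (for the Friedman test a subject must
respond in all three conditions; for a paired test, in both). Per long
channel and chromophore the battery is: a Friedman test across the three
conditions, per-condition Wilcoxon signed-rank tests against zero, and post
hoc paired Wilcoxon signed-rank tests for the three condition pairs (the
within-subject design calls for signed-rank, not rank-sum). Each test type
forms one Benjamini–Hochberg FDR family per chromophore (and per condition
or pair) across the 16 long channels, mirroring a per-column correction
structure; cells with fewer than 5 contributing subjects are reported as
missing and stay out of their family. Post hoc tests are computed for all
channels regardless of the Friedman outcome.

The habituation screen fits, per subject, channel, condition and
chromophore, an OLS regression of the 15 trial scalars on trial index; a
significant positive slope (p < 0.05, uncorrected — an exploratory screen)
is sensitization, a significant negative slope habituation. The heart-rate
analysis extracts, per event, the 5 s stimulus window, the 15 s
post-stimulus interval and the 15 s pre-stimulus interval from the 1 Hz
series (the first event's pre-interval is the last 15 s of the baseline),
aggregates the mean of per-event maxima per condition, and compares
stimulus versus post-interval maxima with paired Wilcoxon tests (one
three-test FDR family) plus a Friedman test on the differences across
conditions.

## What the simulator emulates

`simulate_recording()` is the forward counterpart of the chain above. Per
subject it draws a pseudo-randomised protocol (15 events per condition, no
more than two consecutive identical stimuli, 5 s stimuli, 15 s ISI, 5 min
baseline; 20 min total), and renders:

- **Cerebral responses** on long channels: amplitude × a canonical
  double-gamma event response. The main bump peaks 4 s after onset (gamma
  dispersion 0.8 s) with a small (5%), fast-decaying undershoot centred at
  10 s. Two deliberate choices: the response peaks *within* the stimulus
  window, because the analysis summarises the middle 2.5 s of the stimulus
  — a shape peaking after offset would make that summary vacuous (see the
  detrending note above); and the undershoot is gone by ~15 s, because a
  longer tail sits inside the next trial's pre-stimulus baseline and
  biases every scalar. Default oxyhemoglobin amplitudes are 0.30/0.27
  µmol/L (S1/SMA) for PAPain, 0.22/0.20 for PA30 and 0 for Brush —
  order-of-magnitude values typical for cortical responses, with the
  painful condition slightly stronger; HHb responds at −25% of the O2Hb
  amplitude.
- **A superficial scalp component**, identical on *all* channels of an ROI
  including its short channel (so SSR can in principle remove it exactly):
  a condition-scaled task-locked response with a faster shape (peak 2.5 s)
  and amplitudes ordered PAPain (0.35) > PA30 (0.18) > Brush (~0), plus
  shared spontaneous fluctuations — a Mayer-wave oscillation (~0.095 Hz,
  0.35 µmol/L), a respiratory oscillation (~0.25 Hz, 0.45 µmol/L) and a
  slow AR(1) component. Treating these systemic oscillations as *shared*
  scalp physiology rather than independent channel noise matters: they
  give the short channel in-segment variance that is uncorrelated with the
  evoked response, which is what makes least-squares SSR identify the
  scalp weight rather than regress out cerebral signal.
- **Nuisance terms in OD space**: per-channel cardiac pulsation (~1.1 Hz)
  with small residual respiratory/Mayer components, linear drift, a slow
  random walk, and white noise (1.5 × 10⁻³ OD per sample).
- **Variability**: lognormal gains per subject (sd 0.25), per
  subject × condition (0.25), per channel (0.15) and per trial (0.30).
- **Heart rate** at 1 Hz: baseline 65 bpm plus a condition-independent
  stimulus-locked transient (3 bpm) peaking 7 s after onset — i.e. inside
  the post-stimulus interval — plus smooth AR(1) noise.

The generator returns the noiseless cerebral and superficial concentration
fields as ground truth, so recovery is measured against what was injected.

What the simulator does *not* emulate: motion artifacts (the emulated
subjects lie prone), layered-tissue optics and partial-volume effects,
condition-specific response latencies, inter-channel anatomical covariance
beyond the shared gains, and heart-rate/fNIRS coupling. Passing tests
therefore certify the pipeline's algebra, calibration and power under this
generative model, not its behaviour on any particular real recording.

## Verification strategy and problem sizes

The test suite asserts, in increasing strength:

- *Exactness*: Beer–Lambert round trips at ≤ 10⁻⁹ relative error;
  Savitzky–Golay annihilation of constants and cubics; pre-stimulus
  medians exactly zero; SSR cancelling a proportional superficial
  component to < 1% residual variance.
- *Oracle equivalence*: exact signed-rank p-values against full 2ⁿ sign
  enumeration (n ≤ 15); the Friedman statistic against its closed form
  (identical rankings, n = 10, χ² = 20) and a complete (3!)⁵ permutation
  distribution at n = 5; BH q-values against the hand-applied step-up rule.
- *Null calibration*: 120 null subjects give a single-subject rejection
  rate within 5% ± 2 points. The measurement uses many subjects rather
  than merely many cells because a subject's 96 cells are strongly
  correlated — the subtracted short-channel signal and the shared scalp
  residual are common to all long channels of an ROI — making the
  per-subject rejection rate fluctuate with a spread of several points.
  Separately, 200 null cohorts of 6 subjects (with a shortened 5-trial protocol — FDR control
  under the null does not depend on the trial count) keep every FDR
  family's mean discovery proportion at or below 5%.
- *Recovery*: 100 cohorts of 16 subjects recover the injected amplitude
  ordering in ≥ 95% of runs; the pipeline's block-average scalars track a
  ground-truth reference — the noiseless cerebral signal pushed through
  the same segmentation, detrending and baselining — within 15%. The
  reference shares the segment conventions because those conventions are
  part of the measurement definition, not an error to correct.
- *Pattern reproduction*: 20 cohorts of 20 subjects under
  `pattern_sim_params()` (equal moderate pressure amplitudes, brushing
  null) reproduce the qualitative effect structure — pressure conditions
  significant against zero after FDR, brushing not, pressure-vs-brush
  contrasts significant, pain-vs-nonpainful not — in ≥ 90% of runs. The
  90% bound is essentially the ceiling the procedure admits: the check
  requires two null FDR families to stay empty simultaneously, each of
  which is allowed to fire at ~5% under the null.

Cohort sizes in the scripts (6–120 subjects, 10–200 runs) were chosen so
each check has the statistical resolution its tolerance needs at desk
scale; `analysis/01–05` rerun the same checks at similar sizes as a
narrative workflow.

## Degenerate inputs and numerical choices

A flat short-channel segment yields α = 0 with a warning rather than an
error; an all-zero cell is a non-responder with p = 1 by convention; ties
in the signed-rank test switch to the tie-corrected normal approximation
with continuity correction; incomplete Friedman rows are dropped with the
count reported; group cells with fewer than 5 subjects are missing, not
errors; untestable (NA) p-values never enter an FDR family. Seeds derive
from a single study seed through one `sample.int` draw, so every artifact
is bit-reproducible from `(seed, parameters)`.

## Known limitations

Amplitude estimates are attenuated by design choices inherited from the
emulated analysis (full-segment detrending, mid-stimulus medians), so they
are comparable within this pipeline but not calibrated absolute
concentrations. The trend-filter bias at the stimulation frequency (~5% of
the mean evoked amplitude) is unavoidable at an 80 s trend window and a
20 s trial cycle. The Responders track with small cohorts produces mostly
missing cells — that is the intended behaviour of requiring 5 subjects per
cell, not a defect. Habituation results are screened uncorrected and should
be read as exploratory.
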