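---
title: "Methods: quantal release mapping and photoconversion turnover analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantal release mapping and photoconversion turnover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`quantalmap` implements the image-analysis side of single-synapse physiology
at the *Drosophila* larval neuromuscular junction (NMJ): per-active-zone (AZ)
evoked release probability (Pr) and spontaneous release rates from
postsynaptic GCaMP movies, synapse-age classification from photoconvertible
glutamate-receptor (GluR) labels, scaffold-protein turnover from
photoconverted signal decay, and puncta morphometrics. Because raw
microscopy of this kind is rarely shared, the package also contains a
synthetic-data generator that renders the same classes of imagery with known
ground truth; every estimator in the package is validated by parameter
recovery against that generator.

## The generative model

`make_geometry()` builds an NMJ as a chain of boutons laid out on a compact
serpentine, each containing AZs with a matched postsynaptic density (PSD)
jittered ~0.08 µm from its AZ. Per synapse the ground truth carries:

* **Evoked Pr** in [0, 1]. Default `uniform(0.02, 0.5)`: release sites at
  these NMJs span roughly two orders of magnitude in strength, and this
  range covers the bulk of it while keeping every site detectable in a
  300-stimulus protocol.
* **Spontaneous rate** (events/min). Default `gamma(shape 2, rate 2)`
  (mean 1/min), matching the ~0.4–1.1 events/min group means typical of
  these synapses.
* **Age** (days), default `uniform(0, 6)` — the span of larval development.
  `growth_mode` redistributes drawn ages across boutons to emulate terminal
  budding (terminal bouton youngest) or internal insertion ("stretching";
  terminal bouton keeps the oldest synapses).
* **Cac status**. A configurable fraction of AZs lacks the Ca~v~2 channel;
  these sites have Pr forced to 0 but keep a nonzero spontaneous rate
  (floored at 0.3/min), emulating immature spontaneous-only release sites.

`simulate_quantal_movie()` renders an 8 Hz single-plane movie under 1 Hz
stimulation (the standard protocol; default 300 s, i.e. 300 stimuli). At
each stimulus every AZ releases independently as a Bernoulli(Pr) trial;
spontaneous events are per-AZ Poisson processes over the non-stimulus
frames. A release event renders as an additive 2D Gaussian flash (σ 0.25 µm)
with single-frame rise and geometric decay (factor 0.5 over 3 frames);
stimuli map to frames as `floor(t × frame_rate)`. The true event log is
returned beside the movie.

**Signal-to-noise.** No flash-amplitude or movie-SNR statistics are
available to copy, so the defaults (flash amplitude 60 on background 100,
Gaussian noise s.d. 10) were chosen once so that detection is non-trivially
hard: the raw single-pixel peak is 6× the noise s.d., well below a naive
per-pixel threshold, so reliable detection requires the spatial smoothing
and rolling baseline described below. All of this is configurable through
`movie_spec()`.

`render_puncta_stack()` renders marker channels as Z-stacks: each synapse is
a Gaussian spot (lateral PSF σ 0.18 µm at 0.133 µm/px, a typical
60×/EMCCD scale) with a Gaussian axial profile whose brightest plane
carries the full amplitude, so a max projection recovers per-synapse
intensities. The photoconvertible GluR channels derive from age: a synapse
older than the chase interval carries "old" (red) signal proportional to
its age at photoconversion; "new" (green) signal is proportional to time
lived since.

`simulate_photoconversion_series()` models pulse-chase turnover: at t = 0
the entire pre-existing green pool converts to red (complete
photoconversion — red(0) equals the pre-conversion green total and no
residual green remains), after which red decays as `2^(−t/T½)` and green
re-accumulates (by default at steady state, so red + green is conserved).

**What the generator does not emulate** — and therefore what passing
recovery tests do *not* establish about real data: muscle-contraction
motion and z-drift (sessions with movement are discarded in practice, and
the package deliberately performs no motion correction), photobleaching
beyond turnover decay, shot-noise (intensity-dependent) statistics —
noise is additive Gaussian — spatially structured autofluorescence, and a
3D PSF. Estimator accuracy on real movies will degrade with motion and
with SNR below the simulated regime.

## Event detection

`detect_events()` is a standard ΔF event detector:

1. **Baseline**: per-pixel rolling 20th percentile over a trailing 16-frame
   window (2 s at 8 Hz — long against the 3-frame flash, short against
   slow drift). The first 15 frames are judged against the first full
   window, so stimuli in the opening seconds are not lost to a partial
   baseline.
2. **Smoothing**: ΔF is smoothed per frame with a σ = 1 px Gaussian,
   which suppresses single-pixel noise ~3.5-fold while costing a ~20%
   reduction of a σ = 0.25 µm flash peak.
3. **Normalisation**: each pixel's smoothed trace is centred by its median
   and divided by its MAD (floored at the field-median MAD — the MAD of a
   short series is itself noisy, and an underestimated denominator would
   inflate z scores).
4. **Peaks**: 8-neighbour local maxima with z ≥ `k_sigma` become events,
   with sub-pixel positions from a 3×3 intensity-weighted centroid.
5. **Refractory rule**: a candidate within 0.5 µm of an event accepted in
   the previous `min_separation = 2` frames is attributed to that flash's
   decay and dropped, so a flash is counted once.

**Why k_sigma = 5.** Subtracting a low percentile baseline makes the null
ΔF distribution slightly right-skewed, so a nominal 4σ cut admits a
measurable trickle of false peaks: on pure-noise movies, false local maxima
concentrate at z ≈ 4.0–4.6 and vanish at z ≥ 5, while true flashes at the
default SNR score z ≈ 17–30. The default threshold is therefore 5; it was
calibrated on detector-only noise simulations and leaves an order of
magnitude of headroom for dimmer events.

## From events to release maps

* **Assignment** (`assign_events()`): each event goes to the nearest ROI
  centre if and only if the distance is ≤ 0.8 µm — the one distance
  threshold the protocol fixes; exact ties go to the lowest ROI id
  (deterministic). ROIs are equal-radius circles (default 0.5 µm), derived
  from detected AZ/PSD puncta or supplied as a CSV (the programmatic
  replacement for manually added ROIs).
* **Evoked vs spontaneous** (`classify_frames()`): frames with ≥ 3
  simultaneous events NMJ-wide are evoked frames, and every event in them
  is evoked — classification is by coincidence, not stimulus timing, so no
  synchronisation with the stimulator is assumed. Events in the frame
  immediately after an evoked frame and within 0.5 µm of an evoked event
  are classed `"decay"` and excluded from rate tallies.
* **Maps** (`release_map()`): per ROI, Pr = evoked count / number of
  stimulations; spontaneous rate = spontaneous count / minutes recorded.
  The stimulation count comes from the protocol (stim rate × duration),
  not from the movie. An ROI with more evoked events than stimulations is
  flagged (double counting suspected) with a warning. Unassigned events are
  excluded from per-ROI tallies but reported in summary attributes, so
  event counts are conserved: evoked + spontaneous + decay equals the total
  detected.

On the generator's study conditions (50 AZs, Pr ~ U(0.02, 0.5), 300
stimuli), true and estimated Pr correlate at r > 0.95 with mean absolute
error well inside 2 binomial standard deviations; the test suite and
`scripts/acceptance.R` recompute this from scratch.

## Puncta detection and pairing

`detect_puncta()` thresholds a max projection and labels 8-connected
components (diagonal contact merges — two overlapping spots are one
punctum, by definition), filtering objects under 4 px. The default
threshold is background + 3 s.d. with background taken as the plane's
median and scaled MAD: puncta occupy a small fraction of pixels, so these
are robust pure-background statistics, and unlike a lower-quartile sample
they are not biased low on max-projected (extreme-value) noise. Each object
gets an intensity-weighted centroid (µm), area (µm² and px), raw and
background-subtracted sums, and mean intensity.

`opposition_pairs()` pairs AZ and PSD sets by greedy global-minimum
mutual-nearest matching within 0.8 µm; ties break to the smallest AZ id
then PSD id, unpaired puncta are retained with `NA`, and pair + unpaired
counts conserve both set sizes. With positional jitter a quarter of the
cutoff (the realistic regime), the greedy pairing coincides with optimal
matching. `colocalize_fraction()` reports the percent of one channel's
puncta lacking a partner in another within a radius, in both directions; an
empty input yields `NA` ("missing"), never 0. `puncta_density()` reports
counts per 10 µm² of NMJ area (densities on these terminals are naturally
of order a few per 10 µm²).

## Synapse age and its relation to output

`classify_age()` classifies a PSD as *old* (existed at photoconversion) if
its red sum exceeds a threshold — 0 for tabular input ("any amount" of old
receptor), or a background-based mean-intensity criterion when measuring
red and green images over identical PSD masks. Red sums are normalised per
NMJ with the brightest PSD set to 1.0 *before* pooling across animals, so
different animals' intensity scales cannot masquerade as age structure;
`norm_red` is invariant to global gain, and classification is monotone in
the threshold. `age_output_correlation()` joins labels to a release map
through the opposition pairing and reports Pearson r plus old/new group
means and fold changes; `bouton_position_fraction()` gives the percent of
old PSDs at the terminal versus second-from-end bouton (the discriminator
between budding and stretching growth), and `count_old_psd_stability()`
tracks conservation of the old-PSD pool across sessions.

## Turnover

`remaining_fraction()` is the percent of photoconverted signal surviving a
chase; `half_life()` converts it to days under three models:

* **exponential** (default): `T½ = dt·ln2 / ln(S0/S1)` — exact first-order
  decay.
* **initial-rate**: `T½ = dt·ln2 / (1 − S1/S0)`, treating the fractional
  loss per unit time as the rate constant. This is the convention behind
  commonly reported single-interval half-lives (it agrees with the
  exponential form to first order and is the form that reproduces
  published single-timepoint values such as 2.56 d from a 27.1% daily
  loss).
* **linear**: extrapolation to 50% loss, `dt·50/(100 − remaining%)`.

`estimate_turnover()` measures the old channel over AZ masks detected at
t = 0 and re-uses those masks at the later timepoint (serial imaging of the
same NMJ: sites do not move, and re-detecting on the faded image would bias
the ratio), subtracting each image's median-outside-masks background before
summing. Under default rendering noise, simulated half-lives of 1–4 d are
recovered within ~5% from two timepoints. `new_accumulation()` gives green
sums and per-area means over AZ masks, and `influx_fold_change()` the
percent increase of group means (used for per-AZ Ca²⁺-influx comparisons).

## Numerical and design choices

* **Coordinates**: images are `[row, col]` matrices (row = y); the centre
  of pixel `(i, j)` is `((j−0.5)·s, (i−0.5)·s)` µm for pixel size `s`.
  All thresholds are compared in µm.
* **Determinism**: every simulation takes a seed; one seeded stream per
  call with a fixed per-AZ draw order, so identical inputs give
  bit-identical ground truth, movies and logs. The caller's RNG state is
  saved and restored.
* **Degenerate inputs**: an all-constant movie yields zero events; a
  saturated/constant plane is flagged; empty puncta sets propagate as
  empty results or `NA` fractions; correlations refuse < 3 pairs or
  zero-variance input; `half_life()` refuses remaining ≥ 100% (no decay);
  a t test between two zero-variance groups reports `NA` (or 1 when the
  means agree) rather than an error.
* **TIFF I/O** is 16-bit multi-page via the `tiff` package, with intensity
  scaled by 1/65535 on write and restored on read.

## Problem sizes in the test suite

The suite validates recovery at the full study conditions — 50 AZs,
300 stimuli at 1 Hz, 8 Hz movies (2,400 frames), across five simulation
seeds — and uses small fields (tens of pixels, tens of seconds) for unit
tests of the detector and geometry, generated at test time. The
brute-force oracles (all-pairs assignment scans, dense spot-rendering
integrals, hand-computed correlation formulas) are implemented in the
tests, independent of the package code paths they check.

## Known limitations

Detection operates on a single plane with no motion or z-drift correction;
AZ-position drift is a verify-only concern (flag, not correct). Closely
spaced AZs (≲ 0.7 µm) can merge into a single punctum/ROI, which deflates
counts and mixes their release statistics. Spontaneous-rate estimates
include the detector's residual false positives, mostly unassigned but a
fraction landing within 0.8 µm of an ROI; at the default threshold this is
a small additive rate. The ≥3-coincidence rule misclassifies the rare
frames in which three or more spontaneous events coincide, and conversely
cannot identify an evoked frame in which fewer than three sites released.
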