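---
title: "Gaze cluster membership: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze cluster membership: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gazecluster)
```

This vignette documents the models implemented in `gazecluster`, the
parameters that matter, the behaviour of the synthetic-data generator, and
the numerical and design choices made where more than one defensible
reading existed.

## The measure

Gaze cluster membership (GCM) treats attention during video viewing as a
collective, per-frame property. For each video frame, the gaze positions of
all viewers with at least one valid sample in that frame's time window are
clustered with DBSCAN; a viewer is attentive in that frame when their
position belongs to any cluster, and inattentive (an outlier) when it does
not. The assumption is deliberately weaker than that of synchrony measures:
a scene may hold several simultaneously meaningful foci, and tracking any
one of them counts as attentive viewing. The accompanying per-frame cluster
count estimates how many such foci the audience is actually resolving.

GCM rests on the eye-mind link — gaze positions indicate where processing
is directed — and on a crowd assumption: enough viewers must be attentive
that their fixations form dense clusters. With predominantly inattentive
audiences the denominator of "density" disappears (see Limitations).

## Per-frame clustering parameters

Both DBSCAN parameters adapt to each frame's data:

* **Minimum cluster size.** `minPts = max(4, ceiling(0.05 * n_valid))`,
  where `n_valid` counts viewers with a valid aggregated position in the
  frame: five percent of the available points, floored at four (the
  smallest neighborhood that meaningfully supports a density estimate in
  2-D). With around 100 viewers this gives 5–6.
* **Neighborhood radius.** The k-distance curve (k = `minPts`, the standard
  pairing of the k-distance plot with DBSCAN's minimum neighborhood) is the
  ascending sort of every point's Euclidean distance to its k-th nearest
  neighbor. ε is the first value of that curve strictly above an outlier
  threshold for the k-distance set.

The threshold estimator is the one genuinely open design point. The moment
form, mean + 1 sd of the k-distances, works when outliers are rare; but the
k-distances of scattered viewers enter the very mean and standard deviation
that are supposed to separate them from the fixation bulk. Measured on
simulated frames with 80 tightly fixating and 20 wandering viewers on a
1680×1050 screen, contamination inflates the threshold to ≈ 230 px, ε lands
at ≈ 250 px, and half of the wandering group attaches to clusters as border
points — the measure stops discriminating, contradicting its own
definition of inattention. The default therefore replaces the moment
estimates with the conventional robust outlier fence,
`median + 2.5 * MAD` (scaled MAD, the moderately conservative cutoff
standard in psychological outlier screening). Median and MAD ignore the
scattered tail, so ε stays on the scale of the coherent fixation clouds
(≈ 4–8 px in the same simulation; attentive group GCM 0.998, wandering
0.017). On homogeneous k-distance curves no value exceeds the fence and ε
falls back to the maximum k-distance, which keeps a single fixation cloud
in one piece; on coincident points ε becomes the smallest positive
representable distance so one cluster still forms. Both estimators give the
same answer on well-separated configurations (e.g. collinear points
{0,1,2,3,4,100} with k = 2: ε = 97 either way); `method = "classic"`
retains the moment form for comparison.

Determinism: clusters are grown from unvisited core points in ascending
point index; a border point reachable from several clusters joins the one
expanded first. Ids are canonicalized by smallest member index, so
labellings are invariant to subject order up to the membership/outlier
distinction and cluster count. One classical subtlety is preserved rather
than patched: when clusters share border points, the later cluster can end
up with fewer than `minPts` members, exactly as in other standard DBSCAN
implementations.

## Series construction

Frame *i* covers the half-open window [i/fps, (i+1)/fps) seconds (0-based
frames; a sample on the boundary belongs to the later frame), and a
subject's frame position is the mean of their valid samples in the window.
The GCM summary is the fraction of *non-missing* frames spent inside a
cluster: frames where a subject has no valid gaze drop out of numerator and
denominator, and the per-subject missing fraction is carried separately as
a covariate rather than silently counted as inattention. Membership and
cluster-count series are smoothed with a centered 5 s moving window
evaluated every 1 s (half-open [g − 2.5, g + 2.5) windows over frame
centers, truncated at the edges; a window with no values is missing).

## Preprocessing rules

* **Blinks** are detected as maximal runs of missing-or-zero pupil (the
  zero-pupil convention of video eye trackers), extended while consecutive
  open-eye samples change faster than `velocity_k = 5` times the MAD of the
  pupil difference series, padded by 60 ms on each side (the eyelid drags
  gaze downward before and upward after a blink), then merged
  (pad-then-merge). The detector's core rule is a documented stand-in: the
  upstream acquisition software's algorithm is proprietary, so sensitivity
  against planted blinks is verified in simulation instead.
* **Off-screen** samples are masked on half-open ranges [0, width) ×
  [0, height); masking is idempotent and only ever grows the missing set.
* **Subject exclusion**: blink count and missing fraction are z-scored
  across subjects (denominator n − 1); a subject is excluded above z = 2 on
  either criterion, one-sided — only unusually artifact-laden recordings
  are dropped. Zero-variance criteria exclude nobody.
* **Interpolation** (linear per axis, nearest value at the edges) exists
  solely because correlated component analysis cannot handle gaps; it is
  applied to masked recordings and never feeds the clustering.

## Correlated component analysis

With per-subject channel-by-time matrices (gaze: the two position channels;
EEG: electrodes), each subject is mean-centered and

* `R_w` = mean over subjects of the within-subject channel covariance,
* `R_b` = mean over ordered subject pairs of the cross-covariance,
  symmetrized,

and components solve `R_b w = λ R_w w`, computed via symmetric whitening
with diagonal loading `1e-6 · trace(R_w)/D` on `R_w` for rank safety.
Per-component ISC is the Rayleigh quotient `(wᵀR_b w)/(wᵀR_w w)` (unloaded
`R_w`), invariant to rescaling of `w`; weights are reported unit-norm with
the largest-magnitude entry positive. With one channel ISC₁ reduces to the
mean pairwise Pearson correlation of unit-variance series, which the tests
use as a closed-form check. "Correlation between each participant and all
other participants" is realized leave-one-out — each subject's component
projection against the mean projection of the others — the lower-variance
standard in this literature; the time-resolved course uses the same
half-open 5 s / 1 s windows as the GCM smoothing so both curves live on one
grid. Gaze ISC is computed on (x, y) position channels. Subjects with a
zero-variance projection in a window are omitted from that window's mean.

## EEG conditioning

The band (0.5–45 Hz) is realized as a 4th-order Butterworth applied
forward–backward (zero phase); the filter family and order are a package
choice, recorded in output metadata, since only the band itself is given.
Re-referencing subtracts the arithmetic mean of the two reference channels.
Epochs of 1 s start 2.5 s before the onset marker; the trailing partial
epoch is dropped. All three rejection comparisons are strict: a channel is
bad above 100 µV peak-to-peak (max − min within the epoch), an epoch is bad
with more than 3 bad channels, a subject is excluded with more than 30 %
bad epochs.

## Analysis models

Continuous variables are z-scored (denominator n − 1), so reported
coefficients are standardized betas. Subject-level outcomes use OLS with
`t = β̂/SE`, `df = n − p`. The longitudinal model for smoothed GCM on the
1 s grid is a random-intercept linear mixed model fitted by REML (through
`lme4`),

```
gcm ~ poi + time + prior + post + post:poi + post:time + (1 | subject)
```

with the knowledge-irrelevant content period as the reference category and
time as the standardized grid second. The response is the smoothed, not the
raw, membership series, matching how the time courses are presented and
reducing frame-level flicker. t statistics use the subject-tied convention
`df = n_subjects − p` with p the fixed-effect rank (105 subjects and 13
fixed-effect columns give df = 92); exact small-sample methods
(Satterthwaite, Kenward–Roger) are out of scope, and for the level-1
effects this df is conservative. The fitter refuses fewer than two subjects
or fewer than two observations per subject; variance components are
reported with the restricted log-likelihood.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
ground truth; its defaults describe the recording situation the package
targets: a 1680×1050 px screen, 500 Hz monocular sampling, 25 fps video,
fixation scatter sd 15 px, 12 blinks/min of mean duration 150 ms (sd 40,
floored at 20 ms), and wandering as a Gaussian random walk with reflecting
screen boundaries, step sd 25 px per sample at 500 Hz — dispersed,
spatially incoherent gaze, which is precisely what the outlier notion of
inattention requires. Attentive gaze tracks an assigned focus (optionally
with a saccadic lag) with scatter clipped to the screen: a fixating
person's recorded gaze stays on-screen, and clipping avoids inflating the
missing-data rate. Off-screen episodes park gaze outside the half-open
screen ranges. Blinks appear as zero-pupil runs with a ±120 px vertical
gaze distortion in the 30 ms before and after — the artifact the 60 ms
padding rule is designed to absorb. All randomness flows from one seeded
generator per call and the caller's RNG state is restored, so identical
inputs and seed give byte-identical output.

The EEG simulator mixes a single band-limited shared source into each
subject's channels through one session-level unit-norm mixing vector,
scaled per subject by a state-dependent SNR, plus independent unit-variance
channel noise. SNR is an amplitude ratio, which makes recovery quality
analytic: the best possible correlation between any projection and the
planted source is `snr/sqrt(snr² + 1)` (0.89 at snr 2, 0.97 at snr 4). The
recovery benchmark therefore plants a strong component (snr 4) — it
verifies that the estimator finds the planted subspace, not that weak
components are magically denoised — while the attentive-versus-wandering
discrimination uses snr 2 against 0.1. Outcome scores are linear in the
z-scored true attention fraction with chosen slope and noise; a long-format
GCM simulator draws rows directly from the mixed model above (independent
residuals) for parameter-recovery and type-I-error studies.

What the generator does **not** emulate: saccade main-sequence dynamics,
pupillary light reflexes, luminance-driven bottom-up salience, head
movement, or temporally structured (autocorrelated) mind-wandering.
Passing tests therefore show that the pipeline recovers the constructs it
defines under controlled violations (blinks, scatter, off-screen loss,
split foci) — not that those constructs capture everything human gaze does
on real footage.

## Problem sizes and calibration checks

The test suite runs, among others: oracle equivalence of the DBSCAN core on
1,000 random instances of up to 30 points against a brute-force
density-connectivity oracle (Warshall closure over the core graph);
discrimination with 100 viewers (80 attentive on two foci 400 px apart,
noise 15 px; 20 wandering) over 60 s × 20 seeds; the dissociation of GCM
and gaze ISC between paired single- and two-focus scenes (30 viewers, 30 s,
20 seeds); CorrCA recovery with 20 subjects × 10 channels × 2 min at
250 Hz; OLS recovery at n = 200 over 100 seeds and mixed-model recovery at
100 subjects × 900 grid seconds over 100 seeds with 95 % CI coverage
counted per coefficient; type-I calibration of the post×POI interaction
tests over 200 null simulations (60 subjects × 240 s); and one full-scale
synthetic session of 105 subjects over 23,664 frames (946.56 s at 25 fps,
500 Hz sampling), generated and analyzed subject-by-subject to keep memory
flat. These sizes are the package's own validation design: large enough for
stable statistics at desk scale, small enough to run routinely.

The type-I calibration holds for the simulator's independent residuals; on
real smoothed series, residual autocorrelation would make the nominal level
optimistic, which is one reason the df convention errs conservative.

## Known limitations

* Clusters covering more screen area raise the base probability of
  membership; no screen-area normalization is applied.
* If an entire audience scatters, the homogeneous-curve fallback (ε = max
  k-distance) connects everyone into one diffuse cluster: GCM is a measure
  of *collective* attention and needs an attentive majority (on the order
  of 50+ viewers) to anchor its clusters.
* Coordinated but irrelevant fixations (everyone watching a distractor)
  count as attentive; membership is spatial, not semantic.
* Clusters are not linked across frames; the cluster-count series is
  per-frame and a "focus" has no temporal identity.
* The mixed model's df convention is an approximation; random slopes and
  exact small-sample df methods are out of scope.
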