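---
title: "Latency-corrected stretch reflex thresholds: model, detectors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latency-corrected stretch reflex thresholds: model, detectors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtkit)
```

## The measurement model

A passive stretch rotates the ankle from 20° of plantarflexion to 0° at a
nominal velocity $v$. Somewhere along the ramp the lengthening muscle
crosses its stretch-reflex threshold: the reflex is initiated mechanically
at the muscle spindles at joint angle $\theta$, but its electrical signature
reaches the surface EMG only one reflex latency $\ell$ later. The classical
stretch reflex threshold (SRT) reads the joint angle at the **EMG** onset
time $t_{on}$, so at constant velocity

$$\mathrm{SRT}(v) \;=\; \theta - \ell\,v,
\qquad
\mathrm{SRT_{corrected}}(v) \;=\; \theta\bigl(t_{on} - \ell\bigr) \;=\; \theta,$$

in the decreasing-plantarflexion convention (angles fall 20° → 0°, so
"earlier in the stretch" means a larger angle, and the corrected SRT is
never smaller than the uncorrected one). The uncorrected measure therefore
fabricates a velocity dependence of slope $-\ell$ (degrees per deg/s) even
for a perfectly velocity-independent reflex, and the correction rotates the
SRT–velocity regression slope by exactly $+\ell$. The tonic stretch reflex
threshold (TSRT) is the y-intercept of that regression — the extrapolated
threshold at zero velocity — and inherits the error only weakly, because
the low-velocity points anchor the intercept. $\ell$ is measured per
subject and muscle as the H-reflex latency (tibial-nerve stimulation;
first deflection after the stimulus). The H-reflex enters the arc at the
popliteal fossa rather than at the spindle, so it underestimates $\ell$ by
at most ~15% of the pathway; `pathway_error_bound()` exposes the resulting
worst case (4.2 ms, i.e. 1.2° at 291 °/s, for a 28 ms latency) but, like
the source method, no correction for it is applied.

An important qualification, visible only once the actuator is modeled
honestly: the identity $\mathrm{SRT}(v) = \theta - \ell v$ assumes the
*whole latency interval* lies in the constant-velocity segment. The
actuator reaches its target velocity in 20–40 ms of roughly constant
acceleration, so a threshold crossed within the first
$\tfrac12 v\,t_{acc}$ degrees of the ramp (≈ 4.4° at 291 °/s) is crossed
*during* acceleration, where the instantaneous velocity is lower than
nominal. The corrected identity $\mathrm{SRT_{corrected}} = \theta$ is
unaffected — it only relies on $t_{on} - \ell$ being the crossing time —
but the uncorrected displacement is smaller than $\ell v$ there. Tests of
the exact linear identity therefore use a threshold of 14°, crossed after
the acceleration phase at all four study velocities; the default
generator threshold of 19° deliberately keeps the more realistic case, in
which early thresholds meet the acceleration phase at high velocities.

## The synthetic study

Because the human recordings behind the method are not redistributable, the
generator reproduces the acquisition at the level the analysis sees:

* **Kinematics.** Constant-acceleration phase (default 30 ms, the middle of
  the actuator's 20–40 ms range) followed by a constant-velocity ramp and
  end plateaus; velocities 55/110/210/291 °/s, 10 stretches per velocity in
  pseudo-random order. The ground-truth crossing time is defined on the
  noiseless commanded trajectory so truth never depends on noise.
* **EMG.** White Gaussian noise band-passed to 20–450 Hz (the spectral
  support of surface EMG) and scaled to a background SD of 1% of the MVC
  RMS reference. The reflex burst is a multiplicative envelope rising
  linearly over 10 ms to 5× the background SD, sustained to the end of the
  trial — a variance increase with the background's own spectrum, which is
  exactly the signal class the AGLR detector models. Contaminated trials
  (for rejection testing) carry a pre-stretch activation at 10% MVC RMS,
  twice the 5% rejection bound.
* **Latencies.** Per subject and muscle, drawn once from a truncated normal
  (28 ± 3 ms, range 23–35 ms) and reused in every trial; H-reflex traces
  place a biphasic H-wave at that latency behind a stimulus artifact and an
  M-wave near 7 ms.
* **Sampling.** 2 kHz: one sample is 0.5 ms, i.e. at most 0.146° at the
  fastest velocity — far below reported SRT variability.

What the generator does **not** model: spindle/motoneuron biophysics,
torque, inter-stretch carry-over such as post-activation depression
(stretches arrive 2.6–2.9 s apart in the source protocol; trials here are
independent), M-wave/H-wave recruitment curves, or non-stationary
background tone. Passing tests on this generator show the *pipeline*
recovers known ground truth under realistic noise; they cannot certify
behavior on pathological EMG (movement artifacts, clonus, voluntary
activity) beyond what the rejection rule catches.

## Signal conditioning

The analysis band-pass is an order-4 Butterworth (20–195 Hz) applied
forward–backward. Zero-phase filtering is mandatory because onset *time* is
the measurand; the price is non-causal smearing — a sufficiently sharp,
high-amplitude burst leaks a few milliseconds *backwards* through the
filter. At the default burst gain this is negligible, but it is why the
noiseless-identity tests feed exact onsets rather than pushing the detector
to infinite SNR (where the baseline variance would also be degenerate).

Trial rejection follows the 5%-of-MVC rule: a trial is discarded when any
muscle's RMS over a 200 ms window, evaluated at every sample of the 500 ms
pre-stretch interval (per-sample evaluation is the strictest reading of a
"sliding" window), exceeds 5% of that muscle's MVC RMS. One contaminated
muscle rejects the whole trial, and the reason is logged.

## Onset detection

**AGLR.** EMG is modeled as zero-mean Gaussian; the baseline variance
$\sigma_0^2$ comes from the 500 ms pre-stretch interval already screened by
the rejection rule. For each endpoint $k$, over a trailing window of $L$
samples (25 ms),

$$g(k) = \frac{L}{2}\left[\frac{\hat\sigma_1^2}{\sigma_0^2}
  - \ln\frac{\hat\sigma_1^2}{\sigma_0^2} - 1\right],$$

with an alarm at the first $k$ where the variance has *increased*
($\hat\sigma_1^2 > \sigma_0^2$; a decrease is never a burst, so the test is
one-sided) and $g(k)$ exceeds the decision threshold. The onset is then the
maximum-likelihood single change point within the $L$ samples before the
alarm, scoring each candidate $j$ by
$\tfrac{n_j}{2}(r_j - \ln r_j - 1)$ over the segment from $j$ to an
estimation buffer $2L$ past the alarm (the buffer stabilizes the segment
variance and shrinks worst-case refinement error on gradual-rise bursts);
ties take the earliest sample. On deterministic step-variance inputs this
refinement coincides with an exhaustive change-point search, which the test
suite verifies.

The decision threshold is calibrated, not assumed: band-limited EMG samples
are strongly correlated at 2 kHz (a 50-sample window holds roughly 18
effective degrees of freedom), so thresholds appropriate for white noise
alarm constantly. Monte Carlo calibration on pure background traces put the
99.5th percentile of the peak statistic near 41; the default threshold is
**45**, giving a false-alarm rate below 1% per trace (re-measured on 1000
traces in the acceptance script) while leaving detection accuracy at the
default burst gain unchanged (median absolute onset error ≈ 4 ms).

**Sustained-SD fallback.** The manual criterion — the signal reaching two
baseline SDs for at least 100 ms — is automated on a rectified,
moving-average envelope. The envelope width matters: with a 10 ms window
the rectified-Gaussian envelope dips below threshold mid-burst, breaking
the 100 ms continuity requirement and pushing onsets ~70 ms into the burst;
the default is therefore **25 ms**, which keeps the fallback within about
±10 ms (centered smoothing anticipates by up to half a window, so its small
bias is early, not late). The last smoothing window of the baseline is
excluded from the baseline statistics because centered smoothing leaks
post-onset samples into it.

**Reconciliation.** The AGLR result stands when both detectors agree within
20 ms; otherwise — disagreement or a missed detection — the sustained-SD
result is used and the trial is flagged for review, with every override
logged (the automated surrogate for visual inspection). This rule
occasionally hands a trial to the coarser detector; per-velocity *medians*
over 10 trials absorb those cases.

**H-reflex latency.** First time in the 15–50 ms search window (after
blanking the stimulus artifact) at which the absolute deviation from the
pre-stimulus baseline exceeds 3 SDs for ≥ 2 ms. Recovery is within 1 ms
across the 23–35 ms range; a flat trace is an error, not a guess.

## Regression, classification, statistics

Per-velocity medians (midpoint convention on even counts) feed an OLS
regression of median SRT on velocity, but only when **all** required
velocities are present — subjects missing a velocity are excluded with a
logged reason rather than silently fitted on fewer points. A slope modulus
below 0.01 deg/(deg/s) is classed `near_zero`: across 55–291 °/s it can
move the SRT by at most 2.36°, below typical within-subject variability.
Zero-variance medians give $R^2 = 0$ with a flag rather than NaN (the class
is `near_zero` regardless); $R^2$ is always reported with the number of
velocities so users can judge how much faith a 4-point extrapolation
deserves.

Method comparisons route by normality of the paired differences
(Shapiro–Wilk at α = 0.05) to the two-sided paired t-test or the Wilcoxon
signed-rank test; Levene's test is reported alongside. Effect size is
Hedges' g with pooled SD and small-sample correction
$J = 1 - 3/(4\,\mathrm{df}-1)$, $\mathrm{df} = 2n-2$. Degenerate inputs are
answered, not thrown: all-zero differences give $p = 1$, $g = 0$ with a
degeneracy flag; constant non-zero differences route to Wilcoxon with the
flag set. The velocity effect is the Friedman test on the complete
subjects × velocities matrix (fully tied matrices report $p = 1$); when the
omnibus is significant, all $\binom{4}{2} = 6$ pairwise Wilcoxon contrasts
are Bonferroni-multiplied. Summaries print mean ± SD under normality and
median (IQR) otherwise.

## Problem sizes used in validation

Chosen to give stable rates while staying desk-scale:

* full-EMG pipeline recovery: 100 independent subjects (40 trials each,
  soleus channel), requiring corrected TSRT within 0.5° of the true 19° and
  |corrected slope| < 0.01 in ≥ 90%;
* velocity-effect pattern: 200 cohorts of n = 12 at the measurement level —
  per-trial SRTs from the commanded kinematics plus 4 ms Gaussian
  onset-timing jitter, matched to the measured detector accuracy. This
  validates the group statistics without simulating ~10⁵ EMG traces; the
  EMG-level claim is carried by the 100-subject run;
* detector calibration: 1000 pure-noise traces (false alarms), 100 bursts
  (accuracy), exhaustive-search equivalence on deterministic steps.

## Known limitations

* The AGLR assumes Gaussian EMG with a quiescent baseline; rhythmic or
  voluntary pre-stretch activity must be caught by the rejection rule
  upstream.
* Detection carries a small positive bias (~3–4 ms at the default burst
  gain) because a linearly rising burst is indistinguishable from baseline
  for its first couple of milliseconds; at the fastest velocity this maps
  to ≲ 0.5° and is visible as corrected TSRT estimates a tenth of a degree
  or two below truth.
* Thresholds crossed during the acceleration phase make the *uncorrected*
  SRT's velocity dependence shallower than $-\ell$; comparisons against the
  constant-velocity closed form are only valid for post-acceleration
  crossings.
* The near-zero-slope class is a descriptive cut at 0.01 deg/(deg/s), not a
  hypothesis test; borderline slopes (0.009 vs 0.011) land in different
  classes by design.
* `reconcile_onsets()` trusts the sustained-SD detector whenever the two
  disagree by more than 20 ms, mirroring manual-correction practice; on
  clean synthetic data the AGLR is usually the more accurate of the two, so
  review-flagged onsets deserve exactly the scrutiny the flag requests.
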