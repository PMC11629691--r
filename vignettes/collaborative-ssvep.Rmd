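---
title: "Collaborative SSVEP decoding and inter-brain coupling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative SSVEP decoding and inter-brain coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepcollab)
```

## The problem

In a steady-state visually evoked potential (SSVEP) brain-computer
interface, each selectable target flickers at its own frequency; attending
a target entrains occipital cortex at that frequency, and the attended
target is identified from the spectral peak of the EEG. In a *collaborative*
setting several participants attend the same stimulus simultaneously, which
raises two analysis questions this package addresses without any EEG
hardware:

1. **Decoding** — does pooling spectral power across participants
   ("collaborative decoding") recognise the target more accurately than one
   brain alone?
2. **Coupling** — how synchronised are the participants' brains, measured
   as the correlation of their channel-wise spectral responses?

## The decoding pipeline

The recognition pipeline is the standard fixed-order chain:

1. resample to 512 Hz (anti-aliased),
2. zero-phase band-pass 4–45 Hz,
3. segment into 1-s epochs aligned to trial onsets,
4. Welch power spectral density (PSD) per channel,
5. per candidate frequency $f$, pool $\mathrm{PSD}(f)$ over the occipital
   channels O1, O2, Oz — and, for collaborative decoding, over those
   channels of *all* participants (one grand mean) —
6. predict $\hat f = \arg\max_f$ pooled power.

Accuracy is the fraction of epochs with $\hat f$ equal to the trial's true
frequency. Decoding regimes are compared as II (individual paradigm,
individual decoding), CI (collaborative paradigm, individual decoding) and
CC (collaborative paradigm, collaborative decoding), with the standardized
mean difference (Cohen's $d$, pooled-SD denominator, |d| > 0.2/0.5/0.8
labelled small/medium/large) quantifying group differences.

## The coupling statistic

For one pair of participants and one target frequency, each trial yields
two vectors of per-channel band power (PSD at the target frequency,
averaged over the trial's 1-s epochs). Per trial, the Pearson correlation
$r_m$ between the two vectors is transformed to $z_m = \operatorname{atanh}
r_m$ (Fisher Z); the coupling estimate is $\bar z$ over the $m$ trials,
reported also back-transformed as $\tanh \bar z$.

**P-value construction.** The source description says only that an overall
P-value is derived from the mean Z value "based on the normal
distribution". We make that precise as follows: under the null of no
coupling each $z_m$ is approximately $N(0, 1/(n_{ch}-3))$, so
$\bar z \sim N(0, 1/(m(n_{ch}-3)))$ and we report the one-sided upper tail
$p = 1 - \Phi\!\left(\bar z \sqrt{m (n_{ch} - 3)}\right)$ — one-sided
because the question is whether synchrony exceeds chance. The construction
is isolated in `coupling_analysis()` so a two-sided or permutation variant
can be swapped in. Its calibration is verified empirically: over 1000
simulated independent-noise pairs the type-I error at $\alpha = 0.05$ must
fall inside the 99% binomial interval [0.032, 0.068] (acceptance criterion
3).

Two readings of "PSD … at 1-s EEG trial" are possible (each 1-s epoch as
its own trial, or band power averaged over a 10-s trial's epochs). Both are
supported — `coupling_analysis()` accepts any nesting of epochs into
trials — and the default, used by `coupling_from_recordings()`, averages
over each annotated trial's epochs, because the tasks are described as 10-s
trials cut into 1-s epochs.

Numerical safeguards: $|r|$ is clamped to $1 - 10^{-7}$ before
$\operatorname{atanh}$ so numerically perfect correlations (e.g. a
participant paired with itself) keep $z$ and $p$ finite, and the returned
$p$ is floored at the smallest positive double so $p \in (0, 1]$ always
holds. Constant vectors raise a degenerate-variance error rather than
returning `NA`.

## The synthetic stated world

`generate_recording()` replaces the VR + amplifier stack. Per trial of
duration $T$ at target $f$:

$$x_c(t) = A\, g_c \sin(2\pi f t + \varphi) \;+\;
  \sigma\, \eta_c(t) \;+\; \kappa\, \gamma_c\, s_c(t)$$

* $A$ (`ssvep_amplitude`, µV, default 5) scales the evoked sinusoid —
  fundamental frequency only, no harmonics, because the decoder uses only
  fundamental power; $\varphi$ is a fresh uniform phase per (participant,
  trial).
* $g_c$ is the occipital gain profile: 1.0 on O1/O2/Oz, 0.3 on parietal
  channels, 0.05 elsewhere, so occipital averaging is meaningfully better
  than whole-head averaging, as the channel choice presumes.
* $\eta_c$ (`noise_amplitude` $\sigma$, µV, default 5) is per-channel
  independent background noise: an equal-power mixture of 1/f-shaped
  ("pink", spectral exponent 1) and white Gaussian noise, normalised to
  unit variance. This is a minimal realistic EEG background; no eye-blink,
  muscle or line-noise artifacts are modelled.
* $s_c$ is a broadband component *identical across participants* within a
  trial, scaled by `coupling_gain` $\kappa$ and by a per-channel gain
  $\gamma_c \sim N(0,1)$ redrawn each trial but shared across participants.

**Why the random per-channel profile $\gamma_c$.** With a flat shared
component the inter-participant correlation of band powers is
$r = s^2/(s+n)^2$ in terms of shared/independent power $s, n$, which caps
at $r = 0.25$ when the shared power equals the noise power — too weak a
knob. With $\gamma_c$ the shared band power varies as
$\gamma_c^2 |S_c|^2$ across channels, whose variance (5 for unit powers,
by the moments of $\chi^2_1$ and the exponential) dominates the
denominator: at $\kappa = \sigma = 1$ the predicted correlation is
$5/(5+2+1) \approx 0.6$. This second-moment calculation was done before
any test was run; the generator then empirically gives mean $r \approx
0.6$ at gain 1 and $\approx 0.9$ at gain 2, rising monotonically from
$\approx 0$ at gain 0 (acceptance criterion 4).

Trials are scheduled round-robin over the target set (default 8, 10, 13 Hz;
10 trials per target; 10 s each), back-to-back, with EDF+-style annotations
carrying the true frequency. All randomness derives from one master seed by
fixed integer arithmetic on (seed, participant, trial) — exact in double
precision and collision-free in practice — so output is bit-reproducible
and adding a participant never perturbs existing participants' data. The
shared-noise stream is keyed on (seed, trial) only, so it is identical
across the group, and per-seed the only thing a gain change alters is the
scale of that shared component (which is why monotonicity holds almost
surely per seed, not only on average).

What a green test on this world does *not* establish: fidelity to real EEG
amplitudes or SNRs (none are published for the source recordings — the
defaults were chosen once for testability), realistic volume conduction
(no head model), artifacts, or non-stationarity.

## Numerical choices

* **Resampler**: frequency-domain resampling — spectrum truncated at the
  new Nyquist (an ideal anti-alias low-pass) and inverse-transformed to
  $\lfloor n \cdot \text{target}/\text{source} \rfloor$ samples. Chosen
  over polyphase FIR because it preserves on-grid tones exactly (within
  1%, tested) and introduces no filter-design parameters; its known edge
  wrap-around is negligible for multi-second recordings. Upsampling is
  rejected.
* **Band-pass**: 4th-order Butterworth prototype (8 poles after the
  band-pass transform), bilinear transform with pre-warping, applied
  forward-backward (zero phase; magnitude response squared) with
  odd-extension padding and steady-state initial conditions. The response
  is asserted: < 1 dB attenuation at 8/10/13 Hz, > 20 dB at ≤ 1 Hz and
  60 Hz. The band is named by the source; order and family are
  conventional EEG choices.
* **Welch PSD**: the paradigm needs 1 Hz resolution to put 13 Hz on-grid,
  and a 1-s epoch at 512 Hz offers exactly 512 samples, so the default is
  one full-length Hann-windowed, mean-detrended segment (Welch degenerating
  to a modified periodogram); segment length and overlap remain
  configurable for longer epochs. One-sided density scaling, verified
  against an independent periodogram oracle and by Parseval's identity on
  white noise.
* **Band-power lookup**: nearest grid bin, ties toward the lower
  frequency; on the default grid the targets are exact bins so ties cannot
  occur.
* **Decoding ties**: equal pooled power predicts the lowest candidate
  frequency — deterministic and independent of candidate order.
* **Degenerate inputs**: zero pooled variance with unequal means (Cohen's
  d), constant correlation inputs, empty result lists, missing channels and
  out-of-range frequencies all raise errors naming the problem; a noiseless
  benchmark reports its effect sizes as "degenerate" rather than inventing
  a d.

## The collaboration protocol

Messages are newline-delimited JSON records (JOIN, ACK, START_PARADIGM,
STIM_SYNC, EEG_DATA, ANALYSIS_RESULT, FEEDBACK, STOP_PARADIGM, ERROR) over
TCP; the server is poll-driven so a whole multi-client session can run
deterministically inside one R process (and `serve()` wraps the poll loop
for standalone use). Design decisions that matter:

* **Client-side preprocessing.** Zero-phase filtering of a continuous
  recording is not the same as filtering isolated 1-s chunks, so the
  simulated client preprocesses its full recording and streams the
  resulting epochs; the `/analysis/ssvep` route then computes PSD +
  decoding. This is what makes the required online/offline *bit*-equality
  achievable (criterion 6); the route still resamples/filters raw-rate
  epochs as a fallback.
* **64-bit sample encoding.** EEG_DATA samples are base64 of little-endian
  IEEE-754 *doubles* (not 32-bit floats): 32-bit encoding would round the
  generator's doubles and silently break the bit-equality contract.
  Likewise all numbers in protocol messages, results files and archives are
  serialised with 17 significant digits, which round-trips doubles exactly.
* **Ordering contract.** START_PARADIGM and STIM_SYNC are broadcast to
  every member before any EEG_DATA is accepted; early data draws an ERROR
  reply ("paradigm not started") on a connection that stays alive.
  Sequence numbers are strictly increasing per (session, participant,
  direction) and asserted gapless in transcripts.
* **Coupling timing.** Buffered per-participant trials are analysed for
  every pair and every target at STOP_PARADIGM (the source does not say
  when coupling runs online; an explicit-request hook would be a
  registered route away).
* **Archives.** Per participant EDF (16-bit, ±200 µV default physical
  range with per-channel auto-ranging — quantisation ≈ 0.006 µV — and
  annotations as EDF+ TALs), plus transcript and results as line-delimited
  JSON; round-trips are lossless up to EDF quantisation, and exactly
  lossless for results.

Latencies are logged via message timestamps but never asserted: the source
platform's "<30 ms" and "<0.27 ms" figures are hardware-dependent and are
not contracts of this package.

## Worked example

```{r example}
cfg <- synthetic_config(sampling_rate = 512, trial_duration = 2,
                        trials_per_target = 2, noise_amplitude = 2,
                        coupling_gain = 1, n_participants = 2, seed = 7)
recs <- generate_group_session(cfg)
psds <- lapply(recs, function(r) lapply(preprocess_pipeline(r), welch_psd))
# individual vs collaborative decoding of the same epochs
acc_ind <- mean(sapply(psds, function(pp)
  recognition_accuracy(lapply(pp, decode_individual))))
acc_coll <- recognition_accuracy(decode_session(psds, "collaborative"))
c(individual = acc_ind, collaborative = acc_coll)
coupling_from_recordings(recs[[1]], recs[[2]], target_frequency = 8)
```

## Known limitations

* The generator is a statistical stand-in, not a biophysical simulation:
  no leadfield, no harmonics, no artifacts, stationary noise.
* The EDF reader supports the continuous 16-bit subset this package
  writes (plus plain EDF), not the full EDF+ zoo (no discontinuous files,
  no per-signal rates besides the annotation channel).
* The protocol has no authentication or encryption and a single server
  process; it is an experiment-logic testbed, not a deployment stack.
* The normal-theory coupling p-value leans on the Fisher-Z variance
  approximation $1/(n_{ch}-3)$; band powers are not Gaussian, so its
  validity is established by the Monte-Carlo calibration test rather than
  assumed.
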