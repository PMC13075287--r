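---
title: "Methods: simulating and decoding a two-channel SSVEP Cheonjiin speller"
author: "ssvepspeller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding a two-channel SSVEP Cheonjiin speller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepspeller)
```

## The system being modeled

A steady-state visual evoked potential (SSVEP) speller presents five
flickering tiles; gazing at one entrains occipital EEG at the tile's flicker
frequency and its harmonics. Five frequencies — 6.67, 7.5, 8.57, 10 and
12 Hz, chosen as integer divisions 60/9 … 60/5 of a 60 Hz display refresh so
every flicker cycle spans a whole number of frames — map one-to-one onto the
commands UP, RIGHT, DOWN, LEFT and SELECT. Those five commands drive a
cursor over a 4 × 4 Cheonjiin keyboard (14 keys, two empty cells): the top
row holds the three vowel elements ㅣ (human), ㆍ (heaven), ㅡ (earth) plus
DELETE; seven multi-tap consonant keys and SPACE/ENTER/PERIOD fill the rest.
All Korean vowels are composed from ordered element sequences (ㆍ then ㅣ
gives ㅓ; ㆍ ㅡ gives ㅗ), consonants by repeated taps (ㄱ → ㅋ → ㄲ), and
syllables assemble by the Unicode composition formula
`0xAC00 + (L·21 + V)·28 + T`.

This package reproduces the full pipeline without hardware: a synthetic EEG
generator stands in for the two occipital electrodes (O1/O2), and every
downstream stage — filtering, sliding-window canonical correlation analysis
(CCA), the accumulation decision rule, the Hangul composition automaton, and
the evaluation metrics — is the same code path an online system would run.

## The decoder

Within each 1.5 s analysis window (updated every 50 ms), the decoder
computes, for every stimulation frequency $f_k$, the leading canonical
correlation $\rho_k$ between the EEG window $X \in \mathbb{R}^{N \times C}$
and a sine–cosine reference template
$Y_k = [\sin 2\pi f_k t_n, \cos 2\pi f_k t_n]$,

$$\rho_k = \max_{w_x, w_y} \frac{\langle X w_x, Y_k w_y\rangle}
{\lVert X w_x\rVert\,\lVert Y_k w_y\rVert},$$

solved as a generalized eigenproblem on the column-centered covariances with
a ridge of $10^{-12}\times\mathrm{trace}$ on the diagonals so degenerate
windows never crash. Correlations are computed per channel and the maximum
across channels is kept (the channel-max strategy; a joint multichannel mode
is available for comparison). The frequency with the largest $\rho$ is the
instantaneous classification; ties break toward the lowest frequency index.

Templates use `n_harmonics = 1` by default — the plain sine–cosine pair —
with up to 3 harmonics available, since harmonic templates are standard in
SSVEP decoding but the minimal pair is the configuration the decision-rule
thresholds were tuned for. The window's time origin is $t_n = n/f_s$ from
$n = 0$; CCA against a sine–cosine pair is phase-invariant, so the origin is
unobservable (tested).

**Decision rule.** Per-update correlation profiles are collected for 1.5 s
(30 updates). A frequency is a valid candidate iff $\rho \ge 0.25$ in at
least 30 % of the updates in the collection window
($\lceil 0.3 \times 30\rceil = 9$); among valid candidates the one with the
highest mean accumulated correlation — the mean over its qualifying updates,
which is what makes a sparse-but-strong candidate lose to a
consistent-but-moderate one — is emitted, otherwise nothing is. After each
emission, updates within a 1 s ignore (refractory) interval are discarded.
Collection windows are consecutive non-overlapping 30-update blocks that
reset after every decision; a sliding-collection variant
(`decision_config(collection = "sliding")`) evaluates the trailing 30
updates at every hop and detects boundary-straddling bursts earlier. The
phrase "30 % of consecutive decoding updates" admits two readings; the
default counts qualifying updates anywhere in the collection window, and
`consistency_mode = "run"` requires a strictly consecutive run instead.

## The preprocessing chain

Each channel passes through: per-window linear detrend (least-squares line
removal — slightly stronger than mean subtraction, removing slow drift
within the window); an order-2 Butterworth band-pass 5–45 Hz; then band-stop
filters 48–52 Hz and 58–62 Hz in that fixed order (both always applied,
covering either mains region). "Order 2" is the design order handed to each
section's Butterworth design (the convention of the usual Python/Matlab
design calls, giving 4th-degree band transfer functions); the measured gain
at 10 Hz is 0.993. The online path filters causally with explicit
filter-state carry-over, so chunked streaming and whole-stream filtering
agree sample-for-sample (tested to 1e-9); a zero-phase mode
(`filter_chain(causal = FALSE)`) exists for offline spectral figures.
Window/hop lengths that do not map to whole sample counts are rejected
rather than rounded, keeping window bookkeeping bit-exact.

## The synthetic EEG generator

`sim_config()` defines the study conditions; its defaults were fixed once,
on first-principles plausibility, and the tests and acceptance runs use them
unchanged:

| parameter | default | meaning |
|---|---|---|
| `fs_hz` | 200 | sampling rate (Hz) |
| `ssvep_amp_uV` | 1.0, 0.4, 0.15 | harmonic amplitudes (µV), harmonics 1–3 |
| `noise_exponent` | 1 | background spectrum $1/f^{\alpha}$ |
| `noise_rms_uV` | 1.0 | broadband background RMS (µV) |
| `alpha_band_amp_uV` | 0.4 | ~10 Hz idle-rhythm RMS (µV) |
| `line_noise_hz`, amp | 60, 0.3 | mains interference |
| `channel_gain` | 1.0, 0.9 | per-channel SSVEP gain |
| `channel_phase_jitter_rad` | 0, 0.2 | per-channel SSVEP phase offset |
| `response_latency_s` | 0.14 | stimulus onset → entrainment delay |

The SSVEP is a sum of phase-locked sinusoidal harmonics (matching both the
CCA reference model and the harmonic peaks real recordings show) rather than
a rectified square-wave response. The background is spectrally shaped
Gaussian noise ($1/f$), an alpha component built as 8–12 Hz band-filtered
noise — deliberately colliding with the 10 Hz stimulus, but incoherent, so
it inflates rather than fabricates 10 Hz correlations — and a 60 Hz line
tone. The two channels share one SSVEP source with per-channel gain and
phase offsets plus independent noise, which is exactly the situation the
channel-max strategy is meant for. A typical harmonic-to-background
amplitude ratio of 1:1 represents a moderate subject;
`high_snr_sim_config()` (gain 3) represents the clean-signal regime and is
what the end-to-end "near-perfect spelling" checks use. Everything is a pure
function of (seed, config): identical inputs give bit-identical streams.

What the generator does *not* model: eye blinks, EMG, electrode drift
(the modeled pipeline applies no artifact removal either), luminance/contrast
effects, attention lapses, or any SSVEP amplitude non-stationarity. Signals
are stationary within a segment, so passing tests show the *decoder* behaves
correctly, not that a human would reach the same numbers; in particular the
accuracy decline real subjects show beyond 2 s windows (a latency/attention
effect) is not promised by the stationary simulator.

**Rest-state false positives.** Band-limiting 1.5 s windows to 5–45 Hz
leaves so few effective degrees of freedom that background-only windows
reach channel-max correlations near 0.25 routinely — for any noise color,
including white. Rest-only streams therefore trigger the r ≥ 0.25 rule at
roughly 0.4 commands/s with a near-uniform command mix. This is a real
property of threshold-based CCA decoders without an idle-state mechanism,
not a simulator artifact; the guided protocols modeled here (like the
original system's feedback-paced operation) sidestep it because gaps between
attended segments are short. It also means a zero-signal-amplitude session
is scored at the 20 % chance level rather than at 0 %.

## Experiment harnesses

`run_experiment1()` replays the single-command protocol: each command twice
per 10-selection set, seed-shuffled order, 4 s attended dwell (the original
sessions were human-paced; 4 s accommodates the ~3 s decision latency of
window + collection), 2 s gaps. Decoded events are attributed to
ground-truth segments by their *data-center* time — an emission at $t$ was
produced by roughly window + collection seconds of trailing data, so it is
assigned by $t - (\text{window}+\text{collection})/2$; the first such event
scores the segment, later ones are trailing re-detections of the same
stimulus. A segment with no emission scores as class `NONE`, an error.
Alongside this emission-scored accuracy the harness reports the
forced-choice accuracy (argmax of the segment's mean correlation profile),
the empirical mean inter-emission time, and ITR under both the rule-derived
selection time ($T$ = collection + ignore = 2.5 s) and the empirical one.

`run_experiment2()` plans the command script for a target word (default the
two-syllable word for "head"), simulates attending to each scripted command,
and replays the *decoded* command stream through the composition automaton,
so one mis-decoded command corrupts the typed text exactly as it would
online. `window_sweep()` re-runs the protocol for windows 0.5–3.0 s in 0.5 s
steps on matched seeds, with ITR computed at $T$ = window + ignore.

The information transfer rate uses the standard discrete-selection formula
$\mathrm{ITR} = [\log_2 N + P\log_2 P +
(1-P)\log_2\frac{1-P}{N-1}]\,60/T$ with $0\log 0 := 0$; at $N = 5$,
$P = 0.83$, $T = 2.5$ s it evaluates to 31.8 bits/min. Precision, recall and
F1 are one-vs-rest macro-averages (the averaging convention is carried in
every report); accuracy equals micro-recall. The spectral tools are an
amplitude-true one-sided FFT spectrum, a neighbor-bin SNR
(20 log10 of the peak over the mean of 10 bins per side, ±1 bins around the
peak and listed harmonics masked, capped at 100 dB — the ratio definition is
this package's, as none is standard), and an event-related spectral
perturbation map (Hann short-time transform, 0.5 s segments, 90 % overlap,
dB relative to per-frequency baseline power).

## The Cheonjiin engine

The composition automaton tracks committed text plus a pending syllable
(initial, vowel-element sequence, up to two final components). Key
behaviors, all chosen where the underlying conventions are genuinely open
and all configurable or documented:

- **Edges and empty cells**: the cursor clamps at grid edges and skips
  through empty cells (`wrap = TRUE` gives a toroidal grid); movement costs
  depend on this, so the layout JSON under `inst/extdata/` is the single
  source of truth and the bundled non-top-row key placement follows the de
  facto Cheonjiin phone arrangement.
- **Multi-tap commit**: moving the cursor or pressing a different key
  commits a tap cycle; there is no timeout, because a BCI has no dwell
  clock. The typing planner inserts a minimal away-and-back detour when two
  successive jamo would otherwise merge on one key.
- **Resyllabification**: a consonant that cannot extend the current
  syllable's final is *held* rather than hard-committed, because a later tap
  may produce a jamo that merges back (ㅎㅏ + ㄹ + [ㄷ→ㅌ] must become 핥,
  not 할ㅌ); a following vowel steals the last final component as the next
  syllable's initial. Doubled consonants and all 11 compound finals are
  supported so arbitrary input cannot corrupt the state.
- **Planner**: text decomposes to jamo → key presses (element sequences for
  vowels, tap counts for consonants); transitions are routed by
  breadth-first shortest paths over the move relation, one SELECT per press.
  Movements and SELECTs are counted separately because the keystroke-economy
  convention in circulation (34 Cheonjiin vs 48 QWERTY movements for the
  greeting word) does not state whether selections count or where the cursor
  starts; the bundled flat QWERTY-style grid exists only for this
  comparison, on which the bundled layouts give 36 vs 51 movement-only from
  the home cell — the direction of the claim, not its exact integers, is the
  reproducible property.

## Numerical choices and problem sizes

Covariance ridge $10^{-12}\times$ trace; all tie-breaks toward the lowest
frequency index; windows/hops rejected unless integer in samples; stream
decoding uses a vectorized equivalent of the per-window CCA (projection onto
orthonormalized centered templates), tested to agree to 1e-9. The test and
acceptance runs use desk-scale problem sizes chosen to keep the full suite
in tens of seconds while leaving sampling slack around every threshold: 100
single-command decisions (10 sets) and 5 word-entry trials at high SNR, 500
decisions for the chance-level check, 100 seeded epochs per SNR rung for the
monotonicity property, 10–20 epochs for ERSP averages.

## Known limitations

- The simulator's stationarity means window-sweep results flatten beyond
  1.5 s instead of declining as real subjects do.
- Human headline numbers (83.33 %/80.67 % accuracy, 32.87/29.53 bits/min)
  depend on three real participants and are out of reach of any simulator
  calibration; the package reproduces the printed *worked-example*
  quantities and the property-level behavior instead.
- The rest-state false-positive rate documented above makes the decoder
  unsuitable for free-running (non-paced) operation without an added
  idle-state criterion; that extension is out of scope.
- The bundled QWERTY comparison grid is a planning fixture, not an IME: it
  has no shift layer, so doubled consonants cost two presses there.
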