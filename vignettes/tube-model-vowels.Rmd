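---
title: "Tube-model vocal tract acoustics and the /u/-like quality of chimpanzee hoo calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tube-model vocal tract acoustics and the /u/-like quality of chimpanzee hoo calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractsim)
```

## The scientific question

Chimpanzee *hoo* calls sound strikingly like the human close back rounded
vowel /u/: their spectra show two prominent resonance peaks (formants), a
low F1 near 300–400 Hz and a low F2 near 900 Hz, inside the human /u/
region. Yet chimpanzee oral anatomy (the simian shelf, a flat tongue, a
narrow pharynx) almost certainly precludes the human articulation of /u/.
`tractsim` asks the purely acoustic question: what tube geometries — within
the articulatory moves a chimpanzee *does* have, namely lip protrusion, lip
rounding, and an inflatable laryngeal air sac — produce an F1–F2 dispersion
in the hoo//u/ region?

The package contains the full workflow: a transmission-line tube simulator,
a five-segment chimpanzee-tract simulacrum swept over an articulatory
parameter grid, comparison of the predicted F1–F2 dispersions with
reference formants for human /u/ and chimpanzee hoos, cascade formant
synthesis of best-fit dispersions, a formant estimator for audio designed
for high-f0 calls, and a synthetic hoo-corpus generator that makes the
whole chain testable without field recordings.

## The acoustic model

### Source-filter assumption

Vocalization is modelled as an ideal glottal volume-velocity source
filtered by the vocal tract. The tract is a sequence of rigid concentric
cylinders (an area function), each described by a length $l_i$ (cm) and a
cross-sectional area $A_i$ (cm²), ordered from glottis to lips. Phonation
itself is not modelled; its spectral envelope enters only as a −12
dB/octave tilt in the synthesis and analysis stages.

### Chain-matrix transfer function

Each cylinder is a segment of acoustic transmission line with
characteristic impedance $Z_i = \rho c / A_i$ and propagation constant
$\gamma = \alpha + jk$, $k = \omega / c$. Its two-port chain (ABCD) matrix
relates pressure and volume velocity at the segment ends:

$$
\begin{pmatrix} p_{\mathrm{in}} \\ U_{\mathrm{in}} \end{pmatrix} =
\begin{pmatrix}
\cosh \gamma l_i & Z_i \sinh \gamma l_i \\
Z_i^{-1} \sinh \gamma l_i & \cosh \gamma l_i
\end{pmatrix}
\begin{pmatrix} p_{\mathrm{out}} \\ U_{\mathrm{out}} \end{pmatrix}.
$$

Multiplying the matrices glottis-to-lips and applying the boundary
conditions — ideal flow source at the glottis, zero pressure (or optionally
a piston-in-baffle radiation inertance) at the lips — gives the
volume-velocity transfer ratio $H(f) = U_{\mathrm{lips}} /
U_{\mathrm{glottis}} = 1 / (C Z_L + D)$. `transfer_function()` returns
$20 \log_{10} |H|$ on a frequency grid; `find_formants()` picks its
prominent peaks. For a single uniform closed–open tube this reduces to
$|1/\cos(2\pi f L / c)|$ with resonances at odd multiples of $c/4L$ — the
quarter-wavelength series that `uniform_tube_resonances()` provides as an
analytic oracle, and that the test suite checks the simulator against for
lengths 5–30 cm.

### Losses

The chain matrix of a lossless cylinder produces genuinely infinite
resonance peaks. Detailed wall-impedance loss circuits (yielding walls,
viscous and thermal boundary layers) are deliberately not modelled: the
claims this package supports concern peak *frequencies*, which are
insensitive to small damping. Instead a single dimensionless
`damping_fraction` (default 0.005) sets the attenuation constant to that
fraction of the wavenumber — equivalent to a small series resistance
proportional to each segment's characteristic impedance. This keeps every
peak finite while shifting peak positions by far less than the 1 Hz
frequency grid. Setting it to 0 recovers the lossless model, which the
invariance tests use.

### Numerical choices

* Frequency grid: 50–5000 Hz at 1 Hz steps by default; peaks are refined by
  parabolic interpolation over the three surrounding grid points, giving
  sub-Hz resolution at negligible cost.
* Peak prominence threshold: 3 dB, rejecting grid ripple without
  suppressing genuine resonances.
* Speed of sound: 35,000 cm/s by default (350 m/s); the dry-air 20 °C
  value 34,300 cm/s is selectable through `acoustic_constants()`. Both are
  exposed because the convention differs across the modelling literature;
  every resonance scales linearly with $c$, so the choice is transparent.
* Invariance tolerances: 0.5 Hz on peak frequencies for segment-splitting
  and area-scaling checks.

## The five-segment chimpanzee tract

`build_tract()` assembles, glottis to lips:

| segment | length (cm) | area (cm²) | role |
|---|---|---|---|
| constriction | 0.125 (fixed) | 0.125 (fixed) | narrow neck before the air sac |
| air sac | 1–2 (swept) | 1–30 (swept) | laryngeal air-sac simulacrum; area 1 = no sac |
| main tract | 18 (fixed) | 1 (fixed) | adult-male chimpanzee vocal tract length |
| lip protrusion | 0.2–3.8 (swept) | 1 (fixed) | tract extension by the large, mobile lips |
| lip opening | 0.2 (fixed) | 0.2–1 (swept) | lip rounding |

The default grid (`param_grid()`) is 19 protrusion lengths × 3 sac lengths
× 30 sac areas × 5 lip-opening areas = 8550 configurations, enumerated
deterministically (protrusion slowest, lip area fastest) so that sweep
output is diffable; `run_sweep()` is pure computation with no randomness,
and repeated runs are byte-identical.

Design points that were genuinely open, and how they were fixed:

* **Protrusion-segment area.** Protrusion extends the tract, rounding is
  carried by the separate lip-opening segment, so the protrusion segment
  inherits the 1 cm² tract bore. It is configurable.
* **The constriction.** A "narrow constriction of 0.125 cm" before the sac
  is ambiguous between a length and an area; it is implemented as a
  segment with both length 0.125 cm and area 0.125 cm², each independently
  configurable, plus a switch to disable the segment entirely. The reading
  is transparent and reversible.
* **Sweep failure policy.** A configuration whose peak picking fails is
  recorded with the failure reason in its `status` column rather than
  aborting or silently dropping a row of an 8550-point sweep. (On the
  default grid, no configuration fails.)

Two robust qualitative behaviours emerge, and are asserted by the test
suite: F1 is non-increasing in lip-protrusion length (lengthening the
front of the tract lowers the first resonance), and F2 is non-increasing
in air-sac area (a voluminous cavity behind the tract pulls the second
resonance down). Reaching the hoo region requires combining long
protrusion with narrow lip opening — articulatory territory available to a
chimpanzee but not to a human.

## Reference formants and "overlap"

`vowel_references()` carries mean ± SD F1/F2 values for /u/ spoken by
adult males, adult females, and children (the classic Peterson–Barney
survey), and two summaries of the same chimpanzee hoo sample
(`chimp_hoo`: F1 374.44 Hz; `chimp_hoo_methods`: F1 358.75 Hz). Both hoo
summaries are preserved as published; `chimp_hoo_methods` is the default
comparison target and neither is "corrected" toward the other.

"Overlap" is operationalized as both F1 and F2 falling within one SD of
the reference means — the published comparisons are visual, so an explicit
box criterion is the package's own choice, and `overlap_report()` states
it. "Closest fit" (`nearest_configuration()`) defaults to Euclidean
distance in Hz; a per-SD-normalized metric is provided because the two
axes have very different spreads, and ties break toward the shorter tract,
then enumeration order.

## Formant synthesis

`synthesize_vowel()` is a classic cascade (Klatt-style) source-filter
synthesizer: an impulse train at `f0` (default 100 Hz — low enough that
the harmonics sample the envelope densely and vowel quality survives),
passed through a −12 dB/octave spectral-tilt filter and then one
second-order digital resonator per formant. Bandwidths default to 60, 90,
then 120 Hz — typical cascade-synthesis values; they are configurable.
Output is normalized to a 0.9 peak, is exactly reproducible, and is
written as 16-bit PCM WAV by `synthesize_to_wav()`. The full Klatt
parameter set (nasality, aspiration, source switching) is out of scope.

## Formant estimation from audio

Linear predictive coding is deliberately not used: when f0 is high, as in
chimpanzee calls, LPC poles lock onto individual harmonics and
"formants" near multiples of f0 are artefacts. `estimate_formants()`
instead automates the visual-inspection / synthesizer-matching tradition:

1. `estimate_f0()`: frame-wise autocorrelation (50 ms frames, 10 ms hop,
   60–600 Hz search, first strong peak within 15% of the maximum to guard
   against octave errors), median across voiced frames; aperiodic input
   returns `NA` ("no f0") rather than a number.
2. The f0 is sharpened by maximizing summed harmonic energy of a comb, and
   harmonic amplitudes are measured by windowed DFT at exact multiples of
   f0, with the broadband noise floor estimated from off-harmonic bins
   (median across harmonics) and power-subtracted.
3. A spectral envelope is interpolated (natural spline) through the
   tilt-compensated harmonic amplitudes; its most prominent maxima are the
   peak-picked formant candidates. An F1 at or below the first harmonic is
   reported at the envelope edge and flagged `f0_coincident`.
4. Analysis-by-synthesis refinement (on by default): the candidates
   initialize a least-squares fit of a cascade-resonator +
   spectral-tilt envelope model to the harmonic amplitudes, weighted by
   local SNR. With plentiful harmonics the tilt is a free parameter; with
   few (the typical hoo case: three or four harmonics above the floor)
   it is fixed at the assumed −12 dB/octave so the fit stays well-posed.
   When peak picking finds fewer maxima than requested — two resonances
   less than a harmonic spacing apart merge visually — the fit is run
   from several displaced starts and the best residual wins
   (`merged_peaks` flag).
5. With no f0 at all, the estimator falls back to peaks of the cepstrally
   smoothed long-term average spectrum (`no_f0` flag).

The harmonic grid is the hard information limit: at f0 = 300 Hz the
envelope is sampled every 300 Hz, so per-call errors above 10% occur when
a formant sits mid-way between harmonics and the SNR is low. The
acceptance checks are therefore *median* relative errors: ≤ 5% at
f0 = 100 Hz and ≤ 10% at f0 = 300 Hz over 100 randomized vowels, which the
suite verifies.

## The synthetic corpus

`generate_corpus()` stands in for field recordings. Its defaults *are* the
study conditions: 8 egressive calls from 3 individuals; durations from a
normal with mean 0.61 s and SD 0.31 s truncated at 0.1 s (a floor is
necessary because the SD is half the mean; a truncated normal is the
minimal assumption given only a mean and SD); F1 ~ N(358.75, 56.93²) Hz
and F2 ~ N(896.25, 133.04²) Hz drawn independently with rejection until
F1 + 50 Hz < F2; f0 ~ 300 ± 30 Hz, placed in the F1 region because
overlap of f0 with F1 is a documented feature of hoo calls (no published
chimpanzee f0 mean exists, so 300 Hz is the package's own choice, fully
configurable). Each individual carries a shared f0 offset with per-call
jitter (variance split 64/36). Calls are rendered through the package's
own synthesizer with a raised-cosine onset/offset ramp and broadband noise
at 25 dB SNR. All draws derive from a single seed; ground truth is drawn
before any audio is rendered, so the ground-truth table is identical with
and without rendering, and repeated runs are byte-identical.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: pant-hoot phase structure, ingressive
segments, reverberant and band-limited field-recording channels,
amplitude and f0 modulation within a call, and formant movement. The
corpus validates the estimator against the *stationary two-formant* model
of a hoo, nothing more.

## Problem sizes and runtimes

The shipped checks use the full 8550-configuration sweep (about 40 s on
one core), 100 round-trip vowels per f0 condition, and a 200-call corpus
for blind recovery — sizes chosen so the whole suite exercises the
study-scale workflow in a few minutes while keeping Monte-Carlo noise on
the median-error statistics small.

## Known limitations

* The air sac is an in-line expansion, not the anatomically more faithful
  side-branch (Helmholtz) topology; soft walls, neck mass, and wall
  vibration — reported elsewhere as the dominant air-sac factors — are not
  modelled. Conclusions about *how much* a real sac shifts formants should
  not be drawn from this simulacrum.
* Tubes are rigid and concentric; there is no time-varying articulation.
* The analysis stage assumes a stationary harmonic source with a smooth
  roll-off; creaky, biphonic, or strongly modulated calls will degrade it.
* The perceptual judgement that a synthesized best-fit vowel "sounds like
  /u/" is not machine-checkable; its computational proxy here is
  formant-space proximity to the reference dispersions.
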