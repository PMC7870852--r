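---
title: "Slow-wave retinal oscillations: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-wave retinal oscillations: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retiwave)
```

## The measurement and its model

Broadband NIRS of the retina records reflected intensity spectra I(λ,t) over
the 780–900 nm window at 1 Hz for about an hour. Relative to a reference
spectrum I₀(λ), the attenuation change ΔA(λ,t) = log₁₀(I₀/I) follows the
modified Beer–Lambert law,

ΔA(λ,t) = d · DPF · Σ_c ε_c(λ) · Δc_c(t),

with d the source–detector distance, DPF the differential pathlength factor,
ε_c the specific extinction coefficient of chromophore c, and Δc_c the
concentration change from baseline. Three chromophores are resolved: HbO₂,
HHb, and oxidized cytochrome-*c*-oxidase, whose CuA centre absorbs broadly in
the NIR. Because tissue CCO concentration is an order of magnitude below
hemoglobin, the fit uses the full >100-wavelength grid (ordinary least
squares via QR, per time point) to avoid crosstalk between the small, broad
oxCCO signature and the hemoglobin spectra. `ucln_unmix()` refuses designs
with condition number above 1e8 rather than returning silently amplified
noise; linearity of the solve and an exact noiseless forward/inverse round
trip are enforced by tests.

Two conventions matter and are made explicit rather than assumed. First,
attenuation is base-10 (optical density); extinction tables must declare
their logarithm convention in a header (`# log_base: 10|e`) and natural-log
tables are divided by ln 10 on load. Second, no established mouse-eye DPF
exists, so `pathlength_model()` defaults to DPF = 1 with a warning: absolute
micromolar scaling is conventional, and every downstream metric in this
package (period, regularity, semblance) is invariant to that overall scale.
Wavelength matching between a recording and a table is exact after rounding
to 0.01 nm; no interpolation of extinction spectra is performed. No published
extinction compilation is bundled: the table is an input, and
`synthetic_extinction_table()` provides a clearly-labelled synthetic
stand-in (smooth, full-rank, NIR-plausible shapes) for simulation and
round-trip work only.

## Isolating the slow waves

The oscillations of interest sit at 0.001–0.002 Hz, far below cardiac and
respiratory rhythms but close to instrumental drift. Preprocessing is
therefore two steps, in this order by default: a low-pass filter with 0.01 Hz
cutoff, then subtraction of a 6th-order polynomial fit per channel. (Both
orders are supported via `detrend_first`; the default follows the
filter-then-detrend reading of the processing description.)

The filter is a Butterworth of order 5 applied forward and backward. Zero
phase is not a nicety here — every downstream result is a phase analysis, so
any group delay would bias semblance directly. A naive forward–backward pass
with zero initial conditions produces large edge transients at so low a
cutoff; the implementation therefore uses odd-reflection padding with
steady-state initial conditions (the transient-matched scheme familiar from
other scientific computing environments), which preserves a constant input
to better than 1e-9 and a mid-band (0.0017 Hz) sinusoid's amplitude to
within 2%.

Detrending fits an orthogonal-polynomial basis on time normalized to
[−1, 1], so the fit is well conditioned at any record length and any input
that is itself a degree ≤ 6 polynomial is removed to numerical precision.
The subtracted trend is kept in the output metadata for inspection. One
intrinsic property deserves note: an OLS polynomial of degree 6 absorbs part
of any low-cycle-count oscillation — about 7% of a 7.5-cycle sinusoid's
amplitude at the worst phase, rising to ~23% at 3.75 cycles (a 16-minute
period over one hour). This attenuates amplitudes, not frequencies or phase
relationships, so period estimates and semblance are essentially unaffected;
amplitude comparisons across periods, which the pipeline does not perform,
would need care. Non-finite samples are rejected at construction — a
recording is either complete or fails loudly; no imputation is attempted.

## Period and regularity

`amplitude_spectrum()` computes a one-sided FFT amplitude spectrum of the
mean-removed channel, zero-padded 16× by default. A 3600-sample record at
1 Hz has native bin spacing ≈ 0.28 mHz, too coarse to separate 8-minute
(2.08 mHz) from 14-minute (1.19 mHz) periods reliably; padding interpolates
the spectrum so the peak can be localized (it adds no true resolution). No
window is applied by default, matching a plain FFT reading of the method;
Hann is available by flag.

The dominant frequency is the magnitude maximum within a search band,
default 0.0008–0.004 Hz. The nominal slow-wave range is 0.001–0.002 Hz, but
the group periods of interest (≈8 min ⇒ 2.1 mHz; ≈16 min ⇒ 1.0 mHz) straddle that
band's edges, so the default is deliberately wider and configurable. Ties
break toward the lower frequency, and an all-zero band is an error rather
than an arbitrary answer.

The regularity index is 100 × peak magnitude / AUC of the full one-sided
magnitude spectrum, with the AUC trapezoidal over bin index. Computing the
AUC over the whole spectrum (not the search band) is the only reading under
which sub-percent indices are plausible for an hour-long record, and it is
the default; a band-limited variant is available. The index is invariant to
amplitude scaling and DC, and a spectrum concentrated in a single interior
bin scores exactly 100.

Per animal, metrics are computed for oxCCO, HbT and HbDiff and pooled as the
mean across those three channels (ratio-then-average for regularity); the
pooled dominant frequency — the reciprocal of the pooled period, keeping the
period–frequency identity exact — is what the semblance stage uses.

## Wavelet semblance

Phase coupling between mitochondrial and hemodynamic signals is resolved
with the complex Morlet CWT (centre-frequency parameter ω₀ = 6, the standard
time-frequency trade-off; values below 5 are rejected as practically
inadmissible). The transform is evaluated in the Fourier domain per scale,
zero-padded to the next power of two at least twice the record length; the
frequency grid is log-spaced over 0.0005–0.01 Hz in 64 voices by default,
and results are robust across ±1 octave of voice density (tested at 32 and
128 voices).

From the cross-wavelet field C = W_a · conj(W_b), semblance is
cos(φ_a − φ_b) = Re(C)/|C| — +1 in phase, 0 at quadrature, −1 antiphase —
mapped over time and frequency. Cells with cross-power below 1e-12 of the
field maximum are flagged undefined rather than contributing noise-driven
±1. The per-animal summary is the time average of the semblance row nearest
the animal's dominant frequency over the whole record.

At millihertz frequencies the cone of influence (the edge-affected region,
taken as within √2 × scale of either end) covers much of a one-hour record.
Whole-record averages therefore include COI cells by default, matching
full-hour summaries; the COI-masked variant is always reported alongside so
the edge sensitivity of any conclusion is visible. For map rendering,
`plot_semblance_map()` restricts the period axis to the animal's period
± 50 s with a diverging palette anchored at −1/0/+1; rendering is a side
output, never an analysis input.

The decisive correctness property is the cosine law: for generated sinusoid
pairs with a known lag φ, the mean semblance at the oscillation frequency
must equal cos φ. The acceptance suite verifies this over φ ∈ {0, π/6, …, π}
with maximum absolute error below 0.05, and the analytic identities +1/0/−1
at lag 0/π/2/π within 0.02; edge effects of the finite record are the
remaining error source.

## The synthetic cohort generator

With no recordings deposited, the generator defines the test bed. All
channels share one slow-wave oscillator: a phase random walk whose
per-sample increment is 2πf·dt·(1 + e). The increment SD is scaled by the
square root of the samples per cycle so that `period_jitter_sd` is the
fractional SD of the cycle-to-cycle period — the quantity the presets are
stated in. Per channel, the oscillation gets an amplitude and a phase lag
relative to oxCCO, plus polynomial drift (normalized time, order ≤ 6 so the
default detrend removes it exactly) and i.i.d. Gaussian noise. One global
seed drives everything: the jitter stream is drawn first, then one noise
stream per channel in channel order, so output is bitwise reproducible. HbT
and HbDiff are never generated directly — always derived — so the defining
identities hold exactly by construction.

The four cohort presets encode the emulated phenotypes: periods 480 s
(young C57), 840 s (old C57) and 960 s (both CFH⁻/⁻ groups), with
cycle-to-cycle jitter 0.02, 0.10, 0.16 and 0.14 respectively — lowest in
young C57, highest in young CFH⁻/⁻, mirroring the regularity
ordering of the phenotypes (young C57 most regular, young CFH⁻/⁻ least). Old groups carry a
modest HbO₂ phase lag (−π/3, −π/6 for young CFH⁻/⁻) emulating the age-related
loss of HbO₂–oxCCO phase synchrony. Amplitudes are 0.2 µM (oxCCO, an order
of magnitude below hemoglobin), 0.6 µM (HbO₂) and 1.0 µM (HHb); with HHb
amplitude above HbO₂ and both in phase, HbDiff = HbO₂ − HHb is
automatically antiphase, reproducing the young-C57 semblance pattern without
any extra mechanism. The noise floor (0.02 µM) and drift magnitudes (a few
µM over the hour) are not characterized for the instrument; they are chosen
once for physiological plausibility and documented here, not fitted.

What the generator does *not* emulate: cardiac/respiratory components (far
above the band and removed by the low-pass anyway), eye-movement artifacts,
amplitude modulation of the oscillations, or photon-transport/eye-geometry
optics. Passing tests therefore demonstrate that the analysis chain recovers
known ground truth under realistic noise, drift and period jitter — not that
it is robust to every artifact of live recordings.

## Group statistics

Cohorts are compared with two-sided Wilcoxon rank-sum tests using midranks
for ties: exact by enumeration of all rank assignments for combined n ≤ 20
(covering cohort sizes of 4–9), and the tie- and
continuity-corrected normal approximation above. Two-sided is the conservative default and recorded as
a limitation. Summaries are mean ± SE with the sample (n−1) standard
deviation. No multiple-testing correction is applied, a deliberate choice at
these exploratory sample sizes; the number of uncorrected contrasts is flagged in every manifest.
The exact path's discreteness at these sample sizes means the normal
approximation can differ from it by a few hundredths in the worst case
(median gap < 0.02); the exact path is authoritative whenever it applies.
Significance tiers follow the printed conventions (* p < 0.05, ** p < 0.005,
**** p < 0.00005, ***** p < 0.00001).

## Pipeline, determinism and problem sizes

`run_pipeline()` orchestrates generation or loading, preprocessing, metrics,
semblance and group statistics, writing tidy tables where every row carries
the animal id, group and a hash of the fully-resolved configuration, plus a
JSON manifest (seed, package version, accumulated warnings — the DPF
default, COI coverage and uncorrected-contrast counts are always flagged).
Reruns with one seed are bit-identical across all numeric tables; per-animal
seeds are drawn once from the global seed. Stage failures abort with the
stage name and animal id.

The test and acceptance suites run at the intended recording scale — hour-long
1 Hz records, cohorts of 4/7/4/9 — with replicate counts (10–50 seeds,
1000 null replicates for type-I control) chosen to give stable Monte-Carlo
estimates at interactive runtimes; the full suite completes in under two
minutes on one core.

## Known limitations

- Absolute concentration scaling depends on an unknown DPF; only relative
  and phase quantities are interpretable by default.
- The degree-6 detrend attenuates low-cycle-count amplitudes (see above).
- Semblance carries no significance model: no red-noise null, no coherence
  normalization — by design; a near-zero
  cross-power cell is undefined, not evidence of decoupling.
- The exact rank-sum path enumerates C(n, n_a) assignments; at n_total = 20
  this is ~185k combinations and fast, but the threshold should not be
  raised casually.
- Preset parameters are phenomenological: they reproduce group-level period,
  regularity ordering and phase structure, not the biophysics beneath them.
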