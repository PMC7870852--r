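# retiwave

Non-invasive retinal metabolism analysis from broadband near-infrared
spectroscopy (bNIRS). The retina carries the densest mitochondrial population
in the body, and its metabolic state can be read optically: reflected NIR
light encodes concentration changes of oxidized cytochrome-*c*-oxidase
(Δ[oxCCO], the terminal electron-transport-chain enzyme and a marker of
mitochondrial oxidative metabolism) together with oxy- and deoxy-hemoglobin
(Δ[HbO₂], Δ[HHb]). In healthy young retinae these signals show spontaneous
slow-wave oscillations (~0.001–0.002 Hz, periods of minutes) in which
mitochondrial and hemodynamic rhythms are phase-locked; the oscillations
lengthen, lose regularity and decouple with age and in the CFH⁻/⁻ mouse, a
model of macular degeneration.

`retiwave` implements the full analysis chain for such recordings, plus a
synthetic cohort generator with known ground truth so every stage is testable
without animal data:

1. **Spectral unmixing** — the multiwavelength modified Beer–Lambert fit.
   Attenuation changes ΔA(λ,t) = log₁₀(I₀(λ)/I(λ,t)) are regressed on
   specific extinction coefficients over the full >100-wavelength grid,

   ΔA(λ,t) = d·DPF·Σ_c ε_c(λ)·Δc_c(t),

   solved per time point by QR least squares (`ucln_unmix()`), yielding
   Δ[oxCCO], Δ[HbO₂], Δ[HHb] and the composites Δ[HbT] = Δ[HHb] + Δ[HbO₂]
   (blood volume) and Δ[HbDiff] = Δ[HbO₂] − Δ[HHb] (oxygenation).
2. **Slow-wave isolation** — zero-phase Butterworth low-pass at 0.01 Hz and
   6th-order polynomial detrending (`preprocess()`).
3. **Oscillation metrics** — zero-padded FFT amplitude spectra; the dominant
   frequency in the slow-wave band gives the period, and the regularity
   index is 100 × peak magnitude / area under the magnitude spectrum
   (`animal_metrics()`).
4. **Wavelet semblance** — complex-Morlet continuous wavelet transforms; the
   semblance cos(φ_a − φ_b) = Re(W_a·conj(W_b))/|W_a·conj(W_b)| resolves the
   mitochondria–hemodynamics phase relationship over time and frequency, and
   is averaged at each animal's dominant frequency
   (`animal_semblance_panel()`).
5. **Group statistics** — mean ± SE summaries and exact two-sided Wilcoxon
   rank-sum tests between cohorts (`summarize_groups()`).

## Worked example

Simulate one young wild-type animal (8-minute oscillations, all hemoglobin
signals phase-locked to oxCCO), isolate the slow waves, and quantify them:

```r
library(retiwave)

preset <- cohort_preset("young_C57", seed = 7)
series <- derive_composites(generate_concentration_series(preset$spec))
clean  <- preprocess(series)                  # 0.01 Hz low-pass + detrend
animal_metrics(clean)
#>  channel dominant_frequency_hz period_min regularity_pct
#>    oxCCO              0.002083          8          1.643
#>      HbT              0.002083          8          1.536
#>   HbDiff              0.002083          8          1.528
#>   pooled              0.002083          8          1.569
```

The 1/480 Hz ground truth is recovered exactly (period 8 min). Semblance at
the dominant frequency shows the young-C57 phenotype — HHb, HbO₂ and HbT in
phase with mitochondrial oscillations, HbDiff in antiphase:

```r
f0 <- 1 / 480
animal_semblance_panel(clean, f0)[, 1:3]
#>          pair at_frequency_hz mean_semblance
#>     HHb-oxCCO         0.00208              1
#>    HbO2-oxCCO         0.00208              1
#>     HbT-oxCCO         0.00208              1
#>  HbDiff-oxCCO         0.00208             -1
```

A full four-cohort run at the default cohort sizes (4/7/4/9 animals) takes about
a minute and writes tidy tables plus a provenance manifest:

```r
cfg <- run_config(mode = "synthetic", output_dir = "demo", seed = 1)
res <- run_pipeline(cfg)
subset(res$group_summary, metric == "period_min")[, 1:5]
#>      metric     group n  mean     se
#>  period_min   old_C57 7 14.37 0.2188
#>  period_min   old_CFH 9 15.73 0.4073
#>  period_min young_C57 4  7.93 0.0468
#>  period_min young_CFH 4 16.01 0.8198
subset(res$group_pvalues, metric == "period_min" &
       group2 == "young_C57")[, c(2, 3, 5, 7)]
#>   group1    group2 p_value signif
#>  old_C57 young_C57 0.00606      *
#>  old_CFH young_C57 0.00280     **
```

Young C57 cohorts separate cleanly from the older and knockout groups in
period, regularity and phase coupling, with the rank-sum contrasts computed
on the exact enumeration path at these sample sizes.

A thin command-line wrapper with `simulate`, `unmix`, `analyze`, `group` and
`run` subcommands is installed at `inst/cli/retiwave.R`.

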