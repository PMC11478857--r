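# sonoyeast

Non-invasive ultrasonic characterization of yeast suspensions for
bioprocess monitoring.

In industrial fermentations the biomass (dispersed yeast cells) and the
composition of the liquid phase both need continuous monitoring, but most
established methods (turbidity, cytometry, hemocytometry) are invasive,
dilution-limited, or offline. Pulse-echo ultrasound measures two
complementary quantities in real time through the vessel wall: the
**attenuation coefficient** α (Np/m), which responds to the dispersed solid
phase (cell concentration, cell diameter, volume density), and the
**speed of sound** c (m/s), which responds to dissolved substances in the
liquid phase. Over the industrially relevant concentration range
(0.0–1.0 wt% dry yeast) both increase linearly with concentration and cell
count.

`sonoyeast` implements the full measurement chain for a buffer-rod
pulse-echo cell as tested, reusable code:

* **Synthetic waveform generator** — a physics-based stand-in for the
  instrument. A tone burst travels down a Plexiglas buffer rod (diameter
  d_B = 17 mm); the buffer–sample interface reflects a first echo with
  amplitude `A1 = A0·e^(−2α_B·d_B)·R12`, and the transmitted wave crosses
  the sample (one-way path d = 37.5 mm), reflects at the Plexiglas
  reflector with a 180° phase inversion (R23 = −R12), and returns as a
  second echo `A2 = A0·e^(−2α_B·d_B)·(1−R12²)·(−R12)·e^(−2αd)` delayed by
  `TOF = 2d/c`. White Gaussian measurement noise is added at a level chosen
  to reproduce the instrument's reported precision. Strain presets
  (S. cerevisiae, WB-06, W 34/70) supply concentration→(c, α) maps,
  cell-count maps and bimodal lognormal cell-size distributions anchored to
  the study's printed values.
* **Echo processing** — extremum-based time-of-flight picking (global
  maximum M1 of the first reflection to global minimum M2 of the inverted
  second reflection), 300-sample DFT windows centered on the extrema with
  carrier-bin magnitudes A1 and A2, water-reference calibration of the
  vessel diameter `d = TOF_w·c_w(T)/2` (c_w from the fifth-order
  temperature polynomial for pure water) and of the amplitude constant
  `C0 = A1,water/R12`, and the calibrated attenuation estimator
  `α = (1/2d)·ln[−A1·(1−(A1/C0)²)/A2]`.
* **Study statistics** — concentration-gradient least-squares regressions
  (α and c against wt% and cells/mL), one-way ANOVA with Tukey–Kramer HSD
  and compact letter displays for the Ringer / suspension / filtrate
  comparison, and the volume-weighted median particle size x₅₀ from binned
  volume-density distributions.

## Worked example

Simulate and analyze a full concentration gradient (11 concentrations ×
3 replicates × 30 records) for the baker's-yeast preset:

```r
library(sonoyeast)
profile <- make_strain_profiles()$s_cerevisiae
exp1 <- run_gradient_experiment(profile, gradient_design(seed = 1))
summary(exp1)
#> Gradient experiment, strain S. cerevisiae
#> <us_calibration> d = 37.5002 mm, C0 = 0.11876, R12(ref) = -0.3715, T = 20.0 degC (n = 30)
#> <gradient_regressions>
#>   alpha ~ wt%     : slope = 12.0006, R^2 = 1.0000
#>   alpha ~ cells/mL: slope = 5.88266e-08, R^2 = 1.0000
#>   c ~ wt%        : slope = 5.41559, R^2 = 0.9995
#>   c ~ cells/mL    : slope = 2.6547e-08, R^2 = 0.9995
#> max relative SD across samples: 0.319%
```

The water calibration recovers the 37.5 mm vessel diameter; all four
gradient regressions are linear with R² > 0.95, and the per-sample
record-to-record spread stays below the 0.40% precision budget. The phase
comparison shows that cells, not solutes, drive attenuation — the
cell-free filtrate groups with the Ringer baseline while the 1 wt%
suspension stands apart:

```r
pc <- simulate_phase_comparison(profile, seed = 7)
anova_tukey(split(pc$estimates$alpha_npm, pc$estimates$phase))
#> <us_group_comparison> one-way ANOVA p = 3.73e-22 (alpha = 0.05)
#>   filtrate           2.0009 +/- 0.0007  (n = 3)  a
#>   ringer             2.0007 +/- 0.0009  (n = 3)  a
#>   suspension        14.0016 +/- 0.0030  (n = 3)  b
#>   groups sharing no letter differ significantly (Tukey-Kramer HSD)
```

And the cell-size summary:

```r
compute_x50(generate_psd(profile))
#> [1] 5.732432
```

A file-based pipeline (`cli_simulate()` → `cli_process()` →
`cli_analyze()`, or `run_demo()` for everything at once) exposes the same
chain over a YAML experiment configuration, delimited-text waveform files
and CSV tables; `inst/scripts/sonoyeast` wraps it for the shell.

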