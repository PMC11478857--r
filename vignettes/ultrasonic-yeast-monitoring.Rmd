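---
title: "Ultrasonic pulse-echo characterization of yeast suspensions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasonic pulse-echo characterization of yeast suspensions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoyeast)
```

## The measurement principle

A single 2 MHz transducer, coupled to a Plexiglas buffer rod of diameter
$d_B$, both emits and receives. The excitation burst of amplitude $A_0$
travels down the rod; at the buffer–sample interface a fraction is
reflected back (first echo) and the rest enters the sample, crosses the
one-way path $d$, reflects off the opposing Plexiglas reflector, and
returns (second echo). With pressure reflection coefficient
$R_{12} = (Z_2 - Z_1)/(Z_2 + Z_1)$ at the buffer–sample interface
($Z = \rho c$ the acoustic impedance), the two received amplitudes are

$$A_1 = A_0\,e^{-2\alpha_B d_B}\,R_{12}, \qquad
  A_2 = A_0\,e^{-2\alpha_B d_B}\,(1 - R_{12}^2)\,R_{23}\,e^{-2\alpha d},$$

where $1 - R_{12}^2 = T_{12}T_{21}$ is the two-way transmission factor,
$\alpha_B$ and $\alpha$ are the buffer and sample attenuation coefficients
(Np/m at the carrier), and $R_{23}$ is the sample–reflector reflection
coefficient. Because buffer and reflector are the same material,
$R_{23} = -R_{12}$: the second echo is phase-inverted. An aqueous sample
has lower impedance than Plexiglas, so $R_{12} < 0$ and the *first* echo is
the inverted one.

Two observables follow:

* **Speed of sound** $c = 2d/\mathrm{TOF}$, with the time of flight
  measured from the global maximum $M_1$ of the first reflection to the
  global minimum $M_2$ of the second. The phase inversion makes these two
  extrema correspond to the same feature of the burst, so the difference is
  an unbiased TOF estimate for a symmetric burst.
* **Attenuation coefficient** from the amplitude ratio. Writing
  $C_0 = A_0 e^{-2\alpha_B d_B}$ (constant while the excitation is
  constant), $A_1 = C_0 R_{12}$ and dividing the amplitude equations gives

$$\alpha = \frac{1}{2d}\,
   \ln\!\left[\frac{-A_1\,\bigl(1 - (A_1/C_0)^2\bigr)}{A_2}\right],$$

with $A_1$ signed and $A_2$ a magnitude. This estimator
(`attenuation_from_amplitudes()`) needs no knowledge of the sample
impedance: the interface reflection is re-estimated per sample from
$A_1/C_0$. The general two-interface form without the equal-material
assumption is exposed as `attenuation_general()` and used as a brute-force
oracle in the tests.

**Sign convention.** Spectral amplitudes are extracted as DFT magnitudes
and are therefore positive, but the logarithm above requires the sign of
$A_1$. Internally $A_1$ carries the sign of the reference reflection
coefficient ($-|A_1|$ for an aqueous sample against Plexiglas). This is the
unique convention under which the estimator's log argument is positive; a
non-positive argument is treated as a calibration/sign failure and raises
an error rather than returning `NaN`.

## Calibration

Both constants of the cell come from a water reference at a known
temperature (20 °C in the study design):

* $d = \overline{\mathrm{TOF}}_w \, c_w(T)/2$, with $c_w(T)$ the
  fifth-order polynomial for the speed of sound in pure water
  (`marczak_polynomial()`, valid 0–95 °C; coefficients transcribed from the
  primary literature since only the polynomial's existence, not its
  coefficients, is quoted in typical instrument descriptions). At 20 °C it
  gives 1482.38 m/s.
* $C_0 = A_{1,w}/R_{12,w}$ with $R_{12,w}$ computed from the known
  material constants (Plexiglas: 1170 kg/m³, 2760 m/s; water: 998.2 kg/m³
  from standard tables). Neither $A_0$ nor $\alpha_B$ is needed — only
  their product enters, and the pipeline is provably invariant to trading
  one against the other (a property test varies both at fixed product).
  The default $\alpha_B = 25$ Np/m is an order-of-magnitude figure for
  PMMA at 2 MHz and is documented as **unvalidated**; nothing downstream
  depends on it.

## The synthetic waveform generator

`simulate_record()` renders the two-echo record directly from the model
above: a 4-cycle sine tone burst at 2 MHz, delayed by the buffer round
trip $2 d_B / c_{\text{plexi}} \approx 12.3\ \mu s$, a second copy delayed
by the sample TOF ($\approx 50\ \mu s$), scaled and sign-flipped per the
amplitude equations, plus additive white Gaussian noise with standard
deviation `noise_sd` × (first-echo peak). Records span the second echo
plus a 10% margin.

Deliberate simplifications — the generator emulates the *signal structure*
the analysis assumes, not the transducer physics:

* no transducer impulse response or ringing; the "four-cycle square
  excitation" of the physical instrument is modeled as a tone burst with a
  Gaussian envelope (see below);
* no third or higher reverberations;
* no frequency-dependent attenuation or dispersion (narrowband treatment
  at the 2 MHz carrier only);
* no forward scattering physics linking the particle-size distribution to
  attenuation — strain profiles prescribe $\alpha(w)$ directly;
* no temperature drift or phase jitter (the study thermostats samples to
  ±0.5 °C).

Passing tests therefore demonstrate that the *processing chain inverts the
stated echo model correctly and precisely at realistic noise*, not that
the chain is robust to transducer artifacts absent from the model.

**Envelope choice.** A truly rectangular 4-cycle burst makes every carrier
cycle an extremum of identical height, so the global-extremum TOF picker is
degenerate: under any noise the picked peak hops between cycles and the
per-record TOF jumps by whole carrier periods (0.5 µs, i.e. ~1% of TOF) —
incompatible with a sub-0.4% instrument. Real transducer bursts are
enveloped; the generator's default Gaussian envelope
($\sigma = T_{\text{burst}}/6$) gives a unique global extremum with a 7%
margin over the runner-up cycle while keeping the carrier content at
2 MHz. A rectangular envelope remains available
(`pulse_parameters(envelope = "rectangular")`) for studying exactly this
failure mode.

**Sampling rate.** The default is 100 MHz (50 samples per carrier cycle),
which keeps a full record at ~7,100 samples and a full 990-record gradient
dataset at a few seconds of compute; the instrument's 1 GHz is available
via `pulse_parameters(sampling_rate = 1e9)`. TOF quantization is one
sample period, so speed-of-sound tolerances are stated in sample periods:
at 100 MHz one period corresponds to ~0.3 m/s, at 1 GHz to ~0.03 m/s.
Analyses that need 0.1 m/s absolute accuracy (the 1 wt% speed-of-sound
recovery) run at 1 GHz, matching the physical instrument.

**Noise level.** The default `noise_relative_sd = 0.001` was set by error
propagation before any end-to-end run: a relative per-sample amplitude
error $\epsilon$ on the DFT magnitudes propagates into
$\sigma_\alpha \approx \sqrt{2}\,\epsilon_A/(2d)$, and with the 300-sample
carrier-bin averaging, $\epsilon_A \approx 0.27\,\cdot$`noise_sd`. At the
Ringer-baseline attenuation (2 Np/m, the smallest along the gradient and
hence the worst relative case) this predicts a relative SD of ~0.3% over
30 records — consistent with, and within, the 0.40% maximum relative SD
the physical instrument reports. The end-to-end suite confirms 0.26–0.35%.

## Strain presets

`make_strain_profiles()` returns three presets anchored to every printed
study value: the 1 wt% S. cerevisiae speed of sound (1488.86 m/s), the
1 wt% cell-count maxima (204, 307, 152 × 10⁶ cells/mL; affine through the
origin since only the maxima are reported), and the volume-weighted median
cell diameters x₅₀ (5.73, 4.61, 5.80 µm). All remaining numbers are
**synthetic**: the Ringer baseline (water + 1.1 m/s electrolyte offset,
2 Np/m effective baseline attenuation), the α and c slopes (chosen to give
comparable 1 wt% attenuation across strains and the reported qualitative
speed ordering), and the size-mixture shapes (two lognormal components;
the top-fermenting strains carry a 10–12% volume fraction cluster mode at
20 µm, the lager strain is unimodal and narrowest). The primary-component
median is solved numerically so the mixture median equals the printed x₅₀
exactly.

## Echo processing: numerical choices

* **Search windows**: first echo in 0.5–1.5 × the expected buffer delay;
  second echo in $M_1$ + 0.5–1.5 × the expected TOF (from a nominal
  1480 m/s, covering ~990–2960 m/s). Both fully overridable, since echo
  location is instrument configuration, not physics.
* **Detrending**: records are mean-subtracted before extremum picking so
  oscilloscope DC offsets cannot bias the global extremum.
* **Noise floor**: by default 5 × the standard deviation of the pre-echo
  quiet segment; an extremum below it raises a "no echo" error instead of
  returning garbage features.
* **Windowing**: 300-sample segments centered on each extremum (150
  before, 149 after), unpadded and unwindowed; amplitudes are the DFT
  magnitudes at the bin nearest 2 MHz, normalized by 2/N. Because both
  segments are centered the same way on the same burst shape, the window
  gain cancels exactly in every ratio the estimators use. Zero-padding and
  cross-correlation TOF estimation are deliberately not implemented.
* **Ties**: `which.max`/`which.min` take the first of exactly equal
  samples; with the enveloped burst exact ties do not occur in practice.
* **Averaging order**: $c$ and $\alpha$ are computed per record and then
  averaged (never computed from averaged features), so the reported SDs
  are genuine record-to-record measurement spread. Per-record failures
  abort the sample by default; an explicit `on_error = "omit"` policy
  drops them with a warning.
* **Temperature**: a record's metadata temperature is trusted; a mismatch
  of more than 0.5 °C against the calibration temperature warns.

## Study statistics

* **Gradient regressions** are ordinary least squares on replicate means
  (three replicates collapse to one point per concentration), matching the
  mean-and-error-bar presentation of gradient figures; fitting all
  replicate points is available via `use_replicate_means = FALSE`. Whether
  published R² values used means or pooled replicates is not stated; with
  this generator both exceed 0.95 comfortably.
* **Group comparisons** use `stats::aov` + `stats::TukeyHSD`, which
  implements the Tukey–Kramer harmonic-mean form for unequal group sizes.
  The compact letter display is built by the standard insert-and-absorb
  algorithm and is property-tested against the pairwise matrix: two groups
  share a letter iff their adjusted p ≥ α.
* **Normality gate**: Shapiro–Wilk per group (normal iff p > α, the
  conventional reading); optionally excludes non-normal groups from the
  ANOVA with a warning, since the study applies ANOVA to normally
  distributed data only.
* **x₅₀** is obtained by linear interpolation of cumulative volume percent
  against log size within the straddling bin — the laser-diffraction
  convention for log-spaced grids. A distribution with all mass in one bin
  degenerates to the bin's geometric midpoint and warns.

## Problem sizes

The unit suite runs reduced designs (3 concentrations × 2 replicates ×
3 records) for speed; the end-to-end suite and the acceptance script run
the full study design (11 × 3 × 30 records per strain at 100 MHz, three
strains) in a few seconds, plus single-sample 1 GHz runs for the
deterministic speed-of-sound checks. Monte-Carlo checks of test operating
characteristics (R² coverage, Shapiro–Wilk level and power) use 100
replicates under fixed seeds.

## Known limitations

* The generator's echo model is exactly the model the estimators invert;
  recovery tests validate implementation and noise propagation, not model
  misspecification (e.g. transducer coloration, multiple scattering).
* Attenuation is narrowband; no attenuation spectroscopy.
* The α and c slopes of the presets, and everything about the filtrate
  phase except its qualitative ordering, are synthetic choices — analyses
  that depend on slope magnitudes cannot be compared against published
  figures, only against the generator's own ground truth.
* The buffer attenuation default is unvalidated (and provably irrelevant
  after calibration).
* Shapiro–Wilk with n = 3 replicate means has essentially no power; the
  gate is useful at the per-record level (n = 30), not the replicate
  level.
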