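# koopgait

Koopman spectral analysis of periodic motion via Hankel dynamic mode
decomposition (DMD), in R.

## What it is for

Walking, and periodic biological motion generally, coordinates many redundant
degrees of freedom into a low-dimensional pattern. Static decompositions
(PCA/SVD) find the pattern but not its dynamics. koopgait treats the motion
as a limit cycle of an unknown nonlinear system and estimates the spectral
objects of its Koopman operator directly from multi-channel angle recordings:

* **eigenvalues** λ_j, mapped to complex frequencies
  ω_j = ln(λ_j)/(2πΔt) — oscillation frequency (Im, Hz) and growth/decay (Re);
* **modes** ψ_j — how the channels (e.g. thigh, shank, foot elevation angles)
  combine at each frequency: the coordinative structure;
* **eigenfunctions** χ_j — complex signals whose argument is the *phase* of
  the cycle, giving a data-driven phase-reduction of the motion.

Four estimators are implemented behind one interface: exact DMD,
companion-matrix DMD, and the two Hankel (delay-embedding) variants — the
row type, whose modes are Koopman-eigenfunction sample paths (and from whose
biorthogonal duals channel-level observable modes are constructed), and the
column type, whose delay-augmented modes are de-duplicated to channel
weights. An evaluation suite (VAF, reconstruction error, DMD/Fourier
spectra, harmonic-frequency deviation, a Fourier-average eigenfunction
oracle, an SVD baseline and planar deviation) and synthetic ground-truth
generators (double pendulum, harmonic gait signals, Van der Pol, linear
systems) complete the toolkit. It is aimed at movement scientists and
dynamical-systems practitioners working with periodic multichannel
recordings.

## Worked example

```r
library(koopgait)

## a 6 s synthetic gait recording: 3 channels, 5 harmonics of 0.8 Hz,
## 100 Hz sampling, 20 dB measurement noise, cycle events attached
gait <- generate_harmonic_gait(gait_config(duration = 6, noise_sd = 0.045,
                                           seed = 1))
gait
#> <angle_series> 3 channel(s) x 601 frames, dt = 0.01 s (6 s total)
#>   channels: thigh, shank, foot
#>   events: 0, 125, 250, 375, 500

## column-type Hankel DMD at the defaults: n = one cycle, m = T, p = 50
fit <- column_type_hankel_dmd(gait, m = 125, n = 125, p = 50)
fit
#> <dmd> method = hankel-col, p = 50 mode(s), dt = 0.01 s
#>   |frequencies| [Hz]: 0.8005, 1.5967, 2.398, 3.1962, 4.0027, ...
```

The five strongest conjugate pairs sit at the five harmonics of the 0.8 Hz
gait frequency. Ranking pairs by how much variance each explains and
reconstructing one mean-centered cycle from the top three:

```r
cyc <- subtract_mean_posture(angle_series(gait$values[, 1:125], dt = 0.01,
                                          labels = gait$labels))
rk <- rank_conjugate_pairs_by_vaf(fit, cyc$values)
head(rk, 3)
#> # A tibble: 3 x 3
#>   modes     frequency_hz    vaf
#> 1 <int [2]>        0.800 0.616
#> 2 <int [2]>        1.60  0.218
#> 3 <int [2]>        2.40  0.0977

rec <- reconstruct(fit, unlist(head(rk$modes, 3)), t = 0:124)
vaf(cyc$values, rec)                   #> 0.938
reconstruction_error(cyc$values, rec)  #> 0.095  (rad)
```

The top three pairs alone account for 93.8% of the variance; the 0.095 rad
residual is the 4th/5th harmonics plus noise. Estimated frequencies deviate
from the true harmonics by about 0.1%:

```r
harmonic_deviation(fit, 0.8, 5, retain = "top-vaf", original = cyc$values)
#>   harmonic target_hz matched_hz deviation
#> 1        1       0.8      0.800  0.000569
#> 2        2       1.6      1.60   0.00206
#> 3        3       2.4      2.40   0.000830
#> 4        4       3.2      3.20   0.00119
#> 5        5       4        4.00   0.000671
```

Phase extraction uses the row type; `autoplot()` methods plot eigenvalue
spectra, spectra and angle series, and `tidy()`/`glance()` return tibbles:

```r
fit_row <- row_type_hankel_dmd(gait, p = 50)   # m, n auto from the events
phases <- eigenfunction_phase(fit_row$eigenfunctions, align = TRUE)
autoplot(fit)                                  # eigenvalues on the unit circle
tidy(fit_row)                                  # one row per mode
```

The end-to-end pipeline (`run_decompose()`) applies the preprocessing chain
(8 Hz zero-phase low-pass → cycle segmentation → mean-posture subtraction)
and writes eigenvalues/modes/spectra/eigenfunctions CSVs plus a JSON report.
A command-line front end over the same functions ships at
`inst/cli/koopgait.R`:

```sh
Rscript inst/cli/koopgait.R simulate --model gait --out angles.csv --seed 1 --noise-sd 0.045
Rscript inst/cli/koopgait.R decompose --in angles.csv --method hankel-row --outdir out/
```

A small synthetic example recording is installed at
`system.file("extdata", "synthetic-gait.csv", package = "koopgait")`.

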