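# semgfatigue

Simulation framework for assessing how reliably the two standard
myoelectric fatigue indices — the **mean frequency (MNF)** and **median
frequency (MDF)** of the surface-EMG power spectrum — can be estimated
once severe muscle fatigue has compressed the spectrum into the
low-frequency band.

During a sustained contraction the sEMG power spectral density (PSD)
shifts progressively towards low frequencies; MNF and MDF are the usual
indices for tracking that shift. On real recordings their true values are
unknown, so the only way to quantify estimator error is simulation: the
package generates synthetic fatigued sEMG with a *known* spectrum,
estimates the PSD with both of the field's workhorse approaches, and
measures how duration, noise level and estimation method drive the error.
It is intended for biomedical-signal researchers choosing an estimator
(and an AR model order) for fatigue monitoring.

## The model and the estimators

The noise-free PSD is the Stulen–De Luca band-pass shape

```
P(f) = k^2 f_h^4 f^2 / [ (f^2 + f_l^2) (f^2 + f_h^2)^2 ]
```

with `k = 1`, cut-offs `f_l = 20` Hz and `f_h = 40` Hz at `f_s = 1024` Hz
— a spectrum collapsed into the 0–60 Hz band, i.e. severe fatigue. Signals
are synthesized by colouring white Gaussian noise with a minimum-phase
shaping filter whose magnitude response is `sqrt(P(f))` (phase from the
Hilbert transform of the log-magnitude), then adding an independent white
noise realization scaled to an exact per-realization SNR.

Two PSD estimators are implemented from first principles:

* **Welch** — averaged modified periodograms: Tukey-windowed segments of
  25 % of the signal, hop 25 % of the segment (13 segments for every
  duration), each zero-padded to the full signal length,
  `I(f) = |DFT(w x)|^2 / (M U f_s)` with `U = mean(w^2)`;
* **Burg** — autoregressive lattice: each stage's reflection coefficient
  minimizes the summed forward and backward squared prediction errors,
  coefficients updated by the Levinson–Durbin step, and
  `P(f) = sigma^2 / (f_s |1 + sum_z a_z e^{-j 2 pi z f / f_s}|^2)`
  at orders 3, 4, 7, 10, 15 and 30.

Per-condition accuracy is summarised by the mean absolute error
`MAE = (1/C) sum_c |y_d - y_c|` against the analytic reference features
of `P(f)`, and analysed with a cascade of factorial ANOVAs
(three-way → two-way per SNR → one-way per duration) with Tukey HSD
post-hoc comparisons between methods.

## Worked example

```r
library(semgfatigue)

ideal_reference()        # ground-truth features of the model spectrum
#>        mnf      mdf total_power source
#> 1 40.76377 31.89088    13.95633  ideal

y <- semg_add_noise(semg_clean(1000, seed = 4), snr_db = 10, seed = 5)
spectral_features(welch_psd(y))
#>      mnf      mdf total_power source
#> 1 59.657 37.32377  0.02603056  welch

fit <- burg(y, order = 3)
fit
#> Burg AR(3) fit on 1024 samples
#> AR coefficients (x[n] = sum phi_z x[n-z] + e):
#>     ar1     ar2     ar3
#>  0.8288  0.1660 -0.1472
#> innovation variance sigma^2 = 0.006381
spectral_features(burg_psd(fit))
#>        mnf      mdf total_power source
#> 1 57.60098 28.37426  0.02524408   burg
```

At 10 dB both single-realization MNF estimates sit ~17–19 Hz above the
40.76 Hz truth — white noise adds a flat floor across the whole 0–512 Hz
band and drags the power-weighted mean up — while the MDF estimates stay
within a few Hz of the 31.89 Hz truth, which is exactly why MDF is the
more noise-robust fatigue index.

A reduced Monte-Carlo grid (100 realizations per condition):

```r
cfg <- study_config(durations_ms = c(250, 1000), snr_db = c(5, 20),
                    realizations = 100, master_seed = 1)
st <- run_grid(cfg)
s <- mae_summary(st, "mdf")
s[s$snr_db == 5 & s$duration_ms == 250, ]
#>   method duration_ms snr_db   mae   sd  bias   n
#> 1 burg10         250      5  9.85 5.60  9.76 100
#> 2 burg15         250      5  8.34 5.67  8.16 100
#> 3  burg3         250      5  5.55 4.97  3.54 100
#> 4 burg30         250      5  8.81 6.42  8.17 100
#> 5  burg4         250      5  7.81 6.16  6.74 100
#> 6  burg7         250      5 10.44 6.18 10.31 100
#> 7  welch         250      5 10.85 6.83 10.74 100
```

Even at 5 dB and 250 ms the best method (Burg order 3) keeps the MDF
error near 5 Hz; `anova_cascade(st, "mdf_err")` runs the factorial ANOVA
cascade and attaches Tukey HSD method comparisons wherever the method
effect is significant. The full-protocol study (8 durations x 4 SNRs x
7 methods x 1000 realizations) is `run_grid(study_config())`, or from a
shell:

```sh
Rscript exec/semgstudy.R study --outdir out --seed 1
Rscript exec/semgstudy.R report --outdir out
```

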