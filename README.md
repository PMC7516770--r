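# disentropy

Dispersion entropy with robust variants for physiological time-series that
contain missing and outlier samples.

## The problem

Entropy estimators are widely used to quantify the irregularity of
physiological signals — beat-to-beat (RR) interval series, EEG channels,
respiratory impedance traces — in settings from wearables to intensive-care
monitoring. Real recordings from those settings are rarely clean: sensor
drop-outs leave gaps, and movement or interference injects out-of-range
spikes. Dispersion entropy (DisEn) is attractive in this space because it is
fast and works on short windows, but the plain algorithm has no notion of a
missing sample, and even a handful of large outliers collapses its class
allocation and drags the estimate far from the truth.

`disentropy` is for signal-processing researchers and monitoring-pipeline
engineers who need DisEn estimates that degrade gracefully under exactly that
kind of contamination, plus the machinery to measure how much any given
contamination level costs.

## The estimator

For a series *x₁ … x_N*, DisEn is computed as:

1. standardise with a location μ and scale σ and map through the log-sigmoid
   *y_j = 1 / (1 + exp(−(x_j − μ)/σ))*;
2. allocate each *y_j* to one of *c* classes, *u_j = round(c·y_j + 0.5)*;
3. form every delay-embedded dispersion pattern
   *(u_i, u_{i+d}, …, u_{i+(m−1)d})* — there are *cᵐ* possible patterns;
4. DisEn = Shannon entropy (nats) of the empirical pattern distribution,
   bounded by *m·ln c*.

Defaults are *m* = 2, *c* = 6, *d* = 1 on 360-sample windows.

Four variants handle contaminated input:

| Variant | Idea |
|---|---|
| `skip_disen` | drop missing samples, concatenate the rest |
| `lininter_disen` | fill gaps by two-point linear interpolation |
| `altmet_disen` | skip, with median / 1.4826·MAD replacing mean / SD |
| `dynskip_disen` | discard samples beyond `cutoff` SDs from the segment mean (default 0.7), then skip |

The package also ships the contamination simulator (mark or overwrite a
percentage *P* of *G*-sample groups; outliers drawn from
Normal(4·max|x|, 0.5) with balanced signs), the windowed ground-truth
evaluation harness (absolute percentage deviation per window, pooled mean ±
SD per setup), a KS + Mann-Whitney comparison layer, synthetic surrogate
families spanning the relevant spectral shapes, and a CLI.

## Worked example

```r
library(disentropy)

# a 10-window low-frequency surrogate (respiratory-impedance-like)
ri <- generate_surrogate("lowfreq_sine_plus_noise", 3600, seed = 42)

# contaminate: 30% of 3-sample groups marked missing
d <- disrupt_series(ri, "missing", P = 30, G = 3, seed = 7)
sum(d$missing)
#> [1] 1080

# score two repair strategies against the clean per-window ground truth
grid  <- window_series(3600)
truth <- ground_truth(ri, grid)
for (v in c("skip", "lininter")) {
  s <- summarize_setup(evaluate_variant(ri, d, v, grid, truth = truth))
  cat(sprintf("%-8s mean |dev| = %5.2f%%  (SD %5.2f%%, %d windows)\n",
              v, s$mean, s$sd, s$n_ok))
}
#> skip     mean |dev| =  4.05%  (SD  4.65%, 10 windows)
#> lininter mean |dev| =  2.35%  (SD  1.74%, 10 windows)

# outliers hurt far more than gaps: original vs cutoff-filtered variant,
# on a broadband (EEG-like) surrogate with 10% outlier segments
eeg    <- generate_surrogate("broadband", 3600, seed = 42)
truth2 <- ground_truth(eeg, grid)
o <- disrupt_series(eeg, "outlier", P = 10, G = 1, seed = 7)
for (v in c("original", "dynskip")) {
  s <- summarize_setup(evaluate_variant(eeg, o, v, grid, truth = truth2))
  cat(sprintf("%-8s mean |dev| = %5.2f%%  (SD %5.2f%%, %d windows)\n",
              v, s$mean, s$sd, s$n_ok))
}
#> original mean |dev| = 37.03%  (SD  1.61%, 10 windows)
#> dynskip  mean |dev| =  0.63%  (SD  0.44%, 10 windows)
```

Reading the numbers: with a third of the samples gone, skipping keeps the
per-window DisEn within ~4% of the clean value and interpolation does better
still on this low-frequency signal (its gaps sit on near-linear stretches).
Ten percent outlier samples, in contrast, pull the plain estimate 37% off —
the spikes stretch the amplitude range so most classes land outside the real
signal — while the cutoff filter removes them and stays within 1%.

`run_experiment()` scales this to the full study design (5 P-levels × 5
G-levels × 10 replicates per mode, with per-setup Mann-Whitney comparisons),
and `inst/cli/disen.R` exposes the same steps as shell subcommands.

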