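---
title: "Dispersion entropy under missing and outlier samples: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersion entropy under missing and outlier samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disentropy)
```

## The estimator

Dispersion entropy treats a univariate series as a symbol stream. The series
is standardised by a location–scale pair (mean and sample SD by default),
squashed into (0, 1) by the log-sigmoid
$y_j = 1/(1 + e^{-(x_j-\mu)/\sigma})$, quantised into $c$ integer classes
$u_j = \mathrm{round}(c\,y_j + 0.5)$, and embedded into dispersion patterns
$(u_i, u_{i+d}, \dots, u_{i+(m-1)d})$. DisEn is the Shannon entropy, in nats,
of the empirical pattern distribution. A single recurring pattern gives 0; if
all $c^m$ patterns occur equally often the value is the maximum $m \ln c$.
The mapping standardises by location and scale, so DisEn is exactly invariant
under $x \mapsto a x + b$, $a > 0$.

Assumptions worth keeping in mind: the estimator is a plug-in entropy on at
most $c^m$ cells, so windows should comfortably exceed $c^m$ embedded vectors
(360 samples against 36 cells at the defaults); and the mapping statistics
are estimated *per analysed segment*, which is what makes the estimator
usable in streaming windows but also what outliers attack.

## Parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `m` (embedding dimension) | samples | 2 | pattern length; $c^m$ must stay small relative to the window |
| `c` (classes) | — | 6 | amplitude resolution vs. cell occupancy trade-off |
| `d` (time delay) | samples | 1 | stride between pattern elements |
| `mapping` | — | `logsig` | the one mapping shipped; the argument is an enum so further mappings can be added |
| `cutoff` | SD multiples | 0.7 | `dynskip_disen` only; see below |
| window length | samples | 360 | deliberately short, to stress small-sample behaviour |

The cutoff deserves a note. `dynskip_disen` computes the mean and SD of the
raw segment *with outliers included*; large spikes inflate that SD, and
values nearer the physiological range are the likeliest to sneak under the
threshold, so a strict cutoff (0.7 SD) is the default. If outliers have
already been mostly removed upstream, a laxer 1–2 SD keeps more valid
samples and is preferable.

## The variants

* `skip_disen` removes missing samples and concatenates the remainder in
  order. Location, scale and patterns are all computed on the retained
  samples, so on a complete series it is bit-identical to the original.
* `lininter_disen` restores the original length by filling each gap from the
  two nearest available neighbours,
  $y(x) = \frac{y_0 (x_1 - x) + y_1 (x - x_0)}{x_1 - x_0}$. A gap touching
  either end of the segment has one neighbour only and is filled by
  nearest-value extension — constant, not extrapolated, so no slope is
  invented from a single point. Gaps lying inside linear stretches of the
  signal are recovered exactly.
* `altmet_disen` is `skip_disen` with the robust pair (median,
  1.4826 × MAD) as mapping statistics. The scale factor makes the MAD
  consistent for the SD under normality (`stats::mad`'s default). Even on
  clean data it deviates slightly from the original — two different
  finite-sample estimators — which is why the harness measures that baseline
  deviation separately (`altmet_baseline_deviation`).
* `dynskip_disen` discards, before anything else, every sample deviating
  more than `cutoff` SDs from the raw-segment mean, then proceeds skip-style
  with the mapping statistics recomputed on the survivors.

Two orderings inside `dynskip_disen` were genuinely open. First, whether the
mapping statistics should be recomputed after removal or reuse the
raw-segment values: we recompute, because the purpose of the filter is to
restore an uncontaminated amplitude range before class allocation; the
choice is isolated in one place. Second, whether the missing mask or the
cutoff filter applies first: missing samples are removed first, so the filter
statistics are estimated from the available samples only. Honouring the mask
at all is an extension — it lets the variant run on jointly gapped and
spiky data — and costs nothing when the mask is empty.

## Degenerate inputs and numerical conventions

* **Class rounding.** `round(c·y + 0.5)` rounds ties half away from zero
  (implemented as `floor(z + 0.5)`, exact for the positive arguments that
  occur), then clips to $[1, c]$. The tie at $y = 0.5$ therefore maps to
  class $c/2 + 1$ for even $c$, deterministically.
* **SD denominator** is $n - 1$ everywhere (R's `sd`), documented so results
  reproduce bit-for-bit.
* **Constant (zero-scale) segments** admit exactly one pattern; the analytic
  entropy limit is 0, and that is what is returned, with a
  `degenerate = TRUE` flag instead of a division by zero. The same
  convention applies when the scaled MAD collapses on a majority-constant
  window (where the mean/SD path would not collapse) — flagged rather than
  silently computed, since a zero robust scale means the class allocation is
  undefined, not that the data are regular.
* **Minimum length.** Any variant needs at least $(m-1)d + 2$ retained
  samples; below that there is no meaningful frequency estimate and a
  `disen_too_short` condition is raised. The evaluation harness records such
  windows as `failed` and excludes them from means while counting them.
* **Zero ground truth.** Windows whose clean DisEn is 0 make the percentage
  deviation undefined; they are flagged `undefined_truth`, excluded, counted.
* **Entropy base** is the natural logarithm; a normalised value
  $H / (m \ln c)$ is reported alongside but never used in summaries.
* **Indexing** is R-native 1-based inclusive throughout (windows, segments,
  gap bounds).

One analytic fact the test-suite leans on: for iid Gaussian input the
log-sigmoid pipeline does *not* approach the $m \ln c$ ceiling. The class
boundaries sit at $y = k/c$, i.e. at $\mathrm{logit}(k/c)$ in standardised
units, so the class occupancies are $\Phi(\mathrm{logit}(k/c))$ differences —
(0.054, 0.190, 0.256, 0.256, 0.190, 0.054) at $c = 6$ — and the large-sample
DisEn at the defaults is $2 H_1 = 3.28681$ nats, about 8% below
$\ln 36 = 3.5835$. Equiprobable classes would require mapping through the
input's own CDF. The suite asserts the 3.28681 figure against simulation at
$N = 10^5$.

## The contamination simulator

A clean series is cut into consecutive groups of $G$ samples (a short
remainder group is kept and selectable rather than silently dropped);
$\mathrm{round}(P/100 \times n_{\text{segments}})$ groups (half-up rounding —
the symmetric, reproducible choice) are drawn uniformly without replacement.
In *missing* mode the selected samples are masked; in *outlier* mode each
selected group receives one draw from $\mathcal N(4 \max |x|, 0.5)$ and one
sign — all samples of a group share both — with signs balanced half
positive, half negative (an odd count gets one fair-coin extra). The
$4\times$ factor puts outliers decisively outside the signal's range while
emulating a bounded instrument; the 0.5 SD lets them vary without re-entering
the physiological range. The default battery is 5 P-levels × 5 G-levels × 10
replicates = 250 disrupted copies per series and mode, each copy's seed
derived deterministically from the base seed and grid position.

Contamination is applied to the whole series *before* windowing, so windows
carry unequal contamination; that variance is intended — it mimics how
drop-outs actually land — and it is the main contributor to the per-window
SD of the deviation summaries.

## Evaluation harness

Ground truth is the original algorithm on each clean, non-overlapping
360-sample window. A variant is scored on the same index range of the
disrupted copy: $|{\rm observed} - {\rm truth}|/{\rm truth} \times 100$. A
(variant, P, G) cell is summarised by the mean and SD over the *pooled* set
of per-window deviations across windows, replicates and series. The
alternative reading — SD across per-series means — is available via
`sd_mode = "by_series"`; the pooled default matches the interpretation of
the SD as window-by-window fluctuation, and the two means coincide for equal
window counts.

The statistical layer standardises each cell's deviations and screens them
against the standard normal with a one-sample KS test, then compares every
unordered pair of variants within a setup by a two-sided Mann-Whitney U test
(`stats::wilcox.test`: exact below 50 observations without ties, otherwise
the tie-corrected normal approximation), flagged at a strict raw threshold
of $10^{-3}$ with no multiplicity correction. Note the KS screen is of the
Lilliefors type (parameters estimated from the data), which makes its
p-values conservative in the anti-normal direction; it is used only to
justify the switch to rank-based tests, never as a calibrated test itself.

## Synthetic surrogates: what they do and do not show

`generate_surrogate` provides, besides degenerate fixtures (constant, ramp,
piecewise-linear), three stochastic families chosen for their spectral
shape, the property that drives interpolation performance:

* `ar_highfreq` — AR(1), coefficient −0.8: power concentrated near Nyquist,
  emulating the sample-to-sample jumpiness of RR interval series;
* `broadband` — AR(1), coefficient +0.35: a broad EEG-like spectrum;
* `lowfreq_sine_plus_noise` — a 0.01 cycles/sample sinusoid with 5% noise,
  emulating low-frequency-dominated respiratory impedance.

The families are verified to order as lowfreq < broadband < highfreq in the
fraction of periodogram power above 0.25 cycles/sample. On them the harness
reproduces the qualitative study findings: skip deviation grows with P;
interpolation beats skipping on the low-frequency family and loses on the
high-frequency one; sparse outliers pull the original DisEn *below* truth
(range inflation squashes the classes); and the cutoff filter dominates the
original at every outlier setup.

What passing these tests does **not** show: the surrogates are stationary,
Gaussian-innovation processes without nonstationarity, 1/f structure,
physiological artifacts (baseline wander, clipping) or long-range
correlations, so absolute deviation levels on real recordings will differ —
on real RR/EEG/RI data the corresponding numbers are several times larger.
The tests certify mechanism and ordering, not field-performance magnitudes.

## Problem sizes

The suite and the acceptance script run on one CPU in well under a minute
each: 500 random instances for the pattern oracle, $N = 10^5$ for the
large-sample checks, and 3600-sample (10-window) surrogates with reduced
replicate counts (10 for the monotonicity check, 3–5 elsewhere) for the
qualitative battery — the mechanisms under test are window-level, so ten
windows per condition is ample to order the variants.

## Known limitations

* Only the log-sigmoid mapping ships; the enum is extensible and a CDF-type
  mapping is the natural next candidate.
* No multiscale or multivariate extensions, and no fuzzy/weighted pattern
  schemes.
* PhysioNet waveform input is out of scope; `read_series` handles the
  single-column CSV dialect, so records must be exported to CSV first.
* The full-study statistical grid (450 pairs) assumes three variants per
  mode; other variant sets simply yield $\binom{k}{2}$ pairs per setup.
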