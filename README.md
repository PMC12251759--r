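# emgswn

Electrode-shift-robust surface-EMG motion classification built around
**sliding-window normalization (SWN)** — a causal, per-channel z-score over a
trailing window — with the full surrounding pipeline: causal preprocessing, a
from-scratch CNN-LSTM sequence classifier with optional adversarial domain
adaptation, the benchmark training regimes, differential-accuracy evaluation,
nonparametric statistics, and a synthetic EMG generator with a parametric
electrode-shift model.

## The problem and the method

Myoelectric decoders degrade when the electrode array is re-donned a few
centimetres away from its training position: the shift changes per-channel
signal amplitudes and frame-level accuracy drops, unless extra data are
collected at the new position (transfer learning, multi-position training,
domain adaptation). SWN removes the amplitude dependence instead. At each
sample time *t*, with trailing-window length *L*<sub>norm</sub>,

y<sub>t</sub> = (x<sub>t</sub> − m<sub>t</sub>) / max(s<sub>t</sub>, ε),

where m<sub>t</sub> and s<sub>t</sub> are the mean and population standard
deviation over the last *L*<sub>norm</sub> samples of that channel. A z-score
is invariant to per-channel gain and offset, and a small electrode shift acts
on band-passed EMG essentially as a per-channel gain — so the classifier's
input becomes (nearly) shift-invariant, in real time, with training data from
a single electrode position and no calibration.

The robustness metric is the **differential classification accuracy**
y<sub>n,i,j</sub> = x<sub>n,i,j</sub> −
x<sup>BASELINE</sup><sub>n,j,j</sub>: cross-position accuracy minus the
same-position baseline under the same normalization. Zero means the shift
costs nothing.

## Worked example

```r
library(emgswn)

# the normalization itself
round(normalize_window(c(1, 2, 3)), 4)
#> [1] -1.2247  0.0000  1.2247

# end-to-end: synthetic 3-position benchmark (per-channel log-normal shift
# gains, sd 0.3, plus 10% neighbour crosstalk), single-position training,
# cross-position evaluation, with and without SWN
tab <- run_shift_experiment(
  seed = 1, n_subjects = 1, n_trials_per_position = 8, trial_duration = 8,
  normalizations = c("swn", "none"), strategies = "vanilla",
  norm_window = 1000, feature_window = 200, epochs = 5,
  sequence_length_s = 2, batch_size = 2)
summarize_shift_experiment(tab)
#> # A tibble: 2 × 3
#>   normalization strategy mean_diff
#>   <chr>         <chr>        <dbl>
#> 1 none          vanilla  -0.0980
#> 2 swn           vanilla  -0.000811
```

Without normalization, testing at a shifted position costs this synthetic
subject 9.8 accuracy points relative to the same-position baseline; with SWN
the cost is under 0.1 points, because after normalization the shifted-position
input is (up to crosstalk) identical to the training-position input. That is
the mechanism the package exists to demonstrate; `vignettes/emgswn-methods.Rmd`
describes every model and design choice.

Other entry points: `generate_benchmark()` (synthetic data),
`preprocess_trial()` (causal chain raw → classifier frames),
`normalize_stream()` / `swn_state_update()` (batch and sample-by-sample SWN),
`build_model()` / `train_strategy()` (CNN-LSTM and the vanilla / TL / ADA /
MIX regimes), `wilcoxon_rank_sum()` / `bonferroni()` / `scheirer_ray_hare()`
(statistics), and `run_experiment()` (config-driven runs with resumable run
directories). A thin command-line front end with `simulate`, `preprocess`,
`swn`, `labels`, `train`, `evaluate`, `sweep`, `stats` and `run` subcommands
is installed at `inst/cli/emgswn`.

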