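# eegsdae

Adaptive feature extraction and directed connectivity inference for noisy
multichannel EEG.

Scalp EEG has a low signal-to-noise ratio, and noise manufactures spurious
edges in brain-connectivity analyses. `eegsdae` implements a pipeline for
analysts who want directed area-to-area connectivity from multichannel
recordings (e.g. mental-fatigue studies contrasting awake, fatigued and
sleep-deprived states):

1. **Preprocessing** — zero-phase Butterworth band-pass + notch filtering,
   and the four-neighbour surface Laplacian
   `V_C = V_CO − (V1 + V2 + V3 + V4)/4`, a spatial high-pass that reduces
   volume-conduction blur (channels without a complete symmetric neighbour
   set pass through, flagged).
2. **Feature extraction** — per brain area, a two-stage stacked denoising
   autoencoder (sigmoid encoder/decoder, masking corruption, minibatch SGD on
   squared reconstruction error) compresses the `c` channels to `n`, then `m`
   hidden series; the extracted feature is the mean of the `m` deepest
   series. Hidden sizes are chosen by maximising
   `c_f = λ·exp(−(e₁+e₂)/(2c)) + (1−λ)·Σⱼ c̄ⱼ³`
   over the admissible grid `m ≤ n < C_def`, `m < C_com`, `m·n ≤ U_def`,
   balancing reconstruction fidelity (`e₁`, `e₂`) against the cubed,
   min-max-normalised, time-summed STFT magnitudes of the feature below
   20 Hz.
3. **Feature quality** — RPFA, the ratio of the power at the dominant
   ("first primary") in-band frequency to the mean in-band power, compared
   across extractors (raw channel average, PCA baseline, autoencoder) with
   paired t-tests; bands are condition-specific (alpha+beta awake,
   delta+theta fatigue / sleep deprivation).
4. **Connectivity** — conditional Granger causality between area features:
   vector autoregression by least squares (order chosen by BIC over
   `p = 1..p_max`, AIC/BIC diagnostics returned),
   `F_{b→a|rest} = ln(var(ξ_a restricted) / Σ_aa)`, with circular-shift
   permutation p-values and an edge list at `P < α` (default 0.01).

A ground-truthed synthetic EEG generator (band-limited rhythms with known
directed lag-coupling, buried in drift and broadband noise, on a grid
montage) makes the whole pipeline testable without any external data; EDF
reading/writing is built in for real recordings.

## Worked example

One minute of synthetic four-area EEG at 120 Hz with a planted causal chain
`area1 → area2 → area3 → area4` (gain 0.6, lag 2 samples), run end to end:

```r
library(eegsdae)
out <- run_pipeline(pipeline_config(seed = 1))

out$edges
#>    from    to      F     p
#> 1 area1 area2 0.0988 0.005
#> 2 area2 area3 0.0783 0.005
#> 3 area3 area4 0.0658 0.005
```

The significant edge list is exactly the planted chain: each row gives the
Granger causality `F` (log ratio of restricted to full residual variance —
larger means the source's past improves prediction of the target more) and
its permutation p-value (0.005 is the smallest value 199 permutations can
resolve). `out$meta$chosen_n` / `chosen_m` hold the hidden sizes the c_f
grid search picked (6 and 1 here), `out$meta$var_order` the BIC-selected lag
order (19), and `out$rpfa` the in-band peak-to-mean table per area and
extractor, e.g. for area 1: original 12.91, PCA 12.95, autoencoder 10.46.

Individual stages are exported (`read_edf()`, `bandpass_notch()`,
`surface_laplacian()`, `stack_train()`, `extract_feature()`, `grid_search()`,
`rpfa()`, `fit_var()`, `conditional_gc()`, `significance()`, ...), and a thin
command-line wrapper ships at `inst/scripts/eegsdae`
(`eegsdae run --config cfg.yaml --seed 1 --out artifacts/`); see
`inst/extdata/demo_config.yaml` for a small YAML configuration.

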