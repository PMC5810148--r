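# senseDynamics

Most eukaryotic genes are transcribed on both strands: a sizeable fraction of
yeast and human genes carry an antisense transcription start site (asTSS)
inside the gene body, close to the sense promoter. `senseDynamics` provides
the quantitative machinery for asking what that antisense transcription does
to the *dynamics* of the sense transcript — its initiation, nuclear
processing and cytoplasmic turnover — even when steady-state transcript
levels do not change. It is aimed at groups combining single-molecule
RNA-FISH, transcriptional shutdown time courses and genome-wide TSS /
chromatin data.

## The model

A gene promoter switches stochastically between an inactive and an active
state with activation rate α and inactivation rate β (min⁻¹). While active,
transcripts initiate at rate γ, so the **mean production rate** is

    r = α γ / (α + β)

Each transcript then traverses N sequential exponential sub-steps of rate k
(RNAPII elongation plus export, pooled), so the initiation-to-export time is
Gamma(N, k) with mean N/k; the transcript counts as *nuclear* throughout
(nascent and post-release nuclear transcripts are not distinguished). In the
cytoplasm it decays at rate δ, with half-life t½ = ln 2 / δ.

Fitting proceeds in two stages from per-cell smFISH counts: δ is measured
independently by fitting A·exp(−δt) to a shutdown time course (and
resampled from a Beta distribution over its 95% confidence interval);
candidate (α, β, γ, k) sets are drawn by Latin hypercube sampling, each
paired with a δ draw, simulated to steady state, and scored against the
observed nuclear and cytoplasmic count distributions with the two-sample
Kolmogorov–Smirnov statistic. The best-fitting sets to the *cytoplasmic*
distribution yield the density of the mean production rate; the best fits to
the *nuclear* distribution constrain the ratio r/k, through which the
production-rate density is projected to obtain the processing-rate density.
The modes of those densities are the reported rates.

The package also implements the accompanying measurement machinery:

* an automated smFISH image-quantification pipeline (background
  subtraction, 3D foci detection, knockout-calibrated intensity cutoffs,
  multi-level-Otsu 3D nuclei detection, seeded cell segmentation, and
  conversion of focus intensities to integer RNA counts per cell and
  compartment);
* sense/antisense TSS identification from tag clusters or transcript
  isoforms, positional statistics with a randomisation null, metagene
  profiles, antisense-level quintile grouping and gene-compaction scores;
* synthetic-data generators that plant known ground truth for every one of
  these inputs (count distributions, decay series, two-channel image
  stacks, and a synthetic genome with planted sTSS/asTSS geometry).

## Worked example

Simulate a population at the low-antisense operating point (production rate
0.425 min⁻¹, processing rate 2.33 min⁻¹, half-life 13.53 min), then infer
the rates back from the counts:

```r
library(senseDynamics)

truth <- model_params(alpha = 0.1, beta = 0.1, gamma = 0.85,
                      n_steps = 30, k = 2.33, delta = log(2) / 13.53)
steady_state_means(truth)
#>     nuclear cytoplasmic
#>    5.472103    8.295857

obs <- gen_fish_counts(truth, n_cells = 2000, seed = 11)$counts
dec <- gen_decay(truth$delta, seed = 12)          # 9 noisy shutdown series
dfit <- fit_exponential(dec$mean_timecourse)
dfit
#> Exponential decay fit
#>   degradation rate: 0.051502 1/min  (95% CI 0.051162 - 0.051842)
#>   half-life: 13.46 min
#>   amplitude: 1.001, RMSE: 0.0009873  (linear-scale fit)

fit <- infer_rates(obs, dfit, n_lhs = 5000, sim_cells = 1000,
                   retain_k = 100, seed = 13)
coef(fit)
#>  production_rate  processing_rate degradation_rate
#>       0.42496506       2.52527811       0.05150244
```

The inferred production-rate mode (0.425 min⁻¹) and processing-rate mode
(2.53 min⁻¹) recover the generating values (0.425 and 2.33) from counts
alone; `plot(fit)` shows the two densities. A run of this size takes about
two minutes on one CPU.

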