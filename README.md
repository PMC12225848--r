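# dtfdecode

Decoding working-memory task conditions and reaction-time classes from
**directed brain connectivity**: an R implementation of the full analysis
chain

> multichannel trial epochs → per-trial MVAR model → directed transfer
> function (DTF) → band-averaged connectivity matrix → proportional
> thresholding → nine directed-graph metrics averaged over three regions
> (27 features) → ReliefF + linear SVM under 100× 80/20 subsampling →
> permutation nulls and binomial selection-frequency significance,

together with a synthetic multi-subject cohort generator with *planted*,
condition-dependent directed couplings, so the whole pipeline is testable
end to end without any recorded data.

Intended users: anyone analysing trial-epoched intracranial/EEG-like
recordings with region labels (here MTL / PFC / OFC) who wants directed,
frequency-resolved connectivity features and a leak-free decoding protocol
with honest significance statistics.

## The model in brief

A trial's channels×samples matrix $X(t)$ is fitted (OLS, order by
Schwarz's Bayesian criterion) as
$X(t) = \sum_{m=1}^p A(m) X(t-m) + E(t)$. With
$\bar A(f) = I - \sum_m A(m) e^{-i 2\pi f m / f_s}$ and
$H(f) = \bar A(f)^{-1}$, the squared DTF

$$\mathrm{DTF}^2_{j \to i}(f) = |H_{ij}(f)|^2 \Big/ \sum_m |H_{im}(f)|^2$$

measures the directed influence of channel $j$ on channel $i$; rows sum to
1 at every frequency. Band matrices (theta 4–8, alpha 8–12, beta 12–30,
low-gamma 30–80, high-gamma 80–200 Hz; half-open bins) are proportionally
thresholded to a fixed edge density, and per-node degree / strength
(in/out/total), clustering, betweenness and eigenvector centrality are
averaged within each region: 27 features per trial. Features selected in
$\ge k$ of 100 subsampling repetitions are significant under an exact
binomial criterion ($k = 43$ at $n{=}100$, $p{=}1/3$, $\alpha{=}0.05$ in
the replication convention; the literal exact-tail inversion gives 42 —
both are provided).

## Worked example

One synthetic subject, 40 identity + 40 spatial trials, with one planted
theta-band coupling MTL→PFC active only in spatial trials:

```r
library(dtfdecode)
spec <- cohort_spec(n_subjects = 1,
                    channels_per_region = c(MTL = 2, PFC = 2, OFC = 2),
                    trials_per_condition = 40, trial_sd = 0,
                    conditions = c("identity", "spatial"),
                    accuracy = 1, seed = 1)
cohort <- generate_cohort(spec)
feats  <- cohort_features(cohort, bands = "theta", pth = 0.2)
run    <- run_decoding(feats, feats$condition,
                       decoding_config(n_repeats = 100, seed = 1))
run
head(sort(run$selection_counts, decreasing = TRUE), 5)
sig <- flag_significant_features(run$selection_counts)
attr(sig, "critical_k")
pt <- permutation_test(feats, feats$condition,
                       decoding_config(n_repeats = 100, seed = 1),
                       n_shuffles = 100, r_perm = 10, observed = run)
pt$p_value
```

Output (printed by the code above):

```
Decoding run: 100 repeats, mean accuracy 0.804
  PFC.out_degree  PFC.in_strength    PFC.in_degree   OFC.out_degree PFC.out_strength
             100              100               98               98               97
critical count: 43
permutation p = 0.010 (null mean 0.498)
```

Reading this: the spatial-vs-identity contrast decodes at 80% (chance 50%;
the permutation null sits at 0.498 and the empirical permutation p is the
smallest attainable with 100 shuffles). The most frequently selected
features are the in/out degree and strength of the coupling's endpoint
regions — the planted MTL→PFC edge raises PFC in-degree/in-strength and
MTL out-strength in spatial trials — and features selected ≥ 43/100 times
are flagged significant under the binomial criterion.

The full pipeline (all bands × contrasts, threshold scan, RT classes,
output files + manifest) is `run_pipeline(pipeline_config(...))`, also
exposed as a CLI:

```sh
Rscript inst/cli/dtfdecode.R simulate --subjects 2 --out cohort/
Rscript inst/cli/dtfdecode.R features --input cohort/ --bands theta --pth 0.2 --out features.csv
Rscript inst/cli/dtfdecode.R decode --features features.csv --contrast spatial-vs-identity --band theta --repeats 100 --out results/
Rscript inst/cli/dtfdecode.R stats --counts results/selection_counts.csv --n 100 --p 0.3333 --out results/stats.json
```

## Layout

- `R/cohort.R` — synthetic cohort generator (AR(2) cores, planted couplings,
  RT/correctness model), stability checks
- `R/var.R` — MVAR fit + SBC order selection, transfer spectrum, DTF², band
  averaging
- `R/graph.R` — proportional thresholding, the nine node metrics, region
  aggregation
- `R/relief.R`, `R/svm.R`, `R/decoding.R` — ReliefF, linear max-margin
  classifier, subsampled decoding, threshold scan, permutation test, RT
  classes
- `R/stats.R` — binomial critical count (both conventions), Kruskal–Wallis,
  Dunn–Šidák, Wilcoxon wrappers
- `R/pipeline.R`, `R/cli.R`, `R/io.R` — orchestration, CLI, HDF5/CSV I/O
- `vignettes/directed-connectivity-decoding.Rmd` — model assumptions,
  parameter choices, generator realism and limitations
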