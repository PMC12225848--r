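---
title: "Decoding working-memory conditions from directed connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding working-memory conditions from directed connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtfdecode)
```

## The problem

Intracranial recordings during a working-memory task yield, per trial, a
multichannel time series with channels in three regions — medial temporal
lobe (MTL), lateral prefrontal cortex (PFC) and orbitofrontal cortex (OFC) —
and a label: the trial's condition (identity / spatial / temporal), its
reaction time, and whether the response was correct. The question this
package operationalizes is whether the *directed* interactions between
channels carry condition- and behaviour-specific information, and which
region × network-metric combinations carry it.

The pipeline is: per-trial MVAR/DTF effective connectivity → proportionally
thresholded directed-graph metrics averaged by region (27 features) →
Relief feature selection + linear SVM decoding under repeated 80/20
subsampling → permutation nulls and a binomial criterion on how often each
feature is selected.

## Effective connectivity: MVAR and the directed transfer function

Each trial's channels×samples matrix $X(t)$ is mean-centered per channel and
modelled as a vector autoregression

$$X(t) = \sum_{m=1}^{p} A(m)\,X(t-m) + E(t),$$

fitted by ordinary least squares at every order $1..p_{max}$ over a common
effective sample, with $p$ chosen by Schwarz's Bayesian criterion
$N\log\det\hat\Sigma(p) + k^2 p \log N$. In the frequency domain
$\bar A(f) = I - \sum_m A(m)e^{-i2\pi f m/f_s}$ and the transfer matrix is
$H(f) = \bar A(f)^{-1}$. The squared directed transfer function is the
row-normalized transfer magnitude

$$\mathrm{DTF}^2_{j\to i}(f) = \frac{|H_{ij}(f)|^2}{\sum_m |H_{im}(f)|^2},$$

so each target row sums to one at every frequency (this is asserted to
machine precision in the tests). Band connectivity is the arithmetic mean of
$\mathrm{DTF}^2(f)$ over a 1-Hz grid restricted to the band.

Numerical choices:

* **Frequency grid** 1 Hz from 1 to $f_s/2$. The narrowest band (theta,
  4–8 Hz) then contains 4 bins; finer grids change band means negligibly
  because the integrand is smooth at the damping values used.
* **Band edges are half-open** $[low, high)$, so a shared printed edge
  (8 Hz between theta and alpha) is counted once, in the upper band.
* **Sign convention** $\bar A(0) = I$, $\bar A(m\ge1) = -A(m)$; with this
  convention $H \bar A = I$ is an identity checked per grid frequency.
* **Order cap**: $p_{max}$ is reduced so that $k\,p_{max} < N/3$; a
  rank-deficient regressor (constant channel) is an error, not a warning.
* One joint MVAR is fitted over *all* channels of a trial. Inter-regional
  connectivity values are entries of this full matrix; a per-region-pair
  bivariate mode is deliberately not implemented, because bivariate DTF
  confounds direct and relayed influence.

## Graph features

Band matrices are proportionally thresholded: the $round(p_{th}\,k(k-1))$
largest off-diagonal entries are retained (ties broken by value, then source
index, then target index — deterministic across runs), giving every trial
the same edge density. On the thresholded graph nine node metrics are
computed: in/out/total degree, in/out/total strength, clustering
coefficient, betweenness centrality, and eigenvector centrality. Choices
where the published formulas are undirected:

* **Clustering** uses the binarized, symmetrized graph (Watts–Strogatz
  form); a directed triangle census is out of scope.
* **Betweenness** uses directed binary shortest paths (Brandes
  accumulation), raw (unnormalized) path-count ratios; unreachable pairs
  contribute zero.
* **Eigenvector centrality** is the Perron eigenvector of
  $(W + W^\top)/2$, entrywise non-negative, unit Euclidean norm; an empty
  graph returns zeros with a warning.

Metric values are averaged within each region, in the fixed order
(MTL, PFC, OFC) × (degree, in_degree, out_degree, strength, in_strength,
out_strength, clustering_coefficient, betweenness_centrality,
eigenvector_centrality) — 27 features per trial. All metric code is
implemented in-package and verified in the tests against independent
oracles (matrix-power path counting, shifted power iteration, neighbor
enumeration, and igraph).

## Decoding

Per repetition of a 100× random-subsampling scheme: a stratified 80/20
split; per-feature z-scoring fit on the training rows (sample sd; zero
variance maps to 0) and applied unchanged to test rows; ReliefF on the
training rows only (k = 10 neighbors, range-normalized differences,
deterministic neighbor ties); the top 9 features by Relief weight (ties to
the lower index); and an L2-regularized squared-hinge linear classifier
(cost 1) scored on the held-out rows. Stratification is a documented
deviation from a plain random split: it guarantees both classes appear in
every test set. The squared hinge is used because it is differentiable —
the optimization (BFGS) is then deterministic, which matters for exact
reproducibility of selection counts; at the near-separable problems
produced here it recovers the maximum-margin solution family of the
standard hinge.

The defaults — 9 of 27 features, ReliefF with 10 neighbors, cost 1,
stratified splits — are configurable; 9-of-27 pins the null selection
probability at exactly 1/3, which the binomial significance criterion
relies on.

### Permutation nulls

The null distribution reruns the *entire* pipeline — split, scaling,
selection, training — on label-shuffled copies. Two p-values are reported:

* `p_value` — the empirical permutation probability
  $(1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_{shuffles})$. This is
  the decision-making p-value. It is exactly valid when the null statistic
  is computed the same way as the observed one, which is why the per-shuffle
  repeat count defaults to the observed repeat count.
* `p_ranksum` — a Wilcoxon rank-sum comparison of the observed per-repeat
  accuracies against the null accuracies, kept for parity with rank-based
  reporting conventions. The per-repeat accuracies within one dataset share
  trials and are therefore dependent; the rank-sum null variance assumes
  independence, so this p-value is descriptive, not calibrated — the reason
  it is not used for decisions.

Reducing per-shuffle repeats (`r_perm`) below the observed repeat count is
supported as a speed measure; it inflates the null spread and is therefore
conservative (never anti-conservative).

### Reaction-time classes

Within each condition, RTs of correct trials are z-scored per subject
(removing between-subject speed offsets, e.g. motor constraints), pooled,
and sorted; the fastest quarter ($\lfloor N/4\rfloor$ trials) forms the
fast class, the slowest quarter the slow class, the middle half is
excluded. Pooling 272 labeled RTs therefore yields 68 + 68 = 136 classified
trials.

## Selection-frequency significance

If a feature is selected $X$ times in $n = 100$ iterations and selection
were chance-level ($p = 9/27 = 1/3$), $X \sim \mathrm{Binomial}(100, 1/3)$.
Two threshold conventions are exposed:

* `exact_tail`: the smallest $k$ with $P(X \ge k) \le \alpha$ by exact CDF
  summation — 42 at $(100, 1/3, 0.05)$, since $P(X \ge 42) = 0.0434$.
* `paper_compat`: `exact_tail + 1` = 43, the strict-exceedance reading in
  which a count is "more frequent than chance" only when it strictly
  exceeds the largest count attainable at level $\alpha$. This matches the
  threshold in published use of this criterion.

Both are exact computations; the package defaults to `paper_compat` for
replication-style reports and documents the discrepancy rather than
claiming either reading is what any particular authors computed.

## The synthetic cohort: what it emulates and what it does not

Real iEEG is not redistributable here, so every stage is exercised on a
generator with known ground truth. Each subject gets channels per region
(defaults 2/3/3 — see below), and per condition a stable MVAR generative
model: every channel carries a damped-oscillator AR(2) core
($a_1 = 2r\cos(2\pi f_0/f_s)$, $a_2 = -r^2$) at its region's node frequency
(default 6 Hz, theta), and each planted coupling adds a single off-diagonal
coefficient active only in its conditions. Trials are independent
realizations with a 500-sample burn-in; trial counts are drawn around
34/35/33 per condition (SD 3); responses are correct with probability 0.88;
RT is $base - effect\cdot[\text{coupling active}] + \mathcal N(0, sd)$,
truncated at 100 ms (defaults 800/150/150 ms — plausible magnitudes for a
two-alternative forced choice, chosen once).

Parameter choices that required judgement:

* **Sampling rate 250 Hz** (the source recordings' rate is not public
  knowledge within this package): keeps fits small; the 80–200 Hz band is
  refused, with a warning, unless $f_s \ge 400$ Hz — never silently
  truncated.
* **Channels 2/3/3 by default.** Realistic per-subject counts (≈ 4 MTL,
  12 PFC, 10 OFC) would need ≈ 5 s windows for 50 samples per channel;
  at the 600-ms analysis window they are not jointly estimable. The
  generator accepts any counts but warns below 50 samples per channel and
  errors below 10.
* **Damping 0.92, coupling gain 0.06.** Band specificity of a single
  off-diagonal coefficient comes entirely from the source's resonance: the
  coupled signature in band $b$ scales as $g^2\,|d(f_b)|^{-2}$, where $d$
  is the source's AR(2) polynomial. A large gain is visible in *every*
  band (the estimated coefficient is itself broadband information); only
  the regime $g \ll |d(f)|$ off-resonance with a sharp resonance yields a
  theta-specific effect. At these defaults theta decoding clearly exceeds
  beta on average, but a weaker beta signature remains — an inherent
  property of coefficient-level coupling, asserted accordingly (mean over
  cohorts) in the tests.

What a green test does **not** establish: the generator has no volume
conduction, no line noise or artifacts, no non-stationarity across the
trial, no epileptiform activity, and all channels share one resonance —
real-data connectivity is harder in ways these tests do not probe.

### A known estimator bias worth understanding

With 150-sample windows, per-trial MVAR coefficient noise (s.e. ≈ 0.03–0.06)
is amplified by the shared resonance inside the DTF normalization, giving
spurious off-diagonal theta-band values of ≈ 0.05–0.15 even with *no*
planted coupling, for any damping. This bias is condition-independent, so
it does not confound decoding, but absolute DTF values at short windows
should not be read as effect sizes. The generator-correctness test
("no spurious connectivity") therefore uses 2.4-s windows, where the bias
falls below 0.05; the short-window bias itself is a documented property.

## Runtime scaling in the test suite

The long acceptance suites follow the stated reductions: the planted-effect
recovery suite uses 20 single-subject cohorts (40 trials per condition,
fixed $p_{th} = 0.2$, theta band) with 100-shuffle nulls at 10 repeats per
shuffle; the type-I calibration suite uses 200 signal-free 40×27 tables
with 100 shuffles and 3 repeats for both the observed and null statistic
(exchangeable, hence calibrated). Full-scale settings (1000 shuffles,
repeats equal to 100) are the package defaults.

## Known limitations

* Only the standard DTF is implemented (no PDC, dDTF, or time-varying
  variants), matching the scope of the analysis it replicates.
* The clustering/betweenness/eigenvector directedness conventions are this
  package's documented choices; the formulas they implement are the
  undirected ones in common use.
* Within-condition fast/slow decoding on synthetic cohorts has no planted
  neural correlate (the RT model depends on condition only), so RT
  decoding is exercised structurally, not for statistical power.
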