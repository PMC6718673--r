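---
title: "Methods: calcium response quantification and twin-pair random-effects contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium response quantification and twin-pair random-effects contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindff)
```

## The scientific problem

Studies of iPSC-derived neurons from monozygotic twin pairs discordant for
schizophrenia compare stimulus-evoked calcium responses between the affected
(ST) and unaffected (HT) member of each pair. Two statistical problems
dominate such designs. First, a single-cell calcium response must be
extracted from a noisy fluorescence trace robustly enough that extrema-based
statistics are usable. Second, cells are nested within subjects and subjects
within pairs, the number of pairs is tiny (here three to five per group),
and pairs differ in their true effect — so a hierarchical model with a
between-pair variance component is needed rather than a cell-level t-test,
which would wildly overstate the effective sample size.

`twindff` implements both stages as a reusable, fully tested pipeline, plus
the companion gene-set overlap statistics used to quantify how strongly
illness-associated differentially expressed genes (DEGs) concentrate among
sex-specific genes. Because raw recordings from such studies are typically
available only on request, the package ships a synthetic-data generator that
emulates the study design with known ground truth; every downstream claim
the test suite makes is checked against that ground truth or against an
independent oracle implementation.

## Response quantification

For each recording, up to ~77 round ROIs are drawn over cell bodies, and
three additional ROIs over cell-free regions provide the background signal.
The pipeline is:

1. **Background subtraction.** The pointwise mean of the background ROIs is
   subtracted from every cell trace.
2. **Denoising.** Each trace is denoised with a level-3 Haar stationary
   (maximal-overlap) wavelet transform. Detail coefficients are
   soft-thresholded at the Donoho–Johnstone universal threshold
   $\lambda_j = \hat\sigma_j \sqrt{2\log N}$ with level-dependent rescaling:
   $\hat\sigma_j = \mathrm{median}(|W_j|)/0.6745$ estimated from each
   level's own coefficients. Scaling coefficients are never thresholded.
3. **dF\*.** The response to an agent applied at time $t_0$ is
   $dF^* = (f - f_0)/f_0$, with $f$ the maximum of the denoised trace in
   the 20 s window after $t_0$ and $f_0$ the minimum in the 50 s window
   before it. Denoising is what makes a min/max-based statistic usable at
   all; on a raw trace both extrema are dominated by noise.
4. **Classification.** KCl depolarises excitable cells only; a cell is kept
   as a neuron when its KCl response is at least 10% of its ionomycin
   response (the cutoff is configurable — only the existence of a KCl
   criterion, not its value, is standard).
5. **Calibration.** Each response is divided by the cell's ionomycin dF\*
   (a receptor-independent, per-cell maximal response), and the agonist
   responses (GABA, glutamate + glycine) are further divided by the
   ionomycin-calibrated KCl response. Algebraically the ionomycin term
   cancels from the final agonist ratio; both stages are nevertheless
   computed and reported, and the cancellation identity is asserted over
   random inputs in the test suite.

### Numerical choices

* **Transform dialect.** The stationary (undecimated) transform is used
  because it is shift invariant: the denoised extremum in a stimulus-locked
  window must not depend on where the onset falls on a dyadic grid. Noise
  is estimated per level by default; a single-level mode (`rescale =
  "single"` in `denoise_config()`) estimates $\hat\sigma$ once from the
  finest level, since both conventions are common in deployed denoisers.
* **Boundary handling.** Series are reflection-padded to a multiple of
  $2^{\text{level}}$ and trimmed after reconstruction; reflection avoids
  wrap-around artifacts near stimulus onsets close to the recording edges.
* **Window endpoints.** The post-window is half-open $(t_0, t_0+20]$ and
  the pre-window closed $[t_0-50, t_0]$; including the onset sample in the
  baseline biases $f_0$ conservatively downward.
* **Degenerate inputs.** A nonpositive $f_0$ aborts with a calibration
  error (it signals failed background subtraction); non-neurons are never
  pushed through the KCl division, whose strict positivity check applies
  to neurons.
* A small residual shrinkage bias (order $10^{-4}$ of the amplitude) is
  visible in dF\* when transients occupy most of a short recording, because
  the level medians then sit on transient tails rather than on flat
  baseline; with realistic pre-stimulus baselines the medians vanish and
  noiseless recovery is exact, which is how the closed-form check in the
  test suite is constructed.

## The two-level twin contrast

Level one pools the cells of one subject under one treatment condition:
within each subject × treatment × agent group of calibrated responses, MAD
outliers are removed (a value farther than $3 \times 1.4826 \times
\mathrm{MAD}$ from the median; if the MAD is zero the filter keeps
everything), then the group is summarised by its mean and the variance of
the mean $s^2/n$ — the whiskers of the usual pair-difference plot are the
SEs of these averages. At least two retained cells are required; the
removals are counted and reported.

Level two forms, per pair, $y_i = \bar x_{ST,i} - \bar x_{HT,i}$ with
variance $v_i$ equal to the sum of the two variances of the mean, and pools
the $y_i$ with an inverse-variance-weighted random-effects model. The
between-pair variance $\tau^2$ uses the DerSimonian–Laird moment estimator

$$\tau^2 = \max\!\left(0,\; \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),
\qquad w_i = 1/v_i,$$

with $Q$ the fixed-effect heterogeneity statistic; the pooled estimate
re-weights by $w_i^* = 1/(v_i + \tau^2)$, and the p-value is the two-sided
normal tail of $Z = \hat\delta / \mathrm{SE}$. Two-sided is the
conservative default; the test reports $Q$, $\tau^2$, $Z$, $p$ and both
levels (per-pair differences and the pool), so the standard two-level
forest-style figure can be drawn directly (`autoplot()` on the fit).

Design points that were genuinely open:

* The first-level "variance" is the variance of the *mean*, not the
  cell-level variance — fixed by the convention that the plotted whiskers
  are SEs of averages.
* Outlier removal is applied within subject × treatment × agent groups,
  the finest grouping at which the filter is well defined.
* A subject whose retained cells are all identical would get infinite
  weight; its variance is floored at $10^{-12}$ with a warning instead.
* Incomplete pairs are dropped with a warning; zero complete pairs is an
  error.
* No multiple-testing correction is applied across agents or treatments:
  contrasts are reported per stratum, as is conventional for this design.

## The synthetic cohort generator

`cohort_design()` states the simulated study conditions on the calibrated
response scale: by default 5 discordant pairs, 50 analysed cells per
subject and condition, an HT baseline response of 0.6, a true mean ST−HT
effect $\delta = 0.3$ in the pre-treatment condition and 0 post-treatment,
between-pair SD $\tau = 0.1$, and within-subject cell SD 0.2. The cohort
size and per-recording cell counts mirror the published design (three TRS
and two non-TRS pairs, up to ~77 neurons per field of view); the response
scale values are the package's own choice of a realistic regime — effects
of roughly half the baseline, pair heterogeneity a third of the effect,
cell noise two-thirds of the effect — made once and not revisited.

Two generators realise the same model. `simulate_cohort_responses()` draws
calibrated responses directly ($\delta_i \sim N(\delta, \tau^2)$ per pair,
cell noise on top) and is what the Monte-Carlo studies use — 2000-cohort
simulations at the trace level would add nothing but denoising time, since
the trace stage is validated separately. `simulate_twin_cohort()` realises
the identical draw as full fluorescence recordings: each cell's
targeted-agent transient amplitude is its intended calibrated response
times the KCl amplitude (the final calibrated ratio reduces to agonist
amplitude over KCl amplitude), so the trace pipeline must recover the same
cohort. A test asserts the two routes agree in the noise-free limit.

Traces are a difference-of-exponentials transient kernel (rise 0.5 s,
decay 4 s, normalised to unit peak *on the sampled grid*, so amplitudes
are exact rather than approximations of a continuous-time peak) on a
constant baseline plus white Gaussian noise, sampled at 2 Hz by default.
The sampling rate is a free parameter, not a claim about any particular
instrument. Aberrant cells ("outliers") are modelled by multiplying the
agonist amplitudes of a configured fraction of cells — giving the MAD
filter a concrete contamination model to remove.

What the generator does **not** emulate: indicator photophysics and
bleaching, movement artifacts, pixel-level segmentation, correlated
(non-white) noise, and non-Gaussian cell populations. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to every pathology of real recordings —
though the MAD filter and the rank-based noise estimator are, by
construction, the components that absorb mild departures.

## Operating characteristics

The test suite and `scripts/acceptance.R` recompute, at fixed seeds:

* agreement of the DerSimonian–Laird implementation with the independent
  `metafor` reference on random instances (relative error $\sim 10^{-14}$);
* type-I error of the full two-level test on 2000 null cohorts
  (5 pairs × 50 cells), which lands near the nominal 0.05;
* unbiased recovery of $\delta = 0.3$ over 500 heterogeneous cohorts;
* near-nominal CI coverage for homogeneous pairs, and the known mild
  undercoverage (~88%) of DL at $k = 5$ when $\tau^2$ dominates the
  within-pair variances — a documented property of the estimator, not a
  defect of the implementation;
* perfect reconstruction of the wavelet transform and the closed-form
  noiseless dF\*.

Problem sizes (2000/500/300 replicates, 1024-sample noise series, cohorts
of 5 × 50) were chosen so the full suite runs in a few minutes while
keeping Monte-Carlo error well below the tolerances asserted.

## DEG overlap statistics

The expression arm operates on plain DEG tables (`gene_id`, `log2fc`,
`padj`). A gene is a DEG when its adjusted p-value is strictly below 0.05
and its absolute log2 fold change is at least 1 ("at least twofold", read
inclusively). `overlap_enrichment()` counts how many of a gene list fall
in a reference set (e.g. sex-specific genes, defined as healthy male vs
female DEGs) and tests the proportion against the reference's share of the
detectable-gene universe with Fisher's exact test and Pearson's χ² (no
continuity correction by default; Yates available). The universe is always
supplied by the caller, never inferred. Because the sidedness of the
published Fisher test and the exact 2×2 margin convention are not
recoverable, both sidedness options and both margin constructions
(`ref_margin = "excluded"` / `"full"`) are exposed; on the published
counts (7 of 19 nominally significant male DEGs sex-specific, universe
2327/19,462) the two constructions give p = 0.00472 and 0.00478 — both
printing as the published 4.8 × 10⁻³.

`simulate_deg_tables()` builds tables whose counts are exact by
construction (sex-specific set size, DEG count, overlap), so the overlap
statistics can be verified by counting rather than sampling. The ranking
score `rank_score()` (log2 fold change × −log10 adjusted p) and the
fold-change conversions are included because they are part of the same
reporting arithmetic: $2^{7.94} \approx 246$ and $2^{0.379} \approx 1.30$
(a 30% change).

## Known limitations

* The DL estimator's small-$k$ undercoverage is inherited by design; with
  three to five pairs, interval estimates should be read accordingly
  (a Knapp–Hartung adjustment would be the natural extension).
* Only the Haar wavelet is implemented; the denoising recipe is specific
  to it, though the thresholding logic would transfer.
* The trace simulator's noise is white; heavy-tailed or drifting baselines
  are exercised only through the outlier filter, not generated.
* `venn_counts()` supports 2–4 sets, the practical range for these
  figures.

## A worked end-to-end run

```{r, eval = FALSE}
cfg <- run_config(seed = 1, design = cohort_design(n_pairs = 3,
                                                   cells_per_subject = 20))
out <- run_end_to_end(cfg, out_dir = "run1")
glance(out$contrasts$GABA_pre)
autoplot(out$contrasts$GABA_pre)
```

The run writes every recording (long CSV + JSON event sidecar), the
per-cell response table (TSV), one JSON per contrast with both levels, and
a manifest with the seed, configuration hash and MD5 of every output;
identical configuration and seed reproduce every file byte for byte.
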