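---
title: "Quantitative DIA phosphoproteomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative DIA phosphoproteomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosdia)
```

# The analysis problem

A two-condition DIA/SWATH phosphoproteome experiment produces a matrix of
phosphopeptide-precursor intensities (rows) across biological replicates
(columns), with substantial missingness concentrated at low abundance, plus
a matched total-proteome matrix quantified at the protein-group level. The
question is which phosphopeptides differ between the two biological states,
and — because a phosphopeptide can change either because its site is
differentially phosphorylated or simply because the carrier protein's
abundance changed — which of those differences reflect genuine signalling
events. phosdia implements the full post-acquisition chain: normalization,
filtering, imputation, moderated differential testing with permutation FDR,
proteome normalization, phosphosite classification, and term enrichment.

# The differential model

Per row, on log2 intensities, the moderated two-sample statistic is

$$ d = \frac{\bar{x}_A - \bar{x}_B}{s + s_0}, \qquad
   s = s_p\sqrt{\tfrac{1}{n_A} + \tfrac{1}{n_B}}, $$

with $s_p$ the pooled standard deviation and $s_0 \ge 0$ a constant added
to the denominator (the SAM convention). At $s_0 = 0$, $d$ is exactly the
classical pooled-variance Student statistic — this identity is an oracle
check in the test suite. A positive $s_0$ (default 0.1) prevents rows with
tiny variance but negligible fold change from dominating the ranking: with
$s_0 \neq 0$ the difference of means also plays a role in significance. A
Welch variant is available by flag; the pooled form is the default because
it is the cited software family's two-sample default.

## Permutation FDR

Significance is controlled by randomization rather than a t reference.
Sample labels are permuted (`n_permutations`, default 250) and $d$ is
recomputed per row. For a symmetric cutoff $c$ on $|d|$, the estimated FDR
is

$$ \widehat{\mathrm{FDR}}(c) =
   \frac{\frac{1}{P}\sum_{p=1}^{P} \#\{\,|d^{*}_{p}| \ge c\,\}}
        {\#\{\,|d_{\mathrm{obs}}| \ge c\,\}}, $$

and the significant set uses the smallest observed $|d|$ whose estimate is
at or below the target level (default 0.01). The scan over a symmetric
cutoff (rather than an asymmetric pair) matches the symmetric volcano
convention. Per-row p-values come from the pooled permutation distribution
of $|d^{*}|$ with the add-one convention, so they are always in $(0,1]$.

Two numerical details matter with small balanced designs:

* **Observed-split exclusion.** With 5 vs 5 samples there are only
  $\binom{10}{5} = 252$ distinct relabelings, so unrestricted draws
  reproduce the observed grouping (or its mirror image) about twice per 250
  randomizations. Such draws re-deliver the observed statistics themselves
  — not null values — and put a noisy floor of roughly $2/250$ on every
  estimated FDR, which at a 0.01 target randomly wipes out the entire
  significant set in a third of runs. phosdia therefore excludes
  relabelings equivalent to the observed grouping whenever an alternative
  split exists. All other duplicates are allowed, matching randomization
  (sampling with replacement) semantics. Explicit permutation matrices
  passed by the caller are used verbatim, including degenerate ones.
* **Untestable rows.** Rows with fewer than two observed values in either
  group are reported with a reason code and `significant = FALSE`, never
  dropped silently; the testable set defines the FDR scan.

The differential test runs on *observed* values only. Imputation is applied
exclusively where a complete matrix is structurally required — PCA and
Pearson hierarchical clustering — because imputed low-tail values would
otherwise manufacture spurious group differences. A switch in the pipeline
could force global imputation, but the default keeps the test honest.

# Preprocessing

**Normalization rows.** Precursors that passed the identification q-value
threshold in at least one sample are eligible for the normalization fit
(the "sparse" selection strategy). Where no q-values exist — synthetic
data, or exports without them — the observed/missing pattern is used as the
pass grid. An empty selection falls back to all rows with a warning rather
than dead-ending toy inputs.

**Local-regression normalization.** Assuming most precursors form a stable
unregulated background with no directional preference, each sample's
deviation from the per-row median reference is smoothed (LOESS, span 0.4 by
default) as a function of reference intensity, and the fitted bias is
subtracted from all rows of that sample. The per-row median is the
reference because the algorithm family is defined against an "average"
profile without prescribing one; the median is robust to the differential
minority. Predicted bias outside the fitted reference range is extrapolated
as a constant (the boundary fit), which keeps extreme rows from receiving
wild corrections. Normalization operates on the log2 scale; whether the
upstream software normalizes raw or log intensities is not documented, and
log scale is the natural domain of a constant-plus-intensity-dependent bias
model.

**Valid-value filter.** A row is kept iff at least 70% of all samples
jointly are observed — with 10 samples, at least 7. The joint (not
per-condition) reading follows the wording "across samples"; a `per_group`
mode exists but is off by default.

**Downshifted-normal imputation.** Per sample with observed mean $\mu$ and
standard deviation $\sigma$, missing cells are drawn from
$\mathcal{N}(\mu - 1.8\sigma,\ (0.3\sigma)^2)$. The phrase "down-shifts the
standard deviation by 1.8 times" is read as shifting the *mean* down by
$1.8\sigma$ while shrinking the width to $0.3\sigma$ — the documented
behaviour of the software that popularized this imputation. The
Monte-Carlo moment check in the test suite pins both parameters.

# Proteome normalization and regulation calls

The adjusted matrix is the per-sample log-ratio
`phospho[row, s] − proteome[group(row), s]`. This is exact arithmetic:
adding any constant to both matrices cancels. A per-sample ratio (rather
than a difference of condition-level differences) was chosen because it
preserves replicate structure, letting the same moderated test run on the
adjusted matrix. The decision rule is then:

| phospho significant | adjusted significant | protein shift ≥ 0.3 log2 | call |
|---|---|---|---|
| yes | yes | — | phospho_driven |
| yes | no | yes | abundance_driven |
| yes | no | no | mixed |
| no | — | — | none |

The 0.3 log2 threshold (≈23% change) for "the protein itself moved" is the
package's own: with 5 + 5 replicates and per-cell noise around 0.5 log2
units, the protein-level mean difference has a standard error near 0.3, so
smaller shifts are indistinguishable from noise. No numeric criterion
exists upstream for "co-occurring changes in total amount". Rows without a
proteome row are `unmatched`. The normalization is applied to *all* matched
rows, not only enriched ones — strictly more information with the same
semantics; the enriched subset is recoverable from the enrichment output.

# Phosphosite classes and motifs

Localization classes partition $[0,1] \times \{\text{motif},
\text{no motif}\}$: probability strictly above 0.75 is class I; $[0.25,
0.75]$ is class II with a matching kinase motif, class III without;
below 0.25 is reported as `ambiguous` and excluded from class fractions,
since the class definitions only cover $[0.25, 1]$. The default motif set —
proline-directed ([pS/pT]-P), basophilic (R at −3), acidophilic (D/E at +3)
— is a pluggable stand-in for a full motif library: three canonical
families that make class II reachable; any list of `kinase_motif()` objects
can replace it.

# The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs: 2
conditions × 5 replicates; 1,200 protein groups carrying ~3,100
phosphopeptide rows (1 + Poisson peptides per group); S/T/Y site
proportions 0.857/0.135/0.008; 60% of localization probabilities above
0.75; 20% of rows truly differential, of which 25% are abundance-driven;
|log2 effect| = 2 with random sign (no directional preference, matching the
normalization assumption); per-cell Gaussian noise of 0.5 log2 units.

Choices the source design does not pin down, fixed once here:

* **Intensity distribution.** Latent per-row log2 abundance is
  $\mathcal{N}(20, 2^2)$ — a log-normal intensity model, the standard
  working assumption for MS intensities; the real data's distribution is
  not documented.
* **Effect magnitude.** The absolute effect equals `effect_size_log2`
  exactly (sign random). A constant trivially has the configured mean
  |shift| and keeps ground-truth recovery sharp.
* **Missingness.** Cells are censored with probability
  $1/(1+e^{\,\text{slope}\,(x - \text{midpoint})})$ — logistic,
  monotone-decreasing in intensity (MNAR), the premise behind
  downshifted-normal imputation. Defaults midpoint 16, slope 1 give ~5%
  missing cells overall, concentrated in the low tail. MCAR and no-censoring
  switches exist for null experiments. The proteome matrix is not censored:
  total-proteome quantification of the same samples is far more complete,
  and one clean reference level per group keeps the ground truth
  interpretable.
* **Abundance-driven placement.** At most one abundance-driven row per
  protein group, so no proteome row ever receives two conflicting effects.
* **Localization-probability mixture.** `frac_class1` mass uniform on
  (0.75, 1]; the remainder split 7:1 between U(0.25, 0.75) and U(0, 0.25),
  roughly mirroring the shape of a deep phospho library's probability
  histogram.

What the generator deliberately does **not** emulate: correlated peptides
within a protein (shared peptides are independent rows), heavy-tailed or
intensity-dependent noise, batch effects, decoys, retention-time structure,
or contaminant species. Passing tests therefore demonstrate that the
statistical machinery is correct under a clean MNAR log-normal model — not
that every real-data pathology is handled.

# Enrichment

Hits are de-duplicated to protein groups before testing (a protein with
five significant phosphosites counts once). Per term the 2×2 table over the
background universe is tested with the two-sided Fisher exact test (summing
hypergeometric probabilities no larger than the observed table's); the
two-sided choice is deliberate so *under*-represented terms (enrichment
factor < 1) are detectable, which a one-sided enrichment test cannot flag.
The enrichment factor is $(k/n)/(K/N)$. Raw p-values are flagged at
α = 0.05 with no across-term correction by default, matching the reporting
convention the pipeline reproduces; Benjamini–Hochberg is one argument
away. The background is all protein groups quantified after quality
filtering — the standard choice where none is stated — and is configurable.

# Problem sizes and reproducibility

The test and acceptance simulations run at desk scale: 200 protein groups
(~500 phosphopeptide rows), 5 vs 5, 250 permutations, 20 seeds for
error-rate averages and 50 for the global-null median — sizes at which the
estimator properties of interest (FDR ≤ 0.05 observed, sensitivity ≥ 0.9,
≥ 80% abundance-driven recovery, null median 0) are already stable.
Everything stochastic takes an explicit seed; a single pipeline seed fans
out to per-stage child seeds by fixed offsets, so reruns are byte-identical
while stages stay independently reproducible.

# Known limitations

* Exactly two conditions; no time-series or multi-factor designs.
* No site-occupancy (stoichiometry) estimation — the adjusted log-ratio
  tracks relative, not absolute, phosphorylation.
* The permutation FDR is a point estimate; with 252 distinct splits its
  granularity is ~0.004, so targets much below 0.01 are not meaningful at
  this design size.
* Protein-group inference itself (from shared peptides) is upstream:
  catalogs arrive with groups assigned.
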