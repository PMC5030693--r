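---
title: "Methods: integrating paired metagenome and metatranscriptome data"
author: "metaPair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating paired metagenome and metatranscriptome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaPair)
```

# The problem

Shotgun metagenomics (DNA) measures what a microbial community *encodes*;
metatranscriptomics (RNA) measures what it *transcribes*. When both assays are
run on the same samples — for example faecal samples from mice at steady state
and at the peak of an induced colitis — the two measurements are strongly
coupled: a taxon that doubles in genomic abundance roughly doubles its
transcript output. The scientifically interesting signal is the part of the
transcriptional change that copy number does **not** explain: orthologous gene
families (NOGs) whose RNA fold change departs from what their DNA fold change
predicts. metaPair implements that integration, together with the upstream
(taxonomic and functional read assignment, normalization, differential
abundance) and downstream (enrichment, ordination, contribution) stages needed
to run it end to end.

# Read assignment

Reads arrive as 12-column tabular protein-alignment hits. Per read, hits are
filtered by a minimum bit score (default 50), a maximum e-value (default
0.01) and a *top-percent* window: only hits scoring at least
`best * (1 - tp/100)` are retained, with the best score computed **after**
the score/e-value filter. With the conventional `tp = 50`, two readings of
"top 50%" diverge wildly (retain the top half of the hit list vs. retain hits
within 50% of the best score); metaPair uses the second, which is the
MEGAN-style convention the defaults come from. The read's taxonomic
assignment is the lowest common ancestor (LCA) of the retained hits' taxa;
its functional assignment is the NOG of the highest-scoring retained hit,
ties broken by smallest subject id so that runs are reproducible across
platforms. Hits lacking a taxon mapping are ignored by the LCA but remain
eligible as NOG best hit — the two annotation channels are independent.
Genus-level counting is by projection: a read contributes to a genus only if
its LCA lies at or below that genus; reads resolved only to higher ranks are
counted to no genus. The best-hit convention can be audited with
`annotationConcordance()`, the fraction of multi-hit reads whose non-best
retained hits agree with the best hit's NOG by strict majority; reads with a
single retained hit are excluded from the denominator, and the statistic is
`NA` (not 0) when no read is eligible.

A deliberate omission: MEGAN's *min-support* filter is not replicated,
because the invocation this stage models does not state it.

# Normalization and detection

Reads-per-million uses the **library size carried in the sample metadata**
(total aligned reads) as its denominator, never the column sum — not every
aligned read is assignable to a feature, and recomputing the denominator from
assigned counts would silently inflate RPM values. The joint detection filter
keeps features whose mean RPM is strictly above 0.1 in both the DNA and the
RNA matrix (per-sample filtering is available behind a flag; the mean is the
default because detection is conventionally reported on average RPM).

Cumulative sum scaling (CSS) divides each sample's counts by the sum of its
counts up to the `p`-quantile (default `p = 0.5`, linear interpolation) of
its **positive** counts, times a scale constant (default 1000). The quantile
is taken over positive counts because sparse microbiome matrices drive
all-count quantiles to zero. The adaptive quantile selection of the original
CSS method is deliberately out of scope: a fixed, configurable `p` keeps the
stage deterministic and unit-testable. Normalized matrices are a distinct
class from count matrices so they cannot be re-normalized by accident.

Diversity uses the Shannon index in nats; rarefaction uses the exact
hypergeometric expectation of subsampled richness (no resampling), which the
test suite verifies against both `vegan::rarefy` and a 10,000-draw
Monte-Carlo oracle.

# Differential abundance

The differential stage is a moderated t-test on `log2(CSS + 1)`: per feature,
an OLS two-group fit; residual variances are shrunk towards a prior
`(d0, s0^2)` estimated across features by the standard moments fit of a
scaled F distribution (`limma::squeezeVar`); the moderated statistic is
referred to a t distribution on `d0 + (n - 2)` degrees of freedom, with BH
control across features. This is an explicit, fully specified stand-in for
the zero-inflated Gaussian of metagenomeSeq, whose exact fitter and
normalization quantile are not pinned down by the analysis this package
models; it preserves the ingredients that matter downstream (CSS scaling,
variance shrinkage, BH). The pseudocount bounds fold changes for zero cells;
the fitted group coefficient *is* the reported log2 fold change, shared by
testing and integration, rather than a separate ratio of means. Passing
`prior = list(d0 = ~0, s0sq = 1)` recovers the ordinary equal-variance
t-test exactly, which the suite uses as a limit check. Significance is
`adjusted p < 0.05`, optionally with a fold-change threshold
(`adjusted p < 0.05` and fold change `> 2` is the conventional replication
rule).

# Fold-change integration and responsive calling

Per-NOG DNA and RNA log2 fold changes (from the two assays, over the jointly
detected universe) are paired, and RNA is regressed on DNA by OLS. For each
NOG the per-observation 95% prediction interval
`yhat ± t * s * sqrt(1 + 1/n + (x0 - xbar)^2 / Sxx)` is computed at its DNA
fold change. A NOG is called *responsive* when it is (a) significantly
differential at the DNA **or** RNA level and (b) outside its prediction
interval. Two genuinely open choices are surfaced as flags rather than
resolved silently:

* **Significance rule.** The methods convention says "DNA or RNA"; the
  figure-legend convention says RNA only. `dna_or_rna` is the default;
  `rna_only` is available.
* **Direction.** Up/down is by the side of the interval (above the upper
  bound = up), which yields the symmetric up/down structure of the analysis
  being modelled; direction by the sign of the RNA fold change is available.

The band is a per-observation prediction interval, not a simultaneous band —
"95%" is taken at face value, and the suite verifies ~95% self-coverage on
simulated data. Features failing the joint detection filter never enter the
regression.

# Pre-ranked GSEA

Features are ranked by fold change (ties broken by feature id, so the order
is a pure function of the data). Walking the list, query members add
`|metric|^w / N_R` and non-members subtract `1/(N - N_hits)`; the enrichment
score is the running-sum value of maximal absolute deviation (signed). The
weight default is `w = 1` (the standard pre-ranked default; the source
analysis does not state its weighting), with `w = 0` giving the classic
Kolmogorov–Smirnov form whose running sum closes at exactly zero — asserted
in the tests. When the maximal `+x` and `-x` deviations tie exactly, the
earliest position wins, compared under a 1e-12 tolerance so floating-point
accumulation order cannot flip the call.

The null permutes set membership over rank positions (equivalently, permutes
ranks against a fixed metric vector), 1000 permutations by default. The
empirical p uses the add-one convention **against the same-sign portion of
the null**: for a positive observed score,
`p = (1 + #{null ES >= obs, null ES >= 0}) / (1 + #{null ES >= 0})`,
mirrored for negative. Comparing a signed ES against the whole null instead
would cap p near `P(ES >= 0) ≈ 0.5` and destroy uniformity under the null;
the same-sign convention is what makes the calibration test (KS uniformity
of p over random query sets) pass, and is the standard pre-ranked behaviour.
The leading edge is the query members at or before the extremum (at or after
it, for negative scores).

# Community statistics

PCA runs on feature-centred, by default unscaled normalized abundances (the
standard biplot convention; scaling is a flag, since only the function used —
not its scaling — is conventionally reported). PERMANOVA partitions pairwise
squared distances (`SS_T = Σ d²/N`, within-group sums over group sizes) into
an F-like ratio with an add-one label-permutation p; the distance defaults to
Bray–Curtis on normalized values and the implementation is cross-checked
against `vegan::adonis2` in the tests. Hypergeometric upper-tail probabilities
drive both category enrichment (with BH across categories and fold enrichment
`(k/n)/(K/N)`) and the two-set overlap statistic.

Genus-per-NOG contribution matrices column-normalize joint genus-by-NOG RNA
counts; the ">1% contribution" rule is applied only at display time
(`topContributors()`), so column sums are exactly 1 in the analysis object. A
NOG is *dominantly* expressed when its maximum genus contribution exceeds
50%. Distribution comparisons between NOG sets use the two-sample KS test on
per-NOG **maximum** contributions — the legend being modelled is ambiguous
between pooled per-genus contributions and per-NOG maxima; the maximum is the
default because it is the quantity the cumulative curves summarize, and the
raw maxima are returned so either can be plotted.

# The synthetic world

No raw data accession exists for the study this pipeline models, so the
generator *is* the test bed, and its defaults are fixed once:

| parameter | default | why |
|---|---|---|
| genera × NOGs/genus | 50 × 20 | desk-scale community; 1000 NOGs |
| base abundance | log-normal, sd 1.5 (nat. log) | abundances spanning ~3 orders of magnitude, as in real gut communities |
| samples per condition | 8 | the replication design (8 vs 8) |
| depth | 1e6 reads/sample/assay | desk-scale stand-in for tens of millions of aligned reads |
| differential genera | 20% at ±2 log2 | a strong community shift, signs split so both directions occur |
| coupling | slope 1, noise sd 0.3 log2 | strong DNA–RNA coupling (genus-level r ≥ 0.9 at these settings) |
| responsive NOGs | 5% at ±3 log2 (RNA only) | transcriptional regulation beyond copy number |
| per-sample jitter | log-normal sd 0.3, shared DNA/RNA | biological variability of the *animal*, hence shared between paired assays |

Counts are multinomial at exactly the configured depth (column sums are
exact — an invariant the tests assert), which reproduces compositionality;
biological variability enters only through the shared per-sample jitter, not
through per-feature negative-binomial dispersion, because no dispersion
estimates exist to calibrate against. The responsive offset δ is applied on
the RNA side only, interpreting "responsive" as transcription beyond
copy-number change. One seeded stream is consumed in a fixed stage order, so
one seed reproduces everything bit-for-bit.

What a green test does **not** establish: the generator has genus-private
NOGs (each NOG belongs to one genus), no shared gene families across genera,
no sequencing-error or mapping-bias model, and no zero-inflation beyond what
multinomial sampling at finite depth produces. Contribution/dominance
statistics are therefore exercised on hand-built multi-genus fixtures, and
real-data behaviour of the zero-heavy tail is outside what the suite can
certify.

# Numerical choices and degenerate inputs

* BH is implemented as the literal step-up (`min_{j>=i} p_(j)·m/j`, capped
  at 1) and tested against brute force and `p.adjust`.
* `s = 0` regressions give zero-width prediction intervals — any off-line
  point is outside, which is the correct limit.
* All-zero samples are an error in CSS (named sample), all-zero sample pairs
  are an error in Bray–Curtis, and `SS_W = 0` is signalled distinctly in
  PERMANOVA rather than returning `Inf`.
* Add-one permutation p-values throughout (GSEA and PERMANOVA), so no
  empirical p is ever exactly 0.
* Seeds are split per pipeline stage as `seed * 1000 + offset`, keeping all
  derived seeds well inside 32-bit integer range.

# A worked run

```{r, eval = FALSE}
sim <- simulatePairedCounts(communityConfig(seed = 1))
dnaRes <- fitDifferential(cssNormalize(sim$dna))
rnaRes <- fitDifferential(cssNormalize(sim$rna))
detected <- detectFilter(rpmNormalize(sim$dna), rpmNormalize(sim$rna))
pairs <- foldChangePairs(dnaRes, rnaRes, features = detected)
fit <- fitFcRegression(pairs)
calls <- classifyResponsive(pairs, fit)
table(calls$class)
```

On this default scenario the suite requires sensitivity ≥ 0.8 and a false
discovery proportion ≤ 0.2 for the planted responsive NOGs, and the
acceptance script re-runs the same pipeline end to end under a caller-chosen
seed.

# Known limitations

The differential model is a moderated t on transformed counts, not a count
model: at very low depths or extreme sparsity a zero-inflated count model
would behave differently. The LCA implementation assumes the taxonomy fits
in memory as a node table. GSEA handles one query set per call (no multi-set
FDR), matching the single-set usage it models. PERMANOVA is one-factor only,
as the design it reproduces is two-group.
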