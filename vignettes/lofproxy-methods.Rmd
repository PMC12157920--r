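---
title: "Graded loss-of-function proxy analysis: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded loss-of-function proxy analysis: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofproxy)
```

## The problem this package addresses

Complete gene knockouts in inbred mice and partial loss-of-function (LOF)
variants in outbred humans rarely produce identical phenotypes. A genetic
reference panel — a collection of recombinant inbred strains whose natural
expression of a focal gene spans a wide, heritable range — offers a middle
ground: strains in the lowest expression quartile can be treated as a graded
"partial knockdown" model and compared against a true knockout contrast.
`lofproxy` implements that comparison as a reproducible pipeline:

1. **Stratify** a strain panel by focal-gene expression into HIGH / LOW
   quartile groups.
2. **Screen** the transcriptome for genes whose expression correlates with
   the focal gene across strains (Pearson, Benjamini–Yekutieli FDR).
3. **Score gene sets** on the LOW-minus-HIGH log2 fold-change ranking with a
   weighted Kolmogorov–Smirnov running-sum enrichment statistic (preranked
   GSEA) and a hypergeometric over-representation test (ORA).
4. **Quantify transcription-factor (TF) regulatory shifts** as the change in
   each TF's correlation with a pathway-average profile between strata
   (Fisher z).
5. **Classify convergence**: which enriched pathways and which
   direction-concordant TFs are shared between the panel contrast, a
   knockout-vs-wildtype contrast, and a high-fat-diet (HFD) arm.

Every stage is exercised end-to-end on a synthetic strain-panel generator
that plants known structure, so the pipeline is testable without any
external download.

## Statistical methods

### Renormalization

Cross-platform comparison uses a single global affine map: all cells are
pooled, z-scored, and rescaled to mean 8 and standard deviation 2 (log2
units), the convention of RMA-summarised strain-panel exports. Because the
map is affine, all correlations, ranks and group contrasts are preserved
exactly; a per-gene mode exists behind `per_gene = TRUE` for exploration.
Global (not per-gene) scaling is the default because the matching published
processing is a global z-score. A constant matrix is an error.

### Probe selection

Exon-level arrays carry several probes per gene. `select_probe()`
operationalises three published criteria: discard probes flagged for
cross-hybridization; require an approximately normal expression distribution
across samples (Shapiro–Wilk, default α = 0.05 — the source names no test,
so a standard omnibus normality test is used); among survivors take the
widest dynamic range (max − min, log2). If nothing passes normality the
widest-range unflagged probe is returned with a warning; if everything is
flagged, that is an error. Range ties break lexicographically by probe id so
the choice is deterministic under row reordering.

### Stratification

Samples are stably sorted ascending on the focal gene (ties by sample id).
Percentiles use `100 * (rank − 1) / (n − 1)`, the formula under which the
middle rank of a 42-strain panel reports the 49th percentile. Group sizes
are explicit parameters: the presets `"paper-chow"` (12, 12) and
`"paper-hfd"` (11, 10) encode the printed quartile group sizes for 42- and
37-sample panels verbatim, because no standard rounding rule yields 12 of
42; a fractional mode (`fraction = 0.25`, half-up rounding) covers generic
inputs.

### Correlation screen

Pearson r of each gene against the focal gene; two-sided p from
`t = r sqrt((n−2)/(1−r²))` on n − 2 df. The screen defaults to raw p < 0.05
(the convention of the genome-wide screen it reproduces), with the
BY-adjusted column always available. Zero-variance genes are flagged and
excluded *before* adjustment so the multiplicity `m` counts testable genes
only. BY is implemented from the step-up definition
`p_(i) = min_{j≥i} min(1, m c(m) p_(j) / j)`, `c(m) = Σ 1/k`; it dominates
Benjamini–Hochberg element-wise and is valid under arbitrary dependence —
appropriate here because gene-level tests share the focal vector.

### GSEA

Genes are ranked by LOW-minus-HIGH mean log2 expression (KO-minus-WT for
the knockout contrast), descending, ties by gene id. Walking the list,
set members increment the running sum by `|score|^w / Σ_hits |score|^w` and
non-members decrement by `1/(N−K)`; the enrichment score (ES) is the
maximum-magnitude deviation, sign retained. `w = 1` (default) is the
standard weighted statistic; `w = 0` is the classic unweighted KS form —
both are first-class and tested. Two numerical choices are worth recording:

* **Tie-break.** For `w = 0` a positive and a negative extremum can tie in
  magnitude exactly. The extremum reached first along the walk wins. This
  rule is the only simple one that keeps complementation antisymmetric
  (the unweighted ES of a set's complement is the negation) while agreeing
  with a plain-loop reference implementation regardless of floating-point
  accumulation order.
* **Degenerate weights.** If all hit scores are zero under `w = 1`, hits
  fall back to equal weights `1/K`.

Significance uses a gene-sampling permutation null — `n_perm` random
same-size sets from the ranked universe — rather than phenotype
permutation, because the panel arm has a single ranking and the n = 3
knockout arm could not support phenotype permutation anyway. The p-value is
the plus-one estimator over same-sign null scores,
`p = (1 + #{|null| ≥ |ES|, same sign}) / (1 + #same-sign)`, so p is never
zero at finite permutations; NES divides ES by the mean |null ES| of
matching sign. If no null shares the observed sign, p is floored at
`1/(1 + n_perm)` with a warning. Set-size bounds default to 5–500 in-universe
members (common practice; the source states none) and permutation seeds are
derived per set from the master seed, so adding a set to a collection never
changes another set's result.

### ORA

Upper-tail hypergeometric test `P(X ≥ k)` for a hit list of size n whose
overlap with a set (size K in a universe of N) is k, BY-adjusted across the
collection, with enrichment ratio `kN/(nK)`. Hits must be a subset of the
universe; sets are intersected with the universe before testing.

### TF correlation shifts

For a pathway (e.g. 81 cytoplasmic ribosomal genes) the per-sample
arithmetic mean over present members is the pathway profile; each TF's
Pearson r against that profile is computed separately within the HIGH and
the LOW stratum. The caption-level reading — correlate against the averaged
profile, not average the per-gene correlations — is implemented. The shift
is `Δr = r_low − r_high` (so a "negative shift" means the TF couples more
negatively in low-expressing strains), tested with the two-sample Fisher-z
comparison: `(atanh(r_low) − atanh(r_high)) / sqrt(1/(n_low−3) +
1/(n_high−3))`, two-sided normal p, stars at 0.05 / 0.01 / 0.001. The source
reports "significant shifts" without naming a test; Fisher z is the standard
large-sample comparison of two independent correlations and is recorded in
output metadata. It is approximate at n = 12 per stratum: the package's own
null simulation shows an empirical size of roughly 3–7% at nominal 5%,
which is the tolerance the tests assert. `|r| = 1` makes z infinite and is
an error unless `clamp = TRUE` (clamps at 1 − 1e−6).

TF differential expression uses Welch's unequal-variance t-test (the source
says only "T-tests"; Welch is the safer default), log2FC oriented
LOW − HIGH or KO − WT, BY-adjusted p reported alongside, and a direction
label (`enriched` / `depleted` / `ns`) driven by the *raw* p threshold,
matching the volcano-plot convention it reproduces. Cross-model TF overlap
intersects significant TFs from two contrasts and keeps only
direction-concordant ones.

### Convergence

Enrichment results from ≥ 2 contrasts are filtered at `alpha` on the
adjusted p and classified by exact set name: `common-all`, `common-pair:a+b`
or `unique:label`. Name identity (not member overlap) is deliberate — it is
deterministic and mirrors named-pathway comparisons. Pathways significant
with opposite NES signs in different contrasts are flagged discordant, never
silently merged. Rank concordance between two contrasts within a gene set is
the Spearman correlation of the shared members' log2FC scores.

## The synthetic world

`sim_config()` describes a planted strain panel; its defaults are fixed
once from the stated study world and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_strains` | 42 | chow-panel size |
| `focal_fold_range` | 3.22 | printed max/min focal fold difference |
| `noise_sd` | 0.5 | residual log2 SD giving realistic planted r |
| `baseline_mean`, `baseline_sd` | 8, 2 | RMA-like log2 marginals |
| modules | 81 − , 89 − , 12 − genes | ribosome-, OxPhos- and fatty-acid-like panels |
| module `beta` | `coupling_for_r(0.6, ...)` | planted gene–focal r of 0.6 |
| `ko_replicates` | 3 | knockout arm size |
| `diet_interaction` | 0.5 | HFD halves TF–pathway coupling |

The focal gene takes *evenly spaced* log2 values over the configured span,
assigned to strains in a seed-determined shuffle — even spacing makes the
fold range and quartile membership exact, so stratification tests are
deterministic. Module genes are `baseline + sign·β·(focal − mean) + ε` with
`ε ~ N(0, noise_sd²)`, which gives the closed-form planted correlation
`β·sd_f / sqrt(β²sd_f² + noise_sd²)` that recovery tests check. TF genes are
built stratum-wise by mixing the first module's standardized average profile
with independent noise at the variance ratio implied by the stratum's target
r — planting per-stratum correlation directly, with a closed-form target,
rather than through a global interaction regression. MID-stratum samples use
the mean of the two targets. Twenty TFs are planted: seven carry a
concordant negative expression shift in both arms (−2 log2 units in the
panel, −4 in the knockout), five a panel-only shift, eight are null. The
knockout shift is deliberately larger than the panel shift because a 3-vs-3
Welch test is the detection bottleneck: the planted cross-arm TF overlap is
meant to be a deterministic truth of the generated world, not a power
question (the spec-level power asymmetry between n = 3 and n = 12 groups is
tested separately at matched moderate effects). The knockout arm silences
the focal gene (panel minimum − 1 log2 unit) and shifts each module by
`ko_effect` in its *loss direction* — a negatively coupled module rises in
knockouts exactly as it does in low-expressing strains — so the panel and
knockout contrasts are concordant by construction, which is the structure
the convergence stage is meant to recover.

Randomness is organised as one master seed expanded into per-gene,
per-arm substreams (hash-derived), so adding genes, TFs or a diet arm never
perturbs columns already generated, and identical config + seed is
bit-identical.

**What the generator does not emulate:** probe-level hybridization, batch
effects, genetic linkage between strains, heavy-tailed or heteroscedastic
noise, and correlated null genes. A green recovery test therefore
establishes that the statistics recover planted linear-Gaussian structure at
realistic effect sizes — not that they are robust to microarray artefacts.

## Degenerate inputs and numerical conventions

* Correlation needs n ≥ 4 samples; stratum correlations need ≥ 4 per
  stratum; group t-tests need ≥ 2 per group.
* p-values are floored at the smallest positive double so BY input
  validation (`p ∈ (0, 1]`) is never violated by underflow.
* A gene set that covers the whole ranked universe, or misses it entirely,
  is a GSEA error (the miss decrement would divide by zero).
* All output orderings (ranked lists, overlap lists, classification tables)
  are deterministic, with lexicographic tie-breaks.

## Known limitations

The Fisher-z shift test is asymptotic and slightly anti-conservative at
quartile-sized strata; a strain-resampling bootstrap would be the natural
sensitivity analysis. The gene-sampling GSEA null ignores inter-gene
correlation, as all preranked implementations do. The convergence stage
matches pathways by name only, so the same biology split across two set
names counts as two pathways. None of the printed dataset-level numbers of
the motivating study are asserted by this package's tests — they require
the original public exports, which are deliberately out of scope.
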