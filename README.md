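# lofproxy

Graded loss-of-function proxy analysis for strain-panel transcriptomics.

## What problem this solves, and for whom

Complete knockouts in inbred mice and partial loss-of-function variants in
humans rarely phenocopy each other. When a gene's expression varies widely
and heritably across a recombinant-inbred strain panel, the strains in the
lowest expression quartile can serve as a *graded* knockdown model: compare
their muscle (or any tissue) transcriptome against the highest quartile, and
ask whether that contrast converges with a true knockout-vs-wildtype
contrast. `lofproxy` is for computational biologists who want that whole
analysis — stratification, correlation screen, enrichment, transcription
factor (TF) regulatory shifts, cross-model convergence — as one tested,
seeded, scriptable pipeline.

## The statistics at its core

* **Stratification** — samples ranked by focal-gene log2 expression;
  HIGH/LOW quartile groups (presets reproduce 12/12 of 42 and 11/10 of 37);
  percentile `100(rank−1)/(n−1)`; linear fold range `2^(max−min)`.
* **Correlation screen** — Pearson r of every gene vs the focal gene, p
  from `t = r√((n−2)/(1−r²))`, Benjamini–Yekutieli step-up FDR
  (`p₍ᵢ₎ = min_{j≥i} min(1, m·c(m)·p₍ⱼ₎/j)`, `c(m) = Σ1/k`).
* **Preranked GSEA** — genes ranked by LOW−HIGH mean log2FC; weighted
  Kolmogorov–Smirnov running sum (hits `|s|^w/Σ|s|^w`, misses `−1/(N−K)`);
  ES = signed maximal deviation; gene-sampling permutation null with a
  plus-one p estimator; NES = ES / mean |same-sign null ES|.
* **ORA** — upper-tail hypergeometric `P(X ≥ k)`, enrichment ratio
  `kN/(nK)`, BY across the collection.
* **TF correlation shifts** — per-TF Pearson r against a pathway-average
  profile within each stratum; `Δr = r_low − r_high`; two-sample Fisher-z
  test `(atanh r_low − atanh r_high)/√(1/(n_low−3)+1/(n_high−3))`; Welch
  t-tests for TF differential expression; direction-concordant overlap
  across models.
* **Convergence** — enriched pathways classified `common-all` /
  `common-pair` / `unique` across panel, knockout and diet contrasts.

A synthetic strain-panel generator (`sim_config()`, `simulate_panel()`,
`simulate_ko()`) plants focal-gene-coupled modules, stratum-dependent TF
couplings and null genes with per-gene RNG substreams, so the full pipeline
runs and is tested without any external data. See
`vignettes/lofproxy-methods.Rmd` for models, defaults and design decisions.

## Worked example

```r
library(lofproxy)

cfg   <- sim_config(n_genes = 2000, seed = 42)   # 42 strains, planted modules
panel <- simulate_panel(cfg)
m     <- panel$matrix

fold_difference(m, "FOCAL")
#> [1] 3.22

strata <- assign_strata(rank_focal(m, "FOCAL"), preset = "paper-chow")
table(strata$label)
#> HIGH  LOW  MID
#>   12   12   18

screen <- correlate_focal(m, "FOCAL")
screen_significant(screen)$count
#> [1] 297

ranked <- rank_by_log2fc(m, strata)
sets   <- truth_gene_sets(panel$truth)
gsea_collection(ranked, sets, n_perm = 500, seed = 42)[,
  c("set", "set_size", "es", "nes", "p", "p_adj")]
#>             set set_size    es  nes       p   p_adj
#> 1 cyto_ribosome       81 0.733 3.16 0.00333 0.00659
#> 2    etc_oxphos       89 0.719 3.23 0.00333 0.00659
#> 3    fatty_acid       12 0.727 1.97 0.00360 0.00659

prof   <- pathway_average(m, sets$cyto_ribosome)
shifts <- tf_shift_table(m, cfg$tf_specs$name, prof, strata)
summarize_shifts(shifts)
#> n_significant    n_negative    n_positive
#>             2             2             0

ko  <- simulate_ko(cfg, panel$truth)
km  <- ko$sample_meta
dep <- tf_differential_expression(m, stratum_samples(strata, "LOW"),
                                  stratum_samples(strata, "HIGH"),
                                  cfg$tf_specs$name)
dek <- tf_differential_expression(ko, km$sample[km$genotype == "KO"],
                                  km$sample[km$genotype == "WT"],
                                  cfg$tf_specs$name)
sig <- function(d) d[!is.na(d$direction) & d$direction != "ns", ]
overlap_tfs(sig(dep), sig(dek))
#> [1] "TF01" "TF02" "TF03" "TF04" "TF05" "TF06" "TF07"
```

Reading the output: the focal gene spans a 3.22-fold range by construction;
297 of ~2000 genes pass the raw-p correlation screen (the three planted
modules plus ~5% false positives among nulls); all three planted modules are
enriched in the LOW stratum (positive NES, BY-adjusted p < 0.01); two of the
strongly shift-planted TFs cross Fisher-z significance at n = 12 per stratum
in this draw (Δr sign is planted for seven); and the cross-model
direction-concordant overlap recovers exactly the seven TFs planted with
expression shifts in both arms.

## Command line

```sh
Rscript inst/cli/lofproxy.R simulate --out demo --seed 1
Rscript inst/cli/lofproxy.R run-all --config demo/run_config.yaml
Rscript inst/cli/lofproxy.R gsea --matrix demo/cd_matrix.tsv --focal FOCAL \
    --gmt demo/modules.gmt --out gsea.tsv --preset paper-chow
```

Subcommands: `simulate`, `run-all`, `screen`, `gsea`, `ora`, `tfshift`,
`report`. `run-all` executes the full pipeline from a YAML config and writes
TSV/JSON artifacts (strata, screen, GSEA, ORA, TF shifts, convergence
report) plus `run_info.json` with the config hash and seed; identical
config + seed reruns are bit-identical.

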