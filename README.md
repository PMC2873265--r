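# foldexpansion

Evolutionary expansion analysis of protein fold architectures across
functional categories, in R.

Protein domains fall into a finite set of structural folds, and a rooted
phylogeny of all folds assigns each fold a relative age. `foldexpansion`
turns such a phylogeny plus protein→fold census tables into:

* **ancestry values** — for fold *f* with node depth *d(f)* (internal
  nodes on the leaf→root path, minus one), *a(f) = d(f) / max d*, a
  relative-age proxy in [0, 1] with 0 the most ancient fold;
* **fold-expansion curves** — per category, the empirical CDF
  *E(θ) = |{f : a(f) ≤ θ}| / |F|* over its nonredundant fold set *F*, a
  proxy for the accumulation of structural sophistication over time;
* **area-under-curve summaries** — the exact step-function integral
  *AUC(θ) = 100·mean(max(0, θ − a(f)))*, with *AUC(1) = 100·(1 − ā)*;
* **era annotation** — boundaries *b₁* (earliest ribonucleotide-reductase
  catalytic fold: the DNA-genome transition) and *b₂* (earliest
  domain-of-life-restricted fold: the divergence of LUCA) partition
  ancestry into the RNA-protein world [0, b₁), the LUCA era [b₁, b₂), and
  the modern era [b₂, 1];
* **coverage reports** — how many of the *n* most ancestral folds a
  category contains, and the minimum ancestry per general functional
  class (phosphoryl transfer, RNA modification, RNA binding, protein
  binding, other).

A synthetic-data generator (caterpillar/random fold trees, Beta-weighted
category sampling, marker placement) makes every stage testable without
any database access.

## Worked example

Using the bundled example inputs (a 21-fold ladder phylogeny and a
three-category census):

```r
library(foldexpansion)
ext <- function(f) system.file("extdata", f, package = "foldexpansion")
cfg <- pipeline_config(census      = ext("example_census.tsv"),
                       tree        = ext("example_tree.nwk"),
                       markers     = ext("example_markers.tsv"),
                       annotations = ext("example_annotations.tsv"),
                       out_dir     = tempfile())
res <- run_pipeline(cfg, quiet = TRUE)
print(res$summary, digits = 3)
#>                category       statistic thr_0.19 thr_0.4 thr_1
#> 1 tRNA-related proteins final_expansion    37.50   75.00 100.0
#> 2 tRNA-related proteins             auc     5.15   18.16  77.0
#> 3    Ribosomal proteins final_expansion    12.50   25.00 100.0
#> 4    Ribosomal proteins             auc     1.06    6.05  46.1
#> 5        Whole proteome final_expansion    11.11   33.33 100.0
#> 6        Whole proteome             auc     1.23    6.02  42.1
res$eras
#> Era partition: RNA-protein world [0, 0.211) | LUCA era [0.211, 0.421) | modern era [0.421, 1]
res$coverage
#> $count
#> [1] 9
#>
#> $absent
#> [1] "a.4"
```

Reading: by the end of the RNA-protein world (ancestry < 0.211, the
earliest RNR-catalytic marker fold) the tRNA-related category had already
acquired 37.5% of its present-day folds versus 12.5% for ribosomal
proteins; 9 of the 10 most ancestral folds occur in the analysed
categories. `run_pipeline()` also writes `ancestry.tsv`, `summary.tsv`,
`curves.tsv`, `eras.tsv`, `report.json` and a reproducibility manifest to
`out_dir`, and `plot_expansion(res$curves, res$eras, path = "curves.png")`
draws the step curves with era markers.

A shell entry point wraps the same functions:

```sh
Rscript inst/scripts/fold-pipeline.R simulate --out-dir sim --seed 3
Rscript inst/scripts/fold-pipeline.R run --config cfg.yaml --out-dir out
```

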