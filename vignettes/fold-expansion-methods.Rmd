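---
title: "Methods: fold ancestry, expansion curves, and era annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fold ancestry, expansion curves, and era annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldexpansion)
```

## The model

Protein domains adopt a limited repertoire of structural topologies —
folds, in the SCOP sense — and a rooted phylogeny of all folds can be
built from their distribution across genomes. `foldexpansion` takes such a
phylogeny as given and asks how the fold repertoire of a *functional
category* of proteins (ribosomal proteins, tRNA-related proteins,
regulatory factors, or any reference set) accumulated over evolutionary
time.

Three quantities carry the analysis:

**Ancestry value.** For a fold $f$ with node depth $d(f)$ — the number of
internal nodes on the path from the leaf to the root, minus one, so a fold
attached directly at the root scores 0 — the ancestry value is

$$a(f) = \frac{d(f)}{\max_g d(g)} \in [0, 1],$$

a purely topological relative-age proxy: 0 is the most ancient fold, 1 the
most recent. Branch lengths are parsed and ignored. The minus-one offset
is an endpoint convention: the node count "from a fold to the root" does
not say whether either endpoint is included, and we pin the convention by
requiring the basal-most fold of a ladder-like tree to score exactly 0,
which is where the most ancient fold (the P-loop NTP hydrolase of the
translational GTPases) is observed to sit. On trees where no leaf is
adjacent to the root (e.g. a balanced quartet) the minimum ancestry is
consequently positive; real fold phylogenies are strongly ladder-like and
have a basal leaf.

**Fold expansion.** For a category with nonredundant fold set $F$ (the
deduplicated union of folds over all the category's proteins), the
expansion at threshold $\theta$ is the cumulative fraction

$$E(\theta) = \frac{|\{f \in F : a(f) \le \theta\}|}{|F|},$$

the empirical CDF of the category's ancestries — a proxy for how much of
the category's present-day structural sophistication was already in place
at relative time $\theta$. The comparison is inclusive ($\le$).

**Area under the expansion curve.** Because $E$ is a right-continuous step
function, its integral over $[0, \theta]$ has the closed form

$$\mathrm{AUC}(\theta) = \frac{100}{|F|} \sum_{f \in F} \max(0,\, \theta - a(f)),$$

expressed in percent of the unit square (ceiling $100\,\theta$). At
$\theta = 1$ this equals $100\,(1 - \bar a)$, one hundred times one minus
the mean fold ancestry — an exact identity the test suite asserts to
$10^{-12}$, alongside agreement with a midpoint Riemann sum at grid
$10^{-5}$. We interpret the area statistic as this absolute (unnormalised
by $\theta$) integral: it is the only reading under which all customary
reported values stay below their ceilings at every threshold.

## Era annotation

Two marker sets partition the ancestry axis into three eras. The first
boundary $b_1$ is the minimum ancestry over folds of
ribonucleotide-reductase catalytic domains: deoxyribonucleotide synthesis
is the enabling step for a DNA genome, so the earliest RNR fold proxies
the exit from the RNA-protein world. The second boundary $b_2$ is the
minimum ancestry over folds restricted to a single taxonomic domain of
life, proxying the divergence of LUCA. Era intervals are half-open,
$[0, b_1)$, $[b_1, b_2)$, $[b_2, 1]$: the marker fold that defines a
transition belongs to the era it inaugurates. Cumulative statistics, by
contrast, keep the inclusive $\le$; the two conventions answer different
questions (membership of a single fold versus accumulated mass up to a
point) and both are exposed as documented behaviour. Markers that
contradict the era model ($b_1 > b_2$) raise a classed inconsistency
error rather than silently reordering.

The coverage report asks how many of the $n$ most ancestral folds
(ties broken lexicographically, so ranking is deterministic) occur in a
census — by default the union over all analysed categories, since nothing
restricts ancient folds to one category. The function rollup reduces a
fold-function annotation table to the minimum ancestry per general
functional class (high-energy phosphoryl transfer, RNA modification, RNA
binding, protein binding, other), i.e. the earliest appearance of each
molecular capability.

## What the synthetic generator emulates

Real inputs for this analysis are database joins (ontology → structures →
fold assignments → ancestry values) that cannot be redistributed here, so
the package ships a generator that emulates their statistical structure:

* **Phylogeny.** `simulate_fold_tree()` produces caterpillar (fully
  ladderized) trees, whose ancestries form an even grid $i/(n-2)$, or
  random bifurcating topologies. The caterpillar is the reference shape
  because it reproduces the ladder-like character of genuine fold
  phylogenies and makes expected values computable by hand.
* **Censuses.** `simulate_census()` samples each category's folds from the
  shared ancestry table with weights proportional to a Beta($\alpha$,
  $\beta$) density evaluated at each fold's ancestry: low mean Beta shapes
  give ancient-biased, early-expanding categories. Sampling existing
  leaves (rather than drawing ancestries directly) keeps every category on
  one shared ancestry scale, as in the real design. Folds are wrapped into
  proteins of 1–3 domains (uniform; the cap is configurable) and repeated
  across proteins at a controlled redundancy, so nonredundant-set
  construction does real deduplication work.
* **Markers.** `simulate_markers()` places the RNR-catalytic and
  domain-restricted markers at the smallest ancestries at or above given
  targets, with optional higher-ancestry decoys that must not move the
  recovered boundaries.

The generator does **not** emulate: correlation between categories sharing
folds, non-uniform fold inventories, uncertainty in the tree, or
incomplete ancestry coverage (that last case is exercised separately
through the `drop_warn` join policy). Passing tests therefore demonstrate
the correctness of the computations and the recoverability of known
parameters — not the biological conclusions one would draw from real
census data.

The bundled six-category specification
(`translation_category_specs()`) fixes, once, Beta shapes whose implied
mean fold ancestries ($\alpha/(\alpha+\beta)$, hence whole-curve areas
$1-\bar a$) sit where such categories sit empirically — tRNA-related
earliest, then translation regulation, then ribosomal proteins, with the
immune-system and whole-proteome references expanding late — and census
sizes of 53/56/40/7/44/550 folds, plausible for those categories. The
design target is the qualitative rank order of early expansion, not any
particular percentage.

## Numerical and design choices

* **Degenerate trees** (single leaf or star: no depth variation) yield
  all-zero ancestries with a warning instead of an error, so toy runs do
  not abort.
* **Missing ancestries** at the census join default to `drop_warn`
  (dropped folds are recorded per category and warned about), because real
  ancestry databases cover fold inventories incompletely; `strict` is
  available when completeness is guaranteed, e.g. for synthetic runs.
* **Ties** in ancestry produce a single curve breakpoint with a multi-fold
  jump; curves are right-continuous.
* **Rounding.** Human-readable tables round percentages to one decimal;
  machine-readable TSV/JSON outputs keep six decimals or full precision,
  so downstream checks never depend on display rounding.
* **Determinism.** Every stochastic operation takes a seed and runs under
  a save/restore of the session RNG state; identical seeds give
  byte-identical artifacts, and the pipeline manifest (inputs with MD5
  checksums, full config, an FNV-1a config fingerprint, seed, versions)
  suffices to reproduce a run.
* **Problem sizes.** The test suite runs its statistical checks at sizes
  chosen so each property is sharply testable at interactive speed: 200
  random censuses of up to 100 folds for the area oracle, 500 random trees
  of up to 8 leaves for the ancestry oracle, a 101-point uniform grid for
  exact era recovery, and 20 replicates of 500 folds drawn from a
  100,001-fold grid for Beta-parameter recovery. The recovery grid is that
  dense for a structural reason: Beta(1, 9) weights concentrate on an
  effective pool of roughly one ninth of the table, and sampling 500 folds
  without replacement from too small a pool depletes the low-ancestry mass
  and biases the recovered mean — a finite-pool artifact, not a property
  of the estimator.
* **Command line.** The package's functions are the primary interface; a
  thin wrapper script (`inst/scripts/fold-pipeline.R`) exposes `run` and
  `simulate` subcommands over YAML configs for shell use. Single-step
  subcommands would each wrap one exported function call, so they are
  omitted in favour of the R API.

## Limitations

The ancestry scale is relative, not calendar time; node counts conflate
rate and time, and the endpoint convention (though pinned as described) is
not recoverable from first principles. Era boundaries inherit whatever
error the marker-fold ancestries carry. The area statistic compares
categories on a common scale but has no significance test attached — the
package deliberately reports description, not inference.
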