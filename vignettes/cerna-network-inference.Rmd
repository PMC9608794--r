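---
title: "Inferring lncRNA–mRNA ceRNA networks from shared miRNA targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA–mRNA ceRNA networks from shared miRNA targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Competing endogenous RNA (ceRNA) theory holds that transcripts sharing
miRNA response elements compete for a limited miRNA pool, so a lncRNA can
de-repress an mRNA by sponging their common miRNAs. `cernet` nominates such
lncRNA–mRNA pairs in a two-group expression study by asking, for every
differentially expressed lncRNA (DEL) × differentially expressed mRNA (DEG)
candidate, whether the two transcripts share more annotated miRNA partners
than independent targeting would produce.

The null model is sampling without replacement: with a universe of `m`
miRNAs, a lncRNA targeted by `n` of them, and an mRNA targeted by `t`, the
shared count under independence is hypergeometric, and the pair's score is
the upper tail

$$P(X \ge r) \;=\; \sum_{i=r}^{\min(n,t)} \frac{\binom{t}{i}\binom{m-t}{n-i}}{\binom{m}{n}}.$$

The model's assumptions are worth stating plainly: (i) the interaction
tables are treated as ground truth, with neither weights nor evidence
grades; (ii) targeting is exchangeable across miRNAs — no account of miRNA
families, expression levels, or binding-site multiplicity; (iii) pairs are
scored independently of each other. These are the standard assumptions of
enrichment-style ceRNA screens; the statistic ranks hypotheses, it does not
estimate effect sizes.

## Pipeline stages and the parameters that matter

1. **Preprocessing** (`quantile_normalize`, `welch_t`, `bh_adjust`,
   `filter_de`). The input matrix is log2-scale intensities. Quantile
   normalization (delegated to `limma::normalizeQuantiles`, ties averaged)
   forces all samples onto the reference distribution given by the row
   means of the column-sorted matrix. Each gene is then tested with a
   two-sided Welch unequal-variance t-test; p-values are
   Benjamini–Hochberg adjusted; a gene is kept iff `fdr < 0.05` and
   `|log2FC| > 1` (both strict, both user-settable, and a `use_raw_p`
   switch filters on unadjusted p for parity with analyses that report raw
   p). We use the plain Welch statistic rather than an empirical-Bayes
   moderated t deliberately: it is self-contained, exactly testable
   against textbook formulas, and with 10 samples per group the moderation
   matters little; results on marginal genes will differ between the two.
2. **Background** (`build_background`). The miRNA universe `m` defaults to
   the miRNAs of the miRNA–mRNA table (`mrna_db`), which mirrors defining
   `m` as the target database's miRNA complement; `union` and
   `intersection` are offered because the two public databases' universes
   differ and the handling of lncRNA-interacting miRNAs absent from the
   mRNA table is a genuine modelling choice. Target sets are clipped to
   the universe so `n ≤ m`, `t ≤ m` always holds — without clipping the
   hypergeometric is ill-defined. Entries emptied by clipping are dropped
   and counted; silent data loss is prohibited throughout.
3. **Network** (`build_network`). An edge is retained iff `p < 0.01` and
   `r > 3`. Both are strict: "more than 3" is read literally as `r ≥ 4`,
   with `min_shared` exposed because such prose rules are sometimes meant
   inclusively. Raw p-values are the default filter (no adjustment across
   pairs), with `adjust_pairs = TRUE` offering BH across all scored pairs
   for the more conservative reading. A gene id appearing as both DEL and
   DEG is an error, since it would break bipartiteness.
4. **Topology** (`select_hubs`). Degree and betweenness are computed on
   the bipartite network (both node classes together, via igraph; Brandes'
   algorithm, undirected, unnormalized, each unordered pair counted once —
   normalization would cancel in ranks but the convention is declared so
   values are portable). Only lncRNAs are ranked; the hub call is the
   intersection of the degree top-k and betweenness top-k with `k = 8` by
   default. All ties at the k-th value are retained — the alternative
   silently drops arbitrary members of a tie.
5. **Subnetworks** (`extract_subnetwork`). A hub's subnetwork is its
   first neighbourhood: adjacent mRNAs plus the shared-miRNA sets stored
   on the retained edges, emitted as typed `sponges`/`targets` edges. The
   miRNAs come from the tested pairs, not recomputed from the background,
   so the subnetwork shows exactly the evidence behind each edge.
6. **Enrichment** (`ora`). Generic over-representation of a gene list
   against user-supplied GMT collections, using the same tail statistic
   with (k, U, q, K) in place of (r, m, n, t). The universe defaults to
   the union of set members; passing the measured-gene list is
   statistically preferable and supported. Significance is flagged on the
   BH-adjusted value by default, on raw p via `use_raw_p`.

## Numerical choices

The tail is summed over `i = r … min(n, t)` in log space via `lchoose`,
with the sum accumulated relative to its largest term. The printed-formula
complement `1 − Σ_{i<r}` is mathematically identical but loses all
precision once the tail is below ~1e-16; the test suite verifies
equivalence against both exhaustive subset enumeration (all `m ≤ 15`) and
the literal complement where it is safe, and against `phyper` at
database-scale arguments. Degenerate rules: `r = 0` returns exactly 1;
zero variance in both groups of a Welch test yields `p = 1` for equal
means and `p = 0` otherwise; BH is capped at 1 and order-preserving.
Quantile-normalization ties receive the mean of the reference values at
the tied positions. All output orderings (edge tables, SIF lines,
centrality reports) are deterministic sorts, so identical inputs reproduce
artifacts byte for byte.

## What the synthetic generator emulates — and what it does not

`sim_config()` / `simulate_study()` generate a coherent study: a miRNA
universe shared by both interaction tables; sparse uniform "base"
targeting; planted lncRNA–mRNA pairs forced to share `planted_shared`
dedicated miRNAs (reserved out of the universe, so planted sharing is
exact and decoy sharing stays at chance level); optionally hub-structured
planting (`n_hub_lnc` hubs × `mrnas_per_hub` partners); and a two-group
log2 expression matrix in which planted-pair genes and a random
`de_fraction` of all genes receive a ±`effect_size` case-group shift
(direction 50/50) under i.i.d. Gaussian noise. All randomness flows from
one seed; identical configurations are bitwise reproducible.

The matrix is padded with filler protein-coding genes (up to `n_genes`)
that have no interactions. This mirrors real arrays, where most measured
genes never enter the candidate pool, and it matters numerically: with
only the few hundred network genes present, quantile normalization
visibly compresses the fold changes of genes in the distribution tails,
because case-shifted genes occupy quantiles with no control counterpart.
With a well-populated matrix (4,000 genes in the benchmark) the planted
±2 shifts survive normalization with a comfortable margin.

The generator does **not** emulate probe-level artifacts, background
correction, batch effects, correlated noise, miRNA sequence features, or
database biases (hub miRNAs, study-driven annotation depth). Passing the
planted-recovery tests therefore demonstrates that the inference machinery
is correct and calibrated under its own null — not that the pipeline's
thresholds are well-chosen for any particular real dataset.

## The benchmark conditions

`benchmark_config()` fixes the study on which end-to-end recovery is
measured: 10 case vs 10 control samples; 4,000 measured genes with 10%
differentially expressed at log2 shift 2 and noise sd 0.5 (baseline
intensities N(8, 2.5²)); 600 miRNAs, 120 lncRNAs, 300 mRNAs with 5 base
targets per gene; 4 planted hub lncRNAs, each sharing 8 dedicated miRNAs
with 6 mRNAs. The interaction sizes are a roughly 1:5 scale-down of the
public databases' miRNA complements; the universe is kept large relative
to the hubs' inflated target counts (a hub carries 48 dedicated + 5 base
miRNAs) because shrinking it dilutes the planted pairs' significance
toward the 0.01 boundary — the benchmark is meant to contain decisively
true positives. At these sizes the whole pipeline runs in about a second,
and the accompanying acceptance script's null-calibration stages (10,000
scored decoy pairs; 5,000 null genes; 2,000 random-query set tests) run
in a few seconds.

## Known limitations

- The Welch filter is anticonservative for very small groups compared to
  moderated statistics; below ~4 samples per group prefer an external DE
  tool and feed its gene lists to `build_network()` directly.
- Identifiers are matched verbatim; no miRBase version harmonization or
  gene-symbol aliasing is attempted, by design — mixed-namespace inputs
  will silently fail to overlap, though the skip counters in the run
  summary make this visible.
- Betweenness on networks with many exact ties (common in small bipartite
  graphs) makes the top-k boundary sensitive; the all-ties-retained rule
  keeps the hub call stable but can return more than `k` retained nodes
  per metric.
- The pair statistic ignores miRNA expression; a pair can score highly on
  miRNAs absent from the studied tissue.
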