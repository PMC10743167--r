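---
title: "Predicting hub genes from EV miRNA cargo: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hub genes from EV miRNA cargo: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evhub)
```

## The problem

Extracellular vesicles (EVs) shuttle miRNAs between cells, and the miRNA
cargo of EVs from metastasis-suppressive versus metastasis-promoting cell
lines differs. Because a miRNA represses its target mRNAs, differential EV
miRNA loading can be propagated computationally into a ranked set of
candidate *hub genes* — genes that sit centrally among the predicted
targets and are therefore plausible mediators of the phenotype. `evhub`
implements that desk pipeline end to end:

1. **Differential loading** — per-miRNA log2 fold change and p-value, with
   a volcano filter and per-direction top-k selection.
2. **Target mapping** — TargetScan-style context-score tables, thresholded
   on the cumulative weighted context++ score (CWCS), pooled into
   per-direction target-gene unions.
3. **GD (global-data) branch** — the target union is scored in a
   protein-interaction network by maximal clique centrality (MCC) and
   degree.
4. **SK (specific-keyword) branch** — an 18-keyword immune/inflammation
   lexicon is matched against gene annotation text; genes are selected by
   bipartite keyword degree.
5. **Integration** — both branches merge into a per-comparison report in
   which each candidate carries its regulating miRNA and the inferred
   (opposite-direction) gene regulation.

## Differential statistic

Vendor small-RNA pipelines are proprietary, so the package documents its
own defensible statistic and also accepts externally computed
`(log2fc, p)` tables via `read_stats()`/`classify_mirnas()`. Counts are
normalised to counts per million (CPM); the reported effect is

$$\log_2\mathrm{FC} = \log_2\frac{\overline{\mathrm{CPM}}_B + c}
{\overline{\mathrm{CPM}}_A + c},$$

with pseudocount $c = 0.5$ (CPM units) guarding low-abundance miRNAs, and
the p-value is a two-tailed Welch t-test on $\log_2(\mathrm{CPM} + c)$.
Welch rather than pooled variance is the safer default for the small,
possibly heteroskedastic group sizes typical of EV sequencing; the
two-sample machinery elsewhere in the package (`two_tailed_t()`) defaults
to the classical pooled test, with Welch behind a flag. No multiple-testing
correction is applied by default — the volcano filter operates on raw
p < 0.05 with fold change > 2 (or < 1/2) — but Benjamini–Hochberg is
available via `classify_mirnas(..., adjust = "BH")`. "Descending order of
fold change" is interpreted per direction (|log2FC| within the down class),
because the selection is symmetric: up to k miRNAs up and k down. Ties
break lexicographically by miRNA id for reproducibility.

## Target mapping

`read_targetscan()` consumes the TargetScan download dialect (configurable
column names) and aggregates duplicate (miRNA, gene) rows to the most
negative score. The default threshold CWCS ≤ −0.4 corresponds to a
predicted repression of about 24% ($1 - 2^{-0.4} \approx 0.242$); the
threshold is inclusive by default with a strictness flag, since score
tables conventionally report the boundary value as passing. Gene identity
is a case-sensitive symbol match after whitespace trimming — alias
resolution is out of scope.

A deliberate bookkeeping choice: the per-comparison total reported by
`build_target_map()` is |up-union| + |down-union|, i.e. direction
subtotals are *added*, not union-ed across directions. That is the
arithmetic a per-group count table implies, and it is what the package's
acceptance fixtures reproduce (comparison totals 405 and 669; grand total
1074 across the two comparisons).

## GD branch: maximal clique centrality

MCC of a vertex $v$ is

$$\mathrm{MCC}(v) = \sum_{C \in M(v)} (|C| - 1)!$$

over the maximal cliques $C$ of size ≥ 2 containing $v$; isolated vertices
score 0. On a triangle-free graph every maximal clique is an edge and MCC
reduces to the degree. Cliques are enumerated by Bron–Kerbosch with Tomita
pivoting (`maximal_cliques()`), guarded by a configurable node-count limit
(default 5000) against pathological inputs; the test suite verifies the
enumeration against both a brute-force subset-enumeration oracle and an
independent library implementation on hundreds of random graphs.

Hub ranking (`rank_hubs()`) orders by MCC descending with degree and then
gene symbol as tie-breaks, reports the top 30 and selects the leading 5 as
candidates. The candidate rule follows the MCC ordering (with degree only
as tie-break) because published hub tables are MCC-sorted even when
described as "high-degree" selections. The STRING-style edge reader
defaults to a combined-score cutoff of 400 (medium confidence), exposed as
a flag since confidence conventions vary between studies.

## SK branch: keyword matching

The default `keyword_lexicon()` holds 18 canonical keywords in three
categories (immune responses; immune cells; inflammation signaling).
Matching is *token-bounded*, not substring-based: text and keywords are
case-folded, hyphens and slashes become spaces, and a keyword matches only
as a bounded token sequence. This prevents "CD3" firing inside "CD34",
which plain substring matching would get wrong and which would corrupt
bipartite degrees. A shipped synonym table covers surface variants
("NF-kB", "NF-κB", "nuclear factor kappa B", "TGF-β", "T-cell", plurals,
"JAK-STAT"); both lexicon and synonyms are user-overridable
(`read_lexicon()` accepts YAML or TSV).

A gene's bipartite degree is the number of distinct canonical keywords in
its annotation; `select_by_degree()` keeps genes at or above the threshold
(default 4, read as ≥ 4: on realistic corpora the observed maximum equals
the threshold, so ≥ and = coincide). Per-comparison networks can overlap
in genes, so both per-comparison and deduplicated counts are observable
from the returned objects.

## Integration

`assign_regulation()` gives each candidate gene the selected miRNA
targeting it with the most negative CWCS (ties lexicographic by miRNA id —
score tables print a single regulator without stating a rule, and the most
negative score is the strongest predicted repressor). The inferred gene
regulation is the opposite of the miRNA loading direction: an up-loaded
miRNA down-regulates its targets. Genes targeted by no selected miRNA are
reported with an explicit `unassigned` status — never silently dropped.
`merge_candidates()` deduplicates genes across branches while retaining
joint provenance (`GD+SK`), and the report round-trips losslessly through
JSON. Whether the headline candidate count should deduplicate across
comparisons is unobservable when the two lists are disjoint; the report is
per-comparison, and cross-comparison pooling is left to the caller.
Biological classification of candidates (tumour-suppressive versus
-promoting) requires external knowledge and is intentionally not computed.

## Synthetic data: what it emulates, and what it does not

Because no raw EV sequencing data are publicly deposited, every stage has
a seeded generator producing inputs with exactly the statistical structure
the stage assumes:

- `gen_counts()` — negative-binomial counts, mean–dispersion
  parameterisation (variance $\mu + \phi\mu^2$), two groups, planted log2
  fold changes. Defaults: dispersion 0.1, baseline mean 500, per-miRNA
  abundances log-normal (sdlog 1) around the baseline so libraries span a
  realistic dynamic range. The design values used in the calibration tests
  (10 samples per group; 2000 null miRNAs; 200 replicates for planted
  |log2FC| = 3 recovery) are package choices — no sequencing design is
  published for the motivating experiment.
- `gen_target_table()` — exact per-miRNA set sizes, disjoint or random
  overlap, scores uniform in a configurable CWCS interval. Disjoint mode
  makes union sizes exactly additive, which is what printed per-group
  count tables imply.
- `gen_ppi()` — Erdős–Rényi background plus planted cliques on reserved
  `clique`-prefixed nodes, kept disconnected from the background so tests
  can identify planted hubs by label without the labels influencing any
  score.
- `gen_annotations()` — filler prose from a fixed keyword-free vocabulary
  with planned keywords embedded at random positions; a decoy-only corpus
  is matcher-verified to produce zero hits.

These generators validate the *pipeline arithmetic and calibration*, not
biology: real count data have correlated library composition, batch
effects and miRNA-family cross-hybridisation; real interaction networks
are scale-free rather than Erdős–Rényi; real annotations use vocabulary
far beyond the filler list. Passing tests therefore demonstrate that the
machinery is correct and calibrated under its stated model, not that the
model captures every property of laboratory data.

## Assay metrics and numerical choices

- `cytotoxicity()` rescales a test OD490 linearly between low and high
  controls; it is affine-invariant and refuses `od_high <= od_low`.
  Biological over/undershoot outside [0, 100]% is returned unclipped with
  a warning rather than masked.
- `invasion_estimate()` scales summed area counts by the sampled membrane
  fraction — a required user input, as no standard fraction exists.
- `grubbs_outlier()` tests the single most extreme observation with
  critical value $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$, $t$ the
  one-tailed Student quantile with $n-2$ df. The default two-sided test
  (statistic $\max_i |x_i - \bar x|/s$, quantile at $\alpha/(2n)$) keeps
  the null flag rate at the nominal $\alpha$ — verified at 10,000
  simulated series — while catching outliers in either direction, which is
  what box-plot outlier marking needs; a prespecified-direction one-sided
  variant at $\alpha/n$ is available. The naive combination of the
  two-sided statistic with the $\alpha/n$ quantile has size $2\alpha$ and
  is deliberately not offered. One observation is flagged per pass;
  iterative re-testing is off by default.
- Degenerate inputs follow explicit conventions: zero-variance series are
  not outlier-tested; a doubly degenerate t-test returns p = 1 for equal
  means and 0 otherwise; a DE group with fewer than two samples yields NA
  p-values but still a fold change.

## Known limitations

- The DE statistic is a documented stand-in for whatever pipeline produced
  a given study's `(log2fc, p)` table; slot in external tables when exact
  concordance matters.
- MCC enumeration is exponential in the worst case; the node guard, and
  restricting the graph to the comparison's target union (as
  `run_comparison()` does), keep practical inputs tractable.
- Keyword matching is lexical. It will not resolve paraphrases ("antigen
  presentation" is not "Immune") and depends on the annotation corpus
  supplied by the user.
- Gene symbols are matched verbatim; cross-database alias drift must be
  resolved upstream.
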