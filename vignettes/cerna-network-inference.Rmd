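---
title: "Inferring circRNA-miRNA-mRNA ceRNA networks with cernets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring circRNA-miRNA-mRNA ceRNA networks with cernets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernets)
```

## The model

Under the competing endogenous RNA (ceRNA) hypothesis, transcripts that share
miRNA response elements (MREs) compete for a limited pool of miRNAs. A
circRNA carrying MREs for a miRNA can sponge it and thereby de-repress that
miRNA's mRNA targets. In a two-condition expression experiment this predicts
a characteristic signature for a genuine circRNA-miRNA-mRNA axis:

* miRNA and mRNA negatively correlated (direct repression),
* miRNA and circRNA negatively correlated (sponging/sequestration),
* circRNA and mRNA positively correlated (shared release from repression),
* differential-expression directions coherent: the miRNA moves opposite to
  both the circRNA and the mRNA.

`cernets` operationalises this as a funnel of screens. Features are first
normalized (counts per million for mRNA/miRNA, back-splice junction reads
per million for circRNAs) and filtered for differential expression; cross
class Pearson correlations are screened directionally with exact p-values
from the transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
freedom; candidate pairs must additionally carry at least one predicted MRE;
and finally each circRNA-mRNA pair is scored by the hypergeometric upper
tail on the overlap of their targeting-miRNA sets,

$$p = \sum_{i \ge x} \frac{\binom{K}{i}\binom{N-K}{M-i}}{\binom{N}{M}},$$

with `N` the screened miRNA universe, `K` and `M` the two targeting sets and
`x` their overlap — the smaller the tail, the more significantly shared the
miRNAs. Pairs supported by both the score and positive co-expression are
ranked by score and truncated to the top 50; triplets are then assembled
under the direction-coherence rule.

With three replicates per group pooled across groups, `n = 6` and the
correlation test has 4 degrees of freedom; at `p < 0.05` the screen
`|r| >= 0.8` is effectively `|r| >= 0.811`. The published pair tables this
package reproduces pin down exactly this convention: every printed p-value
matches the `t(df = 4)` transform of the printed `r` to at least three
significant figures (see `tests/testthat/test-acceptance.R`).

## A worked run

```{r, eval = FALSE}
run <- cerna_pipeline(sim_config(seed = 1))
run
summary(run$network)
```

Each filtering stage logs a `before -> after` line and the funnel is kept in
`run$funnel`; every threshold that was applied is serialized into the run
manifest, so no filter is hidden.

## Classification of back-splice junctions

The five-category taxonomy is evaluated in precedence order: **exonic**
(both junction ends on exon boundaries of one same-strand transcript, exact
by default with a configurable `boundary_tolerance`), **intronic** (contained
in a single intron of a same-strand transcript), **sense_overlapping** (any
other same-strand gene overlap), **antisense** (opposite-strand overlap
only), **intergenic** (none). The category names are standard in circRNA
catalogues; published catalogues rarely define the boundaries, so the
precedence above is this package's explicit definition, chosen so that
junctions whose ends rarely coincide exactly with annotated exon boundaries
fall into the dominant sense-overlapping class, as observed in real
catalogues. circRNA *length* is the genomic span `end - start`: the spans
reported in the tables this package mirrors (maxima near 10^5 nt) are only
consistent with genomic span, not spliced length. `exon_count` is the number
of exons of the best (largest-overlap, ties by id) same-strand transcript
strictly overlapped by the junction span.

Catalogue summaries follow the conventional definitions; N50 is computed by
descending-length accumulation and is cross-checked in the tests against an
independent formulation (the largest length whose `>= L` members hold half
the total).

## The synthetic-data generator

No public dataset accompanies the analyses this package generalises, so the
generator is a first-class module that emulates the study design: two groups
(`X_LC`, `D_LC`) of three replicates, negative-binomial counts, and planted
circRNA-miRNA-mRNA triplets with known categories, directions, and MRE
positions. Its defaults are the package's statement of the study
conditions:

* `samples_per_group = 3` — so correlation tests run at `n = 6`, `df = 4`,
  matching the published p-values.
* `nb_dispersion = 0.05` — a tight but realistic bulk RNA-seq dispersion;
  variance `mu + 0.05 mu^2`.
* `repression_strength = 2` — log2-fold repression of a planted target per
  standard deviation of effective miRNA activity; with `nb_dispersion =
  0.05` this reproduces the strong-effect regime in which >90% of planted
  miRNA-mRNA pairs show `r <= -0.8` at `n = 6`.
* `sponge_strength = 0.5` — log2 attenuation of miRNA activity per standard
  deviation of the sponging circRNA. The *measured* miRNA level is drawn
  from the attenuated activity (the free-miRNA interpretation), which gives
  the miRNA-circRNA anticorrelation a mechanism rather than leaving it to
  opposite group effects alone.
* `de_lfc = 3` — the log2 group effect planted into miRNAs and circRNAs.
  Planted features are meant to be *clearly* differentially expressed; an
  effect of 2 sits at the detection boundary of a 3-vs-3 Welch test at
  `|log2FC| >= 1`, `p < 0.05` (about 90% per-feature recovery), whereas 3
  places them inside the detectable regime without being degenerate.
* `activity_sd = 0.2` — per-sample log2 activity noise, small relative to
  the group effect, comparable to the dispersion-induced noise.
* mRNA differential expression is *mediated*: planted mRNAs carry no group
  term of their own and respond only through repression. Zeroing
  `repression_strength` therefore removes mRNA DE and all planted
  correlation signal — the design that makes the null control (zero final
  triplets with effects off) meaningful.

Sequences are RNA-alphabet strings with planted MREs: at each planted
position the target carries the reverse complement of the miRNA seed
(positions 2-8) preceded by `site_extension = 8` nt of Watson-Crick 3'
pairing (an extension length rather than a fraction — equivalent and easier
to reason about), a guard base that terminates extension exactly at the
planted block, and rejection sampling that removes accidental seed
complements of *any* bundled miRNA elsewhere. miRNA sets are themselves
redrawn until no seed collides with another miRNA's plantable block, so
planted sites are recovered at exactly their planted offsets and precision
of the end-to-end pipeline is not eroded by accidental MREs.

Everything derives from one root seed through fixed per-stage labels:
identical configurations yield byte-identical bundles, and single stages can
be regenerated independently.

### What the generator does and does not emulate

It reproduces the statistical structure the screens assume — count
overdispersion, library-size variation (+/-20%), directional correlations
with a mechanistic sponge, seed-complement binding sites, and the five
genomic categories by construction. It does not emulate read-level
artefacts, multi-isoform splicing, shared miRNAs across triplets, GC or
length biases, or annotation errors. Passing the plant-recover gates
therefore demonstrates that the pipeline's logic is faithful, not that its
thresholds are optimal for any particular real dataset.

## Numerical and design choices

* **DE statistic.** Welch's t on `log2(normalized + 1)` rather than a
  negative-binomial GLM: deterministic, dependency-free, and sufficient to
  exercise fold-change/p-value threshold logic. The module boundary admits
  an exact NB test as a drop-in replacement. Raw p drives the default
  filter; BH-adjusted values are always computed and reported.
* **Correlation scale.** Screens run on `log2(normalized + pseudocount)` by
  default (`corr_log2`), the standard scale for expression co-expression;
  plain normalized values are selectable.
* **Threshold boundaries.** `|r| >= r_min` (inclusive) with `p < p_max`
  (strict); DE uses `|log2FC| >= 1` (mRNA) and fold change > 2 on the log2
  scale (miRNA/circRNA) at `p < 0.05`. A `p < 0.5` variant sometimes quoted
  for circRNAs is selectable but treated as a typo for 0.05 by default.
* **MRE scorer.** A deterministic seed-and-extend stand-in for
  thermodynamic predictors: perfect Watson-Crick seed (base score 40), +5
  per Watson-Crick 3' pair, +2 per G:U wobble, mismatch terminates, no
  gaps; energy proxy `-(7 + 0.45 WC + 0.2 GU)`. Monotone in pairing extent
  and in the magnitude range of published tables. External predictor output
  can be substituted through `read_pair_table()`, which validates the
  pair-summary invariants and skips violating rows with a warning.
  `max_energy` reports the energy of the maximum-score site, the convention
  the published single-site rows make indistinguishable from the
  most-negative-energy convention.
* **ceRNA universe.** `N` defaults to the screened miRNA set entering pair
  prediction (configurable to all quantified miRNAs); the upper tail
  includes the observed overlap, and `x = 0` pairs are never scored. The
  significance cutoff defaults to `alpha = 1` — all sharing pairs are
  ranked and the top 50 kept — because published "ceRNA score" pipelines
  typically rank rather than threshold; `alpha < 1` and BH correction are
  available.
* **Tie-breaks.** Every ordering is deterministic: p ascending, then |r|
  descending, then lexicographic ids; chromosome counts by count then name;
  greedy site selection by score then position.
* **Degenerate inputs.** Zero-variance expression rows are excluded from
  correlation (counted and reported), zero libraries are an error,
  `|r| = 1` maps to `p = 0`, both-groups-constant DE rows get `p = 1` (or 0
  if separated), and empty stages propagate as empty tables rather than
  errors.

## Problem sizes used in validation

The shipped tests validate the hypergeometric kernel against exhaustive
enumeration for every argument combination with `N <= 12`, N50 against a
brute-force oracle on 1,000 random multisets, the classifier against
planted categories on a 10,000-junction catalogue (agreement must be 100%),
and the end-to-end pipeline on the default 80-gene/30-miRNA/40-circRNA
bundle with 20 planted triplets (recall >= 0.9, precision >= 0.8 at the
default seed) plus 100 zero-effect null bundles (>= 95% empty networks).
These sizes keep the whole suite to about a minute while exercising every
code path at catalogue scale.

## Limitations

The DE screen is a transformed-scale t-test, not a count model; the MRE
scorer is not thermodynamic; correlation screens at `n = 6` have limited
resolution (under independence `E|r|` is already ~0.36, which is why the
screens combine correlation with binding and score evidence); and the
hypergeometric score assumes exchangeable miRNAs within the universe. The
package infers candidate regulatory axes — experimental validation remains
the arbiter.
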