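---
title: "The Kh screen: exchangeability-partitioned Ka/Ks for detecting positive selection between close relatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Kh screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The classical test for positive selection compares the nonsynonymous
substitution rate $K_a$ with the synonymous rate $K_s$: $K_a/K_s > 1$
signals adaptive change. Between very close relatives — here, ortholog
pairs from two recently diverged species with a synonymous divergence
peaking near $K_s \approx 0.02$ — this test is weak twice over: counts are
tiny, and positive selection at a few sites is diluted by purifying
selection over the rest of the gene, dragging the gene-wide $K_a/K_s$ back
below 1.

The Kh screen sharpens the numerator. Not all amino-acid replacements are
equal: the 75 *elementary* amino-acid pairs (those connected by a single
nucleotide change between sense codons) can be ranked from most to least
exchangeable by an empirical evolutionary index. Purifying selection
removes radical (low-exchangeability) changes far more efficiently than
conservative ones, so the signal of positive selection concentrates in the
most exchangeable classes. The screen therefore replaces $K_a$ with

$$K_h = K_{10}^{*},\qquad
K_i^{*} = \mathrm{JC}\!\left(\frac{\sum_{j: r_j \le i} N_j}
                                   {\sum_{j: r_j \le i} L_j}\right),$$

the Jukes–Cantor-corrected cumulative rate over the 10 highest-ranked
classes, where $N_j$ and $L_j$ are the observed substitutions and
kappa-weighted mutation-opportunity sites of class $j$. By construction
$K_{75}^{*}$ is exactly the classical $K_a$ computed from the pooled
elementary counts, so the familiar ratio is recovered at the end of the
curve. A gene is a candidate positively selected gene (PSG) when
$K_h/K_s > 1$ with Fisher's exact $p < 0.05$, after filtering.

## The per-gene procedure

1. **Validation.** Input is a two-record, in-frame codon alignment. Codon
   columns containing a gap or `N` in either sequence, or a stop codon, are
   excluded from all counting.
2. **kappa.** The transition/transversion rate ratio is estimated from
   fourfold-degenerate third positions (codon family fourfold-degenerate
   *and* first two positions identical across the pair) with the Kimura
   two-parameter closed form. Genes with at least 50 such sites use their
   own estimate; others, and genes whose estimate is degenerate, fall back
   to the cohort-pooled estimate (see *Numerical choices*).
3. **Sites.** Each codon position contributes one site unit, split
   $\kappa : 1 : 1$ between its transition neighbour and the two
   transversion neighbours, accruing to $L_s$, to the $L_j$ of the
   neighbour's class, or to an excluded stop-opportunity weight. Per codon,
   synonymous + class + stop weights sum to 3 exactly. Site totals are
   averaged over the two sequences.
4. **Substitutions.** Per codon column: a single-nucleotide synonymous
   difference adds 1 to $N_s$; a single-nucleotide amino-acid difference is
   elementary and increments its class; a multi-nucleotide column with
   differing amino acids is tallied once as *non-elementary* and enters no
   class (and never $K_a$); the synonymous content of any multi-nucleotide
   column is credited to $N_s$ as the number of synonymous steps averaged
   over all minimal mutational pathways that avoid stop codons.
5. **Rates and test.** $K_s = \mathrm{JC}(N_s/L_s)$; cumulative $K_i^{*}$
   as above; $K_h = K_{10}^{*}$, $K_a = K_{75}^{*}$. Significance of
   $K_h/K_s$ (and $K_a/K_s$) comes from Fisher's exact test on
   $[[N_h, L_h - N_h], [N_s, L_s - N_s]]$ with fractional quantities
   rounded half-away-from-zero for the test only.
6. **Filters and call.** Genes with $K_a > 0.05$, $K_s > 0.08$ or
   $K_s < 0.005$ are removed (likely alignment/orthology artefacts at the
   high end, no information at the low end); remaining genes with
   $K_h/K_s > 1$ and $p < 0.05$ are candidate PSGs.

Cohort-level analyses concatenate genes by summing counts before
correcting: the full-cohort $K_i^{*}/K_s$ curve, and *supergenes* — after
sorting genes with $K_a > 0$ by descending $K_a$ (ties broken by gene id
for determinism), consecutive blocks of 100 genes are pooled, the trailing
remainder dropped, and $K_h/K_s$ is regressed on $K_a/K_s$ through the
origin. Under selection that suppresses only low-exchangeability changes
this slope exceeds 1; on real ortholog sets it has been observed near 2
(the "twofold approximation").

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `ka_max` | 0.05 | remove genes with implausibly high $K_a$ (dimensionless rate) |
| `ks_max` | 0.08 | remove genes far above the cohort's divergence peak |
| `ks_min` | 0.005 | remove genes whose $K_s$ carries no information |
| `p_threshold` | 0.05 | PSG significance level |
| `h_cutoff_rank` | 10 | classes defining $K_h$; configurable because the high-exchangeability band is conventionally the top 10–12 classes |
| `bin_size` | 100 | genes per supergene |
| `fisher_sided` | two | see *Design choices* |
| `kappa_policy` | per-gene | `per-gene`, `global`, or `fixed:X` |
| `kappa_min_sites` | 50 | fourfold sites required to trust a per-gene kappa |

## The exchangeability ranking

The ranking of the 75 classes is an *input*: `load_ei_ranking()` reads any
TSV with columns `aa1`, `aa2`, `rank` and validates it exhaustively (all 75
elementary pairs exactly once, ranks a permutation of 1..75, every pair
reachable by one nucleotide change, no stops). The bundled file
`ei_ranking_synthetic.tsv` is a deterministic **synthetic stand-in**
generated by `synthetic_ei_ranking()`: classes are ordered by
transition-weighted codon connectivity combined with hydropathy and
residue-volume similarity, which reproduces the qualitative shape of
empirical indices (common conservative exchanges such as D/E, K/R, S/T,
I/V rank high; rare radical ones rank low). It is not a transcription of
any published index, and substantive analyses of real data should supply
one. Every result in this package's tests holds for an arbitrary valid
ranking; only the *identity* of the top classes depends on it.

## The simulator

`simulate_cohort()` generates ortholog pairs by evolving two lineages
independently from a common ancestor (a star tree of two, no indels).
Mutations are proposed per codon position at transition : transversion
rates $\kappa : 1$, scaled so a fully neutral site accrues `branch_length`
expected substitutions per lineage; synonymous proposals are accepted,
stop-creating proposals rejected, and an elementary proposal of class $j$
is fixed with probability $\omega_{r_j}$ (values above 1 accelerate the
class beyond the neutral rate by thinning against the class maximum). The
defaults — 500-codon genes, $\kappa = 2$, `branch_length` 0.01 per lineage,
hence pairwise $K_s \approx 0.02$ — reproduce the divergence regime of a
recently separated species pair. Every accepted event is logged by class,
so the counting engine can be verified *exactly* against the generative
truth (in one-hit-per-codon mode, which removes multi-hit ambiguity).

What the simulator does **not** emulate: insertion/deletion and alignment
error, among-site rate variation, codon-usage and GC-content bias
(ancestors are drawn uniformly over sense codons), assembly or orthology
noise, and more than two taxa. Passing calibration on these cohorts shows
the estimator chain is internally consistent and correctly sized under the
stated model — not that real transcriptome-derived ortholog pairs meet
those assumptions.

Two behaviours of the method itself, quantified by the calibration runs:

* **Endpoint counting under multi-hits.** Classes are assigned to observed
  codon *differences*, not to historical events; two accepted changes at
  the same position in different lineages can appear as one change of a
  different class (e.g. V→I and V→L showing as I/L). At $K_s \approx 0.02$
  this is rare.
* **Non-elementary exclusion.** Multi-nucleotide amino-acid changes enter
  neither $K_a$ nor any class, so neutral cohort $K_i^{*}/K_s$ sits a few
  percent *below* 1 (about 0.95–0.98 at this divergence, as the calibration
  tests and `scripts/acceptance.R` measure). The published screen counts
  the same way; the deficit cancels in the $K_h/K_s$ vs $K_a/K_s$ contrast.

## Numerical choices

* **Jukes–Cantor domain.** $\mathrm{JC}(p) = -\tfrac34\log(1-\tfrac43 p)$
  requires $p < 0.75$; saturated proportions yield `NA` rates and the gene
  is filtered (`ks_undefined`) rather than erroring the cohort.
* **kappa edge cases.** No fourfold differences at all → uninformative
  default 2 (flagged). Transitions but no transversions → capped at 50.
  The closed form can fall to or below zero when transitions are rarer
  than the transversion-implied expectation; such estimates are floored at
  0.1 and flagged, and flagged genes fall back to the cohort-pooled kappa.
* **Fisher rounding.** Fractional sites (and pathway-averaged fractional
  counts) are rounded half-away-from-zero for the 2×2 table only; rates
  always use the fractional values.
* **Stop handling.** Stop-creating mutation opportunities are excluded
  from numerators and denominators alike, without renormalising the
  remaining weights; the excluded mass is reported as `stop_weight`.
* **Pathway averaging.** For multi-nucleotide synonymous content, minimal
  pathways passing through a stop codon are excluded; if every ordering
  does, all orderings are used with stop-adjacent steps never counted as
  synonymous.
* **Determinism.** Supergene sorting breaks $K_a$ ties lexicographically;
  simulation substreams are seeded per gene index, so cohorts are
  reproducible and order-independent.

## Design choices

* **Pool-then-correct.** $K_i^{*}$ applies the Jukes–Cantor correction to
  the pooled proportion, not to averaged per-class distances; this is what
  makes $K_{75}^{*}$ *exactly* the classical $K_a$ of the pooled counts.
* **Two-sided Fisher by default.** The PSG call combines $p < 0.05$ with
  the one-directional criterion $K_h/K_s > 1$, so sidedness mostly
  cancels; `fisher_sided = "greater"` is available.
* **Kappa granularity.** Published practice estimates kappa from fourfold
  sites without stating granularity; per-gene estimates are used when they
  rest on at least 50 sites, otherwise the cohort-pooled estimate — a
  compromise between respecting gene-level heterogeneity and the
  instability of tiny-count closed forms.
* **Origin regression.** The twofold approximation is a proportionality
  claim, so the supergene regression runs through the origin by default;
  an intercept variant is provided since the published fit's form is not
  stated.
* **Unordered pairs.** Exchange classes ignore the direction of change:
  two extant sequences give no ancestral polarity.

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on simulated
cohorts chosen to give stable Monte-Carlo estimates at interactive
runtimes: neutral calibration averages the cohort-level $K_i^{*}/K_s$
curve over 60 (tests) or 20 (acceptance script) replicate cohorts of 200
genes × 500 codons — a single such cohort leaves ~0.1 standard error on
the rank-1 ratio, which the averaging brings to ~0.01 — and the type-I
rate of the Fisher test is measured on 500 neutral genes. Oracle
equivalence uses 1,000 random 50-codon alignments against an independent
brute-force classifier.

## Limitations

* The bundled exchangeability ranking is synthetic (above); identities of
  specific top classes, and hence which genes are called PSGs on real
  data, require a published index.
* The screen detects departure of high-exchangeability substitution rates
  from the synonymous rate; it cannot determine the direction of selection
  at individual sites, and per-gene power at $K_s \approx 0.02$ is modest
  (a handful of substitutions per gene), which is exactly why the filters
  and the supergene pooling exist.
* No multiple-testing correction is applied to the PSG scan, matching the
  published procedure; at $\alpha = 0.05$ a 200-gene neutral cohort
  yields a few false positives by construction.
* Alternative genetic codes are accepted, but the class count then differs
  from 75 and a matching ranking must be supplied; only the standard code
  is exercised by the tests.
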