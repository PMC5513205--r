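---
title: "Comparing functional potential and expression in microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing functional potential and expression in microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmp)
```

## The problem

Shotgun metagenomics (MG) measures which genes a microbial community
*carries*; shotgun metaproteomics (MP) measures which proteins it actually
*expresses*. In a gut-microbiota cohort the two layers can disagree
substantially: community composition tends to look similar under both, while
functional profiles diverge, with expressed functions dominated by catabolic
and fermentation enzymes regardless of gene copy number. `mgmp` implements a
complete comparative pipeline for paired MG/MP cohorts: both layers are
reduced to the same kind of observation — an annotated unit (a read, or a
peptide-spectrum match) carrying a subject, a taxonomic lineage and a KEGG
orthologous group (KO) — and every downstream statistic treats the layers
symmetrically.

## The core statistic: per-subject log expression ratios

For a feature $i$ (a taxon at some rank, a KO, or a KO–taxon pair) with
relative abundances $a_{is}$ and $b_{is}$ in two conditions for subject $s$,
the package computes

$$r_{is} = \log_{10}\frac{a_{is} + \mathrm{CF}}{b_{is} + \mathrm{CF}},
\qquad \mathrm{CF} = 10^{-5},$$

and summarises each feature by the mean over subjects. The additive
correction factor removes the discontinuity when a feature is undetected in
one layer: both-zero gives exactly 0, and the ratio converges to the naive
one when abundances are large relative to CF. The set of per-subject ratios
is tested against zero with a two-tailed one-sample *t*-test, and p-values
are adjusted across all tested features by the Benjamini–Hochberg step-up
procedure, with significance called at FDR $\alpha = 0.05$. The same
machinery serves two contrasts: MP versus MG per feature, and, within one
layer, one taxonomic partition versus another (Firmicutes versus
Bacteroidetes per KO, each side renormalised within its subtree per
subject).

Choices worth making explicit:

* **Log base.** Base 10, matching the power-of-ten form of CF; exposed in
  `contrast_spec()`.
* **Abundance filter.** Features enter the test only if their mean relative
  abundance over the pooled subject columns of both conditions strictly
  exceeds 0.01 % ($10^{-4}$); the filter is a cohort mean, not per-subject,
  and filtered tables are never renormalised.
* **Degenerate vectors.** All ratios identically zero gives $t = 0$,
  $p = 1$ (no evidence). Zero variance with nonzero mean cannot yield a
  finite $t$; such features are flagged `degenerate` with the raw p floored
  at machine precision rather than an exact zero.
* **Denominators.** Relative abundance divides by the total weight of units
  *mappable at the requested level* ("annotated"), for both layers, so the
  two layers are on commensurable scales and columns sum to 1 over detected
  features. Dividing by the subject's total including unmapped units is
  available as `denominator = "all"`.

## Taxonomy and LCA

Taxa live in an explicit ranked tree (root, superkingdom, phylum, class,
order, family, genus; intermediate ranks may be absent from a lineage).
Ambiguous assignments — a set of candidate taxa for one unit — resolve to
the deepest node ancestral to all candidates (`lca()`); the empty set is
"unassigned". Upstream annotation tools expose tuning knobs that their
documentation rarely pins down, so `lca_config()` makes the two that matter
explicit: a minimum-support count below which a resolved node is truncated
to a fallback rank (or dropped), defaulting to *off* (`min_support = 0`,
`fallback_rank = "none"`). These defaults implement plain set-LCA and make
no claim of reproducing any particular annotation tool's behaviour.

## Inter-individual variability

Three complementary views:

* **Bray–Curtis contrasts.** For each subject pair,
  $1 - 2\sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)$ per layer
  (computed via `vegan::vegdist`), then a paired Wilcoxon signed-rank test
  (zero differences dropped, continuity-corrected normal approximation when
  an exact distribution is unavailable, as in R's `stats`) on the two
  layers' values over the same pairs. The $\binom{n}{2}$ pairs are not
  independent observations; the test is reported as the field convention,
  and simulation checks in the test suite assert only the *direction* of
  the effect, which is robust to the dependence.
* **Coefficient of variation.** Per feature, $\mathrm{sd}/\mathrm{mean}$
  across subjects in percent, zeros included (excluding them would bias
  sparse features towards conservation), with sample (n−1) standard
  deviation by default. Strict thresholds classify features as variable
  (> 150 %) or conserved (< 60 %); a CV exactly at a threshold is
  intermediate.
* **Between-layer Spearman.** Per subject, the rank correlation (average
  ranks on ties) between MG and MP profiles on the union of features,
  summarised as cohort mean ± sd. Subjects with fewer than three detected
  features are excluded.

## Attribution: who is doing what

`build_attribution()` crosses KOs with genera on one layer (typically MP)
and applies prevalence rules before display: a KO appears as its own row
only if detected in at least $\lceil n/2 \rceil$ subjects ("at least half",
minimal-integer reading, so 8 of 15); a genus appears as its own column only
if it expresses some configured KO in at least two subjects; pathway rows
and phylum columns aggregate *all* members found in at least one subject,
retained or not, so totals are conserved. Cells are
$\log_{10}(\text{mean abundance} + \mathrm{CF})$ — the CF keeps empty cells
finite so a heatmap can render them as floor values. `pathway_shares()` and
`taxon_shares()` divide pre-log pathway/phylum totals by the grand total.
The shipped `default_pathways()` — polysaccharide degradation, sugar
transport, aldose/ketose interconversion, catabolic pathways, glycolysis,
and acetate/propionate/butyrate biosynthesis, with representative KOs — is a
curation for simulation and examples, not an authoritative KEGG mapping.

## The synthetic cohort generator

Because raw cohort sequencing and MS data are not shippable, every stage is
exercised on synthetic cohorts with known truth. The generative model is
deliberately minimal:

1. per subject, genus proportions are one Dirichlet draw centred on the
   cohort base composition with concentration `taxon_dispersion` (the
   paper-scale default 10 yields phylum ranges of roughly 10–80 % for a
   45 % phylum, i.e. realistic gut-level inter-individual spread);
2. each genus carries a fixed function profile over KOs; optionally, each
   subject's *expressed* profile is itself a Dirichlet perturbation
   (`mp_function_dispersion`), which is what makes MP functionally more
   variable than MG;
3. unit counts per layer are multinomial at the layer depth over the joint
   genus × KO cells — 200 000 for MG (a subsampled read count) and 7 000
   for MP (a typical PSM yield) by default;
4. planted effects multiply MP cell probabilities by $10^{e}$ and the cell
   matrix is renormalised. Compositional closure therefore shifts realised
   ratios of *non*-effect features slightly; `expected_log_ratio()` reports
   the post-normalisation truth, and all recovery tests score against it
   rather than against the nominal $e$.

Records are emitted aggregated (one row per subject × layer × taxon × KO
with `weight` = count), which is semantically identical to unit-level rows
(`aggregate = FALSE` expands them) and keeps depth-$10^5$ simulations cheap.

What the generator does **not** model: sequencing or MS error, ORF calling,
annotation bias between layers, genome-size effects, read-length limits on
LCA resolution, or any correlation structure beyond the shared subject
composition. Passing tests therefore demonstrate that the *pipeline
mathematics* is correct and well-calibrated under a plausible community
model — not that any biological conclusion transfers to real data.

`default_cohort_spec()` encodes the emulated study conditions: 15 subjects,
Firmicutes/Bacteroidetes-dominated composition, the depths above, and
planted effects that reproduce the qualitative expression pattern expected
of a healthy gut (SCFA-biosynthesis and glycolytic enzymes expressed above
genetic potential; replication and biosynthesis machinery below it;
genus-level offsets such as *Faecalibacterium* high and *Escherichia* low).
Its function-profile weights were chosen, once, so that the generator's
analytic MP expectation puts roughly half of configured carbohydrate
metabolism in glycolysis, ~12 % in butyrogenesis, a few percent each in
propionogenesis/acetogenesis/transport/interconversion, and splits the
total nearly evenly between Firmicutes and Bacteroidetes with a minor
Actinobacteria contribution — the composition a healthy-gut metaproteome is
expected to show.

## Numerical choices and degenerate inputs

* Subsampling is exact multivariate-hypergeometric (sequential conditional
  draws over weighted rows), per subject, MG only by default; requesting
  more units than a subject has is an error naming the subject.
* Genus→phylum aggregation commutes with normalisation exactly in exact
  arithmetic; floating-point summation order leaves last-ulp differences,
  so tests assert equality at $10^{-12}$.
* All randomness flows through explicit seeds; generation, subsampling and
  the full pipeline are byte-deterministic given spec + seed, and the RNG
  state of the caller is restored afterwards.
* Ties in Spearman use average ranks; Wilcoxon zero differences are
  dropped (classic signed-rank), not Pratt-corrected.
* An all-zero subject profile makes its Bray–Curtis pairs undefined; they
  are reported as `NA` with a warning, and dropped from the paired test.

## Problem sizes used by the test and acceptance suites

Simulation-based checks use 50 replicates of 15-subject cohorts with 100
features at depth $10^5$ (type-I error and ±1 planted-effect recovery), 20
features at depths $2\times10^4$/$5\times10^3$ (variability direction), and
a single default cohort at the full 200 000/7 000 depths for the worked
summaries. These sizes give Monte-Carlo error comfortably below every
asserted tolerance while keeping a full run in the low minutes on one core.

## Known limitations

* Plain BH is the only FDR procedure offered; features are treated as
  independent test units although compositional data guarantee they are
  not (no CLR/ALR transform is applied, matching the conventional
  proportion-based workflow this package reproduces).
* The Wilcoxon contrast treats subject pairs as independent (see above).
* LCA min-support filtering operates after per-unit resolution; it does not
  emulate score-based filtering of candidate hits upstream.
* The default pathway configuration and taxonomy are compact curations for
  simulation; real analyses should supply their own via
  `pathway_config()` / `build_taxonomy()`.
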