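# mgmp — comparative metagenome / metaproteome analysis

`mgmp` is an R package for researchers comparing the **functional
potential** (shotgun metagenome, MG) and the **expressed functions**
(shotgun metaproteome, MP) of a microbial community cohort — typically a
human gut cohort where each subject contributes both sequencing reads and
peptide-spectrum matches (PSMs). Both layers are reduced to annotated
observation units (subject, taxonomic lineage, KEGG orthologous group,
count weight) and compared symmetrically.

## What it computes

The core statistic is the per-subject **log expression ratio**. For feature
*i* (a taxon, a KO, or a KO–taxon pair) with relative abundances *a*ᵢₛ
(MP) and *b*ᵢₛ (MG) in subject *s*:

    r_is = log10( (a_is + CF) / (b_is + CF) ),   CF = 1e-5

The per-feature set {r_is} is tested against zero with a one-sample
two-tailed *t*-test, Benjamini–Hochberg adjusted across features (FDR
α = 0.05), after a strict 0.01 % mean-relative-abundance filter. Positive
mean ratios mark functions expressed above their genetic potential. The
same machinery contrasts two taxonomic partitions within one layer (e.g.
Firmicutes vs Bacteroidetes per KO). Around it:

* **Taxonomy / LCA** — ranked trees, lowest-common-ancestor resolution of
  ambiguous assignments, optional min-support truncation
  (`build_taxonomy()`, `lca()`, `assign_lca()`);
* **Abundance** — relative-abundance tables at any rank / KO / KO×rank
  level, strict mean-abundance filtering, exact hypergeometric per-subject
  subsampling (`relative_abundance()`, `filter_features()`,
  `subsample_units()`);
* **Variability** — Bray–Curtis dissimilarity contrasts between layers
  (paired Wilcoxon signed-rank), CV-based conserved/variable classification
  (>150 % / <60 %), per-subject between-layer Spearman ρ;
* **Attribution** — pathway-grouped KO × genus matrices with prevalence
  rules (KO rows: detected in ≥⌈n/2⌉ subjects; genus columns: expressing a
  function in ≥2 subjects) and pathway/phylum shares
  (`build_attribution()`, `pathway_shares()`, `taxon_shares()`);
* **Synthetic cohorts** — a Dirichlet-multinomial generator with planted
  log₁₀ MP/MG effects and analytic expectations, so the whole pipeline is
  testable without external data (`cohort_spec()`, `generate_cohort()`,
  `null_cohort()`, `expected_log_ratio()`);
* **Workflows** — `cmd_simulate()` and `cmd_full_analysis()` write
  export-ready TSVs plus a run manifest; `inst/scripts/mgmp.R` is a thin
  shell wrapper.

## Worked example

```r
library(mgmp)
spec <- default_cohort_spec(seed = 1)   # 15 subjects, MG 200k reads, MP 7k PSMs
rec  <- generate_cohort(spec)

mp <- relative_abundance(rec, "KO", spec$taxonomy, layer = "MP")
mg <- relative_abundance(rec, "KO", spec$taxonomy, layer = "MG")
rt <- ratio_test(mp, mg)
rt
#> <ratio_test> KO: 51 features, 15 subjects, cf=1e-05, alpha=0.05
#>   significant: 41 (11 up, 30 down)
summary(rt, n = 5)
#> ratio test: 41/51 features significant at FDR 0.05
#>  feature mean_log_ratio t_statistic     p_raw p_adjusted significant ...
#>   K03043        -0.7260      -27.58 1.329e-13  6.778e-12        TRUE
#>   K01872        -0.9386      -21.55 3.907e-12  6.642e-11        TRUE
#>   ...
```

Most KOs differ between expression and potential — the replication and
biosynthesis machinery (RNA polymerase K03043, alanyl-tRNA ligase K01872,
gyrase K02469) sits below genetic potential, while ferritin (K02217) and
the glycolytic/SCFA enzymes sit above it, exactly the planted pattern.
Taxonomic profiles, by contrast, agree well between layers:

```r
spearman_between_layers(
  relative_abundance(rec, "phylum", spec$taxonomy, layer = "MG"),
  relative_abundance(rec, "phylum", spec$taxonomy, layer = "MP"))
#> <layer_correlation> phylum: rho = 0.94 +/- 0.09 (mean +/- sd, n = 15 subjects)

att <- build_attribution(rec, default_pathways(), spec$taxonomy,
                         n_subjects = 15, layer = "MP")
round(100 * pathway_shares(att), 1)
#> polysaccharide_degradation  sugar_transport  interconversion  catabolic_pathways
#>                        7.4              6.9              6.3                 9.3
#>                 glycolysis     acetogenesis  propionogenesis       butyrogenesis
#>                       52.6              1.3              2.5                13.7
round(100 * taxon_shares(att), 1)
#> p__Actinobacteria p__Bacteroidetes p__Firmicutes p__Proteobacteria p__Verrucomicrobia
#>               2.6             48.9          47.8               0.4                0.3
```

Glycolysis carries about half of the expressed carbohydrate metabolism,
butyrogenesis is the largest fermentation contribution, and Firmicutes and
Bacteroidetes split the total nearly evenly — the profile the default
cohort spec is built to emulate.

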