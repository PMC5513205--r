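Package: mgmp
Title: Comparative Metagenome and Metaproteome Analysis of Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the functional potential (shotgun metagenome,
    MG) and the expressed functions (shotgun metaproteome, MP) of a microbial
    community cohort. Annotated observation units (reads or peptide-spectrum
    matches carrying a taxonomic lineage and a KEGG orthologous group) are
    aggregated into filtered relative-abundance tables at any taxonomic rank or
    functional level; per-subject log abundance ratios between two layers (MP
    versus MG) or between two taxonomic partitions (e.g. Firmicutes versus
    Bacteroidetes) are tested for deviation from zero by one-sample t-tests
    with Benjamini-Hochberg false-discovery-rate control; inter-individual
    variability is quantified by Bray-Curtis dissimilarity contrasts,
    coefficient-of-variation classification and per-subject between-layer
    Spearman correlation; and pathway-grouped function-by-taxon attribution
    matrices summarise which taxa express which metabolic activities.
    A Dirichlet-multinomial cohort simulator with planted per-feature
    log-ratio effects makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
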