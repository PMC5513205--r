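# Default study conditions: a gut-like taxonomy, a carbohydrate-metabolism
# pathway configuration, and a 15-subject cohort spec whose composition,
# sampling depths and planted expression effects emulate a healthy adult gut
# cohort profiled by shotgun metagenomics (reads subsampled to a common
# depth) and shotgun metaproteomics (thousands of PSMs per sample).

#' A compact gut-microbiota reference taxonomy
#'
#' Sixteen common gut genera under five phyla (Firmicutes, Bacteroidetes,
#' Actinobacteria, Proteobacteria, Verrucomicrobia), with family-level
#' intermediate nodes. Intended for simulation and examples, not as an
#' authoritative reference.
#'
#' @return A [build_taxonomy()] object.
#' @export
default_taxonomy <- function() {
  e <- function(child, parent, rank) data.frame(child = child, parent = parent,
                                                rank = rank, stringsAsFactors = FALSE)
  edges <- rbind(
    e("k__Bacteria", "root", "superkingdom"),
    e(c("p__Firmicutes", "p__Bacteroidetes", "p__Actinobacteria",
        "p__Proteobacteria", "p__Verrucomicrobia"), "k__Bacteria", "phylum"),
    e(c("f__Ruminococcaceae", "f__Lachnospiraceae", "f__Veillonellaceae",
        "f__Streptococcaceae"), "p__Firmicutes", "family"),
    e(c("f__Bacteroidaceae", "f__Prevotellaceae", "f__Rikenellaceae",
        "f__Porphyromonadaceae"), "p__Bacteroidetes", "family"),
    e("f__Bifidobacteriaceae", "p__Actinobacteria", "family"),
    e("f__Coriobacteriaceae", "p__Actinobacteria", "family"),
    e("f__Enterobacteriaceae", "p__Proteobacteria", "family"),
    e("f__Sutterellaceae", "p__Proteobacteria", "family"),
    e("f__Akkermansiaceae", "p__Verrucomicrobia", "family"),
    e(c("g__Faecalibacterium", "g__Ruminococcus", "g__Subdoligranulum"),
      "f__Ruminococcaceae", "genus"),
    e(c("g__Roseburia", "g__Coprococcus", "g__Butyrivibrio", "g__Dorea"),
      "f__Lachnospiraceae", "genus"),
    e("g__Dialister", "f__Veillonellaceae", "genus"),
    e("g__Streptococcus", "f__Streptococcaceae", "genus"),
    e("g__Bacteroides", "f__Bacteroidaceae", "genus"),
    e("g__Prevotella", "f__Prevotellaceae", "genus"),
    e("g__Alistipes", "f__Rikenellaceae", "genus"),
    e("g__Parabacteroides", "f__Porphyromonadaceae", "genus"),
    e("g__Bifidobacterium", "f__Bifidobacteriaceae", "genus"),
    e("g__Collinsella", "f__Coriobacteriaceae", "genus"),
    e("g__Escherichia", "f__Enterobacteriaceae", "genus"),
    e("g__Parasutterella", "f__Sutterellaceae", "genus"),
    e("g__Akkermansia", "f__Akkermansiaceae", "genus")
  )
  build_taxonomy(edges)
}

#' Default carbohydrate-metabolism pathway configuration
#'
#' A reconstruction of the pathway groups running from polysaccharide uptake
#' and degradation to short-chain fatty acid production: polysaccharide
#' degradation, sugar transport, aldose/ketose interconversion, catabolic
#' pathways (pentose phosphate and related), glycolysis, acetogenesis,
#' propionogenesis and butyrogenesis, each with representative KEGG
#' orthologous groups. User-overridable; the KO-to-pathway assignment is a
#' curation, not ground truth.
#'
#' @return A [pathway_config()].
#' @export
default_pathways <- function() {
  pathway_config(list(
    polysaccharide_degradation = c("K01176", "K01179", "K01181", "K01198",
                                   "K05349", "K01190"),
    sugar_transport = c("K10112", "K02025", "K02026", "K21572", "K21573"),
    interconversion = c("K01804", "K01805", "K01818", "K01812"),
    catabolic_pathways = c("K00874", "K01628", "K01783", "K00615", "K00616"),
    glycolysis = c("K00844", "K01810", "K00850", "K01623", "K01803",
                   "K00134", "K00927", "K01834", "K01689", "K00873"),
    acetogenesis = c("K00625", "K00925"),
    propionogenesis = c("K01847", "K05606", "K01026"),
    butyrogenesis = c("K00626", "K00074", "K01715", "K00248", "K01034",
                      "K00929")
  ))
}

# Housekeeping (non-carbohydrate) functions shared by all genera.
default_housekeeping_kos <- function() {
  c("K01915",  # glutamine synthetase
    "K00262",  # glutamate dehydrogenase (NADP)
    "K02358",  # elongation factor Tu
    "K04077",  # chaperonin GroEL
    "K03043",  # RNA polymerase beta subunit
    "K01872",  # alanyl-tRNA synthetase
    "K02469",  # DNA gyrase subunit A
    "K01448",  # N-acetylmuramoyl-L-alanine amidase (cell wall)
    "K02217",  # ferritin
    "K02406")  # flagellin
}

#' Default 15-subject cohort specification
#'
#' A Firmicutes/Bacteroidetes-dominated community over the
#' [default_taxonomy()] genera, with between-subject Dirichlet compositional
#' noise, MG depth 200000 (a read count subsampled to a common per-subject
#' depth) and MP depth 7000 (a typical per-sample PSM yield), genus-specific
#' carbohydrate-metabolism repertoires over the [default_pathways()] KOs plus
#' housekeeping functions, extra between-subject variability of the expressed
#' (MP) functional profiles, and planted log10 MP/MG effects emulating the
#' qualitative expression pattern of a healthy gut cohort: catabolic and
#' SCFA-biosynthesis enzymes expressed above genetic potential,
#' replication/biosynthesis machinery below it, and genus-level expression
#' offsets (e.g. Faecalibacterium high, Escherichia low).
#'
#' @param seed Integer seed stored in the spec.
#' @param n_subjects Cohort size (default 15).
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L, n_subjects = 15L) {
  tree <- default_taxonomy()
  props <- c(
    g__Faecalibacterium = 0.16, g__Ruminococcus = 0.07, g__Subdoligranulum = 0.03,
    g__Roseburia = 0.06, g__Coprococcus = 0.04, g__Butyrivibrio = 0.02,
    g__Dorea = 0.03, g__Dialister = 0.03, g__Streptococcus = 0.01,
    g__Bacteroides = 0.20, g__Prevotella = 0.12, g__Alistipes = 0.07,
    g__Parabacteroides = 0.06,
    g__Bifidobacterium = 0.04, g__Collinsella = 0.01,
    g__Escherichia = 0.02, g__Parasutterella = 0.01,
    g__Akkermansia = 0.02
  )
  stopifnot(abs(sum(props) - 1) < 1e-12)
  pw <- default_pathways()
  hk <- default_housekeeping_kos()
  funs <- c(unlist(unname(pw)), hk)

  # per-genus weight over pathway groups; remainder goes to housekeeping
  groups <- c(names(pw), "housekeeping")
  base_w <- c(polysaccharide_degradation = 0.03, sugar_transport = 0.04,
              interconversion = 0.05, catabolic_pathways = 0.08,
              glycolysis = 0.18, acetogenesis = 0.012, propionogenesis = 0.006,
              butyrogenesis = 0.002)
  genus_extra <- list(
    g__Faecalibacterium = c(butyrogenesis = 0.065, sugar_transport = 0.03),
    g__Roseburia = c(butyrogenesis = 0.05),
    g__Coprococcus = c(butyrogenesis = 0.035),
    g__Butyrivibrio = c(butyrogenesis = 0.045, polysaccharide_degradation = 0.04),
    g__Ruminococcus = c(interconversion = 0.05, polysaccharide_degradation = 0.05),
    g__Dialister = c(propionogenesis = 0.18),
    g__Bacteroides = c(polysaccharide_degradation = 0.15, sugar_transport = 0.08,
                       interconversion = 0.07, propionogenesis = 0.025,
                       catabolic_pathways = 0.05, glycolysis = 0.13),
    g__Prevotella = c(polysaccharide_degradation = 0.16, sugar_transport = 0.06,
                      glycolysis = 0.07, catabolic_pathways = 0.03),
    g__Parabacteroides = c(polysaccharide_degradation = 0.08, sugar_transport = 0.04,
                           glycolysis = 0.06),
    g__Alistipes = c(catabolic_pathways = 0.05, glycolysis = 0.06,
                     sugar_transport = 0.03),
    g__Bifidobacterium = c(interconversion = 0.12, catabolic_pathways = 0.10,
                           polysaccharide_degradation = 0.08),
    g__Collinsella = c(interconversion = 0.04),
    g__Akkermansia = c(polysaccharide_degradation = 0.10)
  )
  profile <- matrix(0, length(props), length(funs),
                    dimnames = list(names(props), funs))
  for (g in names(props)) {
    w <- base_w
    extra <- genus_extra[[g]]
    if (!is.null(extra)) w[names(extra)] <- w[names(extra)] + extra
    w <- c(w, housekeeping = max(0, 1 - sum(w)))
    for (grp in names(w)) {
      kos <- if (grp == "housekeeping") hk else pw[[grp]]
      profile[g, kos] <- w[[grp]] / length(kos)
    }
    profile[g, ] <- profile[g, ] / sum(profile[g, ])
  }

  effects <- c(
    # functions expressed above genetic potential
    structure(rep(0.8, length(pw$butyrogenesis)), names = pw$butyrogenesis),
    structure(rep(0.4, length(pw$glycolysis)), names = pw$glycolysis),
    structure(rep(0.4, length(pw$propionogenesis)), names = pw$propionogenesis),
    K00262 = 0.6, K02217 = 0.7, K02406 = 0.6,
    # replication / biosynthesis machinery below potential
    K03043 = -0.5, K01872 = -0.6, K02469 = -0.5, K01448 = -0.5,
    # genus-level expression offsets
    g__Faecalibacterium = 0.3, g__Ruminococcus = 0.25, g__Prevotella = 0.25,
    g__Streptococcus = -0.4, g__Escherichia = -0.5, g__Parasutterella = -0.3
  )

  cohort_spec(
    tree, props, profile,
    n_subjects = n_subjects,
    taxon_dispersion = 10,
    mg_depth = 200000, mp_depth = 7000,
    effect_log_ratio = effects,
    unannotated_fraction = 0.05,
    mg_function_dispersion = Inf,
    mp_function_dispersion = 40,
    seed = seed
  )
}
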