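# End-to-end workflows: simulate a cohort to disk, and run the full
# comparative analysis (abundance -> differential -> variability ->
# attribution) writing export-ready TSVs plus a run manifest.

#' Simulate a cohort and write records, truth and config to disk
#'
#' Writes `taxonomy.tsv`, `records.tsv`, `spec.yaml` and `truth.tsv` (one row
#' per planted effect key with its true log10 effect and the
#' generator-expected post-normalisation mean log ratio at its level) into
#' `out_dir`. The spec is validated before any file is written.
#'
#' @param spec A [cohort_spec()] (or path to a spec YAML).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the generated record data.frame.
#' @export
cmd_simulate <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  stopifnot(inherits(spec, "cohort_spec"))
  rec <- generate_cohort(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_taxonomy(spec$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  write_cohort_spec(spec, file.path(out_dir, "spec.yaml"))
  write_records(rec, file.path(out_dir, "records.tsv"), tree = spec$taxonomy)
  eff <- spec$effect_log_ratio
  if (length(eff)) {
    type <- ifelse(names(eff) %in% spec$taxa, "taxon", "function")
    exp_tx <- expected_log_ratio(spec, "genus")
    exp_ko <- expected_log_ratio(spec, "KO")
    expected <- ifelse(type == "taxon",
                       exp_tx[names(eff)], exp_ko[names(eff)])
    truth <- data.frame(feature = names(eff), type = type,
                        effect_log10 = unname(eff),
                        expected_mean_log_ratio = unname(expected),
                        stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(feature = character(0), type = character(0),
                        effect_log10 = numeric(0),
                        expected_mean_log_ratio = numeric(0))
  }
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(rec)
}

#' Run the full comparative MG/MP analysis
#'
#' Executes, in order: optional per-subject MG subsampling; filtered
#' relative-abundance tables per layer and level; MP-vs-MG ratio tests per
#' level; a Firmicutes-vs-Bacteroidetes (or user-chosen partition) KO-level
#' ratio test per layer; genus- and KO-level Bray-Curtis dissimilarity
#' contrasts between layers; CV conservation classes per layer; per-subject
#' between-layer Spearman summaries; and the MP attribution matrix with
#' pathway/phylum shares. All results are written as TSVs under `out_dir`
#' together with a `manifest.txt` recording package version, seed and
#' parameters; numeric outputs are byte-stable across reruns of the same
#' configuration.
#'
#' @param records Annotation records (data.frame or records TSV path).
#' @param taxonomy A taxonomy (or taxonomy TSV path).
#' @param pathways A [pathway_config()] (or pathway file path).
#' @param out_dir Output directory.
#' @param levels Taxonomic/functional levels to analyse.
#' @param contrast A [contrast_spec()] (cf, alpha, log base, filter).
#' @param filter_threshold Mean-abundance filter for exported tables and CV.
#' @param subsample Optional per-subject MG subsampling depth.
#' @param seed Seed for the subsampling step.
#' @param denominator Passed to [relative_abundance()].
#' @param partition Length-2 character vector of disjoint taxon subtrees for
#'   the within-layer contrast (default Firmicutes vs Bacteroidetes).
#' @return Invisibly, a list with all intermediate objects (`tables`,
#'   `ratio_tests`, `partition_tests`, `dissimilarity`, `cv`, `spearman`,
#'   `attribution`, `shares`).
#' @export
cmd_full_analysis <- function(records, taxonomy, pathways = default_pathways(),
                              out_dir,
                              levels = c("phylum", "genus", "KO"),
                              contrast = contrast_spec(),
                              filter_threshold = 1e-4,
                              subsample = NULL, seed = 1L,
                              denominator = c("annotated", "all"),
                              partition = c("p__Firmicutes", "p__Bacteroidetes")) {
  denominator <- match.arg(denominator)
  if (is.character(taxonomy)) {
    if (!file.exists(taxonomy))
      stop_mgmp("taxonomy file not found: ", taxonomy, class = "mgmp_config_error")
    taxonomy <- read_taxonomy(taxonomy)
  }
  if (is.character(records)) {
    if (!file.exists(records))
      stop_mgmp("records file not found: ", records, class = "mgmp_config_error")
    records <- read_records(records)
  }
  if (is.character(pathways)) {
    if (!file.exists(pathways))
      stop_mgmp("pathway file not found: ", pathways, class = "mgmp_config_error")
    pathways <- read_pathways(pathways)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(subsample))
    records <- subsample_units(records, subsample, seed = seed, layers = "MG")

  res <- list()
  # filtered abundance tables per layer and level
  res$tables <- list()
  for (layer in c("MG", "MP")) {
    for (lv in levels) {
      tab <- suppressMessages(
        relative_abundance(records, lv, taxonomy, layer = layer,
                           denominator = denominator))
      key <- paste(layer, lv, sep = ".")
      res$tables[[key]] <- tab
      write_abundance(filter_features(tab, filter_threshold),
                      file.path(out_dir, sprintf("abundance_%s_%s.tsv",
                                                 tolower(layer), gsub(":", "_", lv))))
    }
  }

  # MP vs MG ratio tests per level
  res$ratio_tests <- list()
  for (lv in levels) {
    rt <- ratio_test(res$tables[[paste0("MP.", lv)]],
                     res$tables[[paste0("MG.", lv)]], contrast)
    res$ratio_tests[[lv]] <- rt
    write_ratio_test(rt, file.path(out_dir, sprintf("ratio_mp_mg_%s.tsv",
                                                    gsub(":", "_", lv))))
  }

  # within-layer partition contrast at KO level
  res$partition_tests <- list()
  pspec <- contrast
  pspec$mode <- "partition"
  for (layer in c("MG", "MP")) {
    pc <- partition_contrast(records, partition[1L], partition[2L], taxonomy,
                             level = "KO", layer = layer)
    rt <- ratio_test(pc$a, pc$b, pspec)
    res$partition_tests[[layer]] <- rt
    write_ratio_test(rt, file.path(out_dir, sprintf("ratio_partition_%s_ko.tsv",
                                                    tolower(layer))))
  }

  # dissimilarity contrasts (genus and KO)
  res$dissimilarity <- list()
  for (lv in intersect(c("genus", "KO"), levels)) {
    bmg <- bray_curtis(res$tables[[paste0("MG.", lv)]])
    bmp <- bray_curtis(res$tables[[paste0("MP.", lv)]])
    cmp <- compare_dissimilarity(bmg, bmp)
    res$dissimilarity[[lv]] <- cmp
    df <- data.frame(bmg[c("subject_a", "subject_b")], bc_mg = bmg$bc,
                     bc_mp = bmp$bc)
    utils::write.table(df, file.path(out_dir, sprintf("dissimilarity_%s.tsv", lv)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # CV conservation classes on filtered tables
  res$cv <- list()
  for (layer in c("MG", "MP")) {
    for (lv in intersect(c("genus", "KO"), levels)) {
      key <- paste(layer, lv, sep = ".")
      cv <- suppressMessages(
        cv_classify(filter_features(res$tables[[key]], filter_threshold)))
      cv$layer <- layer
      res$cv[[key]] <- cv
      utils::write.table(cv, file.path(out_dir, sprintf("variability_%s_%s.tsv",
                                                        tolower(layer), lv)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # per-subject between-layer Spearman correlation per level
  res$spearman <- list()
  sp_rows <- list()
  for (lv in levels) {
    sp <- suppressMessages(
      spearman_between_layers(res$tables[[paste0("MG.", lv)]],
                              res$tables[[paste0("MP.", lv)]]))
    res$spearman[[lv]] <- sp
    sp_rows[[lv]] <- data.frame(level = lv, rho_mean = sp$mean, rho_sd = sp$sd,
                                n_subjects = sp$n_used)
  }
  utils::write.table(do.call(rbind, sp_rows),
                     file.path(out_dir, "spearman_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # attribution (MP layer)
  n_subj <- length(unique(records$subject))
  res$attribution <- build_attribution(records, pathways, taxonomy,
                                       n_subjects = n_subj, cf = contrast$cf,
                                       layer = "MP")
  write_attribution(res$attribution, file.path(out_dir, "attribution_mp.tsv"))
  res$shares <- list(pathway = pathway_shares(res$attribution),
                     taxon = taxon_shares(res$attribution))
  sh <- rbind(
    data.frame(kind = "pathway", id = names(res$shares$pathway),
               share = unname(res$shares$pathway)),
    data.frame(kind = "phylum", id = names(res$shares$taxon),
               share = unname(res$shares$taxon))
  )
  utils::write.table(sh, file.path(out_dir, "shares.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- c(
    sprintf("package: mgmp %s", as.character(utils::packageVersion("mgmp"))),
    sprintf("seed: %s", seed),
    sprintf("levels: %s", paste(levels, collapse = ",")),
    sprintf("cf: %g", contrast$cf),
    sprintf("alpha: %g", contrast$alpha),
    sprintf("filter_threshold: %g", filter_threshold),
    sprintf("subsample: %s", subsample %||% "none"),
    sprintf("denominator: %s", denominator),
    sprintf("partition: %s", paste(partition, collapse = " vs ")),
    "outputs:",
    paste0("  ", sort(list.files(out_dir)))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(res)
}
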