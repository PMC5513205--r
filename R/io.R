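# Plain-text (TSV / YAML) round-tripping for records, abundance tables,
# ratio-test results and cohort specs. Upstream annotation tools in this
# niche emit tab-delimited hit tables, so everything stays tab-delimited.

#' Read / write annotation records as TSV
#'
#' Dialect: columns `subject`, `layer`, `unit`, `taxon_path` (semicolon
#' root-to-node lineage, or a bare taxon id), `ko`, `weight`.
#'
#' @param records Record data.frame.
#' @param path File path.
#' @param tree Optional taxonomy used to serialise full lineages on write.
#' @return `read_records` returns the record data.frame with `taxon` set to
#'   the lineage leaf.
#' @export
write_records <- function(records, path, tree = NULL) {
  df <- records
  df$taxon_path <- if (!is.null(tree)) lineage(tree, df$taxon) else df$taxon
  df <- df[c("subject", "layer", "unit", "taxon_path", "ko", "weight")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("subject", "layer", "unit", "taxon_path", "ko", "weight")
  if (!all(need %in% names(df)))
    stop_mgmp("records TSV needs columns: ", paste(need, collapse = ", "),
              class = "mgmp_config_error")
  if (!all(df$layer %in% c("MG", "MP")))
    stop_mgmp("layer must be MG or MP", class = "mgmp_config_error")
  df$taxon <- lineage_leaf(df$taxon_path)
  df[c("subject", "layer", "unit", "taxon", "ko", "weight")]
}

#' Read / write an abundance table as TSV with a metadata header
#'
#' Metadata (layer, level, filter state) is stored in `#`-prefixed sidecar
#' lines above the tab-separated matrix (first column `feature`, remaining
#' columns subject ids).
#'
#' @param table An [abundance_table()].
#' @param path File path.
#' @export
write_abundance <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# layer: %s", table$layer),
               sprintf("# level: %s", table$level),
               sprintf("# filtered: %s", table$filtered)), con)
  df <- data.frame(feature = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), ": ", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- kv[2L]
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df$feature
  abundance_table(m, meta$layer %||% "MG", meta$level %||% "genus",
                  filtered = identical(meta$filtered, "TRUE"))
}

#' Write ratio-test results as a sorted TSV
#'
#' One row per feature (sorted by mean log ratio) with the statistics needed
#' to recreate differential-feature bar graphs.
#'
#' @param x A [ratio_test()] object.
#' @param path File path.
#' @export
write_ratio_test <- function(x, path) {
  stopifnot(inherits(x, "ratio_test"))
  tab <- x$table[order(x$table$mean_log_ratio), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise / load a cohort spec as YAML
#'
#' The taxonomy is stored separately (see [write_taxonomy()]); the YAML holds
#' a `taxonomy` entry with its file name, resolved relative to the YAML's
#' directory on read.
#'
#' @param spec A [cohort_spec()].
#' @param path YAML path.
#' @param taxonomy_file File name recorded for the taxonomy TSV.
#' @export
write_cohort_spec <- function(spec, path, taxonomy_file = "taxonomy.tsv") {
  obj <- list(
    taxonomy = taxonomy_file,
    n_subjects = spec$n_subjects,
    base_taxon_props = as.list(spec$base_taxon_props),
    functions = spec$functions,
    function_profile = lapply(seq_along(spec$taxa), function(i)
      as.list(spec$function_profile[i, ])),
    taxon_dispersion = spec$taxon_dispersion,
    mg_depth = spec$mg_depth, mp_depth = spec$mp_depth,
    effect_log_ratio = as.list(spec$effect_log_ratio),
    unannotated_fraction = spec$unannotated_fraction,
    mg_function_dispersion = spec$mg_function_dispersion,
    mp_function_dispersion = spec$mp_function_dispersion,
    seed = spec$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @param taxonomy Optional pre-built taxonomy (otherwise read from the file
#'   named in the YAML).
#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path, taxonomy = NULL) {
  obj <- yaml::read_yaml(path)
  need <- c("base_taxon_props", "functions", "function_profile")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop_mgmp("cohort spec YAML missing field(s): ", paste(miss, collapse = ", "),
              class = "mgmp_config_error")
  if (is.null(taxonomy)) {
    tf <- file.path(dirname(path), obj$taxonomy %||% "taxonomy.tsv")
    if (!file.exists(tf))
      stop_mgmp("taxonomy file not found: ", tf, class = "mgmp_config_error")
    taxonomy <- read_taxonomy(tf)
  }
  props <- unlist(obj$base_taxon_props)
  funs <- unlist(obj$functions)
  profile <- do.call(rbind, lapply(obj$function_profile, function(r) unlist(r)[funs]))
  rownames(profile) <- names(props)
  colnames(profile) <- funs
  cohort_spec(
    taxonomy, props, profile,
    n_subjects = obj$n_subjects %||% 15L,
    taxon_dispersion = obj$taxon_dispersion %||% 10,
    mg_depth = obj$mg_depth %||% 200000, mp_depth = obj$mp_depth %||% 7000,
    effect_log_ratio = unlist(obj$effect_log_ratio) %||% numeric(0),
    unannotated_fraction = obj$unannotated_fraction %||% 0,
    mg_function_dispersion = obj$mg_function_dispersion %||% Inf,
    mp_function_dispersion = obj$mp_function_dispersion %||% Inf,
    seed = obj$seed %||% 1L
  )
}
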