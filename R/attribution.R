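# Function-by-taxon attribution: pathway-grouped KO x genus matrices of mean
# relative abundance with prevalence-based retention rules, answering "who is
# doing what" for a set of metabolic pathways.

#' Pathway membership configuration
#'
#' @param pathways Named list: pathway name -> character vector of member KO
#'   ids. A KO may belong to at most one pathway; names must be unique.
#' @return An object of class `pathway_config`.
#' @export
pathway_config <- function(pathways) {
  stopifnot(is.list(pathways), length(pathways) >= 1)
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)) ||
      any(names(pathways) == ""))
    stop_mgmp("pathways must have unique non-empty names", class = "mgmp_config_error")
  kos <- unlist(pathways, use.names = FALSE)
  if (anyDuplicated(kos))
    stop_mgmp("KO(s) assigned to more than one pathway: ",
              paste(unique(kos[duplicated(kos)]), collapse = ", "),
              class = "mgmp_config_error")
  structure(lapply(pathways, as.character), class = "pathway_config")
}

#' Read / write a pathway configuration
#'
#' Plain-text format: one pathway per line, `name<TAB>KO1,KO2,...`;
#' `#` comment lines allowed.
#'
#' @param path File path.
#' @export
read_pathways <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop_mgmp("malformed pathway line(s): ", paste(lines[bad], collapse = "; "),
              class = "mgmp_config_error")
  pw <- lapply(parts, function(p) strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  names(pw) <- vapply(parts, `[`, character(1), 1L)
  pathway_config(pw)
}

#' @param config A `pathway_config` to serialise.
#' @rdname read_pathways
#' @export
write_pathways <- function(config, path) {
  lines <- vapply(names(config), function(nm)
    paste0(nm, "\t", paste(config[[nm]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a pathway-grouped function x taxon attribution matrix
#'
#' From one layer's records (typically MP), computes the mean relative
#' abundance (over all `n_subjects`, zeros included) of every KO x genus
#' combination at the `"KO:genus"` level, then assembles a matrix whose rows
#' are pathway totals plus retained member KOs and whose columns are phylum
#' totals plus retained genera:
#'
#' * a KO row is retained only if the KO is detected (any taxon) in at least
#'   `ceiling(n_subjects / 2)` subjects;
#' * a genus column is retained only if the genus expresses at least one
#'   configured KO in at least 2 subjects;
#' * each pathway row aggregates all member KOs found in at least one
#'   subject, and each phylum column aggregates all its member genera,
#'   whether or not individually retained;
#' * a grand-total row and column are included.
#'
#' @param records Single-layer annotation records.
#' @param config A [pathway_config()].
#' @param tree The taxonomy.
#' @param n_subjects Cohort size used for means and the retention rule
#'   (default: number of distinct subjects in `records`).
#' @param cf Correction factor for the log display values (cells are
#'   `log10(mean + cf)` so empty cells stay finite).
#' @param layer Optional layer subset.
#' @return An object of class `function_taxon_matrix`: `abundance` (pre-log
#'   means), `values` (log10(mean + cf)), `prevalence` (subjects with nonzero
#'   abundance per cell), `row_info`, `col_info`, `n_subjects`, `config`.
#' @export
build_attribution <- function(records, config, tree, n_subjects = NULL,
                              cf = 1e-5, layer = NULL) {
  stopifnot(inherits(config, "pathway_config"), inherits(tree, "taxonomy"))
  if (!is.null(layer)) records <- records[records$layer == layer, , drop = FALSE]
  if (!length(config)) stop_mgmp("empty pathway config", class = "mgmp_config_error")
  n_subjects <- n_subjects %||% length(unique(records$subject))
  tab <- suppressMessages(relative_abundance(records, "KO:genus", tree))
  v <- tab$values
  ko <- sub("\\|.*$", "", rownames(v))
  genus <- sub("^[^|]*\\|", "", rownames(v))
  cfg_kos <- unlist(unname(config))
  sel <- ko %in% cfg_kos
  if (!any(sel))
    stop_mgmp("no configured KO observed in the records", class = "mgmp_config_error")
  v <- v[sel, , drop = FALSE]; ko <- ko[sel]; genus <- genus[sel]
  phylum <- ancestor_at_rank(tree, genus, "phylum")

  # per-cell cohort means (absent subjects count as zeros) and prevalence
  mean_cell <- rowSums(v) / n_subjects
  prev_cell <- rowSums(v > 0)

  # KO-level detection across any taxon
  ko_prev <- vapply(split(seq_along(ko), ko),
                    function(i) sum(colSums(v[i, , drop = FALSE]) > 0), numeric(1))
  need <- ceiling(n_subjects / 2)
  pathway_of <- structure(rep(names(config), lengths(config)), names = cfg_kos)
  kos_seen <- names(ko_prev)[ko_prev >= 1]
  kos_kept <- names(ko_prev)[ko_prev >= need]

  # genus retention: expresses >= 1 configured KO in >= 2 subjects
  genus_prev <- vapply(split(seq_along(genus), genus),
                       function(i) sum(colSums(v[i, , drop = FALSE] > 0) > 0), numeric(1))
  genera_kept <- names(genus_prev)[genus_prev >= 2]
  phyla <- sort(unique(phylum[!is.na(phylum)]))

  row_ids <- character(0); row_type <- character(0); row_pathway <- character(0)
  for (pw in names(config)) {
    row_ids <- c(row_ids, pw)
    row_type <- c(row_type, "pathway"); row_pathway <- c(row_pathway, pw)
    member <- intersect(config[[pw]], kos_kept)
    row_ids <- c(row_ids, member)
    row_type <- c(row_type, rep("ko", length(member)))
    row_pathway <- c(row_pathway, rep(pw, length(member)))
  }
  row_ids <- c(row_ids, "total")
  row_type <- c(row_type, "total"); row_pathway <- c(row_pathway, NA)

  col_ids <- character(0); col_type <- character(0); col_phylum <- character(0)
  for (ph in phyla) {
    col_ids <- c(col_ids, ph)
    col_type <- c(col_type, "phylum"); col_phylum <- c(col_phylum, ph)
    member <- sort(intersect(unique(genus[!is.na(phylum) & phylum == ph]), genera_kept))
    col_ids <- c(col_ids, member)
    col_type <- c(col_type, rep("genus", length(member)))
    col_phylum <- c(col_phylum, rep(ph, length(member)))
  }
  col_ids <- c(col_ids, "total")
  col_type <- c(col_type, "total"); col_phylum <- c(col_phylum, NA)

  cell_sum <- function(row_kos, col_genera) {
    i <- ko %in% row_kos & genus %in% col_genera
    sum(mean_cell[i])
  }
  cell_prev <- function(row_kos, col_genera) {
    i <- ko %in% row_kos & genus %in% col_genera
    if (!any(i)) return(0)
    sum(colSums(v[i, , drop = FALSE] > 0) > 0)
  }
  kos_for_row <- function(r, ty, pw) {
    if (ty == "pathway") intersect(config[[pw]], kos_seen)
    else if (ty == "total") kos_seen
    else r
  }
  genera_for_col <- function(cl, ty, ph) {
    if (ty == "phylum") unique(genus[!is.na(phylum) & phylum == ph])
    else if (ty == "total") unique(genus)
    else cl
  }
  A <- matrix(0, length(row_ids), length(col_ids), dimnames = list(row_ids, col_ids))
  P <- A
  for (i in seq_along(row_ids)) {
    rk <- kos_for_row(row_ids[i], row_type[i], row_pathway[i])
    for (j in seq_along(col_ids)) {
      cg <- genera_for_col(col_ids[j], col_type[j], col_phylum[j])
      A[i, j] <- cell_sum(rk, cg)
      P[i, j] <- cell_prev(rk, cg)
    }
  }
  structure(
    list(abundance = A, values = log10(A + cf), prevalence = P,
         row_info = data.frame(id = row_ids, type = row_type,
                               pathway = row_pathway, stringsAsFactors = FALSE),
         col_info = data.frame(id = col_ids, type = col_type,
                               phylum = col_phylum, stringsAsFactors = FALSE),
         n_subjects = n_subjects, cf = cf, config = config),
    class = "function_taxon_matrix"
  )
}

#' @export
print.function_taxon_matrix <- function(x, ...) {
  cat(sprintf("<function_taxon_matrix> %d pathways / %d retained KOs x %d phyla / %d retained genera (n = %d subjects)\n",
              sum(x$row_info$type == "pathway"), sum(x$row_info$type == "ko"),
              sum(x$col_info$type == "phylum"), sum(x$col_info$type == "genus"),
              x$n_subjects))
  invisible(x)
}

#' Pathway and phylum shares of the attribution total
#'
#' Fractions of the grand-total (pre-log) abundance contributed by each
#' pathway row ([pathway_shares()]) or each phylum column ([taxon_shares()]);
#' the fractions sum to 1.
#'
#' @param matrix A [build_attribution()] result.
#' @return Named numeric vector of fractions.
#' @export
pathway_shares <- function(matrix) {
  stopifnot(inherits(matrix, "function_taxon_matrix"))
  i <- matrix$row_info$type == "pathway"
  tot <- matrix$abundance[, "total"][i]
  if (sum(tot) <= 0)
    stop_mgmp("zero grand total", class = "mgmp_domain_error")
  tot / sum(tot)
}

#' @rdname pathway_shares
#' @export
taxon_shares <- function(matrix) {
  stopifnot(inherits(matrix, "function_taxon_matrix"))
  j <- matrix$col_info$type == "phylum"
  tot <- matrix$abundance["total", ][j]
  if (sum(tot) <= 0)
    stop_mgmp("zero grand total", class = "mgmp_domain_error")
  tot / sum(tot)
}

#' Write an attribution matrix and its prevalence sidecar as TSV
#'
#' @param matrix A `function_taxon_matrix`.
#' @param path Output path for the log-abundance matrix; the prevalence
#'   matrix goes to `<path>.prevalence`.
#' @export
write_attribution <- function(matrix, path) {
  df <- data.frame(row = rownames(matrix$values), row_type = matrix$row_info$type,
                   matrix$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pf <- data.frame(row = rownames(matrix$prevalence), matrix$prevalence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(pf, paste0(path, ".prevalence"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
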