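# Relative-abundance tables: aggregation of annotation records at a
# taxonomic rank, KO level, or combined KO x rank level, with low-abundance
# filtering and per-subject random subsampling.

#' Construct an abundance table
#'
#' Mostly internal; users normally obtain tables from [relative_abundance()].
#'
#' @param values Numeric matrix, features x subjects, entries in `[0, 1]`.
#' @param layer `"MG"` or `"MP"`.
#' @param level Annotation level label (a rank, `"KO"`, or `"KO:<rank>"`).
#' @param filtered Whether a low-abundance filter has been applied (columns of
#'   a filtered table no longer sum to 1).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, layer, level, filtered = FALSE) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)),
            layer %in% c("MG", "MP"))
  if (any(values < 0))
    stop_mgmp("abundances must be non-negative", class = "mgmp_domain_error")
  if (anyDuplicated(rownames(values)))
    stop_mgmp("duplicate feature ids", class = "mgmp_structure_error")
  structure(list(values = values, layer = layer, level = level,
                 filtered = isTRUE(filtered)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> layer=%s level=%s: %d features x %d subjects%s\n",
              x$layer, x$level, nrow(x$values), ncol(x$values),
              if (x$filtered) " (filtered)" else ""))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Feature and subject ids of an abundance table
#' @param table An `abundance_table`.
#' @export
features <- function(table) rownames(table$values)

#' @rdname features
#' @export
subjects <- function(table) colnames(table$values)

# Map each record to its feature id at the requested level (NA = excluded).
record_feature <- function(records, level, tree) {
  if (level == "KO") {
    ifelse(records$ko == "unannotated", NA_character_, records$ko)
  } else if (grepl("^KO:", level)) {
    rk <- sub("^KO:", "", level)
    tx <- ancestor_at_rank(tree, records$taxon, rk)
    ifelse(is.na(tx) | records$ko == "unannotated", NA_character_,
           paste(records$ko, tx, sep = "|"))
  } else {
    if (!level %in% taxonomy_ranks())
      stop_mgmp("unknown level: ", level, class = "mgmp_config_error")
    ancestor_at_rank(tree, records$taxon, level)
  }
}

#' Relative abundance of features at an annotation level
#'
#' Aggregates record weights by feature (a taxon mapped to the requested rank
#' via the taxonomy, a KO, or a KO/taxon pair) and divides by the per-subject
#' total, so that each subject's abundances sum to 1 over detected features.
#' Records that cannot be mapped to the level (taxa placed above the rank,
#' unassigned taxa, unannotated KOs) are excluded from that level.
#'
#' @param records Annotation record data.frame (columns `subject`, `layer`,
#'   `taxon`, `ko`, `weight`); must contain a single layer unless `layer` is
#'   given.
#' @param level A rank label from [taxonomy_ranks()], `"KO"`, or
#'   `"KO:<rank>"` (e.g. `"KO:genus"`).
#' @param tree The active taxonomy (may be `NULL` for pure-`"KO"` tables).
#' @param layer Optional layer to subset to before aggregating.
#' @param denominator `"annotated"` (default): divide by the total weight of
#'   records mapped at this level, so columns sum to 1 over detected features;
#'   `"all"`: divide by the subject's total record weight including unmapped
#'   units.
#' @return An [abundance_table()]; subjects with no records are absent from
#'   the columns (with a message).
#' @export
relative_abundance <- function(records, level, tree = NULL,
                               layer = NULL,
                               denominator = c("annotated", "all")) {
  denominator <- match.arg(denominator)
  if (!is.null(layer)) records <- records[records$layer == layer, , drop = FALSE]
  lay <- unique(records$layer)
  if (length(lay) != 1L)
    stop_mgmp("records must come from a single layer (got: ",
              paste(lay, collapse = ", "), ")", class = "mgmp_config_error")
  if (any(records$weight < 1))
    stop_mgmp("record weights must be >= 1", class = "mgmp_domain_error")
  feat <- record_feature(records, level, tree)
  all_subj <- sort(unique(records$subject))
  keep <- !is.na(feat)
  tot <- if (denominator == "all") {
    tapply(records$weight, records$subject, sum)
  } else {
    tapply(records$weight[keep], records$subject[keep], sum)
  }
  rec <- records[keep, , drop = FALSE]
  feat <- feat[keep]
  if (!nrow(rec))
    stop_mgmp("no records mappable at level ", level, class = "mgmp_config_error")
  fids <- sort(unique(feat))
  sids <- sort(unique(rec$subject))
  dropped <- setdiff(all_subj, sids)
  if (length(dropped))
    message("relative_abundance: no mappable records for subject(s) ",
            paste(dropped, collapse = ", "), "; column(s) omitted")
  m <- matrix(0, nrow = length(fids), ncol = length(sids),
              dimnames = list(fids, sids))
  idx <- cbind(match(feat, fids), match(rec$subject, sids))
  counts <- tapply(rec$weight, list(factor(feat, fids), factor(rec$subject, sids)), sum)
  counts[is.na(counts)] <- 0
  m[] <- counts
  m <- sweep(m, 2L, as.numeric(tot[sids]), `/`)
  abundance_table(m, lay, level)
}

#' Filter features on cohort mean relative abundance
#'
#' Keeps features whose mean relative abundance across subjects (zeros
#' included) strictly exceeds `threshold`; columns are not renormalised
#' afterwards. The default `1e-4` is the conventional 0.01 percent cut used
#' before differential analysis.
#'
#' @param table An [abundance_table()].
#' @param threshold Strict lower bound on the cohort mean abundance.
#' @return A filtered `abundance_table` (possibly with zero rows).
#' @export
filter_features <- function(table, threshold = 1e-4) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- rowMeans(table$values) > threshold
  abundance_table(table$values[keep, , drop = FALSE], table$layer, table$level,
                  filtered = TRUE)
}

#' Randomly subsample annotation units per subject
#'
#' Draws, for each subject of the targeted layer(s), a uniform sample of `n`
#' units without replacement (multivariate hypergeometric over the weighted
#' records), emulating read subsampling to a common depth. Deterministic
#' given `seed`.
#'
#' @param records Annotation records.
#' @param n Units to retain per subject and layer.
#' @param seed Integer seed.
#' @param layers Layers to subsample (default `"MG"`, the layer whose depth
#'   varies most between subjects); other layers pass through untouched.
#' @return Records with reduced weights (zero-weight rows dropped). Errors if
#'   any targeted subject has fewer than `n` units, naming the subject.
#' @export
subsample_units <- function(records, n, seed = 1L, layers = "MG") {
  stopifnot(n >= 0)
  key <- paste(records$subject, records$layer, sep = "\r")
  target <- records$layer %in% layers
  out_w <- records$weight
  with_seed(seed, {
    for (grp in sort(unique(key[target]))) {
      idx <- which(key == grp & target)
      w <- records$weight[idx]
      N <- sum(w)
      if (n > N) {
        sj <- records$subject[idx[1L]]
        stop_mgmp("subsample size ", n, " exceeds the ", N,
                  " available units for subject ", sj, " (",
                  records$layer[idx[1L]], ")", class = "mgmp_depth_error")
      }
      # sequential conditional hypergeometric draws over the weighted rows
      drawn <- integer(length(idx))
      rem_total <- N
      rem_draw <- as.integer(n)
      for (i in seq_along(idx)) {
        if (rem_draw == 0L) break
        ki <- stats::rhyper(1L, w[i], rem_total - w[i], rem_draw)
        drawn[i] <- ki
        rem_draw <- rem_draw - ki
        rem_total <- rem_total - w[i]
      }
      out_w[idx] <- drawn
    }
  })
  rec <- records
  rec$weight <- out_w
  rec <- rec[rec$weight > 0L, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
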