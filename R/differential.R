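# Per-subject log abundance ratio statistics: the core contrast between
# functional potential (MG) and expression (MP), or between two taxonomic
# partitions within one layer (e.g. Firmicutes vs Bacteroidetes per KO).
#
# For each feature, the per-subject log10((a + CF)/(b + CF)) ratios are
# tested for deviation from zero with a one-sample two-tailed t-test; raw
# p-values are Benjamini-Hochberg adjusted across all tested features.

#' Contrast settings for the log-ratio test
#'
#' @param mode `"layer"` (MP vs MG) or `"partition"` (two taxon subtrees
#'   within one layer); informational, recorded in results.
#' @param cf Correction factor added to both numerator and denominator before
#'   the log, removing the discontinuity when a feature is missing in one
#'   condition. Default `1e-5` (one hundredth of the 0.01 percent abundance
#'   filter).
#' @param alpha FDR level for the significance call (default 0.05).
#' @param log_base Base of the logarithm (default 10, matching the
#'   power-of-ten form of `cf`).
#' @param filter_threshold Features are tested only if their mean relative
#'   abundance across the pooled subject columns of both conditions strictly
#'   exceeds this value (default `1e-4`); `NULL` disables the filter.
#' @export
contrast_spec <- function(mode = c("layer", "partition"), cf = 1e-5,
                          alpha = 0.05, log_base = 10,
                          filter_threshold = 1e-4) {
  mode <- match.arg(mode)
  if (cf <= 0) stop_mgmp("cf must be > 0", class = "mgmp_config_error")
  if (alpha <= 0 || alpha >= 1)
    stop_mgmp("alpha must be in (0, 1)", class = "mgmp_config_error")
  structure(list(mode = mode, cf = cf, alpha = alpha, log_base = log_base,
                 filter_threshold = filter_threshold),
            class = "contrast_spec")
}

#' Correction-factor log ratio
#'
#' `log_ratio(a, b)` returns `log10((a + cf) / (b + cf))`, elementwise. The
#' additive correction factor keeps the ratio defined and continuous for all
#' non-negative abundances (both-zero gives exactly 0) and converges to the
#' naive log ratio when both abundances are large relative to `cf`.
#'
#' @param a,b Non-negative abundances (vectors or matrices, recycled).
#' @param cf Correction factor, > 0.
#' @param base Log base (default 10).
#' @export
log_ratio <- function(a, b, cf = 1e-5, base = 10) {
  if (any(a < 0) || any(b < 0))
    stop_mgmp("abundances must be non-negative", class = "mgmp_domain_error")
  if (cf <= 0) stop_mgmp("cf must be > 0", class = "mgmp_domain_error")
  log((a + cf) / (b + cf), base = base)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up adjusted p-values, capped at 1 (delegates to
#' [stats::p.adjust()] with `method = "BH"` after domain validation).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_mgmp("p-values must lie in [0, 1]", class = "mgmp_domain_error")
  stats::p.adjust(p, method = "BH")
}

# Align two abundance tables on the union of their features (missing = 0).
# Subjects must coincide exactly.
align_tables <- function(table_a, table_b) {
  sa <- subjects(table_a); sb <- subjects(table_b)
  if (!identical(sort(sa), sort(sb)))
    stop_mgmp("subject sets differ between the two tables",
              class = "mgmp_alignment_error")
  subj <- sort(sa)
  feats <- sort(union(features(table_a), features(table_b)))
  expand <- function(tab) {
    m <- matrix(0, length(feats), length(subj), dimnames = list(feats, subj))
    m[features(tab), ] <- tab$values[, subj, drop = FALSE]
    m
  }
  list(a = expand(table_a), b = expand(table_b), features = feats, subjects = subj)
}

#' Test per-subject log abundance ratios against zero
#'
#' The package's core estimator. For every feature in the union of the two
#' tables' features (absent = 0 abundance), the per-subject log10 ratio
#' `(a + cf)/(b + cf)` is computed and the set of per-subject ratios is
#' tested for deviation from zero with a one-sample two-tailed t-test; the
#' global log ratio is the arithmetic mean over subjects. Raw p-values are
#' BH-adjusted across all tested features and called significant at
#' `spec$alpha`.
#'
#' Features are tested only after the mean-abundance filter in
#' `spec$filter_threshold`, computed over the pooled columns of both
#' conditions. Degenerate ratio vectors (zero variance) give `p = 1` when the
#' mean is also zero (no evidence) and are flagged `degenerate` with the raw
#' p floored at machine precision when the mean is nonzero.
#'
#' @param table_a,table_b [abundance_table()]s over identical subjects
#'   (numerator and denominator condition, e.g. MP and MG).
#' @param spec A [contrast_spec()].
#' @return An object of class `ratio_test`: the per-feature results are in
#'   `$table` (feature, mean_log_ratio, t_statistic, p_raw, p_adjusted,
#'   significant, degenerate), the per-subject log-ratio matrix in
#'   `$log_ratios`. Methods: `print`, `summary`, `coef` (named
#'   mean-log-ratio vector), `plot` (top differential features bar chart),
#'   `as.data.frame`.
#' @examples
#' rec <- null_cohort(n_subjects = 5, n_features = 10, depth = 1e4)
#' tr <- attr(rec, "spec")$taxonomy
#' mp <- relative_abundance(rec, "genus", tr, layer = "MP")
#' mg <- relative_abundance(rec, "genus", tr, layer = "MG")
#' rt <- ratio_test(mp, mg)
#' summary(rt)
#' @export
ratio_test <- function(table_a, table_b, spec = contrast_spec()) {
  stopifnot(inherits(table_a, "abundance_table"),
            inherits(table_b, "abundance_table"),
            inherits(spec, "contrast_spec"))
  al <- align_tables(table_a, table_b)
  if (length(al$subjects) < 2)
    stop_mgmp("need >= 2 subjects", class = "mgmp_alignment_error")
  if (!is.null(spec$filter_threshold)) {
    keep <- rowMeans(cbind(al$a, al$b)) > spec$filter_threshold
    al$a <- al$a[keep, , drop = FALSE]
    al$b <- al$b[keep, , drop = FALSE]
    al$features <- al$features[keep]
  }
  if (!length(al$features))
    stop_mgmp("no features pass the abundance filter", class = "mgmp_config_error")
  lr <- log_ratio(al$a, al$b, cf = spec$cf, base = spec$log_base)
  n <- length(al$subjects)
  m <- rowMeans(lr)
  s <- apply(lr, 1L, stats::sd)
  tstat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, sign(m) * Inf))
  p <- ifelse(s > 0, 2 * stats::pt(-abs(tstat), df = n - 1),
              ifelse(m == 0, 1, .Machine$double.xmin))
  degen <- s == 0 & m != 0
  if (any(degen))
    message("ratio_test: ", sum(degen),
            " feature(s) with zero-variance nonzero ratios flagged degenerate")
  padj <- bh_adjust(p)
  res <- data.frame(
    feature = al$features,
    mean_log_ratio = m,
    t_statistic = tstat,
    p_raw = p,
    p_adjusted = padj,
    significant = padj <= spec$alpha,
    degenerate = degen,
    n_subjects = n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(table = res, log_ratios = lr, spec = spec,
         layers = c(a = table_a$layer, b = table_b$layer),
         level = table_a$level),
    class = "ratio_test"
  )
}

#' @export
print.ratio_test <- function(x, ...) {
  cat(sprintf("<ratio_test> %s: %d features, %d subjects, cf=%g, alpha=%g\n",
              x$level, nrow(x$table), x$table$n_subjects[1L],
              x$spec$cf, x$spec$alpha))
  cat(sprintf("  significant: %d (%d up, %d down)\n",
              sum(x$table$significant),
              sum(x$table$significant & x$table$mean_log_ratio > 0),
              sum(x$table$significant & x$table$mean_log_ratio < 0)))
  invisible(x)
}

#' @export
summary.ratio_test <- function(object, n = 10L, ...) {
  tab <- object$table[order(object$table$p_adjusted,
                            -abs(object$table$mean_log_ratio)), ]
  out <- list(n_features = nrow(tab),
              n_significant = sum(tab$significant),
              alpha = object$spec$alpha,
              top = utils::head(tab, n))
  class(out) <- "summary.ratio_test"
  out
}

#' @export
print.summary.ratio_test <- function(x, ...) {
  cat(sprintf("ratio test: %d/%d features significant at FDR %g\n",
              x$n_significant, x$n_features, x$alpha))
  print(x$top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ratio_test <- function(object, ...) {
  structure(object$table$mean_log_ratio, names = object$table$feature)
}

#' @export
as.data.frame.ratio_test <- function(x, ...) x$table

#' @param x A `ratio_test`.
#' @param n Number of top features (by |mean log ratio|, significant first)
#'   to display on each side.
#' @rdname ratio_test
#' @export
plot.ratio_test <- function(x, n = 10L, ...) {
  tab <- x$table[x$table$significant, , drop = FALSE]
  if (!nrow(tab)) tab <- x$table
  tab <- tab[order(tab$mean_log_ratio), ]
  sel <- unique(rbind(utils::head(tab, n), utils::tail(tab, n)))
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(sel$mean_log_ratio, names.arg = sel$feature, horiz = TRUE,
                    las = 1, cex.names = 0.7,
                    col = ifelse(sel$mean_log_ratio > 0, "firebrick", "steelblue"),
                    xlab = sprintf("mean log%g ratio (%s / %s)", x$spec$log_base,
                                   x$layers["a"], x$layers["b"]), ...)
  invisible(sel)
}

#' Split records into two taxon-partition abundance tables
#'
#' Builds, from one layer's records, two KO-level relative-abundance tables
#' restricted to two disjoint taxonomic subtrees (e.g. the Firmicutes and
#' Bacteroidetes phyla), each renormalised within its partition per subject.
#' Subjects with no units in one partition appear as all-zero columns there,
#' so the per-subject paired ratios stay defined.
#'
#' @param records Annotation records from a single layer (or use `layer`).
#' @param node_a,node_b Taxon ids of the two disjoint subtrees.
#' @param tree The taxonomy.
#' @param level Feature level for the tables (default `"KO"`).
#' @param layer Optional layer subset.
#' @return List with `a` and `b` abundance tables.
#' @export
partition_contrast <- function(records, node_a, node_b, tree, level = "KO",
                               layer = NULL) {
  if (!is.null(layer)) records <- records[records$layer == layer, , drop = FALSE]
  for (nd in c(node_a, node_b))
    if (!nd %in% tree$nodes)
      stop_mgmp("unknown partition node: ", nd, class = "mgmp_config_error")
  if (node_a %in% ancestors(tree, node_b) || node_b %in% ancestors(tree, node_a))
    stop_mgmp("partition subtrees overlap: ", node_a, " / ", node_b,
              class = "mgmp_config_error")
  subj <- sort(unique(records$subject))
  under <- function(node) {
    uniq <- unique(records$taxon)
    ok <- vapply(uniq, function(tx) {
      !is.na(tx) && tx != "unassigned" && tx %in% tree$nodes &&
        node %in% ancestors(tree, tx)
    }, logical(1))
    records[records$taxon %in% uniq[ok], , drop = FALSE]
  }
  build <- function(sub) {
    tab <- suppressMessages(relative_abundance(sub, level, tree))
    miss <- setdiff(subj, subjects(tab))
    if (length(miss)) {
      zeros <- matrix(0, nrow(tab$values), length(miss),
                      dimnames = list(features(tab), miss))
      v <- cbind(tab$values, zeros)
      tab <- abundance_table(v[, sort(colnames(v)), drop = FALSE],
                             tab$layer, tab$level)
    }
    tab
  }
  list(a = build(under(node_a)), b = build(under(node_b)))
}
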