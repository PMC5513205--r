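# Inter-individual variability analyses: Bray-Curtis dissimilarity contrasts
# between omic layers, coefficient-of-variation conservation classes, and
# per-subject between-layer Spearman correlation.

#' Pairwise Bray-Curtis dissimilarity between subjects
#'
#' For each (lexicographically ordered) subject pair, 1 - 2 * sum(min(x, y)) /
#' (sum(x) + sum(y)) over the table's features, computed with
#' [vegan::vegdist()]. Subjects with an all-zero profile produce `NA` pairs
#' (reported with a warning).
#'
#' @param table An [abundance_table()] with >= 2 subjects.
#' @return Data.frame with columns `subject_a`, `subject_b`, `bc`, one row
#'   per pair, pairs ordered lexicographically.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values[, sort(colnames(table$values)), drop = FALSE]
  if (ncol(v) < 2)
    stop_mgmp("need >= 2 subjects", class = "mgmp_config_error")
  zero <- colSums(v) == 0
  if (any(zero))
    warning("all-zero subject profile(s): ",
            paste(colnames(v)[zero], collapse = ", "),
            "; their pairs are undefined (NA)")
  d <- as.matrix(suppressWarnings(vegan::vegdist(t(v), method = "bray")))
  pr <- t(utils::combn(colnames(v), 2L))
  bc <- d[pr]
  bc[zero[pr[, 1L]] | zero[pr[, 2L]]] <- NA_real_
  data.frame(subject_a = pr[, 1L], subject_b = pr[, 2L], bc = bc,
             stringsAsFactors = FALSE)
}

#' Compare paired dissimilarity sets between two layers
#'
#' Wilcoxon signed-rank test (continuity-corrected normal approximation when
#' an exact p cannot be used, zero differences dropped) on the paired
#' Bray-Curtis values of the same subject pairs measured in two layers. A
#' two-tailed p is reported; the sign of `median_difference` (layer1 -
#' layer2) gives the direction.
#'
#' @param bc1,bc2 Outputs of [bray_curtis()] for the two layers (same subject
#'   pairs in the same order), or plain equal-length numeric vectors.
#' @return An object of class `dissimilarity_contrast` with fields `pairs`,
#'   `bc1`, `bc2`, `statistic` (signed-rank V), `p_two_tailed`,
#'   `median_difference`.
#' @export
compare_dissimilarity <- function(bc1, bc2) {
  pairs <- NULL
  if (is.data.frame(bc1) && is.data.frame(bc2)) {
    if (!identical(bc1[c("subject_a", "subject_b")],
                   bc2[c("subject_a", "subject_b")]))
      stop_mgmp("subject pairs differ between the two dissimilarity sets",
                class = "mgmp_alignment_error")
    pairs <- bc1[c("subject_a", "subject_b")]
    x <- bc1$bc; y <- bc2$bc
  } else {
    x <- as.numeric(bc1); y <- as.numeric(bc2)
    if (length(x) != length(y))
      stop_mgmp("paired vectors must have equal length",
                class = "mgmp_alignment_error")
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  d <- x - y
  if (all(d == 0)) {
    stat <- 0; p <- 1
  } else {
    wt <- stats::wilcox.test(x, y, paired = TRUE, correct = TRUE)
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(pairs = pairs, bc1 = x, bc2 = y, statistic = stat,
                 p_two_tailed = p, median_difference = stats::median(d)),
            class = "dissimilarity_contrast")
}

#' @export
print.dissimilarity_contrast <- function(x, ...) {
  cat(sprintf(
    "<dissimilarity_contrast> %d pairs: median BC %.3f vs %.3f (diff %+.3f), V=%g, two-tailed p=%.3g\n",
    length(x$bc1), stats::median(x$bc1), stats::median(x$bc2),
    x$median_difference, x$statistic, x$p_two_tailed))
  invisible(x)
}

#' Classify features as conserved or variable by coefficient of variation
#'
#' Per feature, CV = sd / mean across subjects (zeros included, so sparse
#' features are not biased towards conservation), reported in percent and
#' classified with strict thresholds: `variable` above `high`, `conserved`
#' below `low`, otherwise `intermediate`. Apply after the 0.01 percent
#' mean-abundance filter for cohort-level summaries.
#'
#' @param table An [abundance_table()].
#' @param high,low CV percent thresholds (defaults 150 and 60).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Data.frame with columns `feature`, `mean_abundance`, `cv_percent`,
#'   `klass`. Features with zero mean are skipped (with a message).
#' @export
cv_classify <- function(table, high = 150, low = 60,
                        sd_type = c("sample", "population")) {
  stopifnot(inherits(table, "abundance_table"), low < high)
  sd_type <- match.arg(sd_type)
  v <- table$values
  mu <- rowMeans(v)
  if (any(mu == 0))
    message("cv_classify: skipping ", sum(mu == 0), " feature(s) with zero mean")
  keep <- mu > 0
  v <- v[keep, , drop = FALSE]; mu <- mu[keep]
  n <- ncol(v)
  s <- apply(v, 1L, stats::sd)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  cv <- 100 * s / mu
  klass <- ifelse(cv > high, "variable", ifelse(cv < low, "conserved", "intermediate"))
  data.frame(feature = rownames(v), mean_abundance = unname(mu),
             cv_percent = unname(cv), klass = unname(klass),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-subject Spearman correlation between two layers
#'
#' For every subject, the Spearman rank correlation (average ranks on ties)
#' between that subject's MG and MP feature-abundance vectors, on the union
#' of both tables' features (missing = 0); the cohort mean and standard
#' deviation summarise layer agreement at the chosen level.
#'
#' @param table_mg,table_mp [abundance_table()]s over identical subjects.
#' @return An object of class `layer_correlation`: `per_subject` (named rho
#'   vector, `NA` where undefined), `mean`, `sd`, `n_used`. Subjects with
#'   fewer than 3 features detected in either layer are excluded (message).
#' @export
spearman_between_layers <- function(table_mg, table_mp) {
  al <- align_tables(table_mg, table_mp)
  rho <- vapply(seq_along(al$subjects), function(j) {
    x <- al$a[, j]; y <- al$b[, j]
    det <- x > 0 | y > 0
    if (sum(det) < 3) return(NA_real_)
    suppressWarnings(stats::cor(x, y, method = "spearman"))
  }, numeric(1))
  names(rho) <- al$subjects
  if (anyNA(rho))
    message("spearman_between_layers: rho undefined for subject(s) ",
            paste(al$subjects[is.na(rho)], collapse = ", "))
  ok <- !is.na(rho)
  structure(list(per_subject = rho, mean = mean(rho[ok]), sd = stats::sd(rho[ok]),
                 n_used = sum(ok), level = table_mg$level),
            class = "layer_correlation")
}

#' @export
print.layer_correlation <- function(x, ...) {
  cat(sprintf("<layer_correlation> %s: rho = %.2f +/- %.2f (mean +/- sd, n = %d subjects)\n",
              x$level, x$mean, x$sd, x$n_used))
  invisible(x)
}
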