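# Synthetic cohort generator.
#
# Communities are simulated with a Dirichlet-multinomial hierarchy: each
# subject's genus proportions are one Dirichlet draw centred on the cohort
# base composition; unit counts (MG reads, MP spectra) are multinomial at the
# layer's sequencing/identification depth over the joint genus x KO cells.
# Per-feature true log10 MP/MG effects are planted multiplicatively on the MP
# cell probabilities, which are then renormalised (compositional closure:
# realised ratios of non-effect features shift slightly; expectation helpers
# report the post-normalisation truth).

#' Specify a synthetic two-layer cohort
#'
#' @param taxonomy A [build_taxonomy()] tree containing every taxon in
#'   `base_taxon_props`.
#' @param base_taxon_props Named probability vector over (genus-level) taxa:
#'   the cohort-mean community composition. Must sum to 1 (tolerance 1e-9).
#' @param function_profile Numeric matrix, taxa x KO functions, each row a
#'   probability vector: the functional repertoire of each taxon. Row names
#'   must match `names(base_taxon_props)`.
#' @param n_subjects Number of subjects (default 15, >= 2).
#' @param taxon_dispersion Dirichlet concentration for between-subject
#'   compositional noise (per-subject proportions ~ Dirichlet(dispersion *
#'   base)); `Inf` disables subject-level variation.
#' @param mg_depth,mp_depth Expected units per subject for the metagenome
#'   (reads) and metaproteome (spectral counts) layers; defaults 200000 and
#'   7000 reflect a subsampled shotgun MG run and a typical LC-MS/MS PSM
#'   yield.
#' @param effect_log_ratio Named numeric vector of true log10 MP/MG effects;
#'   names must be taxa (rows) or functions (columns). A taxon effect applies
#'   to all that taxon's cells, a function effect to all that function's
#'   cells; effects add on the log scale. Zero/absent means null.
#' @param unannotated_fraction Fraction of each taxon's units carrying no
#'   functional annotation (`ko = "unannotated"`); default 0.
#' @param mg_function_dispersion,mp_function_dispersion Dirichlet
#'   concentrations for per-subject, per-layer noise on each taxon's function
#'   profile; `Inf` (default) means the profile is identical across subjects.
#'   Setting a finite `mp_function_dispersion` makes expressed functions more
#'   variable between subjects than the gene potential.
#' @param seed Integer seed; generation is fully reproducible given the spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [null_cohort()], [cohort_expectation()]
#' @export
cohort_spec <- function(taxonomy, base_taxon_props, function_profile,
                        n_subjects = 15L,
                        taxon_dispersion = 10,
                        mg_depth = 200000, mp_depth = 7000,
                        effect_log_ratio = numeric(0),
                        unannotated_fraction = 0,
                        mg_function_dispersion = Inf,
                        mp_function_dispersion = Inf,
                        seed = 1L) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  taxa <- names(base_taxon_props)
  if (is.null(taxa) || any(!taxa %in% taxonomy$nodes))
    stop_mgmp("base_taxon_props must be named by taxa present in the taxonomy",
              class = "mgmp_config_error")
  if (any(base_taxon_props < 0) || abs(sum(base_taxon_props) - 1) > 1e-9)
    stop_mgmp("base_taxon_props must be a probability vector (sum 1, tol 1e-9)",
              class = "mgmp_config_error")
  if (all(base_taxon_props == 0))
    stop_mgmp("degenerate all-zero taxon proportions", class = "mgmp_config_error")
  function_profile <- as.matrix(function_profile)
  if (!identical(rownames(function_profile), taxa))
    stop_mgmp("function_profile rows must match names(base_taxon_props)",
              class = "mgmp_config_error")
  funs <- colnames(function_profile)
  if (is.null(funs))
    stop_mgmp("function_profile must have KO column names", class = "mgmp_config_error")
  rs <- rowSums(function_profile)
  if (any(function_profile < 0) || any(abs(rs - 1) > 1e-9))
    stop_mgmp("function_profile rows must each sum to 1 (tol 1e-9)",
              class = "mgmp_config_error")
  if (mg_depth <= 0 || mp_depth <= 0)
    stop_mgmp("depths must be > 0", class = "mgmp_config_error")
  if (n_subjects < 2)
    stop_mgmp("n_subjects must be >= 2", class = "mgmp_config_error")
  if (unannotated_fraction < 0 || unannotated_fraction >= 1)
    stop_mgmp("unannotated_fraction must be in [0, 1)", class = "mgmp_config_error")
  if (length(effect_log_ratio)) {
    keys <- names(effect_log_ratio)
    unknown <- setdiff(keys, c(taxa, funs))
    if (is.null(keys) || length(unknown))
      stop_mgmp("effect_log_ratio keys not among taxa/functions: ",
                paste(unknown, collapse = ", "), class = "mgmp_config_error")
  }
  structure(
    list(taxonomy = taxonomy, taxa = taxa, functions = funs,
         base_taxon_props = base_taxon_props,
         function_profile = function_profile,
         n_subjects = as.integer(n_subjects),
         taxon_dispersion = taxon_dispersion,
         mg_depth = mg_depth, mp_depth = mp_depth,
         effect_log_ratio = effect_log_ratio,
         unannotated_fraction = unannotated_fraction,
         mg_function_dispersion = mg_function_dispersion,
         mp_function_dispersion = mp_function_dispersion,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_subjects, "subjects,", length(x$taxa), "taxa,",
      length(x$functions), "functions\n")
  cat(sprintf("  depths MG=%g MP=%g, taxon dispersion=%g, %d planted effect(s), seed=%d\n",
              x$mg_depth, x$mp_depth, x$taxon_dispersion,
              length(x$effect_log_ratio), x$seed))
  invisible(x)
}

# function column labels including the optional unannotated sink
spec_fun_cols <- function(spec) {
  if (spec$unannotated_fraction > 0) c(spec$functions, "unannotated") else spec$functions
}

# Joint taxon x function cell probabilities for one layer, given the taxon
# proportions and per-taxon function profile in force for a subject.
joint_probs <- function(spec, taxon_props, profile, layer) {
  u <- spec$unannotated_fraction
  P <- taxon_props * profile
  if (u > 0) P <- cbind(P * (1 - u), unannotated = taxon_props * u)
  if (layer == "MP" && length(spec$effect_log_ratio)) {
    e <- spec$effect_log_ratio
    mult_t <- 10^ifelse(spec$taxa %in% names(e), e[spec$taxa], 0)
    cols <- colnames(P)
    mult_f <- 10^ifelse(cols %in% names(e), e[cols], 0)
    P <- P * mult_t  # row-wise recycling over columns
    P <- sweep(P, 2, mult_f, `*`)
  }
  s <- sum(P)
  if (s <= 0)
    stop_mgmp("degenerate all-zero cell probabilities", class = "mgmp_config_error")
  P / s
}

#' Expected joint cell proportions of a cohort spec
#'
#' The generator's own post-normalisation expectation, at the cohort base
#' composition (before subject-level Dirichlet noise): the taxon x function
#' proportion matrix for each layer. This is the ground truth that
#' planted-effect recovery is scored against.
#'
#' @param spec A [cohort_spec()].
#' @return List with matrices `mg` and `mp` (taxa x functions, each summing
#'   to 1).
#' @export
cohort_expectation <- function(spec) {
  base_profile <- spec$function_profile
  list(
    mg = joint_probs(spec, spec$base_taxon_props, base_profile, "MG"),
    mp = joint_probs(spec, spec$base_taxon_props, base_profile, "MP")
  )
}

#' Generator-expected log10 MP/MG ratio at an aggregation level
#'
#' @param spec A [cohort_spec()].
#' @param level A rank label (aggregate over functions), `"KO"` (aggregate
#'   over taxa), or `"KO:genus"`-style combined level.
#' @param cf Correction factor added to both layers before the log (default 0:
#'   the pure expectation).
#' @return Named numeric vector of expected log10 ratios.
#' @export
expected_log_ratio <- function(spec, level = "genus", cf = 0) {
  ex <- cohort_expectation(spec)
  agg <- function(P) {
    if (level == "KO") {
      out <- colSums(P)
      out[names(out) != "unannotated"]
    } else if (grepl("^KO:", level)) {
      rk <- sub("^KO:", "", level)
      at <- ancestor_at_rank(spec$taxonomy, rownames(P), rk)
      cells <- expand.grid(tx = at, ko = colnames(P), stringsAsFactors = FALSE)
      keep <- !is.na(cells$tx) & cells$ko != "unannotated"
      key <- paste(cells$ko, cells$tx, sep = "|")[keep]
      tapply(as.vector(P)[keep], key, sum)
    } else {
      at <- ancestor_at_rank(spec$taxonomy, rownames(P), level)
      rs <- rowSums(P)
      tapply(rs[!is.na(at)], at[!is.na(at)], sum)
    }
  }
  mg <- agg(ex$mg); mp <- agg(ex$mp)
  feats <- sort(union(names(mg), names(mp)))
  g <- ifelse(feats %in% names(mg), mg[feats], 0)
  p <- ifelse(feats %in% names(mp), mp[feats], 0)
  structure(log10((p + cf) / (g + cf)), names = feats)
}

#' Generate annotation records for a synthetic cohort
#'
#' Draws, per subject, genus proportions from a Dirichlet centred on the base
#' composition, then per layer a multinomial of unit counts over the joint
#' genus x KO cells (with planted MP effects applied and renormalised), and
#' emits one annotation record per observed cell.
#'
#' @param spec A [cohort_spec()].
#' @param aggregate If `TRUE` (default) one record per
#'   subject/layer/taxon/function with `weight` = unit count; if `FALSE`,
#'   expanded to one weight-1 record per unit. Both forms carry identical
#'   counts.
#' @return A data.frame of annotation records with columns `subject`, `layer`
#'   (`"MG"`/`"MP"`), `unit`, `taxon`, `ko`, `weight`. Per subject and layer,
#'   total weight equals the layer depth exactly.
#' @export
generate_cohort <- function(spec, aggregate = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  out <- vector("list", spec$n_subjects * 2L)
  k <- 0L
  with_seed(spec$seed, {
    for (s in subjects) {
      props <- if (is.finite(spec$taxon_dispersion)) {
        p <- rdirichlet1(spec$taxon_dispersion * spec$base_taxon_props)
        names(p) <- spec$taxa
        p
      } else spec$base_taxon_props
      for (layer in c("MG", "MP")) {
        fdisp <- if (layer == "MG") spec$mg_function_dispersion else spec$mp_function_dispersion
        profile <- spec$function_profile
        if (is.finite(fdisp)) {
          profile <- t(apply(profile, 1L, function(row) rdirichlet1(fdisp * row)))
          dimnames(profile) <- dimnames(spec$function_profile)
        }
        P <- joint_probs(spec, props, profile, layer)
        depth <- if (layer == "MG") spec$mg_depth else spec$mp_depth
        counts <- stats::rmultinom(1L, size = depth, prob = as.vector(P))[, 1L]
        nz <- which(counts > 0L)
        cell_tx <- rownames(P)[(nz - 1L) %% nrow(P) + 1L]
        cell_ko <- colnames(P)[(nz - 1L) %/% nrow(P) + 1L]
        k <- k + 1L
        out[[k]] <- data.frame(
          subject = s, layer = layer,
          unit = sprintf("%s_%s_c%05d", s, layer, seq_along(nz)),
          taxon = cell_tx, ko = cell_ko,
          weight = counts[nz], stringsAsFactors = FALSE
        )
      }
    }
  })
  rec <- do.call(rbind, out[seq_len(k)])
  rownames(rec) <- NULL
  if (!aggregate) rec <- expand_records(rec)
  rec
}

# Expand aggregated records to one weight-1 row per unit.
expand_records <- function(records) {
  idx <- rep.int(seq_len(nrow(records)), records$weight)
  rec <- records[idx, , drop = FALSE]
  rec$weight <- 1L
  rec$unit <- paste0(rec$unit, "_u", stats::ave(idx, idx, FUN = seq_along))
  rownames(rec) <- NULL
  rec
}

#' A null cohort: uniform composition, no planted effects
#'
#' Convenience wrapper around [generate_cohort()] for error-rate simulations:
#' `n_features` genera split over two phyla, each expressing a single private
#' KO, uniform base proportions, equal MG and MP depths, and all true log
#' MP/MG effects zero.
#'
#' @param n_subjects,n_features,depth,seed Cohort dimensions; `n_features >= 2`,
#'   `depth > 0`.
#' @param dispersion Between-subject Dirichlet concentration (default 200).
#' @return For `null_cohort_spec` a [cohort_spec()]; for `null_cohort` the
#'   generated record data.frame (with the spec attached as attribute
#'   `"spec"`).
#' @export
null_cohort_spec <- function(n_subjects = 15L, n_features = 100L, depth = 1e5,
                             seed = 1L, dispersion = 200) {
  if (n_features < 2)
    stop_mgmp("n_features must be >= 2", class = "mgmp_config_error")
  if (depth <= 0)
    stop_mgmp("depth must be > 0", class = "mgmp_config_error")
  genera <- sprintf("g__T%03d", seq_len(n_features))
  phyla <- rep(c("p__A", "p__B"), length.out = n_features)
  edges <- rbind(
    data.frame(child = c("p__A", "p__B"), parent = "root", rank = "phylum"),
    data.frame(child = genera, parent = phyla, rank = "genus")
  )
  tree <- build_taxonomy(edges)
  kos <- sprintf("K%05d", seq_len(n_features))
  profile <- diag(n_features)
  dimnames(profile) <- list(genera, kos)
  props <- structure(rep(1 / n_features, n_features), names = genera)
  cohort_spec(tree, props, profile, n_subjects = n_subjects,
              taxon_dispersion = dispersion,
              mg_depth = depth, mp_depth = depth, seed = seed)
}

#' @rdname null_cohort_spec
#' @export
null_cohort <- function(n_subjects = 15L, n_features = 100L, depth = 1e5,
                        seed = 1L, dispersion = 200) {
  spec <- null_cohort_spec(n_subjects, n_features, depth, seed, dispersion)
  rec <- generate_cohort(spec)
  attr(rec, "spec") <- spec
  rec
}
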