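# Shared fixtures and independent oracles, built in code.

# Small gut-like fixture tree: two Ruminococcaceae genera share a family.
fixture_tree <- function() {
  build_taxonomy(data.frame(
    child  = c("k__Bacteria",
               "p__Firmicutes", "p__Bacteroidetes",
               "f__Ruminococcaceae", "f__Lachnospiraceae", "f__Bacteroidaceae",
               "g__Faecalibacterium", "g__Ruminococcus", "g__Roseburia",
               "g__Bacteroides"),
    parent = c("root",
               "k__Bacteria", "k__Bacteria",
               "p__Firmicutes", "p__Firmicutes", "p__Bacteroidetes",
               "f__Ruminococcaceae", "f__Ruminococcaceae", "f__Lachnospiraceae",
               "f__Bacteroidaceae"),
    rank   = c("superkingdom", "phylum", "phylum",
               "family", "family", "family",
               "genus", "genus", "genus", "genus"),
    stringsAsFactors = FALSE
  ))
}

# Hand-built record set for a given subject/layer: counts named by
# "taxon|ko" keys.
make_records <- function(counts, subject = "S01", layer = "MG") {
  ks <- strsplit(names(counts), "|", fixed = TRUE)
  data.frame(
    subject = subject, layer = layer,
    unit = sprintf("%s_%s_%03d", subject, layer, seq_along(counts)),
    taxon = vapply(ks, `[`, character(1), 1L),
    ko = vapply(ks, function(x) if (length(x) > 1) x[2L] else "unannotated",
                character(1)),
    weight = as.integer(counts), stringsAsFactors = FALSE
  )
}

# Independent brute-force LCA oracle: intersect root-to-node paths, take the
# deepest shared node.
brute_lca <- function(tree, taxa) {
  if (length(taxa) == 0) return("unassigned")
  paths <- lapply(taxa, function(tx) ancestors(tree, tx))
  common <- Reduce(intersect, paths)
  common[which.max(tree$depth[common])]
}

# Random ranked taxonomy with <= n_nodes nodes (plus root).
random_tree <- function(n_nodes, seed) {
  set.seed(seed)
  ranks <- taxonomy_ranks()
  child <- character(0); parent <- character(0); rank <- character(0)
  nodes <- "root"; node_rank <- c(root = 1L)
  for (i in seq_len(n_nodes)) {
    repeat {
      p <- sample(nodes, 1L)
      ri <- node_rank[[p]]
      if (ri < length(ranks)) break
    }
    cand <- (node_rank[[p]] + 1L):length(ranks)
    r <- if (length(cand) == 1L) cand else sample(cand, 1L)
    id <- sprintf("n%03d", i)
    child <- c(child, id); parent <- c(parent, p)
    rank <- c(rank, ranks[r])
    nodes <- c(nodes, id); node_rank[[id]] <- r
  }
  build_taxonomy(data.frame(child = child, parent = parent, rank = rank,
                            stringsAsFactors = FALSE))
}

# Attribution fixture: 15 subjects, two pathways, controlled detection
# patterns around the retention-rule boundaries.
attribution_fixture <- function() {
  tr <- fixture_tree()
  cfg <- pathway_config(list(
    glycolysis = c("K00134", "K01689"),
    butyrogenesis = c("K00626", "K00248")
  ))
  subj <- sprintf("S%02d", 1:15)
  recs <- list()
  for (i in seq_along(subj)) {
    counts <- c("g__Faecalibacterium|K00134" = 40,     # all 15 subjects
                "g__Bacteroides|K00134" = 40)
    if (i <= 7)  counts["g__Faecalibacterium|K01689"] <- 10  # 7 < ceiling(15/2)
    if (i <= 8)  counts["g__Faecalibacterium|K00626"] <- 20  # exactly 8 subjects
    if (i <= 2)  counts["g__Roseburia|K00248"] <- 5          # genus in exactly 2
    if (i == 1)  counts["g__Ruminococcus|K00626"] <- 5       # genus in only 1
    recs[[i]] <- make_records(counts, subject = subj[i], layer = "MP")
  }
  list(records = do.call(rbind, recs), tree = tr, config = cfg)
}

# Brute-force Benjamini-Hochberg step-up oracle:
# adj_(i) = min(1, min_{k >= rank(i)} m * p_(k) / k).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
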