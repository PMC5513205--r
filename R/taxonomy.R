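# Ranked taxonomy representation and lowest-common-ancestor (LCA) resolution.
#
# Taxon identifiers are opaque strings conventionally prefixed by rank
# ("p__Firmicutes", "g__Faecalibacterium"). Lineages serialise as
# semicolon-joined root-to-node paths. Intermediate ranks may be absent from a
# lineage; all operations work on the explicit tree, not on rank positions.

#' Ordered taxonomic rank labels
#'
#' The rank vocabulary used throughout the package, ordered from the root down
#' to genus. Rank labels along any root-to-leaf path must be strictly
#' increasing in this order, but intermediate ranks may be skipped.
#'
#' @export
taxonomy_ranks <- function() {
  c("root", "superkingdom", "phylum", "class", "order", "family", "genus")
}

rank_index <- function(rank) match(rank, taxonomy_ranks())

#' Build a ranked taxonomy tree from an edge list
#'
#' @param edges A data.frame with columns `child`, `parent`, `rank` (the
#'   child's rank, one of [taxonomy_ranks()]) and optionally `name` (display
#'   string; defaults to the child id). Exactly one node must act as root:
#'   it appears only as a parent (or as a self-edge / edge with `NA` parent).
#'
#' @return An object of class `taxonomy`: a list with components `nodes`,
#'   `parent` (named character, root maps to `NA`), `rank`, `name` and `depth`
#'   (edges to root), plus `root`.
#'
#' @details Inputs violating the tree invariants are rejected: duplicated
#'   children with conflicting parents, cycles, unknown rank labels, or rank
#'   labels that do not strictly increase from parent to child.
#'
#' @examples
#' tr <- build_taxonomy(data.frame(
#'   child  = c("k__Bacteria", "p__Firmicutes", "f__Ruminococcaceae",
#'              "g__Faecalibacterium"),
#'   parent = c("root", "k__Bacteria", "p__Firmicutes", "f__Ruminococcaceae"),
#'   rank   = c("superkingdom", "phylum", "family", "genus")
#' ))
#' lca(tr, c("g__Faecalibacterium"))
#' @export
build_taxonomy <- function(edges) {
  stopifnot(is.data.frame(edges), nrow(edges) >= 1,
            all(c("child", "parent", "rank") %in% names(edges)))
  child  <- as.character(edges$child)
  parent <- as.character(edges$parent)
  rank   <- as.character(edges$rank)
  name   <- if ("name" %in% names(edges)) as.character(edges$name) else child

  # self-edges and NA/"" parents mark an explicit root row
  self <- is.na(parent) | parent == "" | parent == child
  root_rows <- child[self]
  child  <- child[!self]; parent <- parent[!self]
  rank   <- rank[!self];  name_c <- name[!self]

  dup <- duplicated(paste(child, parent, sep = "\r"))
  child <- child[!dup]; parent <- parent[!dup]; rank <- rank[!dup]
  name_c <- name_c[!dup]
  if (anyDuplicated(child))
    stop_mgmp("duplicate child with conflicting parents: ",
              paste(unique(child[duplicated(child)]), collapse = ", "),
              class = "mgmp_structure_error")

  nodes <- unique(c(child, parent, root_rows))
  roots <- unique(c(root_rows, setdiff(parent, child)))
  if (length(roots) != 1L)
    stop_mgmp("taxonomy must have exactly one root, found: ",
              paste(roots, collapse = ", "), class = "mgmp_structure_error")
  root <- roots

  bad <- !rank %in% taxonomy_ranks()
  if (any(bad))
    stop_mgmp("unknown rank label(s): ", paste(unique(rank[bad]), collapse = ", "),
              class = "mgmp_structure_error")

  parent_map <- structure(rep(NA_character_, length(nodes)), names = nodes)
  parent_map[child] <- parent
  rank_map <- structure(rep(NA_character_, length(nodes)), names = nodes)
  rank_map[child] <- rank
  rank_map[root] <- "root"
  name_map <- structure(nodes, names = nodes)
  name_map[child] <- name_c
  if (root %in% edges$child[self]) {
    i <- which(edges$child == root & self)[1L]
    if ("name" %in% names(edges)) name_map[root] <- as.character(edges$name[i])
  }

  # depth by walking to root; detects cycles and orphaned chains
  depth <- structure(rep(NA_integer_, length(nodes)), names = nodes)
  depth[root] <- 0L
  for (nd in nodes) {
    path <- character(0)
    cur <- nd
    while (is.na(depth[cur])) {
      if (cur %in% path)
        stop_mgmp("cycle detected at node ", cur, class = "mgmp_structure_error")
      path <- c(path, cur)
      nxt <- parent_map[[cur]]
      if (is.na(nxt) && cur != root)
        stop_mgmp("node ", cur, " has no path to root", class = "mgmp_structure_error")
      cur <- nxt
    }
    if (length(path))
      depth[path] <- depth[cur] + rev(seq_along(path))
  }

  # rank labels must strictly increase parent -> child
  for (ch in child) {
    pr <- parent_map[[ch]]
    ri_c <- rank_index(rank_map[[ch]])
    ri_p <- rank_index(rank_map[[pr]])
    if (!is.na(ri_p) && ri_c <= ri_p)
      stop_mgmp("rank of ", ch, " (", rank_map[[ch]],
                ") does not descend below its parent ", pr, " (", rank_map[[pr]], ")",
                class = "mgmp_structure_error")
  }

  structure(
    list(nodes = nodes, parent = parent_map, rank = rank_map,
         name = name_map, depth = depth, root = root),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy>", length(x$nodes), "nodes, root =", x$root, "\n")
  tab <- table(factor(x$rank, levels = taxonomy_ranks()))
  cat("  ranks:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Root-to-self ancestor chain of a taxon
#'
#' @param tree A [build_taxonomy()] object.
#' @param taxon A single taxon id.
#' @return Character vector of node ids from the taxon itself up to the root.
#' @export
ancestors <- function(tree, taxon) {
  if (!taxon %in% tree$nodes)
    stop_mgmp("unknown taxon id: ", taxon, class = "mgmp_lookup_error")
  out <- character(tree$depth[[taxon]] + 1L)
  cur <- taxon
  for (i in seq_along(out)) {
    out[i] <- cur
    cur <- tree$parent[[cur]]
  }
  out
}

#' Map taxa to their ancestor at a given rank
#'
#' @param tree A taxonomy.
#' @param taxa Character vector of taxon ids ("unassigned" allowed).
#' @param rank Target rank label.
#' @return Character vector: the ancestor-or-self at `rank`, or `NA` when the
#'   taxon's lineage has no node at that rank (including taxa placed above it).
#' @export
ancestor_at_rank <- function(tree, taxa, rank) {
  stopifnot(rank %in% taxonomy_ranks())
  uniq <- unique(taxa)
  res <- vapply(uniq, function(tx) {
    if (is.na(tx) || tx == "unassigned" || !tx %in% tree$nodes) return(NA_character_)
    cur <- tx
    repeat {
      if (identical(tree$rank[[cur]], rank)) return(cur)
      cur <- tree$parent[[cur]]
      if (is.na(cur)) return(NA_character_)
    }
  }, character(1))
  unname(res[match(taxa, uniq)])
}

#' LCA resolution settings
#'
#' @param min_support Minimum number of assignments that must resolve to a
#'   node for it to be reported by [assign_lca()]; nodes below the threshold
#'   are truncated to `fallback_rank` (or dropped to "unassigned" when
#'   `fallback_rank = "none"`). `0` disables the filter.
#' @param fallback_rank A rank label or `"none"`.
#' @export
lca_config <- function(min_support = 0L, fallback_rank = "none") {
  stopifnot(length(min_support) == 1L, min_support >= 0,
            fallback_rank == "none" || fallback_rank %in% taxonomy_ranks())
  structure(list(min_support = as.integer(min_support),
                 fallback_rank = fallback_rank),
            class = "lca_config")
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that is an ancestor-or-self of every taxon in the
#' set; the empty set resolves to `"unassigned"`.
#'
#' @param tree A taxonomy.
#' @param taxa Character vector (a set) of taxon ids present in `tree`.
#' @param config An [lca_config()] (reserved for [assign_lca()]'s support
#'   filter; plain `lca()` ignores it).
#' @return A single taxon id, or `"unassigned"`.
#' @export
lca <- function(tree, taxa, config = lca_config()) {
  taxa <- unique(taxa)
  if (length(taxa) == 0L) return("unassigned")
  common <- ancestors(tree, taxa[1L])
  for (tx in taxa[-1L]) {
    common <- common[common %in% ancestors(tree, tx)]
  }
  common[1L]  # paths run self -> root, so the first shared node is deepest
}

#' Resolve candidate-taxon sets by LCA with a minimum-support filter
#'
#' Each element of `candidates` (a list of character vectors) is resolved to
#' its LCA; then any resolved node supported by fewer than
#' `config$min_support` assignments is truncated to its ancestor at
#' `config$fallback_rank`, or set to `"unassigned"` when no fallback applies.
#'
#' @param tree A taxonomy.
#' @param candidates List of character vectors of candidate taxon ids.
#' @param config An [lca_config()].
#' @return Character vector of resolved taxon ids (may contain "unassigned").
#' @export
assign_lca <- function(tree, candidates, config = lca_config()) {
  assigned <- vapply(candidates, function(s) lca(tree, s, config), character(1))
  if (config$min_support > 1L) {
    counts <- table(assigned)
    low <- assigned %in% names(counts)[counts < config$min_support] &
      assigned != "unassigned"
    if (any(low)) {
      if (config$fallback_rank == "none") {
        assigned[low] <- "unassigned"
      } else {
        fb <- ancestor_at_rank(tree, assigned[low], config$fallback_rank)
        assigned[low] <- ifelse(is.na(fb), "unassigned", fb)
      }
    }
  }
  assigned
}

#' Serialise a taxon as its semicolon-joined root-to-node lineage
#'
#' @param tree A taxonomy.
#' @param taxa Character vector of taxon ids; "unassigned" passes through.
#' @return Character vector of lineage strings (root omitted).
#' @export
lineage <- function(tree, taxa) {
  uniq <- unique(taxa)
  res <- vapply(uniq, function(tx) {
    if (is.na(tx) || tx == "unassigned") return("unassigned")
    path <- rev(ancestors(tree, tx))
    paste(path[path != tree$root], collapse = ";")
  }, character(1))
  unname(res[match(taxa, uniq)])
}

# Leaf (deepest) element of a serialized lineage string.
lineage_leaf <- function(paths) {
  vapply(strsplit(paths, ";", fixed = TRUE),
         function(p) p[length(p)], character(1))
}

#' Read / write a taxonomy edge-list TSV
#'
#' The fixture format is a UTF-8 TSV with header `child, parent, rank, name`.
#'
#' @param path File path.
#' @return For `read_taxonomy`, a `taxonomy` object.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (!all(c("child", "parent", "rank") %in% names(df)))
    stop_mgmp("taxonomy TSV needs columns child, parent, rank",
              class = "mgmp_config_error")
  build_taxonomy(df)
}

#' @param tree A taxonomy to serialise.
#' @rdname read_taxonomy
#' @export
write_taxonomy <- function(tree, path) {
  ch <- setdiff(tree$nodes, tree$root)
  df <- data.frame(child = ch, parent = unname(tree$parent[ch]),
                   rank = unname(tree$rank[ch]), name = unname(tree$name[ch]),
                   stringsAsFactors = FALSE)
  df <- df[order(tree$depth[df$child], df$child), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
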