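# Gene-tree/species-tree reconciliation after Zmasek & Eddy: LCA
# mapping, duplication calls, loss counts and duplication age classes.
# Both trees must be rooted and binary; gene trees are taken as rooted
# (no automatic rooting -- rooting changes duplication calls).

#' LCA mapping of gene-tree nodes onto a species tree
#'
#' Each gene-tree leaf maps to its species; each internal node maps to
#' the species-tree LCA of its children's mappings (computed bottom-up).
#'
#' @param gene_tree Rooted binary [ape::phylo].
#' @param species_tree Rooted binary [ape::phylo].
#' @param species_map Named character vector: gene leaf label -> species
#'   (tip label of `species_tree`).
#' @return Integer vector over gene-tree node ids giving the mapped
#'   species-tree node id.
#' @export
lca_map <- function(gene_tree, species_tree, species_map) {
  assert_rooted_binary(gene_tree, "gene tree")
  assert_rooted_binary(species_tree, "species tree")
  miss <- setdiff(gene_tree$tip.label, names(species_map))
  if (length(miss) > 0)
    stop("species map missing gene leaves: ", paste(miss, collapse = ", "))
  sp_of_leaf <- species_map[gene_tree$tip.label]
  bad <- setdiff(unique(sp_of_leaf), species_tree$tip.label)
  if (length(bad) > 0)
    stop("species absent from species tree: ", paste(bad, collapse = ", "))

  sdepth <- node_edge_depths(species_tree)
  spar <- node_parents(species_tree)
  s_lca <- function(u, v) {
    while (u != v) {
      if (sdepth[u] >= sdepth[v]) u <- spar[u] else v <- spar[v]
    }
    u
  }

  ntip <- ape::Ntip(gene_tree)
  nnode <- ntip + gene_tree$Nnode
  mapping <- integer(nnode)
  mapping[seq_len(ntip)] <- match(sp_of_leaf, species_tree$tip.label)
  tr <- ape::reorder.phylo(gene_tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[k, 1]
    child <- tr$edge[k, 2]
    if (mapping[parent] == 0L) mapping[parent] <- mapping[child]
    else mapping[parent] <- s_lca(mapping[parent], mapping[child])
  }
  mapping
}

# Children list for each internal node.
node_children <- function(tree) {
  kids <- vector("list", ape::Ntip(tree) + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  kids
}

#' Duplication nodes from an LCA mapping
#'
#' An internal gene-tree node is a duplication iff it shares its mapping
#' with at least one of its children.
#'
#' @param gene_tree Rooted binary [ape::phylo].
#' @param mapping Output of [lca_map()].
#' @return Integer vector of duplication node ids (internal nodes).
#' @export
infer_duplications <- function(gene_tree, mapping) {
  ntip <- ape::Ntip(gene_tree)
  kids <- node_children(gene_tree)
  internal <- ntip + seq_len(gene_tree$Nnode)
  dup <- vapply(internal, function(g)
    any(mapping[kids[[g]]] == mapping[g]), logical(1))
  internal[dup]
}

#' Reconciliation loss count
#'
#' For each gene-tree edge (g, c): losses are the number of species-tree
#' edges skipped between `mapping(g)` and `mapping(c)` minus one
#' (clamped at 0), plus one if `g` is a duplication whose child moved to
#' a different species-tree node.
#'
#' @param gene_tree Rooted binary [ape::phylo].
#' @param species_tree Rooted binary [ape::phylo].
#' @param mapping Output of [lca_map()].
#' @param duplication_nodes Output of [infer_duplications()].
#' @return Total loss count (integer).
#' @export
count_losses <- function(gene_tree, species_tree, mapping, duplication_nodes) {
  sdepth <- node_edge_depths(species_tree)
  total <- 0L
  for (e in seq_len(nrow(gene_tree$edge))) {
    g <- gene_tree$edge[e, 1]
    cc <- gene_tree$edge[e, 2]
    d <- sdepth[mapping[cc]] - sdepth[mapping[g]]
    total <- total + max(0L, d - 1L) +
      as.integer(g %in% duplication_nodes && d > 0L)
  }
  total
}

#' Classify duplications as ancestral or recent
#'
#' A duplication is "ancestral" iff its mapped species-tree node is the
#' labelled ancestor itself or a deeper node (towards the root);
#' otherwise "recent".
#'
#' @param duplication_nodes Gene-tree duplication node ids.
#' @param mapping Output of [lca_map()].
#' @param species_tree Rooted binary [ape::phylo].
#' @param ancestor Either a species-tree node label (tip or internal
#'   label) or a character vector of >= 2 species whose MRCA defines the
#'   boundary.
#' @return Named character vector (`"ancestral"`/`"recent"`) indexed by
#'   duplication node id.
#' @export
classify_event_depth <- function(duplication_nodes, mapping, species_tree,
                                 ancestor) {
  anc_node <- if (length(ancestor) > 1) {
    bad <- setdiff(ancestor, species_tree$tip.label)
    if (length(bad) > 0) stop("unknown species: ", paste(bad, collapse = ", "))
    ape::getMRCA(species_tree, ancestor)
  } else {
    node_by_label(species_tree, ancestor)
  }
  spar <- node_parents(species_tree)
  on_root_path <- anc_node
  v <- anc_node
  while (v != root_node(species_tree)) {
    v <- spar[v]
    on_root_path <- c(on_root_path, v)
  }
  cls <- ifelse(mapping[duplication_nodes] %in% on_root_path,
                "ancestral", "recent")
  stats::setNames(cls, duplication_nodes)
}

#' Assign paralog leaf pairs to duplication events
#'
#' Emits every unordered leaf pair whose gene-tree LCA is a duplication
#' node, labelled with that node's age class; pairs whose LCA is a
#' speciation (orthologs) are excluded.
#'
#' @param gene_tree Rooted binary [ape::phylo].
#' @param duplication_nodes Duplication node ids.
#' @param age_class Output of [classify_event_depth()] (optional; if
#'   `NULL`, pairs are labelled `"unassigned"`).
#' @return Data frame: `seq1`, `seq2`, `lca_node`, `age_class`.
#' @export
assign_pairs_to_events <- function(gene_tree, duplication_nodes,
                                   age_class = NULL) {
  ntip <- ape::Ntip(gene_tree)
  out <- data.frame(seq1 = character(0), seq2 = character(0),
                    lca_node = integer(0), age_class = character(0),
                    stringsAsFactors = FALSE)
  if (ntip < 2) return(out)
  mr <- ape::mrca(gene_tree)
  combs <- utils::combn(ntip, 2)
  lcas <- mr[cbind(combs[1, ], combs[2, ])]
  keep <- lcas %in% duplication_nodes
  if (!any(keep)) return(out)
  lcas <- lcas[keep]
  cls <- if (is.null(age_class)) rep("unassigned", length(lcas))
         else unname(age_class[as.character(lcas)])
  data.frame(seq1 = gene_tree$tip.label[combs[1, keep]],
             seq2 = gene_tree$tip.label[combs[2, keep]],
             lca_node = lcas, age_class = cls, stringsAsFactors = FALSE)
}

#' Full reconciliation of a gene tree against a species tree
#'
#' @inheritParams lca_map
#' @param ancestor Optional ancestor label/species set for age classes
#'   (see [classify_event_depth()]).
#' @return A list of class `reconciliation_result`: `mapping`,
#'   `duplication_nodes`, `n_duplications`, `n_losses`, `age_class`,
#'   `pair_cohorts`.
#' @export
reconcile <- function(gene_tree, species_tree, species_map, ancestor = NULL) {
  mapping <- lca_map(gene_tree, species_tree, species_map)
  dups <- infer_duplications(gene_tree, mapping)
  losses <- count_losses(gene_tree, species_tree, mapping, dups)
  cls <- if (!is.null(ancestor))
    classify_event_depth(dups, mapping, species_tree, ancestor) else NULL
  pairs <- assign_pairs_to_events(gene_tree, dups, cls)
  structure(list(mapping = mapping, duplication_nodes = dups,
                 n_duplications = length(dups), n_losses = losses,
                 age_class = cls, pair_cohorts = pairs),
            class = "reconciliation_result")
}

#' @export
print.reconciliation_result <- function(x, ...) {
  cat(sprintf("reconciliation: %d duplications, %d losses, %d paralog pairs\n",
              x$n_duplications, x$n_losses, nrow(x$pair_cohorts)))
  invisible(x)
}
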