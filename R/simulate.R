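# Truth-emitting simulator: species trees, duplication/loss histories
# at configured epochs, GY94 codon evolution, and clone sets with
# planted homopolymer indels / premature stops.
#
# Time is measured in synonymous-distance units per lineage ("dS-time"):
# a duplication placed at depth u yields descendant pairs whose expected
# NG86 dS is 2u. Branch lengths in expected substitutions per codon are
# obtained from dS-time by inverting the analytically computed expected
# NG86 dS under the generating GY94 kernel (root-finding, tol 1e-8), so
# simulated synonymous depths land on the estimator's own scale.
# Duplication epochs are placed deterministically (configured), not
# drawn from a birth-death prior, so the emitted truth is exact.

#' Preset four-species ultrametric species tree
#'
#' Balanced tree `((A,B),(C,D))` with leaf depths 0, the two inner
#' speciations at dS-time 0.1 and the root at 0.25; internal nodes are
#' labelled `AB`, `CD` and `ROOT`.
#'
#' @return An [ape::phylo] with branch lengths in dS-time units.
#' @export
species_tree_preset <- function() {
  ape::read.tree(text =
    "((A:0.1,B:0.1)AB:0.15,(C:0.1,D:0.1)CD:0.15)ROOT;")
}

#' Simulation configuration
#'
#' @param species_tree Rooted binary ultrametric [ape::phylo] with
#'   branch lengths in dS-time units (default [species_tree_preset()]).
#' @param dup_epochs List of epochs; each epoch is a list with `label`,
#'   `depth` (dS-time of the duplication; pair dS target = 2 * depth),
#'   `edges` (character vector of species-tree child-node labels, or
#'   `"stem"` for the root stem) and `count` (lineages duplicated per
#'   edge crossing the depth; `Inf` duplicates all). The default plants
#'   one ancestral duplication on the stem at depth 0.4 (pair dS 0.8)
#'   and recent duplications on every terminal edge at depth 0.075
#'   (pair dS 0.15).
#' @param loss_rate Per-lineage Poisson loss rate per dS-time unit
#'   within species-tree branches (default 0).
#' @param L Alignment length in codons (default 500, >= 10).
#' @param kappa,omega GY94 parameters of the generating model
#'   (defaults 2 and 0.2).
#' @param pi_mode `"uniform"` or `"dirichlet"` (seeded draw).
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(species_tree = species_tree_preset(),
                       dup_epochs = list(
                         list(label = "ancestral", depth = 0.4,
                              edges = "stem", count = Inf),
                         list(label = "recent", depth = 0.075,
                              edges = c("A", "B", "C", "D"), count = Inf)),
                       loss_rate = 0, L = 500L, kappa = 2, omega = 0.2,
                       pi_mode = c("uniform", "dirichlet"), seed) {
  if (missing(seed)) stop("seed is mandatory")
  pi_mode <- match.arg(pi_mode)
  if (L < 10) stop("L must be >= 10 codons")
  if (loss_rate < 0) stop("loss_rate must be >= 0")
  assert_rooted_binary(species_tree, "species tree")
  structure(list(species_tree = species_tree, dup_epochs = dup_epochs,
                 loss_rate = loss_rate, L = as.integer(L), kappa = kappa,
                 omega = omega, pi_mode = pi_mode, seed = as.integer(seed)),
            class = "sim_config")
}

sim_pi <- function(config) {
  ct <- codon_tables()
  if (config$pi_mode == "uniform") {
    pi <- rep(1 / 61, 61)
  } else {
    pi <- stats::rgamma(61, shape = 5, rate = 1)
    pi <- pi / sum(pi)
  }
  names(pi) <- ct$codons
  pi
}

# dS-time depth of each species-tree node (leaves at 0). Requires an
# ultrametric tree.
species_node_depths <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- node_parents(tree)
  elen <- numeric(n)
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- root_node(tree)
  above <- vapply(seq_len(n), function(v) {
    d <- 0
    while (v != root) {
      d <- d + elen[v]
      v <- par[v]
    }
    d
  }, numeric(1))
  total <- max(above[seq_len(ape::Ntip(tree))])
  if (max(abs(above[seq_len(ape::Ntip(tree))] - total)) > 1e-8)
    stop("species tree must be ultrametric in dS-time")
  total - above
}

#' Simulate a gene duplication/loss history
#'
#' Top-down construction along the species tree: gene lineages
#' bifurcate at each configured duplication point and are killed by
#' Poisson loss events within species-tree branches; surviving leaves
#' are named `species_copyN`. Resamples (up to 100 tries) if all
#' lineages are lost.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_history`: `gene_tree` ([ape::phylo],
#'   branch lengths in dS-time, node labels `D<eventid>`/`S`),
#'   `species_map` (leaf -> species), `truth` (a `sim_truth` list with
#'   `events` data frame, `n_duplications_retained`, `depths`), and
#'   `config`.
#' @export
simulate_gene_history <- function(config) {
  set.seed(config$seed)
  for (try in 1:100) {
    h <- sim_history_once(config)
    if (!is.null(h)) return(h)
  }
  stop("all gene lineages lost in 100 attempts; lower loss_rate")
}

sim_history_once <- function(config) {
  sp <- config$species_tree
  ntip_s <- ape::Ntip(sp)
  sdepth <- species_node_depths(sp)
  kids_s <- node_children(sp)
  root_s <- root_node(sp)
  labels_s <- c(sp$tip.label,
                if (!is.null(sp$node.label)) sp$node.label
                else paste0("N", seq_len(sp$Nnode)))

  # mutable state collected during recursion
  env <- new.env()
  env$nodes <- list()    # each: list(id, type, depth, children ids, species)
  env$events <- list()
  env$leaf_counter <- integer(ntip_s)
  new_node <- function(type, depth, species_node, label = NA_character_) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- list(id = id, type = type, depth = depth,
                            species = species_node, label = label,
                            children = integer(0))
    id
  }
  add_child <- function(parent, child) {
    env$nodes[[parent]]$children <- c(env$nodes[[parent]]$children, child)
  }
  record_event <- function(type, label, location, depth, node_id = NA) {
    env$events[[length(env$events) + 1L]] <- data.frame(
      event_id = length(env$events) + 1L, type = type, epoch = label,
      species_location = location, depth = depth, node_id = node_id,
      stringsAsFactors = FALSE)
  }

  # duplication points per species edge (child node id), sorted deep-first
  edge_dups <- function(child_node) {
    pts <- list()
    top <- if (child_node == root_s) Inf else
      sdepth[node_parents(sp)[child_node]]
    bottom <- sdepth[child_node]
    for (ep in config$dup_epochs) {
      targets <- ep$edges
      loc <- labels_s[child_node]
      is_stem <- child_node == root_s
      hit <- if (is_stem) "stem" %in% targets else loc %in% targets
      if (hit && ep$depth > bottom + 1e-12 && ep$depth <= top)
        pts[[length(pts) + 1L]] <- list(label = ep$label, depth = ep$depth,
                                        count = ep$count)
    }
    if (length(pts) == 0) return(pts)
    pts[order(-vapply(pts, `[[`, numeric(1), "depth"))]
  }

  # walk one species edge carrying a set of live lineage node ids from
  # depth `from` down to the species node `child_node`; returns surviving
  # lineage ids at the bottom.
  walk_edge <- function(child_node, lineages, from) {
    bottom <- sdepth[child_node]
    pts <- edge_dups(child_node)
    segs <- c(vapply(pts, `[[`, numeric(1), "depth"), bottom)
    seg_labels <- c(lapply(pts, identity), list(NULL))
    cur_depth <- from
    for (si in seq_along(segs)) {
      target <- segs[si]
      # losses on (cur_depth, target): exponential waiting in dS-time.
      # The root stem is not a species-tree branch, so it carries no
      # loss exposure (duplication events there are still honoured).
      if (config$loss_rate > 0 && is.finite(cur_depth) &&
          child_node != root_s) {
        survived <- logical(length(lineages))
        for (li in seq_along(lineages)) {
          tloss <- stats::rexp(1, config$loss_rate)
          if (tloss < cur_depth - target) {
            record_event("loss", NA_character_, labels_s[child_node],
                         cur_depth - tloss)
            survived[li] <- FALSE
          } else survived[li] <- TRUE
        }
        lineages <- lineages[survived]
      }
      if (length(lineages) == 0) return(integer(0))
      ev <- seg_labels[[si]]
      if (!is.null(ev)) {
        ndup <- if (is.infinite(ev$count)) length(lineages)
                else min(ev$count, length(lineages))
        for (li in seq_len(ndup)) {
          d_id <- new_node("duplication", ev$depth, child_node)
          record_event("duplication", ev$label, labels_s[child_node],
                       ev$depth, d_id)
          env$nodes[[d_id]]$event_id <- length(env$events)
          c1 <- new_node("lineage", ev$depth, child_node)
          c2 <- new_node("lineage", ev$depth, child_node)
          add_child(d_id, c1)
          add_child(d_id, c2)
          # replace lineage li's payload: d_id takes its place in tree
          env$nodes[[lineages[li]]]$children <- d_id
          lineages[li] <- c1
          lineages <- c(lineages, c2)
        }
      }
      cur_depth <- target
    }
    # reached species node child_node
    if (child_node <= ntip_s) {
      for (li in lineages) {
        env$leaf_counter[child_node] <- env$leaf_counter[child_node] + 1L
        leaf <- new_node("leaf", 0,
                         child_node,
                         label = paste0(sp$tip.label[child_node], "_copy",
                                        env$leaf_counter[child_node]))
        env$nodes[[leaf]]$species_label <- sp$tip.label[child_node]
        env$nodes[[li]]$children <- leaf
      }
    } else {
      for (li in lineages) {
        s_id <- new_node("speciation", sdepth[child_node], child_node)
        env$nodes[[li]]$children <- s_id
        for (k in kids_s[[child_node]]) {
          c_id <- new_node("lineage", sdepth[child_node], k)
          add_child(s_id, c_id)
          walk_edge(k, c_id, sdepth[child_node])
        }
      }
    }
    lineages
  }

  start <- new_node("lineage", Inf, root_s)
  walk_edge(root_s, start, Inf)

  res <- sim_build_phylo(env$nodes, start)
  if (is.null(res)) return(NULL)
  events <- if (length(env$events) > 0) do.call(rbind, env$events)
            else data.frame(event_id = integer(0), type = character(0),
                            epoch = character(0),
                            species_location = character(0),
                            depth = numeric(0), node_id = integer(0))
  retained_ids <- res$retained_dup_events
  events$retained <- logical(nrow(events))
  events$retained[events$type == "duplication" &
                    events$node_id %in% retained_ids] <- TRUE
  truth <- structure(
    list(events = events,
         n_duplications_retained = sum(events$retained),
         depths = res$depths),
    class = "sim_truth")
  structure(list(gene_tree = res$tree, species_map = res$species_map,
                 truth = truth), class = "sim_history")
}

# Collapse lineage bookkeeping nodes and unifurcations, drop dead
# subtrees, and emit an ape phylo with dS-time branch lengths.
sim_build_phylo <- function(nodes, start_id) {
  # resolve: return list(kind = "leaf"/"node"/"dead", ...)
  resolve <- function(id) {
    nd <- nodes[[id]]
    if (nd$type == "leaf")
      return(list(kind = "leaf", label = nd$label, depth = 0,
                  species = nd$species_label))
    kids <- nd$children
    if (length(kids) == 0) return(list(kind = "dead"))
    res_kids <- lapply(kids, resolve)
    res_kids <- Filter(function(x) x$kind != "dead", res_kids)
    if (length(res_kids) == 0) return(list(kind = "dead"))
    if (nd$type == "lineage" || length(res_kids) == 1) {
      # pass-through (unifurcation suppressed)
      if (length(res_kids) == 1) return(res_kids[[1]])
      stop("lineage node with multiple children")  # should not happen
    }
    list(kind = "node", type = nd$type, id = id, depth = nd$depth,
         children = res_kids,
         event_id = if (!is.null(nd$event_id)) nd$event_id else NA)
  }
  root <- resolve(start_id)
  if (root$kind == "dead") return(NULL)
  if (root$kind == "leaf") return(NULL)  # a single surviving copy: no tree

  # count tips/nodes
  count <- function(x) if (x$kind == "leaf") c(1L, 0L)
    else Reduce(`+`, lapply(x$children, count)) + c(0L, 1L)
  cnt <- count(root)
  ntip <- cnt[1]; nnode <- cnt[2]
  if (ntip < 2) return(NULL)

  env <- new.env()
  env$edge <- matrix(0L, ntip + nnode - 1L, 2L)
  env$elen <- numeric(ntip + nnode - 1L)
  env$k <- 0L
  env$tipi <- 0L
  env$nodei <- ntip
  env$tiplab <- character(ntip)
  env$nodelab <- character(nnode)
  env$species_map <- character(ntip)
  env$depths <- numeric(ntip + nnode)
  env$retained <- integer(0)
  assign_ids <- function(x) {
    if (x$kind == "leaf") {
      env$tipi <- env$tipi + 1L
      id <- env$tipi
      env$tiplab[id] <- x$label
      env$species_map[id] <- x$species
      env$depths[id] <- 0
      id
    } else {
      env$nodei <- env$nodei + 1L
      id <- env$nodei
      env$nodelab[id - ntip] <- if (x$type == "duplication")
        paste0("D", x$id) else "S"
      if (x$type == "duplication")
        env$retained <- c(env$retained, x$id)
      env$depths[id] <- x$depth
      for (ch in x$children) {
        cid <- assign_ids(ch)
        env$k <- env$k + 1L
        env$edge[env$k, ] <- c(id, cid)
        env$elen[env$k] <- x$depth - env$depths[cid]
      }
      id
    }
  }
  assign_ids(root)
  tree <- structure(list(edge = env$edge, edge.length = env$elen,
                         Nnode = nnode, tip.label = env$tiplab,
                         node.label = env$nodelab),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  # species of tip i
  sm <- stats::setNames(env$species_map, env$tiplab)
  # map species node id to label
  list(tree = tree, species_map = sm, depths = env$depths,
       retained_dup_events = env$retained)
}
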