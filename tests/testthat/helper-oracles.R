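# Independent brute-force oracles. These deliberately avoid the
# package's internal tables and code paths: the genetic code is read
# directly from Biostrings, pathway enumeration is recursive, the
# likelihood oracle sums over ancestral states with Matrix::expm, and
# the reconciliation oracle minimises duplications over all valid maps.

oracle_code <- Biostrings::GENETIC_CODE
oracle_sense <- names(oracle_code)[oracle_code != "*"]

oracle_translate <- function(codon) unname(oracle_code[codon])

# NG86 site counts for one codon: per position, synonymous fraction of
# the 3 single-nucleotide changes; changes to stops excluded from the
# numerators only.
oracle_site_counts <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa0 <- oracle_translate(codon)
  s <- 0
  n <- 0
  for (pos in 1:3) {
    for (nuc in c("A", "C", "G", "T")) {
      if (nuc == ch[pos]) next
      alt <- ch
      alt[pos] <- nuc
      aa1 <- oracle_translate(paste(alt, collapse = ""))
      if (aa1 == "*") next
      if (aa1 == aa0) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(s = s, n = n)
}

# Recursive enumeration of all orderings of single-nucleotide steps
# between two codons; paths through stop codons are dropped and the
# remainder averaged. Returns c(sd, nd).
oracle_path_diffs <- function(a, b) {
  if (a == b) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining) {
    # returns list of c(syn, non, ok) across completions
    out <- list()
    for (pos in remaining) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[pos] <- strsplit(b, "")[[1]][pos]
      nxt <- paste(nxt, collapse = "")
      step_syn <- as.numeric(oracle_translate(cur) == oracle_translate(nxt) &&
                               oracle_translate(nxt) != "*")
      step_non <- 1 - step_syn
      bad <- oracle_translate(nxt) == "*"
      rest <- setdiff(remaining, pos)
      if (length(rest) == 0) {
        out[[length(out) + 1]] <- c(step_syn, step_non, !bad)
      } else {
        for (sub in walk(nxt, rest)) {
          out[[length(out) + 1]] <- c(step_syn + sub[1], step_non + sub[2],
                                      (!bad) && sub[3])
        }
      }
    }
    out
  }
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  paths <- walk(a, diff_pos)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 1
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

oracle_ng86_pair <- function(a_codons, b_codons) {
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(a_codons)) {
    sa <- oracle_site_counts(a_codons[k])
    sb <- oracle_site_counts(b_codons[k])
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    d <- oracle_path_diffs(a_codons[k], b_codons[k])
    Sd <- Sd + d["sd"]
    Nd <- Nd + d["nd"]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       dS = jc(unname(Sd / S)), dN = jc(unname(Nd / N)))
}

# Likelihood by direct summation over all ancestral state assignments
# (rooted binary trees only; practical for <= 3 leaves).
oracle_enum_loglik <- function(tree, aln, params) {
  states <- genedup:::encode_codon_states(aln)[tree$tip.label, , drop = FALSE]
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  Qs <- lapply(params$omega_by_class, function(w)
    gy94_rate_matrix(params$kappa, w, params$pi))
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Qs[[params$branch_class[e]]] *
                             params$branch_lengths[e])))
  internal <- (ntip + 1):nnode
  grid <- do.call(expand.grid, rep(list(1:61), length(internal)))
  ll <- 0
  for (s in seq_len(ncol(states))) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      asn <- integer(nnode)
      asn[internal] <- as.integer(grid[g, ])
      asn[seq_len(ntip)] <- states[, s]
      p <- unname(params$pi[asn[ntip + 1]])
      for (e in seq_len(nrow(tree$edge)))
        p <- p * Ps[[e]][asn[tree$edge[e, 1]], asn[tree$edge[e, 2]]]
      tot <- tot + p
    }
    ll <- ll + log(tot)
  }
  ll
}

# Minimal duplication count over all valid reconciliation maps: each
# internal gene node maps to any species node that is an ancestor (or
# equal) of both its children's maps; leaves are fixed. A node is a
# speciation only when its children's maps fall into the two distinct
# child subtrees of its own map (equivalently, their species LCA is the
# map itself and neither child maps to it); anything else counts as a
# duplication.
oracle_min_dups <- function(gene_tree, species_tree, species_map) {
  ntip <- ape::Ntip(gene_tree)
  spar <- genedup:::node_parents(species_tree)
  sroot <- genedup:::root_node(species_tree)
  sdep <- genedup:::node_edge_depths(species_tree)
  ancestors <- function(v) {
    out <- v
    while (v != sroot) { v <- spar[v]; out <- c(out, v) }
    out
  }
  slca <- function(u, v) {
    while (u != v) if (sdep[u] >= sdep[v]) u <- spar[u] else v <- spar[v]
    u
  }
  kids <- genedup:::node_children(gene_tree)
  leaf_sp <- match(species_map[gene_tree$tip.label], species_tree$tip.label)
  best <- function(g) {
    # returns named numeric: for each allowed map of g, min dups in subtree
    if (g <= ntip)
      return(stats::setNames(0, leaf_sp[g]))
    left <- best(kids[[g]][1])
    right <- best(kids[[g]][2])
    res <- c()
    for (ml in as.integer(names(left))) {
      for (mr in as.integer(names(right))) {
        for (m in intersect(ancestors(ml), ancestors(mr))) {
          is_spec <- (m == slca(ml, mr)) && ml != m && mr != m
          dups <- left[[as.character(ml)]] + right[[as.character(mr)]] +
            as.integer(!is_spec)
          key <- as.character(m)
          if (is.null(res[key]) || is.na(res[key]) || res[key] > dups)
            res[key] <- dups
        }
      }
    }
    res
  }
  min(best(ntip + 1L))
}

# Exact two-sided Wilcoxon p by full enumeration of group assignments.
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(vals), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# All rooted binary topologies on n labelled leaves (as nested lists).
all_rooted_topologies <- function(leaves) {
  if (length(leaves) == 1) return(list(leaves[[1]]))
  out <- list()
  n <- length(leaves)
  # split leaves into left/right, first leaf always on the left to
  # avoid double counting
  others <- leaves[-1]
  for (k in 0:(n - 2)) {
    for (subset in utils::combn(seq_along(others), k, simplify = FALSE)) {
      left <- c(leaves[1], others[subset])
      right <- others[setdiff(seq_along(others), subset)]
      if (length(right) == 0) next
      for (lt in all_rooted_topologies(left))
        for (rt in all_rooted_topologies(right))
          out[[length(out) + 1]] <- list(lt, rt)
    }
  }
  out
}

topology_to_newick <- function(x) {
  f <- function(n) if (!is.list(n)) n else
    paste0("(", f(n[[1]]), ",", f(n[[2]]), ")")
  paste0(f(x), ";")
}
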