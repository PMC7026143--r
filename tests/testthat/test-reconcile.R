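sp3 <- species_tree_3()

test_that("LCA mapping follows the textbook cases", {
  # gene tree congruent with the species tree: no duplications, no losses
  gt <- ape::read.tree(text = "((a1:1,b1:1):1,c1:2);")
  sm <- c(a1 = "A", b1 = "B", c1 = "C")
  rec <- reconcile(gt, sp3, sm)
  expect_equal(rec$n_duplications, 0L)
  expect_equal(rec$n_losses, 0L)
  expect_equal(nrow(rec$pair_cohorts), 0L)

  # one ancient duplication: ((a1,b1),(a2,b2)) over (A,B)
  gt2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  sm2 <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")
  map2 <- lca_map(gt2, sp3, sm2)
  ab_node <- genedup:::node_by_label(sp3, "AB")
  # all three internal gene nodes map to the A-B ancestor
  expect_equal(unname(map2[5:7]), rep(ab_node, 3))
  dups2 <- infer_duplications(gt2, map2)
  expect_equal(dups2, 5L)  # exactly the root
  # the four cross pairs are paralogs, the two within-clade pairs are not
  pairs <- assign_pairs_to_events(gt2, dups2)
  expect_setequal(paste(pairs$seq1, pairs$seq2),
                  c("a1 a2", "a1 b2", "b1 a2", "b1 b2"))

  # asymmetric loss: (a1,(a2,b2)) -> 1 duplication, 1 loss
  gt3 <- ape::read.tree(text = "(a1:2,(a2:1,b2:1):1);")
  sm3 <- c(a1 = "A", a2 = "A", b2 = "B")
  rec3 <- reconcile(gt3, sp3, sm3)
  expect_equal(rec3$n_duplications, 1L)
  expect_equal(rec3$n_losses, 1L)
})

test_that("unknown species and non-binary trees are rejected", {
  gt <- ape::read.tree(text = "((a1:1,b1:1):1,x1:2);")
  expect_error(lca_map(gt, sp3, c(a1 = "A", b1 = "B", x1 = "X")),
               "absent from species tree")
  expect_error(lca_map(gt, sp3, c(a1 = "A", b1 = "B")), "missing")
  multi <- ape::read.tree(text = "((a1,b1,c1),d1);")
  expect_error(lca_map(multi, sp3,
                       c(a1 = "A", b1 = "B", c1 = "C", d1 = "C")),
               "binary")
})

test_that("duplication counts match the minimal-event oracle (<= 4 leaves)", {
  specs <- list(c("A"), c("A", "B"), c("A", "B", "C"))
  set.seed(99)
  n_checked <- 0
  for (n_leaves in 2:4) {
    topos <- all_rooted_topologies(as.list(paste0("g", seq_len(n_leaves))))
    for (topo in topos) {
      nw <- topology_to_newick(topo)
      gt <- ape::read.tree(text = nw)
      # all species assignments over 3 species
      assignments <- expand.grid(rep(list(c("A", "B", "C")), n_leaves),
                                 stringsAsFactors = FALSE)
      for (r in seq_len(nrow(assignments))) {
        sm <- stats::setNames(as.character(assignments[r, ]), gt$tip.label)
        mapping <- lca_map(gt, sp3, sm)
        dups <- infer_duplications(gt, mapping)
        expect_equal(length(dups), oracle_min_dups(gt, sp3, sm),
                     info = paste(nw, paste(sm, collapse = "")))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 9 + 3 * 27 + 15 * 81)
})

test_that("pruning a leaf never increases the duplication count", {
  set.seed(5)
  for (rep in 1:15) {
    cfg <- sim_config(seed = 600 + rep, L = 10, loss_rate = 0.3)
    h <- simulate_gene_history(cfg)
    rec <- reconcile(h$gene_tree, cfg$species_tree, h$species_map)
    drop <- sample(h$gene_tree$tip.label, 1)
    gt2 <- ape::drop.tip(h$gene_tree, drop)
    if (is.null(gt2) || ape::Ntip(gt2) < 2) next
    rec2 <- reconcile(gt2, cfg$species_tree,
                      h$species_map[gt2$tip.label])
    expect_lte(rec2$n_duplications, rec$n_duplications)
  }
})

test_that("relabelling leaves within a species changes nothing", {
  set.seed(6)
  cfg <- sim_config(seed = 77, L = 10, loss_rate = 0)
  h <- simulate_gene_history(cfg)
  rec <- reconcile(h$gene_tree, cfg$species_tree, h$species_map,
                   ancestor = "ROOT")
  # swap the labels of two copies of species A
  a_leaves <- names(h$species_map[h$species_map == "A"])[1:2]
  gt2 <- h$gene_tree
  i <- match(a_leaves, gt2$tip.label)
  gt2$tip.label[i] <- rev(gt2$tip.label[i])
  rec2 <- reconcile(gt2, cfg$species_tree, h$species_map, ancestor = "ROOT")
  expect_equal(rec2$n_duplications, rec$n_duplications)
  expect_equal(rec2$n_losses, rec$n_losses)
  expect_equal(sort(unname(rec2$age_class)), sort(unname(rec$age_class)))
})

test_that("age classes split at the labelled ancestor", {
  gt <- ape::read.tree(text = "(((a1:1,a2:1):1,b1:2):1,c1:3);")
  sm <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  mapping <- lca_map(gt, sp3, sm)
  dups <- infer_duplications(gt, mapping)
  # the a1/a2 duplication maps to leaf A: recent relative to AB ancestor
  cls <- classify_event_depth(dups, mapping, sp3, "AB")
  expect_equal(unname(cls), "recent")
  # relative to leaf A itself the same node is ancestral
  cls2 <- classify_event_depth(dups, mapping, sp3, "A")
  expect_equal(unname(cls2), "ancestral")
  # duplication mapped to the root is ancestral for a root label
  gt2 <- ape::read.tree(text = "((a1:1,c1:1):1,(a2:1,c2:1):1);")
  sm2 <- c(a1 = "A", c1 = "C", a2 = "A", c2 = "C")
  m2 <- lca_map(gt2, sp3, sm2)
  d2 <- infer_duplications(gt2, m2)
  expect_equal(unname(classify_event_depth(d2, m2, sp3, "ROOT")),
               "ancestral")
  expect_error(classify_event_depth(d2, m2, sp3, "NOPE"), "unknown")
  # MRCA form: ancestor given as a species pair
  expect_equal(unname(classify_event_depth(d2, m2, sp3, c("A", "B"))),
               "ancestral")
})
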