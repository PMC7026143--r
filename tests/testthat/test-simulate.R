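test_that("lossless default history has the forced leaf count and truth", {
  cfg <- sim_config(seed = 51, L = 20, loss_rate = 0)
  h <- simulate_gene_history(cfg)
  # 4 species x 2 ancestral lineages x 2 recent copies
  expect_equal(ape::Ntip(h$gene_tree), 16L)
  expect_equal(h$truth$n_duplications_retained, 9L)
  expect_true(ape::is.binary(h$gene_tree))
  expect_true(ape::is.rooted(h$gene_tree))
  # species map covers every leaf
  expect_setequal(names(h$species_map), h$gene_tree$tip.label)

  # a single root duplication over two species gives ((a,b),(a,b))
  sp2 <- ape::read.tree(text = "(A:0.2,B:0.2)ROOT;")
  cfg2 <- sim_config(species_tree = sp2,
                     dup_epochs = list(list(label = "anc", depth = 0.3,
                                            edges = "stem", count = 1)),
                     loss_rate = 0, L = 20, seed = 52)
  h2 <- simulate_gene_history(cfg2)
  expect_equal(ape::Ntip(h2$gene_tree), 4L)
  rec <- reconcile(h2$gene_tree, sp2, h2$species_map)
  expect_equal(rec$n_duplications, 1L)
  expect_equal(rec$duplication_nodes, genedup:::root_node(h2$gene_tree))
})

test_that("fixed seeds reproduce identical histories and truth tables", {
  cfg <- sim_config(seed = 53, L = 15, loss_rate = 0.2)
  h1 <- simulate_gene_history(cfg)
  h2 <- simulate_gene_history(cfg)
  expect_identical(ape::write.tree(h1$gene_tree), ape::write.tree(h2$gene_tree))
  expect_identical(h1$truth$events, h2$truth$events)
  a1 <- evolve_alignment(h1$gene_tree, cfg)
  # reseed to reproduce the same stream position
  h3 <- simulate_gene_history(cfg)
  a3 <- evolve_alignment(h3$gene_tree, cfg)
  expect_identical(a1$seqs, a3$seqs)
})

test_that("evolution respects the sense-codon state space and zero branches", {
  cfg <- sim_config(seed = 54, L = 40, loss_rate = 0)
  h <- simulate_gene_history(cfg)
  aln <- evolve_alignment(h$gene_tree, cfg)
  ct <- codon_tables()
  m <- codon_matrix(aln)
  expect_false(any(m %in% ct$stops))
  # zero-length tree: child identical to parent everywhere
  sp2 <- ape::read.tree(text = "(A:0,B:0)ROOT;")
  cfg2 <- sim_config(species_tree = sp2, dup_epochs = list(),
                     loss_rate = 0, L = 25, seed = 55)
  h2 <- simulate_gene_history(cfg2)
  a2 <- evolve_alignment(h2$gene_tree, cfg2)
  expect_identical(unname(a2$seqs[1]), unname(a2$seqs[2]))
})

test_that("closed loop: reconciliation recovers every lossless history", {
  set.seed(56)
  for (rep in 1:100) {
    # random epoch structure on the 4-species preset
    epochs <- list(list(label = "ancestral", depth = runif(1, 0.3, 0.6),
                        edges = "stem", count = sample(1:2, 1)))
    if (runif(1) < 0.7)
      epochs <- c(epochs, list(list(label = "recent",
                                    depth = runif(1, 0.01, 0.09),
                                    edges = sample(c("A", "B", "C", "D"),
                                                   sample(1:4, 1)),
                                    count = Inf)))
    cfg <- sim_config(dup_epochs = epochs, loss_rate = 0, L = 10,
                      seed = 5600 + rep)
    h <- simulate_gene_history(cfg)
    rec <- reconcile(h$gene_tree, cfg$species_tree, h$species_map,
                     ancestor = "ROOT")
    expect_equal(rec$n_duplications, h$truth$n_duplications_retained)
    # epoch class of every retained duplication is recovered
    ev <- h$truth$events
    retained <- ev[ev$type == "duplication" & ev$retained, ]
    lab <- h$gene_tree$node.label
    for (r in seq_len(nrow(retained))) {
      node <- ape::Ntip(h$gene_tree) +
        which(lab == paste0("D", retained$node_id[r]))
      expect_true(node %in% rec$duplication_nodes)
      expect_equal(unname(rec$age_class[as.character(node)]),
                   retained$epoch[r])
    }
  }
})

test_that("sibling pair dS matches the epoch target on average", {
  ds_hat <- numeric(0)
  for (rep in 1:20) {
    sp2 <- ape::read.tree(text = "(A:0.1,B:0.1)ROOT;")
    cfg <- sim_config(species_tree = sp2,
                      dup_epochs = list(list(label = "e", depth = 0.2,
                                             edges = "stem", count = 1)),
                      loss_rate = 0, L = 200, kappa = 2, omega = 0.2,
                      seed = 700 + rep)
    h <- simulate_gene_history(cfg)
    aln <- evolve_alignment(h$gene_tree, cfg)
    m <- codon_matrix(aln)
    # the two A copies coalesce at the duplication (depth 0.2 -> dS 0.4)
    r <- ng86_pairwise(m["A_copy1", ], m["A_copy2", ])
    ds_hat <- c(ds_hat, r$dS)
  }
  se <- sd(ds_hat) / sqrt(length(ds_hat))
  expect_lt(abs(mean(ds_hat) - 0.4), 3 * se)
})

test_that("datasets on disk are complete and parseable", {
  outdir <- withr::local_tempdir()
  cfg <- sim_config(seed = 57, L = 20, loss_rate = 0)
  res <- make_dataset(cfg, outdir)
  expect_true(all(file.exists(res$files)))
  aln <- read_codon_fasta(res$files[["alignment"]])
  expect_equal(aln$n_codons, 20L)
  gt <- read_newick(res$files[["gene_tree"]])
  sm <- read_species_map(res$files[["species_map"]])
  expect_setequal(names(sm), gt$tip.label)
  truth <- read_table_tsv(res$files[["truth"]])
  expect_true(all(c("event_id", "type", "epoch", "retained") %in%
                    names(truth)))
  cfg_echo <- jsonlite::read_json(res$files[["config"]])
  expect_equal(cfg_echo$seed, 57L)
})
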