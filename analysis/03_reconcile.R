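#!/usr/bin/env Rscript
# Zmasek-Eddy reconciliation of the simulated gene tree against the
# species tree: duplication calls, loss count, age classes relative to
# the species-tree root, and paralog-pair cohorts.
# Writes results/reconciliation.tsv and results/pair_cohorts.tsv.

suppressPackageStartupMessages(library(genedup))

gt <- read_newick("results/data/gene_tree.nwk")
sp <- read_newick("results/data/species_tree.nwk")
sm <- read_species_map("results/data/species_map.tsv")

rec <- reconcile(gt, sp, sm, ancestor = "ROOT")

ntip <- ape::Ntip(gt)
node_df <- data.frame(
  node = seq_len(ntip + gt$Nnode),
  label = c(gt$tip.label, gt$node.label),
  mapping = rec$mapping,
  is_duplication = seq_len(ntip + gt$Nnode) %in% rec$duplication_nodes,
  stringsAsFactors = FALSE)
write_table(node_df, path = "results/reconciliation.tsv")
write_table(rec$pair_cohorts, path = "results/pair_cohorts.tsv")

truth <- read_table_tsv("results/data/truth_events.tsv")
cat(sprintf("Inferred %d duplications (%d in truth) and %d losses.\n",
            rec$n_duplications,
            sum(truth$type == "duplication" & truth$retained),
            rec$n_losses))
cat(sprintf("Paralog pairs: %d ancestral, %d recent.\n",
            sum(rec$pair_cohorts$age_class == "ancestral"),
            sum(rec$pair_cohorts$age_class == "recent")))
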