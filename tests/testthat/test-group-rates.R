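test_that("group concatenation is codon-respecting and order-invariant", {
  set.seed(31)
  g1 <- aln_from_codons(t1 = c("ATG", "AAA", "CCC"),
                        t2 = c("ATG", "AAG", "CCC"))
  g2 <- aln_from_codons(t1 = c("GGG", "TTT", "TCT"),
                        t2 = c("GGG", "TTC", "TCT"))
  gmap <- data.frame(gene = c("rpl2", "rpl14"), group = "rpl",
                     stringsAsFactors = FALSE)
  out <- concat_by_group(list(rpl2 = g1, rpl14 = g2), gmap)
  expect_equal(out$rpl$n_codons, 6L)
  out_rev <- concat_by_group(list(rpl14 = g2, rpl2 = g1), gmap)
  expect_identical(out$rpl$seqs, out_rev$rpl$seqs)
  # sorted gene order within the concatenation
  expect_equal(attr(out$rpl, "genes")$gene, c("rpl14", "rpl2"))

  # missing taxa padded with gaps
  g3 <- aln_from_codons(t1 = c("AAA", "AAA"))
  out2 <- concat_by_group(list(rpl2 = g1, rpl14 = g3), gmap)
  expect_match(out2$rpl$seqs[["t2"]], "^------")

  # unmapped gene warns, empty group warns
  expect_warning(concat_by_group(list(rpl2 = g1, zzz = g2), gmap),
                 "not in group map")
  gmap2 <- rbind(gmap, data.frame(gene = "psbA", group = "psb"))
  expect_warning(concat_by_group(list(rpl2 = g1, rpl14 = g2), gmap2),
                 "no genes")
})

test_that("pairwise-outgroup terminal rates behave at the fixed points", {
  aln <- aln_from_codons(ref = c("ATG", "AAA", "CCC", "GGG"),
                        same = c("ATG", "AAA", "CCC", "GGG"),
                        far = c("ATG", "AAG", "CCA", "GGG"))
  tr <- terminal_branch_rates(aln, NULL, mode = "pairwise_outgroup",
                              ref_taxon = "ref")
  expect_equal(tr$dN[tr$taxon == "same"], 0)
  expect_equal(tr$dS[tr$taxon == "same"], 0)
  expect_error(terminal_branch_rates(aln, NULL, mode = "pairwise_outgroup",
                                     ref_taxon = "nope"), "missing")
  expect_error(terminal_branch_rates(aln, NULL, mode = "zzz"), "arg")
})

test_that("doubled omega on focal tips raises focal dN in both modes", {
  # two-class simulation: focal branches evolve with omega x2
  sp <- species_tree_6()
  cfg <- sim_config(species_tree = sp, dup_epochs = list(), loss_rate = 0,
                    L = 240, kappa = 2, omega = 0.2, seed = 314)
  h <- simulate_gene_history(cfg)
  gt <- h$gene_tree
  ntip <- ape::Ntip(gt)
  focal_taxa <- c("E_copy1", "F_copy1")
  branch_omega <- rep(0.2, nrow(gt$edge))
  focal_edges <- gt$edge[, 2] <= ntip &
    gt$tip.label[pmin(gt$edge[, 2], ntip)] %in% focal_taxa
  branch_omega[focal_edges] <- 0.4
  set.seed(314)
  aln <- evolve_alignment(gt, cfg, pi = uniform_pi(),
                          branch_omega = branch_omega)

  # pairwise mode, reference = background taxon A
  pr <- terminal_branch_rates(aln, NULL, mode = "pairwise_outgroup",
                              ref_taxon = "A_copy1")
  focal <- pr$dN[pr$taxon %in% focal_taxa]
  other <- pr$dN[!pr$taxon %in% focal_taxa]
  expect_gt(median(focal), median(other))

  # free-ratio ML mode sees the same acceleration and ranks concordantly
  mr <- terminal_branch_rates(aln, gt, mode = "free_ratio_ml",
                              n_starts = 1, control = list(factr = 1e9))
  focal_ml <- mr$dN[mr$taxon %in% focal_taxa]
  other_ml <- mr$dN[!mr$taxon %in% focal_taxa]
  expect_gt(median(focal_ml), median(other_ml))
  merged <- merge(pr, mr, by = "taxon", suffixes = c("_pw", "_ml"))
  rho <- cor(merged$dN_pw, merged$dN_ml, method = "spearman")
  expect_gt(rho, 0.7)
})

test_that("clade rate tests report per-group Bonferroni results", {
  set.seed(33)
  rows <- rbind(
    data.frame(group = "rpl", taxon = paste0("f", 1:4),
               dN = c(0.30, 0.31, 0.29, 0.33), dS = runif(4, 0.2, 0.3)),
    data.frame(group = "rpl", taxon = paste0("o", 1:4),
               dN = c(0.10, 0.12, 0.11, 0.09), dS = runif(4, 0.2, 0.3)),
    data.frame(group = "atp", taxon = paste0("f", 1:4),
               dN = runif(4, 0.1, 0.12), dS = runif(4, 0.2, 0.3)),
    data.frame(group = "atp", taxon = paste0("o", 1:4),
               dN = runif(4, 0.1, 0.12), dS = runif(4, 0.2, 0.3)))
  res <- clade_rate_test(rows, focal_taxa = paste0("f", 1:4), n_groups = 2)
  expect_equal(nrow(res), 4L)  # 2 groups x {dN, dS}
  rpl_dn <- res[res$group == "rpl" & res$metric == "dN", ]
  expect_equal(rpl_dn$direction, 1)
  # complete separation of 4 vs 4: exact two-sided p = 2/choose(8,4)
  expect_equal(rpl_dn$p, 2 / choose(8, 4), tolerance = 1e-12)
  expect_equal(rpl_dn$p_adj, min(1, rpl_dn$p * 2))
  # identical distributions give p = 1 (no signal)
  rows2 <- data.frame(group = "x", taxon = c(paste0("f", 1:3), paste0("o", 1:3)),
                      dN = rep(c(0.1, 0.2, 0.3), 2),
                      dS = rep(c(0.1, 0.2, 0.3), 2))
  res2 <- clade_rate_test(rows2, paste0("f", 1:3))
  expect_equal(res2$p, c(1, 1))
  # too-small groups are skipped with a warning, retained groups remain
  rows3 <- rbind(rows2,
                 data.frame(group = "y", taxon = c("f9", "o9"),
                            dN = 1:2, dS = 1:2))
  ws <- testthat::capture_warnings(
    res3 <- clade_rate_test(rows3, c(paste0("f", 1:3), "f9")))
  expect_length(ws, 2)  # one skip per rate type
  expect_match(ws, "fewer than 2", all = TRUE)
  expect_setequal(unique(res3$group), "x")
  # all groups too small: error after the warnings
  rows4 <- data.frame(group = "y", taxon = c("f1", "o1"), dN = 1:2, dS = 1:2)
  expect_error(suppressWarnings(clade_rate_test(rows4, "f1")), "no group")
})

test_that("default group map lists the eight rpl complex partners", {
  gm <- default_group_map()
  expect_setequal(gm$gene[gm$group == "rpl"],
                  c("rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "rpl23",
                    "rpl33", "rpl36"))
  expect_setequal(unique(gm$group),
                  c("atp", "pet", "ndh", "psa", "psb", "rpo", "rps", "rpl"))
})
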