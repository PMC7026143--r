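test_that("pairwise identity uses gap-excluded comparable columns", {
  aln <- codon_alignment(c(a = "ACGT--", b = "ACGA--", c = "AC-TAA"))
  m <- pairwise_identity(aln)
  expect_equal(diag(m), c(a = 100, b = 100, c = 100))
  expect_equal(m["a", "b"], 75)        # 3/4 over comparable columns
  expect_equal(m["a", "c"], 100)       # "AC-T" vs "ACGT" -> 3/3
  expect_equal(m, t(m))
  # no comparable columns -> NA
  aln2 <- codon_alignment(c(a = "AAA---", b = "---AAA"))
  expect_true(is.na(pairwise_identity(aln2)["a", "b"]))
})

test_that("gc content matches hand values and is length-additive", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("AC-GT-"), 50)
  expect_error(gc_content("---"), "empty")
  s1 <- "ACGTAC"
  s2 <- "GGTTAACC"
  combined <- gc_content(paste0(s1, s2))
  expected <- (gc_content(s1) * nchar(s1) + gc_content(s2) * nchar(s2)) /
    (nchar(s1) + nchar(s2))
  expect_equal(combined, expected)
})

test_that("integrity classification follows the three pseudogene rules", {
  ct <- codon_tables()
  intact <- paste0("ATG", paste(rep("GCA", 17), collapse = ""), "TAA")
  expect_equal(classify_integrity(intact)$status, "intact")

  premature <- paste0("ATG", paste(rep("GCA", 3), collapse = ""), "TAA",
                      paste(rep("GCA", 13), collapse = ""), "TAA")
  cls <- classify_integrity(premature)
  expect_equal(cls$status, "pseudogene")
  expect_equal(cls$reason, "premature_stop")
  expect_equal(cls$stop_codon_index, 5L)

  # 1-bp deletion against the reference length -> frameshift
  del1 <- substring(intact, 2)
  cls2 <- classify_integrity(del1, ref_length = nchar(intact))
  expect_equal(cls2$reason, "frameshift")

  no_stop <- paste0("ATG", paste(rep("GCA", 18), collapse = ""))
  expect_equal(classify_integrity(no_stop)$reason, "no_terminal_stop")

  expect_error(classify_integrity("ATG"), "shorter")
})

test_that("species summaries report ranges, mutation types and integrity", {
  pc <- make_paralog_clones(species = c("sp1", "sp2"), n_intact = c(3L, 2L),
                            n_pseudo = c(1L, 0L), seed = 7)
  tab <- summarize_species(pc$clone_sets, pc$alignment,
                           ref_length = pc$ref_length)
  expect_equal(nrow(tab), 2L)
  r1 <- tab[tab$species == "sp1", ]
  expect_equal(r1$intact_copy_number, 3L)
  expect_equal(r1$pseudogene_number, 1L)
  expect_equal(r1$integrity, "I & P (1)")
  expect_equal(tab$integrity[tab$species == "sp2"], "I")
  expect_match(r1$mutation_type, "SNPs")

  # identical clones: degenerate ranges, no mutation types
  two <- c(x1 = "ATGGCAGCATAA", x2 = "ATGGCAGCATAA")
  tab2 <- summarize_species(list(spX = two),
                            codon_alignment(two))
  expect_equal(tab2$identity_range, "100")
  expect_equal(tab2$mutation_type, "")

  # substitution + in-frame indel -> "Indels/SNPs"
  pairX <- c(y1 = "ATGGCAGCAGCATAA", y2 = "ATGGAA---GCATAA")
  tab3 <- summarize_species(list(spY = pairX), codon_alignment(pairX))
  expect_equal(tab3$mutation_type, "Indels/SNPs")

  expect_warning(summarize_species(list(spZ = character(0),
                                        spX = two),
                                   codon_alignment(two)),
                 "no sequences")
})

test_that("identity permutation invariance", {
  set.seed(41)
  seqs <- vapply(1:4, function(i)
    paste(random_codons(10), collapse = ""), character(1))
  names(seqs) <- paste0("s", 1:4)
  m1 <- pairwise_identity(codon_alignment(seqs))
  m2 <- pairwise_identity(codon_alignment(rev(seqs)))
  expect_equal(m1["s1", "s3"], m2["s1", "s3"])
})
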