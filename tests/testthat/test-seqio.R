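test_that("codon FASTA reading enforces frame and alphabet", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ATGAAA", ">b", "ATGAAG"), path)
  aln <- read_codon_fasta(path)
  expect_equal(aln$n_codons, 2L)
  expect_equal(aln$taxa, c("a", "b"))

  writeLines(c(">a", "ATGAAAT", ">b", "ATGAAGT"), path)
  expect_error(read_codon_fasta(path), "frame error")

  writeLines(c(">a", "ATG---AAA", ">b", "ATGCCCAAA"), path)
  aln <- read_codon_fasta(path)
  expect_equal(unname(codon_matrix(aln)[1, 2]), "---")

  writeLines(c(">a", "ATGAAA", ">b", "ATGAA?"), path)
  expect_error(read_codon_fasta(path), "parse error")

  writeLines(c(">a", "ATGAAA", ">b", "ATGAAGCCC"), path)
  expect_error(read_codon_fasta(path), "unequal")

  writeLines(c(">a", "ATGAAA", ">a", "ATGAAG"), path)
  expect_error(read_codon_fasta(path), "duplicate")
})

test_that("FASTA round-trips and codon slicing count columns", {
  set.seed(1)
  aln <- aln_from_codons(random_codons(17), random_codons(17),
                         random_codons(17))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_codon_fasta(aln, path)
  back <- read_codon_fasta(path)
  expect_identical(back$seqs, aln$seqs)
  expect_equal(ncol(codon_matrix(back)), (back$length - back$frame) / 3)
})

test_that("newick reading validates structure", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):0.5,C:1.5);", path)
  tr <- read_newick(path)
  expect_equal(ape::Ntip(tr), 3L)
  expect_length(genedup:::node_children(tr)[[genedup:::root_node(tr)]], 2L)

  writeLines("(A,B,C);", path)
  tr <- read_newick(tr_path <- path)  # accepted as a tree...
  expect_s3_class(tr, "phylo")
  expect_error(genedup:::assert_rooted_binary(tr), "rooted|binary")

  writeLines("((A,B);", path)
  expect_error(read_newick(path), "parse error")

  writeLines("((A:1,A:1):0.5,C:1.5);", path)
  expect_error(read_newick(path), "duplicate")
})

test_that("newick round-trip preserves topology and lengths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)AB:0.5,C:1.5)R;", path)
  tr <- read_newick(path)
  out <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, out)
  tr2 <- read_newick(out)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE))
})

test_that("write_table is typed, deterministic and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(a = c("x", "y"), b = c(1L, 2L),
                   c = c(0.123456789, NaN), stringsAsFactors = FALSE)
  write_table(df, c(a = "chr", b = "int", c = "dbl"), path)
  lines <- readLines(path)
  expect_equal(lines[1], "a\tb\tc")
  expect_match(lines[3], "NA$")
  back <- read_table_tsv(path)
  expect_equal(back$a, df$a)
  expect_equal(back$b, df$b)
  expect_equal(back$c[1], signif(df$c[1], 6))
  expect_true(is.na(back$c[2]))

  # empty rows -> header-only file
  write_table(df[0, ], c(a = "chr", b = "int", c = "dbl"), path)
  expect_equal(readLines(path), "a\tb\tc")

  # schema mismatch
  expect_error(write_table(df, c(a = "chr", missing_col = "dbl"), path),
               "schema mismatch")
})

test_that("cleandata filtering drops gapped and ambiguous codon columns", {
  aln <- aln_from_codons(c("ATG", "AAA", "CCC"),
                         c("ATG", "---", "CCC"),
                         c("ATG", "AAA", "CCN"))
  out <- cleandata_filter(aln)
  expect_equal(out$n_codons, 1L)
  expect_equal(unname(codon_matrix(out)[, 1]), rep("ATG", 3))

  # no gaps -> identity
  aln2 <- aln_from_codons(c("ATG", "AAA"), c("ATG", "AAG"))
  expect_identical(cleandata_filter(aln2)$seqs, aln2$seqs)

  # everything filtered -> degenerate input error
  aln3 <- aln_from_codons(c("---", "AAA"), c("ATG", "--A"))
  expect_error(cleandata_filter(aln3), "degenerate")
})
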