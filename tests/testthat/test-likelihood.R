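test_that("zero-length two-leaf likelihood collapses to root frequencies", {
  set.seed(2)
  codons <- random_codons(15)
  aln <- aln_from_codons(A = codons, B = codons)
  tree <- ape::read.tree(text = "(A:0,B:0);")
  pi <- f3x4_frequencies(aln, pseudocount = TRUE)
  par <- codon_model_params(2, 0.3, pi, tree$edge.length)
  ll <- pruning_loglik(tree, aln, par)
  idx <- codon_tables()$index[codons]
  expect_equal(ll, sum(log(pi[idx])), tolerance = 1e-10)
})

test_that("pruning equals ancestral-state enumeration on 3-leaf trees", {
  set.seed(31)
  for (rep in 1:4) {
    tree <- ape::read.tree(text = sprintf("((A:%.3f,B:%.3f):%.3f,C:%.3f);",
                                          runif(1, 0.05, 0.4),
                                          runif(1, 0.05, 0.4),
                                          runif(1, 0.05, 0.3),
                                          runif(1, 0.05, 0.4)))
    L <- sample(5:12, 1)
    aln <- aln_from_codons(A = random_codons(L),
                           B = random_codons(L),
                           C = random_codons(L))
    pi <- f3x4_frequencies(aln, pseudocount = TRUE)
    par <- codon_model_params(runif(1, 1, 4), runif(1, 0.1, 1.5), pi,
                              tree$edge.length)
    expect_equal(pruning_loglik(tree, aln, par),
                 oracle_enum_loglik(tree, aln, par), tolerance = 1e-8)
  }
})

test_that("site independence: duplicating every site doubles the lnL", {
  set.seed(4)
  codons <- list(A = random_codons(10), B = random_codons(10),
                 C = random_codons(10))
  tree <- ape::read.tree(text = "((A:0.2,B:0.1):0.1,C:0.3);")
  aln1 <- aln_from_codons(A = codons$A, B = codons$B, C = codons$C)
  aln2 <- aln_from_codons(A = rep(codons$A, 2), B = rep(codons$B, 2),
                          C = rep(codons$C, 2))
  pi <- uniform_pi()
  par <- codon_model_params(2, 0.5, pi, tree$edge.length)
  expect_equal(2 * pruning_loglik(tree, aln1, par),
               pruning_loglik(tree, aln2, par), tolerance = 1e-8)
})

test_that("lnL is invariant under alignment leaf reordering", {
  set.seed(9)
  aln <- aln_from_codons(A = random_codons(12), B = random_codons(12),
                         C = random_codons(12))
  aln_rev <- codon_alignment(rev(aln$seqs))
  tree <- ape::read.tree(text = "((A:0.2,B:0.1):0.1,C:0.3);")
  par <- codon_model_params(2, 0.5, uniform_pi(), tree$edge.length)
  expect_equal(pruning_loglik(tree, aln, par),
               pruning_loglik(tree, aln_rev, par), tolerance = 1e-10)
})

test_that("likelihood rejects invalid input", {
  aln <- aln_from_codons(A = c("ATG"), B = c("ATG"))
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,C:0.1);")
  par <- codon_model_params(2, 0.5, uniform_pi(), tree$edge.length)
  expect_error(pruning_loglik(tree, aln, par), "missing leaf")
  tree2 <- ape::read.tree(text = "(A:0.1,B:-0.5);")
  expect_error(codon_model_params(2, 0.5, uniform_pi(), tree2$edge.length),
               ">= 0")
})

test_that("a single-class alternative reproduces the null fit", {
  set.seed(12)
  cfg <- sim_config(species_tree = species_tree_3(), dup_epochs = list(),
                    loss_rate = 0, L = 60, kappa = 2, omega = 0.3, seed = 12)
  h <- simulate_gene_history(cfg)
  aln <- evolve_alignment(h$gene_tree, cfg)
  f1 <- fit_branch_model(h$gene_tree, aln, n_starts = 1)
  f2 <- fit_branch_model(h$gene_tree, aln,
                         branch_class_map = rep(1L, nrow(h$gene_tree$edge)),
                         n_starts = 1)
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-6)
  expect_true(f1$converged)
  # bounds respected
  expect_true(all(f1$params$omega_by_class >= 1e-4 &
                    f1$params$omega_by_class <= 20))
  expect_true(all(f1$params$branch_lengths >= 0 &
                    f1$params$branch_lengths <= 50))
})

test_that("LRT statistics, chi-square p and Bonferroni behave", {
  f0 <- structure(list(lnL = -100), class = "likelihood_fit")
  f1 <- structure(list(lnL = -100), class = "likelihood_fit")
  r <- lrt(f0, f1, df = 1)
  expect_equal(r$stat, 0)
  expect_equal(r$p, 1)
  expect_equal(r$p_adj, 1)

  f2 <- structure(list(lnL = -100 + 3.841 / 2), class = "likelihood_fit")
  r2 <- lrt(f0, f2, df = 1)
  expect_equal(r2$p, 0.05, tolerance = 1e-3)

  # Bonferroni clamps at 1 (the "p = 1.00 after correction" behaviour)
  f3 <- structure(list(lnL = -100 + stats::qchisq(0.6, 1) / 2),
                  class = "likelihood_fit")
  r3 <- lrt(f0, f3, df = 1, n_tests = 3)
  expect_equal(r3$p, 0.4, tolerance = 1e-10)
  expect_equal(r3$p_adj, 1)

  # worse alternative flags an optimiser failure
  f4 <- structure(list(lnL = -101), class = "likelihood_fit")
  expect_warning(lrt(f0, f4, df = 1), "optimizer failure")
})

test_that("LRT is invariant to a constant added to both lnL values", {
  f0 <- structure(list(lnL = -500), class = "likelihood_fit")
  f1 <- structure(list(lnL = -497), class = "likelihood_fit")
  g0 <- structure(list(lnL = -1500), class = "likelihood_fit")
  g1 <- structure(list(lnL = -1497), class = "likelihood_fit")
  expect_equal(lrt(f0, f1, 1)$stat, lrt(g0, g1, 1)$stat)
})

test_that("branch dN/dS decomposition is consistent with omega", {
  pi <- uniform_pi()
  fitlike <- structure(list(
    params = codon_model_params(2, c(0.25, 1.0), pi,
                                c(0.1, 0.2, 0.3, 0.15),
                                branch_class = c(1L, 1L, 2L, 2L)),
    tree = ape::read.tree(text = "((A:0.1,B:0.2):0.3,C:0.15);")),
    class = "likelihood_fit")
  bd <- branch_dnds(fitlike)
  # dN/dS ratio per branch equals that branch's omega class value
  expect_equal(bd$dN / bd$dS, bd$omega, tolerance = 1e-10)
  # neutral class: dN = dS = t
  expect_equal(bd$dN[bd$omega == 1], bd$t[bd$omega == 1], tolerance = 1e-10)
})
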