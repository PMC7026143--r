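# Shared in-code fixtures.

sense_codons <- function() codon_tables()$codons

# Random sense-codon sequence as a codon vector.
random_codons <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(sense_codons(), n, replace = TRUE)
}

# A correlated codon-pair: b differs from a at a fraction of codons.
mutated_codons <- function(a, prop = 0.2) {
  b <- a
  k <- max(1, round(length(a) * prop))
  idx <- sample(seq_along(a), k)
  b[idx] <- sample(sense_codons(), k, replace = TRUE)
  b
}

aln_from_codons <- function(...) {
  seq_list <- list(...)
  seqs <- vapply(seq_list, paste, character(1), collapse = "")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("s", seq_along(seqs))
  codon_alignment(seqs)
}

uniform_pi <- function() {
  pi <- rep(1 / 61, 61)
  names(pi) <- sense_codons()
  pi
}

species_tree_3 <- function()
  ape::read.tree(text = "((A:0.1,B:0.1)AB:0.15,C:0.25)ROOT;")

species_tree_6 <- function()
  ape::read.tree(text = paste0(
    "(((A:0.08,B:0.08):0.08,(C:0.08,D:0.08):0.08):0.09,",
    "(E:0.16,F:0.16):0.09)ROOT;"))
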