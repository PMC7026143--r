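# Functional-group rate comparison: concatenate genes per complex
# (atp/pet/ndh/psa/psb/rpo/rps/rpl), estimate per-taxon terminal rates
# on a constraint tree, and test a focal clade against the rest.

#' Default plastid functional-group membership table
#'
#' Editable default mapping of plastid genes to the eight functional
#' groups, including the eight large-ribosomal-subunit genes whose
#' products assemble with rpl32.
#'
#' @return Data frame with columns `gene` and `group`.
#' @export
default_group_map <- function() {
  groups <- list(
    atp = c("atpA", "atpB", "atpE", "atpF", "atpH", "atpI"),
    pet = c("petA", "petB", "petD", "petG", "petL", "petN"),
    ndh = c("ndhA", "ndhB", "ndhC", "ndhD", "ndhE", "ndhF", "ndhG",
            "ndhH", "ndhI", "ndhJ", "ndhK"),
    psa = c("psaA", "psaB", "psaC", "psaI", "psaJ"),
    psb = c("psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH",
            "psbI", "psbJ", "psbK", "psbL", "psbM", "psbN", "psbT", "psbZ"),
    rpo = c("rpoA", "rpoB", "rpoC1", "rpoC2"),
    rps = c("rps2", "rps3", "rps4", "rps7", "rps8", "rps11", "rps12",
            "rps14", "rps15", "rps18", "rps19"),
    rpl = c("rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "rpl23",
            "rpl33", "rpl36"))
  data.frame(gene = unlist(groups, use.names = FALSE),
             group = rep(names(groups), lengths(groups)),
             stringsAsFactors = FALSE)
}

#' Concatenate gene alignments by functional group
#'
#' Genes within a group are concatenated in sorted gene-name order
#' (reproducible regardless of input order); taxa missing from a gene
#' are padded with gap codons. Genes absent from the group map are
#' excluded with a warning.
#'
#' @param gene_alignments Named list of `codon_alignment` objects (names
#'   are gene names).
#' @param group_map Data frame with columns `gene`, `group` (default
#'   [default_group_map()]).
#' @return Named list of per-group `codon_alignment` objects, each with
#'   attribute `genes` (data frame `gene`, `n_codons`).
#' @export
concat_by_group <- function(gene_alignments, group_map = default_group_map()) {
  if (is.null(names(gene_alignments)) || anyDuplicated(names(gene_alignments)))
    stop("gene_alignments must be uniquely named by gene")
  unmapped <- setdiff(names(gene_alignments), group_map$gene)
  if (length(unmapped) > 0)
    warning("genes not in group map, excluded: ",
            paste(unmapped, collapse = ", "))
  all_taxa <- sort(unique(unlist(lapply(gene_alignments, `[[`, "taxa"))))
  out <- list()
  for (grp in unique(group_map$group)) {
    genes <- sort(intersect(group_map$gene[group_map$group == grp],
                            names(gene_alignments)))
    if (length(genes) == 0) {
      warning("group '", grp, "' has no genes; skipped")
      next
    }
    parts <- lapply(genes, function(g) {
      a <- gene_alignments[[g]]
      pad <- paste(rep("-", a$n_codons * 3), collapse = "")
      s <- stats::setNames(rep(pad, length(all_taxa)), all_taxa)
      body <- substring(a$seqs, a$frame + 1L, a$frame + a$n_codons * 3L)
      s[a$taxa] <- body
      s
    })
    seqs <- do.call(paste0, parts)
    names(seqs) <- all_taxa
    aln <- codon_alignment(seqs, frame = 0L)
    attr(aln, "genes") <- data.frame(
      gene = genes,
      n_codons = vapply(genes, function(g) gene_alignments[[g]]$n_codons,
                        integer(1)),
      stringsAsFactors = FALSE)
    out[[grp]] <- aln
  }
  out
}

#' Per-taxon terminal-branch dN and dS for a gene group
#'
#' `free_ratio_ml` fits a free-ratio branch model (one omega class per
#' branch) on the constraint tree and reports each terminal branch's
#' model-based dN and dS (see [branch_dnds()]). `pairwise_outgroup`
#' computes NG86 rates of each taxon against a designated reference
#' taxon -- fast, and rank-concordant with the ML mode at low divergence.
#'
#' @param group_aln A per-group `codon_alignment`.
#' @param constraint_tree Rooted binary [ape::phylo] whose leaves are a
#'   subset of the alignment taxa.
#' @param mode `"free_ratio_ml"` or `"pairwise_outgroup"`.
#' @param ref_taxon Reference taxon (pairwise mode).
#' @param ... Passed to [fit_branch_model()] in ML mode.
#' @return Data frame: `taxon`, `dN`, `dS`.
#' @export
terminal_branch_rates <- function(group_aln, constraint_tree,
                                  mode = c("free_ratio_ml",
                                           "pairwise_outgroup"),
                                  ref_taxon = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "free_ratio_ml") {
    tree <- constraint_tree
    keep <- intersect(tree$tip.label, group_aln$taxa)
    if (length(keep) < length(tree$tip.label))
      stop("constraint tree leaves missing from alignment: ",
           paste(setdiff(tree$tip.label, keep), collapse = ", "))
    fit <- fit_branch_model(tree, group_aln,
                            branch_class_map = seq_len(nrow(tree$edge)), ...)
    bd <- branch_dnds(fit)
    term <- bd[bd$child_label != "", c("child_label", "dN", "dS")]
    names(term)[1] <- "taxon"
    rownames(term) <- NULL
    term
  } else {
    if (is.null(ref_taxon)) stop("pairwise_outgroup mode needs ref_taxon")
    if (!ref_taxon %in% group_aln$taxa)
      stop("reference taxon missing: ", ref_taxon)
    aln <- cleandata_filter(group_aln)
    m <- codon_matrix(aln)
    taxa <- setdiff(aln$taxa, ref_taxon)
    rows <- lapply(taxa, function(tx) {
      r <- ng86_pairwise(m[tx, ], m[ref_taxon, ])
      data.frame(taxon = tx, dN = r$dN, dS = r$dS, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}

#' Focal-clade rate test per functional group
#'
#' Within each group, compares focal-taxon rates against the remaining
#' taxa with a two-sided Wilcoxon rank-sum test, separately for dN and
#' dS, with Bonferroni correction across groups.
#'
#' @param group_rate_rows Data frame with columns `group`, `taxon`,
#'   `dN`, `dS`.
#' @param focal_taxa Character vector of focal taxa.
#' @param n_groups Bonferroni correction count (default: number of
#'   groups tested per metric).
#' @return Data frame: `group`, `metric`, `n_focal`, `n_other`, `W`,
#'   `p`, `p_adj`, `direction` (sign of focal median minus other
#'   median).
#' @export
clade_rate_test <- function(group_rate_rows, focal_taxa, n_groups = NULL) {
  stopifnot(all(c("group", "taxon", "dN", "dS") %in% names(group_rate_rows)))
  groups <- unique(group_rate_rows$group)
  rows <- list()
  for (grp in groups) {
    sub <- group_rate_rows[group_rate_rows$group == grp, ]
    for (metric in c("dN", "dS")) {
      v <- sub[[metric]]
      ok <- !is.na(v)
      focal <- v[ok & sub$taxon %in% focal_taxa]
      other <- v[ok & !(sub$taxon %in% focal_taxa)]
      if (length(focal) < 2 || length(other) < 2) {
        warning("group '", grp, "' (", metric,
                "): fewer than 2 taxa per side; skipped")
        next
      }
      wt <- wilcoxon_rank_sum(focal, other)
      rows[[length(rows) + 1]] <- data.frame(
        group = grp, metric = metric,
        n_focal = length(focal), n_other = length(other),
        W = wt$w_stat, p = wt$p_two_sided, p_adj = NA_real_,
        direction = sign(stats::median(focal) - stats::median(other)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no group had enough taxa on both sides")
  for (metric in unique(out$metric)) {
    sel <- out$metric == metric
    m <- if (is.null(n_groups)) sum(sel) else n_groups
    out$p_adj[sel] <- pmin(1, out$p[sel] * m)
  }
  out
}
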