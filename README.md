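# genedup

Inference of recurrent gene duplication in small gene families from
codon substitution rates, synonymous-distance (Ks) mixture peaks, and
gene-tree/species-tree reconciliation.

## The problem

Functional transfer of an organellar gene to the nucleus (intracellular
gene transfer), followed by rounds of duplication — for example through
repeated polyploidisation — leaves a family of nuclear paralogs whose
pairwise synonymous divergence records when each duplication happened.
The nuclear-encoded plastid *rpl32* gene of monkshoods (*Aconitum*) is
the motivating case: multiple divergent copies per species, a mix of
intact genes and pseudogenes, duplication episodes at very different
depths, accelerated evolution of the interacting plastid-encoded *rpl*
subunits, and heteroplasmic homopolymer variants in plastid *matK*.
`genedup` provides a tested, fully reproducible implementation of that
inferential chain for anyone analysing comparable paralog surveys.

## What is implemented

* **NG86 pairwise rates** — Nei–Gojobori counting with equal-weight
  pathway averaging over multi-hit codons (stop-blocked paths dropped
  and renormalised) and Jukes–Cantor correction:
  `dS = -(3/4) log(1 - 4 pS / 3)`, with saturation (`p >= 3/4`)
  reported as `NA`. `ng86_site_counts()`, `ng86_pairwise()`,
  `ng86_rates()`.
* **GY94/F3×4 codon models** — rate matrix
  `q_ij = pi_j kappa^[ti] omega^[nonsyn]` over the 61 sense codons,
  scaled to one substitution per codon per unit time; Felsenstein
  pruning likelihood; one-/two-/free-ratio branch models by bounded
  quasi-Newton ML; likelihood-ratio tests `2ΔlnL ~ χ²_df` with
  Bonferroni correction. `gy94_rate_matrix()`, `pruning_loglik()`,
  `fit_branch_model()`, `branch_dnds()`, `lrt()`.
* **Ks peak detection** — Gaussian mixtures on paralog-pair dS by EM
  (seeded k-means++ initialisation, σ floor, monotone lnL) with BIC
  selection `-2 lnL + (3K-1) log n`. `fit_gmm_em()`, `select_k_bic()`,
  `collect_ds()`.
* **Reconciliation** — Zmasek–Eddy LCA mapping, duplication calls,
  loss counts, ancestral/recent age classes, paralog-pair cohorts.
  `reconcile()`, `lca_map()`, `infer_duplications()`,
  `assign_pairs_to_events()`.
* **Cohort and clade tests** — self-implemented Wilcoxon rank-sum
  (exact by enumeration for small untied samples; tie-corrected,
  continuity-corrected normal approximation otherwise);
  functional-group concatenation and focal-clade rate tests.
  `wilcoxon_rank_sum()`, `compare_cohorts()`, `concat_by_group()`,
  `terminal_branch_rates()`, `clade_rate_test()`.
* **Clone-survey summaries** — paralog integrity classification
  (premature stop / frameshift / missing terminal stop), identity and
  GC range tables, homopolymer-run location and
  frameshift/in-frame/intact calls with per-individual heteroplasmy
  reports. `classify_integrity()`, `summarize_species()`,
  `locate_homopolymer()`, `call_clones()`, `summarize_individuals()`.
* **A truth-emitting simulator** — species trees, duplication/loss
  histories at configured epochs (truth tables exact), GY94 codon
  evolution with branch lengths calibrated so planted synonymous
  depths land on the NG86 estimator's own scale, optional per-branch
  ω acceleration, and clone-set generators with planted pseudogenes
  and homopolymer indels. `sim_config()`, `simulate_gene_history()`,
  `evolve_alignment()`, `make_dataset()`.

## Worked example

Simulate the default study conditions — four species, one ancestral
duplication (pair dS target 0.8), recent duplications on every
terminal edge (pair dS target 0.15), 10% stochastic loss — then run
the chain:

```r
library(genedup)

cfg <- sim_config(loss_rate = 0.1, seed = 42)
h   <- simulate_gene_history(cfg)
aln <- evolve_alignment(h$gene_tree, cfg)

rates <- ng86_rates(aln)
rec   <- reconcile(h$gene_tree, cfg$species_tree, h$species_map,
                   ancestor = "ROOT")
rec
#> reconciliation: 9 duplications, 0 losses, 72 paralog pairs

ds  <- collect_ds(rates, rec$pair_cohorts)
fit <- select_k_bic(ds$entries$ds, k_max = 4, seed = 42)
fit
#> mixture_model: K = 2, lnL = 108.583, BIC = -195.783
#>   means: 0.1409, 0.7282
#>   sds:   0.01654, 0.04189
#>   w:     0.1111, 0.8889

compare_cohorts(ds)
#>      cohort  n median_ds
#> 1    recent  8 0.1414159
#> 2 ancestral 64 0.7300089
#> Wilcoxon p = 1.671e-10; ancestral > recent: TRUE
```

Reading the output: reconciliation recovers all nine planted
duplications (the stem duplication plus eight recent terminal-edge
ones); BIC selects two dS peaks whose means (0.14 and 0.73) sit near
the planted synonymous depths (0.15 and 0.8); and the ancestral cohort
is significantly more diverged than the recent cohort — the two-epoch
duplication history is read back from sequence data alone.

The numbered scripts under `analysis/` run the same chain as a
narrative workflow (simulation, rates, reconciliation, Ks peaks,
branch-model LRTs, functional-group tests, clone-survey summaries),
writing their tables under `results/`.

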