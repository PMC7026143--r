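---
title: "Methods: inferring recurrent gene duplication from codon rates, Ks peaks and reconciliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring recurrent gene duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genedup)
```

# The scientific problem

When an organellar gene such as plastid *rpl32* relocates to the nucleus
and is subsequently duplicated — for instance through repeated
polyploidisation — the surviving paralogs carry a record of those
duplication episodes in their synonymous divergence. `genedup`
implements the full inferential chain for reading that record in small
gene families:

1. **Pairwise substitution rates.** Nei–Gojobori (1986) counting with
   pathway averaging and Jukes–Cantor correction yields dS and dN per
   sequence pair.
2. **Duplication dating.** The pooled paralog-pair dS values form a Ks
   distribution; Gaussian mixtures fitted by EM with BIC model
   selection identify the duplication peaks.
3. **Event placement.** Zmasek–Eddy least-common-ancestor
   reconciliation of the rooted gene tree against the species tree
   calls duplication nodes, counts implied losses, and splits
   paralog pairs into *recent* and *ancestral* cohorts relative to a
   user-named ancestor.
4. **Selection tests.** Goldman–Yang (1994) codon models with F3×4
   frequencies and Felsenstein pruning support one-ratio, two-ratio
   and free-ratio branch models; nested models are compared by
   likelihood-ratio tests with Bonferroni correction.
5. **Cohort and clade contrasts.** A self-contained Wilcoxon rank-sum
   test (exact by enumeration for small samples, tie-corrected normal
   approximation otherwise) compares divergence cohorts and
   functional-group rates.
6. **Clone-survey summaries.** Paralog integrity classification
   (premature stops, frameshifts, missing terminal stops), identity/GC
   summary tables, and homopolymer-run heteroplasmy calls for clone
   sets around slippage-prone tracts.

A truth-emitting simulator (`sim_config()`, `simulate_gene_history()`,
`evolve_alignment()`) generates every input with known ground truth, so
each stage is tested against what was planted rather than against
itself.

# Models and conventions

## NG86 pairwise rates

Site counts use the convention that each codon position contributes a
denominator of 3 and changes into stop codons are excluded from the
numerators, so a codon's `s + n` equals 3 minus the stop-excluded
fraction. Multi-hit codon pairs are averaged over all orderings of
single-nucleotide steps with equal weight; orderings passing through a
stop codon are dropped and the remainder renormalised. In the rare case
where every ordering is blocked, all orderings are used with
stop-involving steps counted as nonsynonymous. `p >= 3/4` saturates the
JC69 correction; such rates are reported as `NA`, excluded downstream,
and counted (`n_excluded_saturated`).

Pairwise dS/dN deliberately uses this deterministic counting method
rather than a pairwise ML estimate: it is exactly reproducible, has a
brute-force enumeration oracle the tests exercise on hundreds of random
pairs, and is accurate enough for building Ks distributions at the
divergences of interest (dS well below saturation).

## GY94 codon model and likelihood

The rate matrix over the 61 sense codons has
`q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]` for
single-nucleotide changes and is rescaled to one expected substitution
per codon per unit branch length, the codeml convention for branch
lengths. Transition matrices come from a symmetrising
eigendecomposition of the reversible generator, with a
scaling-and-squaring fallback. F3×4 frequencies multiply
position-specific nucleotide frequencies and renormalise over sense
codons; the plain estimator is used for reporting, while model fitting
adds a 0.5 pseudocount at positions with an absent nucleotide because
the eigendecomposition requires strictly positive frequencies.

`fit_branch_model()` maximises the pruning log-likelihood jointly over
κ, per-class ω and all branch lengths with bounded L-BFGS-B (κ ∈
[0.01, 100], ω ∈ [1e-4, 20], t ∈ [0, 50]; κ and ω on the log scale).
The default is three seeded starts (one heuristic, two perturbed); the
likelihood-ratio analyses in this package use a single start with the
alternative model initialised at the null optimum, which guarantees
`lnL_alt >= lnL_null`, keeps the statistic non-negative by
construction, and makes a 100-replicate calibration affordable. Per-
branch dN and dS are recovered from a fitted model by splitting each
branch's expected substitutions into synonymous and nonsynonymous flux
under the fitted matrix and dividing by the model-based site fractions
evaluated at ω = 1 — the ratio of the two is exactly the branch's ω.

## Mixture peaks

Mixtures are fitted on raw dS (not log-transformed) capped at
`ds_cap = 3` — beyond that the JC69 correction is dominated by
saturation artifacts. EM uses k-means++-style seeded initialisation, a
σ floor of 1e-3 against component collapse, convergence at
|ΔlnL| < 1e-6, and `BIC = -2 lnL + (3K - 1) log n`; `select_k_bic()`
takes the best of 10 seeded runs per K and returns the minimal-BIC
model. A "peak" is a fitted component mean of the selected model.

## Reconciliation

Gene trees must arrive rooted and binary; multifurcations are rejected
rather than silently resolved, because arbitrary resolution changes
duplication counts, and silent re-rooting would hide errors.
A node is a duplication iff it maps to the same species-tree node as
one of its children. Losses follow the standard path-length counting:
for each gene-tree edge, the number of species-tree edges skipped minus
one (clamped at zero), plus one when a duplication's child maps below
it. The ancestral/recent boundary is a required user parameter (a
species-tree node label or an MRCA-defining species set) — no automatic
depth threshold is imposed.

## Wilcoxon rank-sum test

Exact p-values are computed by dynamic programming over the rank-sum
distribution whenever the smaller sample has at most 10 observations
and there are no ties; otherwise a normal approximation with
tie-corrected variance and a 0.5 continuity correction is used. All
tests are two-sided. The tests cross-check both branches against full
enumeration and against `stats::wilcox.test()`.

# The simulator and what it does (and does not) emulate

Time is measured in **synonymous-distance units per lineage**: a
duplication placed at depth *u* yields descendant pairs with expected
pairwise NG86 dS of 2*u*. The conversion from dS-time to branch lengths
in expected substitutions per codon inverts the *analytically computed
expectation of the NG86 estimator itself* under the generating GY94
kernel (root-finding to 1e-8); because the mapping is applied to
ultrametric node depths and telescoped along paths, every pair's total
divergence hits its target exactly in expectation. This choice puts
simulated synonymous depths on the same scale as the estimates the
pipeline produces, which is what the closed-loop recovery checks
measure.

Duplication epochs are placed deterministically at configured
species-tree positions, so the emitted truth tables are exact; losses
are a Poisson pruning process within species-tree branches (the root
stem carries duplications but no loss exposure, so a configured
stem duplication is never silently erased). Lineage-specific
rate acceleration can be planted per branch (`branch_omega`); such
branches are rescaled to preserve the synonymous clock, so ω shifts
move dN without distorting dS — the pattern relaxed constraint
produces in real data.

The default study conditions are a four-species balanced ultrametric
tree, one ancestral duplication on the stem (pair dS target 0.8),
recent duplications on every terminal edge (pair dS target 0.15), 500
codons, κ = 2, ω = 0.2, uniform codon frequencies. Five hundred codons
is longer than a single *rpl32*-sized gene; it was chosen so that
per-pair dS estimates are precise enough (s.d. ≈ 0.07 at dS 0.8) for
peak positions to be interpretable, comparable to pooling information
across a full paralog set.

Features of real data deliberately *not* emulated: indels and alignment
error in the main alignment (gaps appear only in clone sets),
among-site rate heterogeneity, codon-usage shifts between paralogs, GC-
biased gene conversion, and concerted evolution. Passing tests
therefore demonstrate correctness of the inferential machinery under
the stated generative model, not robustness to those violations.

## A caution on pooled paralog pairs

All pairs descending from one duplication share parts of their tree
path, so pooled dS values are positively correlated within events. With
many pairs per event the BIC occasionally (about one run in five under
the default conditions) resolves this within-event structure as an
extra mixture component and reports K = 3 instead of 2 — the same
phenomenon that makes "adjusted" mixture fits report additional peaks
inside an ancestral duplication cohort on real data. The cohort
comparison (medians and Wilcoxon contrast) is insensitive to this and
is the robust summary.

# Numerical choices

* Pattern compression of alignment columns before pruning; per-node
  rescaling against underflow only when partial likelihoods drift
  below 1e-250.
* Eigendecomposition reconstruction is checked row-stochastically;
  negative round-off entries are clamped and rows renormalised.
* Optimiser convergence: L-BFGS-B `factr = 1e7` (about 1e-9 relative);
  the LRT calibration loop relaxes to `factr = 1e9`, still two orders
  of magnitude tighter than the 0.05-level decision boundary.
* Mixture EM stops at |ΔlnL| < 1e-6 or 500 iterations; non-convergence
  is flagged, never silent.
* Ties in `locate_homopolymer()` resolve leftmost; clone anchoring uses
  exact 15-bp flanks because generic aligners misplace gaps inside
  homopolymer tracts.
* All randomness flows from one root seed through named per-stage
  derived seeds, each kept below 2^31.

# Problem sizes used by the checks

The test-suite and the acceptance script run, among others: 200
random 50-codon pairs against the NG86 enumeration oracle; 20 random
3-leaf likelihood cases against 61²-state enumeration; ω recovery on
six-leaf, 500-codon alignments (5 seeds per truth value); a
100-replicate two-ratio LRT calibration on 3-leaf, 120-codon
alignments; 20-seed mixture recovery at n = 300; exhaustive
reconciliation checks for all rooted gene-tree topologies on up to 5
leaves over a 3-species tree; and the full pipeline on the default
two-epoch conditions. These sizes were chosen to give each check clear
statistical resolution while keeping a complete run in the minutes
range on a single core.

# Known limitations

* Pairwise rates are NG86, not ML; at dS approaching saturation the
  JC69 correction is biased and such pairs are excluded rather than
  corrected.
* Site-model tests (positive selection at individual codons) are out
  of scope; only branch models are implemented.
* Reconciliation is parsimony-based (LCA); no probabilistic
  duplication-loss model, no horizontal transfer events.
* The simulator does not generate alignment gaps, so `cleandata`
  filtering is exercised by constructed fixtures rather than by the
  generative model.
* Free-ratio terminal dN/dS extraction is one of several defensible
  readings of "per-taxon rates on a constraint tree"; the pairwise
  outgroup mode is provided as the fast alternative, and the two are
  rank-concordant at low divergence.
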