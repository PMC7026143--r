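# GY94 sequence evolution along simulated gene trees, with branch
# lengths calibrated so that dS-time is on the NG86 estimator's scale,
# plus clone-set generators for the summary and heteroplasmy modules.

#' Expected NG86 dS between two sequences at divergence t
#'
#' Analytic expectation under the GY94 kernel: expected pathway-averaged
#' synonymous differences per codon at total divergence `t`
#' (substitutions per codon), divided by the NG86 synonymous site count
#' at equilibrium, then JC69-corrected.
#'
#' @param t Total divergence of the pair, expected substitutions per
#'   codon.
#' @param kappa,omega,pi GY94 parameters.
#' @return Expected dS (scalar; `NA` if saturated).
#' @export
expected_ng86_ds <- function(t, kappa, omega, pi) {
  Q <- gy94_rate_matrix(kappa, omega, pi)
  eig <- gy94_eigen(Q)
  P <- transition_probs(eig, t)
  diffs <- ng86_diff_tables()
  sites <- ng86_site_table()
  E_sd <- sum(pi * rowSums(P * diffs$sd))
  E_s <- sum(pi * sites$s)
  jc69_correct(E_sd / E_s)
}

#' Convert a target pair dS into a branch length
#'
#' Solves `expected_ng86_ds(t) = target_ds` for the total divergence
#' `t` (Newton iteration with a bracketing fallback, tolerance 1e-8).
#'
#' @param target_ds Target expected NG86 dS of the pair (>= 0).
#' @param kappa,omega,pi GY94 parameters.
#' @param tol Convergence tolerance (default 1e-8).
#' @return Total divergence in expected substitutions per codon.
#' @export
ds_to_branch_length <- function(target_ds, kappa, omega, pi, tol = 1e-8) {
  if (target_ds < 0) stop("target_ds must be >= 0")
  if (target_ds == 0) return(0)
  Q <- gy94_rate_matrix(kappa, omega, pi)
  eig <- gy94_eigen(Q)
  diffs <- ng86_diff_tables()
  sites <- ng86_site_table()
  E_s <- sum(pi * sites$s)
  f <- function(t) {
    P <- transition_probs(eig, t)
    jc69_correct(sum(pi * rowSums(P * diffs$sd)) / E_s) - target_ds
  }
  # Newton with numeric derivative, bisection fallback
  t <- target_ds  # decent starting guess: dS-scale is within ~2x of t
  lo <- 0
  hi <- 50
  for (it in 1:100) {
    ft <- f(t)
    if (is.na(ft)) { t <- (lo + t) / 2; next }
    if (abs(ft) < tol) return(t)
    if (ft > 0) hi <- min(hi, t) else lo <- max(lo, t)
    h <- max(1e-6, 1e-4 * t)
    df <- (f(t + h) - ft) / h
    t_new <- if (is.finite(df) && df > 0) t - ft / df else NA
    if (is.na(t_new) || t_new <= lo || t_new >= hi) t_new <- (lo + hi) / 2
    t <- t_new
  }
  t
}

# Per-lineage substitutions-per-codon depth g(u) for dS-time depth u:
# half the total divergence that gives pair dS = 2u. Telescoping over an
# ultrametric gene tree makes every pair's total divergence exact.
ds_time_to_subs_depth <- function(u, kappa, omega, pi) {
  vapply(u, function(ui) {
    if (ui <= 0) 0 else ds_to_branch_length(2 * ui, kappa, omega, pi) / 2
  }, numeric(1))
}

#' Evolve a codon alignment along a gene tree
#'
#' The root sequence is drawn from the equilibrium frequencies; each
#' branch evolves every site independently by the GY94 transition
#' kernel. Branch lengths of the input tree are in dS-time units and
#' are converted to expected substitutions per codon via the NG86
#' calibration, so sibling copies from an epoch at dS-time depth `u`
#' have expected pairwise NG86 dS close to `2u`. The state space is the
#' 61 sense codons: no stop codon ever appears in frame.
#'
#' @param gene_tree Rooted binary [ape::phylo], ultrametric in dS-time.
#' @param config A `sim_config` (uses `L`, `kappa`, `omega`,
#'   `pi_mode`).
#' @param pi Optional explicit codon frequencies (overrides
#'   `pi_mode`).
#' @param branch_omega Optional per-edge omega vector (rows of
#'   `gene_tree$edge`) overriding `config$omega` on those branches --
#'   used to plant lineage-specific rate acceleration. Such branches
#'   are rescaled so their synonymous flux matches the background
#'   calibration: omega changes raise (or lower) dN while the
#'   synonymous clock is preserved.
#' @return A `codon_alignment` over the gene-tree leaves.
#' @export
evolve_alignment <- function(gene_tree, config, pi = NULL,
                             branch_omega = NULL) {
  assert_rooted_binary(gene_tree, "gene tree")
  if (is.null(pi)) pi <- sim_pi(config)
  if (!is.null(branch_omega) &&
      length(branch_omega) != nrow(gene_tree$edge))
    stop("branch_omega must have one entry per edge")
  ct <- codon_tables()
  # node depths in dS-time from the (ultrametric) branch lengths
  ntip <- ape::Ntip(gene_tree)
  nn <- ntip + gene_tree$Nnode
  par <- node_parents(gene_tree)
  elen <- numeric(nn)
  elen[gene_tree$edge[, 2]] <- gene_tree$edge.length
  root <- root_node(gene_tree)
  above <- vapply(seq_len(nn), function(v) {
    d <- 0
    while (v != root) { d <- d + elen[v]; v <- par[v] }
    d
  }, numeric(1))
  depth_ds <- max(above[seq_len(ntip)]) - above
  gdepth <- ds_time_to_subs_depth(pmax(depth_ds, 0), config$kappa,
                                  config$omega, pi)
  omegas <- if (is.null(branch_omega)) rep(config$omega, nrow(gene_tree$edge))
            else branch_omega
  eigs <- list()
  tscale <- list()
  rho_bg <- attr(gy94_rate_matrix(config$kappa, config$omega, pi),
                 "rho_syn")
  for (w in unique(omegas)) {
    Qw <- gy94_rate_matrix(config$kappa, w, pi)
    eigs[[as.character(w)]] <- gy94_eigen(Qw)
    # preserve the synonymous clock on omega-shifted branches
    tscale[[as.character(w)]] <- rho_bg / attr(Qw, "rho_syn")
  }

  L <- config$L
  states <- matrix(NA_integer_, nn, L)
  states[root, ] <- sample.int(61, L, replace = TRUE, prob = pi)
  tr <- ape::reorder.phylo(gene_tree, "cladewise")
  edge_key <- paste(gene_tree$edge[, 1], gene_tree$edge[, 2])
  for (k in seq_len(nrow(tr$edge))) {
    a <- tr$edge[k, 1]
    b <- tr$edge[k, 2]
    e <- match(paste(a, b), edge_key)
    t_b <- max(0, gdepth[a] - gdepth[b]) * tscale[[as.character(omegas[e])]]
    if (t_b == 0) {
      states[b, ] <- states[a, ]
      next
    }
    P <- transition_probs(eigs[[as.character(omegas[e])]], t_b)
    out <- integer(L)
    for (s in unique(states[a, ])) {
      idx <- which(states[a, ] == s)
      out[idx] <- sample.int(61, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[b, ] <- out
  }
  seqs <- vapply(seq_len(ntip), function(i)
    paste(ct$codons[states[i, ]], collapse = ""), character(1))
  names(seqs) <- gene_tree$tip.label
  codon_alignment(seqs, frame = 0L)
}

#' Generate a complete simulated dataset on disk
#'
#' Runs [simulate_gene_history()] and [evolve_alignment()] and writes
#' the standard files every other module consumes: `alignment.fasta`,
#' `gene_tree.nwk`, `species_tree.nwk`, `species_map.tsv`,
#' `truth_events.tsv` and `config.json`, plus (optionally) clone sets
#' for the paralog-summary and heteroplasmy modules.
#'
#' @param config A `sim_config`.
#' @param outdir Writable output directory (created if missing).
#' @param clones Also write `matk_clones.fasta` and `matk_ref.fasta`
#'   from [make_matk_clones()] (default `TRUE`).
#' @return Invisibly, a list with the in-memory objects (`history`,
#'   `alignment`, `files`).
#' @export
make_dataset <- function(config, outdir, clones = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hist <- simulate_gene_history(config)
  aln <- evolve_alignment(hist$gene_tree, config)
  files <- c(
    alignment = file.path(outdir, "alignment.fasta"),
    gene_tree = file.path(outdir, "gene_tree.nwk"),
    species_tree = file.path(outdir, "species_tree.nwk"),
    species_map = file.path(outdir, "species_map.tsv"),
    truth = file.path(outdir, "truth_events.tsv"),
    config = file.path(outdir, "config.json"))
  write_codon_fasta(aln, files[["alignment"]])
  write_newick(hist$gene_tree, files[["gene_tree"]])
  write_newick(config$species_tree, files[["species_tree"]])
  write_table(data.frame(leaf = names(hist$species_map),
                         species = unname(hist$species_map),
                         stringsAsFactors = FALSE),
              c(leaf = "chr", species = "chr"), files[["species_map"]])
  ev <- hist$truth$events
  write_table(ev, c(event_id = "int", type = "chr", epoch = "chr",
                    species_location = "chr", depth = "dbl",
                    node_id = "int", retained = "lgl"), files[["truth"]])
  cfg_echo <- list(loss_rate = config$loss_rate, L = config$L,
                   kappa = config$kappa, omega = config$omega,
                   pi_mode = config$pi_mode, seed = config$seed,
                   species_tree = ape::write.tree(config$species_tree),
                   dup_epochs = config$dup_epochs)
  jsonlite::write_json(cfg_echo, files[["config"]], auto_unbox = TRUE,
                       digits = NA)
  if (clones) {
    mk <- make_matk_clones(seed = config$seed)
    files <- c(files,
               matk_ref = file.path(outdir, "matk_ref.fasta"),
               matk_clones = file.path(outdir, "matk_clones.fasta"))
    writeLines(c(">matk_ref", mk$ref), files[["matk_ref"]])
    con <- file(files[["matk_clones"]], "w")
    writeLines(unlist(lapply(names(mk$clones), function(id)
      c(paste0(">", id), mk$clones[[id]]))), con)
    close(con)
  }
  invisible(list(history = hist, alignment = aln, files = files))
}

# Random in-frame CDS of n_codons sense codons ending in a stop codon.
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ct <- codon_tables()
  body <- sample(setdiff(ct$codons, "ATG"), n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, sample(ct$stops, 1)), collapse = "")
}

#' Generate a clone set with homopolymer-length heteroplasmy
#'
#' Builds a reference CDS carrying a poly-T tract and clone sets for
#' several individuals whose tract lengths vary over a configured
#' spectrum, emulating slippage variants: non-triplet contractions are
#' frameshifts, triplet contractions are single-residue losses.
#'
#' @param ref_run_length Reference tract length in bp (default 11).
#' @param run_lengths Named list: individual -> integer vector of clone
#'   tract lengths (default: five individuals spanning 8-11 bp).
#' @param n_codons Reference length in codons (default 120).
#' @param seed Seed for the reference draw.
#' @return A list: `ref` (reference CDS string), `clones` (named
#'   character vector `IND|cloneN`), `region`
#'   ([locate_homopolymer()] output), `truth` (data frame of planted
#'   tract lengths per clone).
#' @export
make_matk_clones <- function(ref_run_length = 11L,
                             run_lengths = list(
                               ind1 = c(11, 11, 8),
                               ind2 = c(11, 10, 9),
                               ind3 = c(8, 8, 11),
                               ind4 = c(11, 9),
                               ind5 = c(10, 8, 11)),
                             n_codons = 120L, seed = 1L) {
  set.seed(seed)
  ct <- codon_tables()
  # plant the tract at a codon boundary mid-gene; non-T guards on both
  # sides keep the run length exact, padding preserves the frame. The
  # draw is repeated until both frameshift offsets expose a premature
  # stop downstream of the tract (true of almost every random CDS).
  run <- paste(rep("T", ref_run_length), collapse = "")
  pad <- paste(rep("A", (3L - (ref_run_length + 2L) %% 3L) %% 3L),
               collapse = "")
  repeat {
    base <- random_cds(n_codons, seed = NULL)
    ins_at <- 3L * (n_codons %/% 2L)
    ref <- paste0(substring(base, 1, ins_at), "G", run, "C", pad,
                  substring(base, ins_at + 1))
    has_shifted_stop <- vapply(1:2, function(del) {
      mut <- paste0(substring(ref, 1, ins_at + 1),
                    paste(rep("T", ref_run_length - del), collapse = ""),
                    substring(ref, ins_at + 2L + ref_run_length))
      n_cod <- nchar(mut) %/% 3L
      cods <- substring(mut, seq(1, by = 3, length.out = n_cod),
                        seq(3, by = 3, length.out = n_cod))
      any(which(is_stop_codon(cods)) <= n_cod - 3L)
    }, logical(1))
    if (all(has_shifted_stop)) break
  }
  region <- locate_homopolymer(ref, "T", min_len = max(6L, ref_run_length - 4L))
  clones <- character(0)
  truth <- list()
  for (ind in names(run_lengths)) {
    for (ci in seq_along(run_lengths[[ind]])) {
      rl <- run_lengths[[ind]][ci]
      clone <- paste0(substring(ref, 1, region$start - 1),
                      paste(rep("T", rl), collapse = ""),
                      substring(ref, region$end + 1))
      id <- paste0(ind, "|clone", ci)
      clones[[id]] <- clone
      truth[[length(truth) + 1L]] <- data.frame(
        clone_id = id, individual = ind, run_length = rl,
        indel_vs_ref = rl - region$length, stringsAsFactors = FALSE)
    }
  }
  list(ref = ref, clones = clones, region = region,
       truth = do.call(rbind, truth))
}

#' Generate paralog clone sets with planted pseudogenes
#'
#' For each species, draws intact copies from a common ancestral CDS by
#' sprinkling substitutions, and optionally plants premature stop
#' codons or frameshifting single-base deletions to create pseudogene
#' copies with known truth.
#'
#' @param species Character vector of species names.
#' @param n_intact Intact copies per species (recycled).
#' @param n_pseudo Pseudogene copies per species (recycled); planted
#'   alternately as premature stops and 1-bp deletions.
#' @param n_codons Ancestral CDS length in codons (default 140).
#' @param sub_rate Per-site substitution probability per copy
#'   (default 0.03).
#' @param seed Seed.
#' @return A list: `clone_sets` (species -> named sequences),
#'   `alignment` (a `codon_alignment` of all intact-length clones),
#'   `ref_length`, `truth` (data frame `clone`, `species`, `status`,
#'   `reason`).
#' @export
make_paralog_clones <- function(species = c("sp1", "sp2"), n_intact = 2L,
                                n_pseudo = 0L, n_codons = 140L,
                                sub_rate = 0.03, seed = 1L) {
  set.seed(seed)
  ct <- codon_tables()
  anc <- random_cds(n_codons, seed = NULL)
  n_intact <- rep_len(n_intact, length(species))
  n_pseudo <- rep_len(n_pseudo, length(species))
  mutate <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    body <- 4:(n - 3)  # keep start/stop codons fixed
    k <- stats::rbinom(1, length(body), sub_rate)
    if (k > 0) {
      pos <- sample(body, k)
      for (p in pos) {
        repeat {
          nb <- sample(NUC, 1)
          if (nb != ch[p]) { cand <- ch; cand[p] <- nb; break }
        }
        # avoid creating in-frame stops in intact copies
        cod_i <- (p - 1) %/% 3 + 1
        cand_codon <- paste(cand[(3 * cod_i - 2):(3 * cod_i)], collapse = "")
        if (!(cand_codon %in% ct$stops) || cod_i == n %/% 3) ch <- cand
      }
    }
    paste(ch, collapse = "")
  }
  clone_sets <- list()
  truth <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    seqs <- character(0)
    for (i in seq_len(n_intact[si])) {
      id <- paste0(sp, "_c", i)
      seqs[[id]] <- mutate(anc)
      truth[[length(truth) + 1L]] <- data.frame(
        clone = id, species = sp, status = "intact",
        reason = NA_character_, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_pseudo[si])) {
      id <- paste0(sp, "_p", i)
      s <- mutate(anc)
      if (i %% 2L == 1L) {
        # plant a premature stop mid-gene
        cod <- n_codons %/% 3L
        substring(s, 3 * cod - 2, 3 * cod) <- "TAA"
        reason <- "premature_stop"
      } else {
        # 1-bp deletion: frameshift relative to the reference length
        cut <- 3L * (n_codons %/% 3L) + 2L
        s <- paste0(substring(s, 1, cut - 1), substring(s, cut + 1))
        reason <- "frameshift"
      }
      seqs[[id]] <- s
      truth[[length(truth) + 1L]] <- data.frame(
        clone = id, species = sp, status = "pseudogene", reason = reason,
        stringsAsFactors = FALSE)
    }
    clone_sets[[sp]] <- seqs
  }
  # alignment over equal-length clones (the 1-bp deletion clones get a
  # terminal gap pad so the container stays rectangular)
  all_seqs <- unlist(unname(clone_sets))
  names(all_seqs) <- unlist(lapply(clone_sets, names))
  maxlen <- max(nchar(all_seqs))
  all_seqs <- vapply(all_seqs, function(s)
    paste0(s, paste(rep("-", maxlen - nchar(s)), collapse = "")),
    character(1))
  aln <- codon_alignment(all_seqs, frame = 0L)
  list(clone_sets = clone_sets, alignment = aln,
       ref_length = nchar(anc), truth = do.call(rbind, truth))
}
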