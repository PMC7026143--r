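# End-to-end orchestration: simulate -> rates -> reconcile -> peaks ->
# groups -> summaries, with a run manifest and deterministic outputs.
# All randomness flows from one root seed via named per-stage seeds.

stage_seed <- function(root_seed, stage) {
  # deterministic per-stage substream; kept well below 2^31
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root_seed) * 1009 + h) %% 2000000011)
}

#' Run the full duplication-inference pipeline on simulated data
#'
#' Executes the stages in dependency order, writing each stage's TSV
#' plus a JSON run manifest under `outdir`:
#' \enumerate{
#'   \item `simulate` -- duplication/loss history + GY94 alignment
#'     ([make_dataset()]);
#'   \item `rates` -- NG86 pairwise rates table ([ng86_rates()]);
#'   \item `reconcile` -- reconciliation, duplication calls and pair
#'     cohorts ([reconcile()]);
#'   \item `peaks` -- dS sample, BIC-selected mixture ([collect_ds()],
#'     [select_k_bic()]);
#'   \item `groups` -- cohort comparison ([compare_cohorts()]);
#'   \item `summaries` -- paralog summary and heteroplasmy reports on
#'     generated clone sets.
#' }
#'
#' @param config A `sim_config`; if `NULL`, the default preset with the
#'   given `seed`.
#' @param outdir Output directory.
#' @param seed Root seed (used when `config` is `NULL`, and for all
#'   stage substreams).
#' @param ancestor Species-tree ancestor label for duplication age
#'   classes (default `"ROOT"`).
#' @param k_max Maximum mixture components for the peaks stage.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = NULL, outdir, seed = 1L,
                         ancestor = "ROOT", k_max = 4L) {
  if (is.null(config)) config <- sim_config(seed = stage_seed(seed, "simulate"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage_rows <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(withCallingHandlers(fn(), warning = note),
                    error = function(e)
                      stop("stage '", name, "' failed: ",
                           conditionMessage(e), call. = FALSE))
    res
  }

  # 1. simulate
  sim <- run_stage("simulate", function()
    make_dataset(config, outdir, clones = TRUE))
  stage_rows$simulate <- length(sim$history$species_map)

  # 2. rates
  rates <- run_stage("rates", function() ng86_rates(sim$alignment))
  write_table(rates,
              c(seq1 = "chr", seq2 = "chr", S = "dbl", N = "dbl",
                Sd = "dbl", Nd = "dbl", pS = "dbl", pN = "dbl",
                dS = "dbl", dN = "dbl", omega = "dbl"),
              file.path(outdir, "rates.tsv"))
  stage_rows$rates <- nrow(rates)

  # 3. reconcile
  rec <- run_stage("reconcile", function()
    reconcile(sim$history$gene_tree, config$species_tree,
              sim$history$species_map, ancestor = ancestor))
  gt <- sim$history$gene_tree
  ntip <- ape::Ntip(gt)
  node_df <- data.frame(
    node = seq_len(ntip + gt$Nnode),
    label = c(gt$tip.label, gt$node.label),
    mapping = rec$mapping,
    is_duplication = seq_len(ntip + gt$Nnode) %in% rec$duplication_nodes,
    age_class = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(rec$age_class))
    node_df$age_class[match(as.integer(names(rec$age_class)),
                            node_df$node)] <- unname(rec$age_class)
  write_table(node_df,
              c(node = "int", label = "chr", mapping = "int",
                is_duplication = "lgl", age_class = "chr"),
              file.path(outdir, "reconciliation.tsv"))
  write_table(rec$pair_cohorts,
              c(seq1 = "chr", seq2 = "chr", lca_node = "int",
                age_class = "chr"),
              file.path(outdir, "pair_cohorts.tsv"))
  stage_rows$reconcile <- rec$n_duplications

  # 4. peaks
  peaks <- run_stage("peaks", function() {
    ds <- collect_ds(rates, rec$pair_cohorts)
    fit <- select_k_bic(ds$entries$ds, k_min = 1L,
                        k_max = min(k_max, floor(nrow(ds$entries) / 3)),
                        seed = stage_seed(seed, "peaks"))
    list(ds = ds, fit = fit)
  })
  peak_df <- data.frame(component = seq_len(peaks$fit$K),
                        weight = peaks$fit$weights, mean = peaks$fit$means,
                        sd = peaks$fit$sds, K = peaks$fit$K,
                        bic = peaks$fit$bic, n = peaks$fit$n)
  write_table(peak_df,
              c(component = "int", weight = "dbl", mean = "dbl",
                sd = "dbl", K = "int", bic = "dbl", n = "int"),
              file.path(outdir, "peaks.tsv"))
  write_table(ds_histogram(peaks$ds),
              c(cohort = "chr", bin_left = "dbl", bin_right = "dbl",
                count = "int"),
              file.path(outdir, "ds_histogram.tsv"))
  stage_rows$peaks <- peaks$fit$K

  # 5. groups (cohort comparison of recent vs ancestral pairs)
  groups <- run_stage("groups", function() compare_cohorts(peaks$ds))
  cohort_df <- groups$report
  cohort_df$wilcoxon_p <- groups$p
  cohort_df$ancestral_gt_recent <- groups$direction_ancestral_gt_recent
  write_table(cohort_df,
              c(cohort = "chr", n = "int", median_ds = "dbl",
                wilcoxon_p = "dbl", ancestral_gt_recent = "lgl"),
              file.path(outdir, "cohorts.tsv"))
  stage_rows$groups <- nrow(cohort_df)

  # 6. summaries (paralog table + heteroplasmy on generated clone sets)
  summaries <- run_stage("summaries", function() {
    pc <- make_paralog_clones(species = c("sp1", "sp2"), n_intact = 2L,
                              n_pseudo = c(1L, 0L),
                              seed = stage_seed(seed, "paralogs") %% 100000L)
    par_tab <- summarize_species(pc$clone_sets, pc$alignment,
                                 ref_length = pc$ref_length)
    mk <- make_matk_clones(seed = stage_seed(seed, "matk") %% 100000L)
    calls <- call_clones(mk$clones, mk$ref, mk$region)
    het <- summarize_individuals(calls)
    list(paralogs = par_tab, calls = calls, heteroplasmy = het)
  })
  write_table(summaries$paralogs,
              c(species = "chr", intact_copy_number = "int",
                pseudogene_number = "int", length_range = "chr",
                alignment_length = "int", identity_range = "chr",
                gc_range = "chr", mutation_type = "chr", integrity = "chr"),
              file.path(outdir, "paralog_summary.tsv"))
  write_table(summaries$calls,
              c(clone_id = "chr", individual = "chr", run_base = "chr",
                run_length = "int", indel_vs_ref = "int", effect = "chr",
                aa_change = "int", stop_codon_index = "int",
                stop_position_nt = "int"),
              file.path(outdir, "matk_calls.tsv"))
  write_table(summaries$heteroplasmy,
              c(individual = "chr", n_clones = "int",
                run_length_spectrum = "chr", n_intact = "int",
                n_in_frame = "int", n_frameshift = "int",
                heteroplasmic = "lgl"),
              file.path(outdir, "heteroplasmy.tsv"))
  stage_rows$summaries <- nrow(summaries$heteroplasmy)

  # manifest
  stage_files <- c("rates.tsv", "reconciliation.tsv", "pair_cohorts.tsv",
                   "peaks.tsv", "ds_histogram.tsv", "cohorts.tsv",
                   "paralog_summary.tsv", "matk_calls.tsv",
                   "heteroplasmy.tsv")
  sums <- tools::md5sum(c(sim$files, file.path(outdir, stage_files)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("genedup")),
    seed = seed,
    config_checksum = unname(tools::md5sum(sim$files[["config"]])),
    stages = names(stage_rows),
    per_stage_counts = stage_rows,
    file_checksums = as.list(stats::setNames(unname(sums),
                                             basename(names(sums)))),
    n_warnings = length(warnings_log),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, rates = rates, reconciliation = rec,
                 peaks = peaks, cohorts = groups, summaries = summaries,
                 manifest = manifest))
}
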