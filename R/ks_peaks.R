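# Building dS (Ks) samples from pairwise-rate tables, mixture-peak
# detection, and recent-vs-ancestral cohort comparison.

#' Collect a dS sample from a rates table
#'
#' Joins the pairwise rates with optional duplication cohorts. Rows with
#' saturated (`NA`) dS are excluded and counted; values above `ds_cap`
#' (saturation artifacts) are excluded and counted separately.
#'
#' @param rates_table Data frame from [ng86_rates()] (columns `seq1`,
#'   `seq2`, `dS`).
#' @param cohorts Optional data frame from [assign_pairs_to_events()]
#'   (columns `seq1`, `seq2`, `age_class`). Pairs not present are
#'   labelled `"unassigned"`. When supplied, only duplication pairs are
#'   retained (ortholog pairs carry no duplication signal).
#' @param ds_cap Upper dS cutoff (default 3.0).
#' @param species_from_label Derive a `species` column by stripping a
#'   `_copyN` suffix from sequence labels (default `TRUE`).
#' @return A list of class `ds_sample`: `entries` (data frame `species`,
#'   `pair_id`, `seq1`, `seq2`, `ds`, `cohort`), `n_excluded_saturated`,
#'   `n_excluded_cap`.
#' @export
collect_ds <- function(rates_table, cohorts = NULL, ds_cap = 3.0,
                       species_from_label = TRUE) {
  stopifnot(all(c("seq1", "seq2", "dS") %in% names(rates_table)))
  df <- rates_table
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  df$pair_id <- key(df$seq1, df$seq2)
  if (!is.null(cohorts)) {
    ck <- key(cohorts$seq1, cohorts$seq2)
    df$cohort <- cohorts$age_class[match(df$pair_id, ck)]
    df <- df[!is.na(df$cohort), , drop = FALSE]
  } else {
    df$cohort <- "unassigned"
  }
  n_sat <- sum(is.na(df$dS))
  df <- df[!is.na(df$dS), , drop = FALSE]
  n_cap <- sum(df$dS > ds_cap)
  df <- df[df$dS <= ds_cap, , drop = FALSE]
  if (nrow(df) == 0)
    stop("degenerate input: no dS values remain after filtering")
  species <- if (species_from_label)
    sub("_copy[0-9]+$", "", df$seq1) else NA_character_
  entries <- data.frame(species = species, pair_id = df$pair_id,
                        seq1 = df$seq1, seq2 = df$seq2, ds = df$dS,
                        cohort = df$cohort, stringsAsFactors = FALSE)
  structure(list(entries = entries, n_excluded_saturated = n_sat,
                 n_excluded_cap = n_cap), class = "ds_sample")
}

#' @export
print.ds_sample <- function(x, ...) {
  cat(sprintf("ds_sample: %d pairs (%d saturated, %d above cap excluded)\n",
              nrow(x$entries), x$n_excluded_saturated, x$n_excluded_cap))
  invisible(x)
}

#' Compare recent and ancestral duplication cohorts
#'
#' Reports per-cohort sample size and median, a two-sided Wilcoxon
#' rank-sum test between the cohorts, the direction flag (ancestral
#' median exceeds recent median) and, optionally, a BIC-selected
#' mixture fit per cohort.
#'
#' @param ds_sample A `ds_sample` with both `"recent"` and
#'   `"ancestral"` cohorts non-empty.
#' @param fit_mixtures Fit per-cohort mixtures (default `FALSE`).
#' @param k_max Maximum K for the per-cohort fits.
#' @param seed Seed for the mixture fits.
#' @return A list of class `cohort_report`: `report` (two-row data
#'   frame `cohort`, `n`, `median_ds`), `wilcoxon`
#'   (`wilcoxon_result`), `p`, `direction_ancestral_gt_recent`,
#'   `mixtures` (list or `NULL`).
#' @export
compare_cohorts <- function(ds_sample, fit_mixtures = FALSE, k_max = 3L,
                            seed = 1L) {
  e <- ds_sample$entries
  rec <- e$ds[e$cohort == "recent"]
  anc <- e$ds[e$cohort == "ancestral"]
  if (length(rec) == 0) stop("cohort 'recent' is empty")
  if (length(anc) == 0) stop("cohort 'ancestral' is empty")
  wt <- wilcoxon_rank_sum(anc, rec)
  report <- data.frame(cohort = c("recent", "ancestral"),
                       n = c(length(rec), length(anc)),
                       median_ds = c(stats::median(rec), stats::median(anc)),
                       stringsAsFactors = FALSE)
  mixtures <- NULL
  if (fit_mixtures) {
    mixtures <- list()
    for (co in c("recent", "ancestral")) {
      v <- e$ds[e$cohort == co]
      km <- max(1L, min(k_max, floor(length(v) / 3)))
      mixtures[[co]] <- select_k_bic(v, k_min = 1L, k_max = km, seed = seed)
    }
  }
  structure(list(report = report, wilcoxon = wt, p = wt$p_two_sided,
                 direction_ancestral_gt_recent =
                   stats::median(anc) > stats::median(rec),
                 mixtures = mixtures),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  print(x$report)
  cat(sprintf("Wilcoxon p = %.4g; ancestral > recent: %s\n",
              x$p, x$direction_ancestral_gt_recent))
  invisible(x)
}

#' Histogram bins for a dS sample
#'
#' Plot-ready binned counts (shared bins across cohorts).
#'
#' @param ds_sample A `ds_sample`.
#' @param binwidth Bin width (default 0.05).
#' @return Data frame: `cohort`, `bin_left`, `bin_right`, `count`.
#' @export
ds_histogram <- function(ds_sample, binwidth = 0.05) {
  e <- ds_sample$entries
  breaks <- seq(0, max(e$ds) + binwidth, by = binwidth)
  out <- lapply(unique(e$cohort), function(co) {
    h <- graphics::hist(e$ds[e$cohort == co], breaks = breaks, plot = FALSE)
    data.frame(cohort = co, bin_left = utils::head(h$breaks, -1),
               bin_right = h$breaks[-1], count = h$counts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
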