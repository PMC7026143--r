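# Per-species paralog summary: copy counts, length/identity/GC ranges,
# mutation types and intact-vs-pseudogene classification (the shape of
# a clone-survey summary table).

#' Pairwise nucleotide identity matrix
#'
#' Identity between two aligned sequences is the fraction of matching
#' characters over columns where both are non-gap, as a percentage.
#' Pairs with no comparable columns are `NA`.
#'
#' @param aln A `codon_alignment` (or any equal-length aligned
#'   sequences wrapped in one).
#' @return Symmetric numeric matrix (%), diagonal 100.
#' @export
pairwise_identity <- function(aln) {
  n <- length(aln$taxa)
  if (n < 2) stop("need at least 2 sequences")
  chars <- do.call(rbind, strsplit(aln$seqs, ""))
  out <- matrix(100, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- chars[i, ] != "-" & chars[j, ] != "-"
      out[i, j] <- out[j, i] <- if (!any(comp)) NA_real_ else
        100 * mean(chars[i, comp] == chars[j, comp])
    }
  }
  out
}

#' GC content of a sequence
#'
#' @param seq Nucleotide string; gaps are removed first.
#' @return `(G + C) / (A + C + G + T) * 100`.
#' @export
gc_content <- function(seq) {
  s <- strsplit(toupper(gsub("-", "", seq)), "")[[1]]
  s <- s[s %in% NUC]
  if (length(s) == 0) stop("empty sequence after gap removal")
  100 * sum(s %in% c("G", "C")) / length(s)
}

#' Classify a paralog sequence as intact or pseudogene
#'
#' A copy is a pseudogene if (a) an internal stop codon occurs before
#' the final three codons, (b) its length differs from `ref_length` by
#' a non-multiple of 3 (frameshift), or (c) it lacks a terminal stop
#' codon; otherwise intact.
#'
#' @param seq Ungapped nucleotide sequence.
#' @param frame Reading-frame offset (default 0).
#' @param ref_length Optional reference CDS length (bp) for the
#'   frameshift check.
#' @return A list: `status` (`"intact"`/`"pseudogene"`), `reason`
#'   (`NA`, `"premature_stop"`, `"frameshift"` or `"no_terminal_stop"`),
#'   `n_codons`, `stop_codon_index` (first internal stop, 1-based, or
#'   `NA`).
#' @export
classify_integrity <- function(seq, frame = 0L, ref_length = NULL) {
  s <- toupper(gsub("-", "", seq))
  body <- substring(s, frame + 1L)
  n_cod <- nchar(body) %/% 3L
  if (n_cod < 2) stop("sequence shorter than 2 codons")
  codons <- substring(body, seq(1L, by = 3L, length.out = n_cod),
                      seq(3L, by = 3L, length.out = n_cod))
  stops <- which(is_stop_codon(codons))
  internal <- stops[stops <= n_cod - 3L]
  first_internal <- if (length(internal) > 0) internal[1] else NA_integer_
  if (length(internal) > 0)
    return(list(status = "pseudogene", reason = "premature_stop",
                n_codons = n_cod, stop_codon_index = first_internal))
  if (!is.null(ref_length) && (nchar(s) - ref_length) %% 3L != 0)
    return(list(status = "pseudogene", reason = "frameshift",
                n_codons = n_cod, stop_codon_index = NA_integer_))
  if (!is_stop_codon(codons[n_cod]))
    return(list(status = "pseudogene", reason = "no_terminal_stop",
                n_codons = n_cod, stop_codon_index = NA_integer_))
  list(status = "intact", reason = NA_character_, n_codons = n_cod,
       stop_codon_index = NA_integer_)
}

fmt_range <- function(v, digits = 1) {
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_character_)
  lo <- signif_round(min(v), digits)
  hi <- signif_round(max(v), digits)
  if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
}

signif_round <- function(x, digits) {
  if (x == round(x)) as.character(round(x)) else as.character(round(x, digits))
}

#' Per-species paralog summary rows
#'
#' Builds a clone-survey summary: intact copy number, length range
#' (ungapped bp), alignment length, identity and GC ranges over intact
#' copies, mutation types among intact pairs (Indels/SNPs), and the
#' integrity code (`"I"` or `"I & P (k)"`).
#'
#' @param clone_sets Named list: species -> named character vector of
#'   clone sequences (aligned or not; gaps allowed).
#' @param alignment A `codon_alignment` of all clones (used for
#'   identity and indel/SNP detection); clone names must match.
#' @param ref_length Optional reference CDS length for frameshift
#'   classification.
#' @return Data frame with one row per species: `species`,
#'   `intact_copy_number`, `pseudogene_number`, `length_range`,
#'   `alignment_length`, `identity_range`, `gc_range`, `mutation_type`,
#'   `integrity`.
#' @export
summarize_species <- function(clone_sets, alignment, ref_length = NULL) {
  idm <- if (length(alignment$taxa) >= 2) pairwise_identity(alignment)
         else NULL
  chars <- do.call(rbind, strsplit(alignment$seqs, ""))
  rownames(chars) <- alignment$taxa
  rows <- list()
  for (sp in names(clone_sets)) {
    clones <- clone_sets[[sp]]
    if (length(clones) == 0) {
      warning("species '", sp, "' has no sequences; skipped")
      next
    }
    cls <- lapply(clones, classify_integrity, ref_length = ref_length)
    intact <- names(clones)[vapply(cls, `[[`, "", "status") == "intact"]
    n_pseudo <- length(clones) - length(intact)
    lens <- nchar(gsub("-", "", clones[intact]))
    gcs <- vapply(clones[intact], gc_content, numeric(1))
    ids <- if (length(intact) >= 2 && !is.null(idm)) {
      sub <- idm[intact, intact]
      sub[upper.tri(sub)]
    } else NA_real_
    mut <- character(0)
    if (length(intact) >= 2) {
      for (k in utils::combn(intact, 2, simplify = FALSE)) {
        a <- chars[k[1], ]; b <- chars[k[2], ]
        if (any(xor(a == "-", b == "-"))) mut <- union(mut, "Indels")
        if (any(a != "-" & b != "-" & a != b)) mut <- union(mut, "SNPs")
      }
    }
    rows[[sp]] <- data.frame(
      species = sp,
      intact_copy_number = length(intact),
      pseudogene_number = n_pseudo,
      length_range = fmt_range(lens, 0),
      alignment_length = alignment$length,
      identity_range = fmt_range(ids, 1),
      gc_range = fmt_range(gcs, 1),
      mutation_type = if (length(mut) == 0) "" else
        paste(sort(mut), collapse = "/"),
      integrity = if (n_pseudo == 0) "I" else
        sprintf("I & P (%d)", n_pseudo),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
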