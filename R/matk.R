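# Homopolymer-run classification of clone sequences around a coding
# hotspot: run-length measurement and frameshift / in-frame-indel /
# intact calls, plus per-individual heteroplasmy summaries.
#
# Clones are anchored to the reference by exact flanking k-mers rather
# than full alignment: generic aligners misplace gaps inside
# homopolymer tracts, anchors do not.

#' Locate a homopolymer run in a reference CDS
#'
#' Finds the longest run of `base` with length at least `min_len`
#' (leftmost on ties).
#'
#' @param ref_cds Reference coding sequence (frame 0).
#' @param base The repeated nucleotide (e.g. `"T"`).
#' @param min_len Minimum qualifying run length (>= 4).
#' @return A list: `start`, `end` (1-based inclusive), `length`,
#'   `base`.
#' @export
locate_homopolymer <- function(ref_cds, base = "T", min_len = 6L) {
  if (min_len < 4) stop("min_len must be >= 4")
  s <- strsplit(toupper(ref_cds), "")[[1]]
  r <- rle(s == toupper(base))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_len)
  if (length(runs) == 0)
    stop("no ", base, "-run of length >= ", min_len, " found")
  best <- runs[which.max(r$lengths[runs])]  # which.max is leftmost on ties
  list(start = starts[best], end = ends[best],
       length = r$lengths[best], base = toupper(base))
}

#' Classify one clone against the reference homopolymer region
#'
#' The clone is anchored by exact `flank`-bp sequences immediately left
#' and right of the reference run; the run length between the anchors
#' gives the signed indel relative to the reference. Non-triplet indels
#' are frameshifts (the downstream frame is translated to the first
#' premature stop); triplet deletions/insertions are in-frame.
#'
#' @param clone_seq Clone nucleotide sequence (ungapped).
#' @param ref_cds Reference CDS (frame 0).
#' @param region Output of [locate_homopolymer()].
#' @param clone_id Identifier carried into the call.
#' @param flank Anchor length in bp (default 15).
#' @return A list of class `homopolymer_call`: `clone_id`, `run_base`,
#'   `run_length`, `indel_vs_ref`, `effect` (`"intact"`,
#'   `"in_frame_deletion"`, `"in_frame_insertion"` or `"frameshift"`),
#'   `aa_change` (residues lost/gained for in-frame indels),
#'   `stop_codon_index` (1-based codon index of the premature stop for
#'   frameshifts, else `NA`), `stop_position_nt` (1-based first
#'   nucleotide of that codon in the mutant CDS).
#' @export
call_clone <- function(clone_seq, ref_cds, region, clone_id = "clone",
                       flank = 15L) {
  ref <- toupper(ref_cds)
  clone <- toupper(gsub("-", "", clone_seq))
  if (region$start - flank < 1 || region$end + flank > nchar(ref))
    stop("reference too short for ", flank, "-bp anchors")
  left <- substring(ref, region$start - flank, region$start - 1L)
  right <- substring(ref, region$end + 1L, region$end + flank)
  lpos <- regexpr(left, clone, fixed = TRUE)
  if (lpos < 0) stop("unalignable clone '", clone_id, "': left anchor not found")
  run_start <- lpos + flank
  rest <- substring(clone, run_start)
  rpos <- regexpr(right, rest, fixed = TRUE)
  if (rpos < 0) stop("unalignable clone '", clone_id, "': right anchor not found")
  between <- substring(rest, 1L, rpos - 1L)
  run_length <- sum(strsplit(between, "")[[1]] == region$base)
  indel <- nchar(between) - (region$end - region$start + 1L)

  mutant <- paste0(substring(ref, 1L, region$start - 1L), between,
                   substring(ref, region$end + 1L))
  effect <- if (indel %% 3L != 0L) "frameshift"
            else if (indel < 0L) "in_frame_deletion"
            else if (indel > 0L) "in_frame_insertion"
            else "intact"
  aa_change <- if (effect %in% c("in_frame_deletion", "in_frame_insertion"))
    abs(indel) %/% 3L else NA_integer_
  stop_idx <- NA_integer_
  stop_nt <- NA_integer_
  if (effect == "frameshift") {
    n_cod <- nchar(mutant) %/% 3L
    codons <- substring(mutant, seq(1L, by = 3L, length.out = n_cod),
                        seq(3L, by = 3L, length.out = n_cod))
    hit <- which(is_stop_codon(codons))
    if (length(hit) > 0) {
      stop_idx <- hit[1]
      stop_nt <- (stop_idx - 1L) * 3L + 1L
    }
  }
  structure(list(clone_id = clone_id, run_base = region$base,
                 run_length = run_length, indel_vs_ref = indel,
                 effect = effect, aa_change = aa_change,
                 stop_codon_index = stop_idx, stop_position_nt = stop_nt),
            class = "homopolymer_call")
}

#' Call a whole clone set
#'
#' @param clones Named character vector of clone sequences; names encode
#'   the individual as `IND|clone`.
#' @param ref_cds Reference CDS.
#' @param region Output of [locate_homopolymer()]; located from
#'   `ref_cds` if `NULL`.
#' @param ... Passed to [call_clone()].
#' @return Data frame with one row per clone: the `homopolymer_call`
#'   fields plus `individual`.
#' @export
call_clones <- function(clones, ref_cds, region = NULL, ...) {
  if (is.null(region)) region <- locate_homopolymer(ref_cds)
  rows <- lapply(names(clones), function(id) {
    cl <- call_clone(clones[[id]], ref_cds, region, clone_id = id, ...)
    data.frame(clone_id = id,
               individual = sub("\\|.*$", "", id),
               run_base = cl$run_base, run_length = cl$run_length,
               indel_vs_ref = cl$indel_vs_ref, effect = cl$effect,
               aa_change = cl$aa_change,
               stop_codon_index = cl$stop_codon_index,
               stop_position_nt = cl$stop_position_nt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-individual heteroplasmy report
#'
#' @param calls Data frame from [call_clones()].
#' @param grouping Optional factor overriding the `individual` column.
#' @return Data frame with one row per individual: `individual`,
#'   `n_clones`, `run_length_spectrum` (e.g. `"8-11"`),
#'   `n_intact`, `n_in_frame`, `n_frameshift`, `heteroplasmic`
#'   (more than one distinct run length within the individual).
#' @export
summarize_individuals <- function(calls, grouping = NULL) {
  grp <- if (is.null(grouping)) calls$individual else grouping
  rows <- lapply(split(calls, grp), function(d) {
    lens <- sort(unique(d$run_length))
    data.frame(
      individual = d$individual[1],
      n_clones = nrow(d),
      run_length_spectrum = if (length(lens) == 1) as.character(lens)
        else paste0(min(lens), "-", max(lens)),
      n_intact = sum(d$effect == "intact"),
      n_in_frame = sum(d$effect %in% c("in_frame_deletion",
                                       "in_frame_insertion")),
      n_frameshift = sum(d$effect == "frameshift"),
      heteroplasmic = length(lens) > 1,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
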