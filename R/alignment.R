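# CodonAlignment container and FASTA I/O.
#
# Sequences are stored as uppercase character strings over the IUPAC
# alphabet plus '-'. Internally coordinates are 0-based half-open; all
# user-facing report output is 1-based inclusive.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Construct an in-frame codon alignment
#'
#' @param seqs Named character vector of aligned nucleotide sequences
#'   (equal lengths, unique names). Case-insensitive; `U` is converted
#'   to `T`.
#' @param frame Reading-frame offset in nucleotides (default 0); the
#'   alignment length minus `frame` must be divisible by 3.
#' @return An object of class `codon_alignment` with fields `taxa`,
#'   `seqs`, `frame`, `length` (alignment columns) and `n_codons`.
#' @export
codon_alignment <- function(seqs, frame = 0L) {
  if (length(seqs) == 0) stop("alignment error: no sequences")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("alignment error: sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("alignment error: duplicate sequence labels")
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("alignment error: sequences have unequal lengths")
  len <- lens[[1]]
  frame <- as.integer(frame)
  if (frame < 0 || frame > 2) stop("frame error: frame must be 0, 1 or 2")
  if ((len - frame) %% 3 != 0)
    stop("frame error: (length - frame) not divisible by 3")
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 IUPAC_CHARS)
  if (length(bad) > 0)
    stop("parse error: non-IUPAC characters: ", paste(bad, collapse = ", "))
  structure(
    list(taxa = names(seqs), seqs = seqs, frame = frame, length = len,
         n_codons = (len - frame) %/% 3L),
    class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequences, %d columns (%d codons, frame %d)\n",
              length(x$taxa), x$length, x$n_codons, x$frame))
  invisible(x)
}

#' Read an aligned FASTA file as a codon alignment
#'
#' @param path Path to an aligned FASTA file.
#' @param frame Reading-frame offset (see [codon_alignment()]).
#' @return A `codon_alignment`.
#' @export
read_codon_fasta <- function(path, frame = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  codon_alignment(seqs, frame = frame)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$taxa)) {
    writeLines(paste0(">", aln$taxa[i]), con)
    s <- aln$seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Matrix of codon strings, taxa x codon columns.
codon_matrix <- function(aln) {
  starts <- aln$frame + seq(1L, by = 3L, length.out = aln$n_codons)
  m <- t(vapply(aln$seqs,
                function(s) substring(s, starts, starts + 2L),
                character(aln$n_codons)))
  if (aln$n_codons == 1L) m <- matrix(m, nrow = length(aln$taxa),
                                      dimnames = list(aln$taxa, NULL))
  rownames(m) <- aln$taxa
  m
}

# Rebuild a codon_alignment from a codon matrix.
codon_matrix_to_alignment <- function(m, frame = 0L) {
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- rownames(m)
  codon_alignment(seqs, frame = frame)
}

# A codon is "clean" when it consists only of A/C/G/T.
codon_is_clean <- function(codons) {
  !grepl("[^ACGT]", codons)
}

#' Remove codon columns containing gaps or ambiguity in any sequence
#'
#' Mirrors codeml's `cleandata = 1` behaviour: any codon column in which
#' any sequence carries a gap or an ambiguity code (`N`, IUPAC codes) is
#' dropped; remaining columns keep their order. Optionally also drops
#' columns containing a stop codon in any sequence, which the
#' likelihood machinery requires.
#'
#' @param aln A `codon_alignment`.
#' @param drop_stop_columns Also drop columns with in-frame stop codons
#'   in any sequence (default `FALSE`).
#' @return A filtered `codon_alignment` (frame 0).
#' @export
cleandata_filter <- function(aln, drop_stop_columns = FALSE) {
  m <- codon_matrix(aln)
  keep <- apply(m, 2L, function(col) all(codon_is_clean(col)))
  if (drop_stop_columns) {
    ct <- codon_tables()
    keep <- keep & apply(m, 2L, function(col) !any(col %in% ct$stops))
  }
  if (!any(keep))
    stop("degenerate input: no codon columns remain after cleandata filtering")
  codon_matrix_to_alignment(m[, keep, drop = FALSE], frame = 0L)
}

# Encode a cleaned alignment as integer codon states (1..61).
# Errors on gaps, ambiguity or stop codons.
encode_codon_states <- function(aln) {
  ct <- codon_tables()
  m <- codon_matrix(aln)
  enc <- ct$index[m]
  if (anyNA(enc)) {
    bad <- unique(m[is.na(enc)])
    stop("alignment contains gap/ambiguous/stop codons (",
         paste(utils::head(bad, 5), collapse = ", "),
         "); run cleandata_filter(drop_stop_columns = TRUE) first")
  }
  matrix(enc, nrow = nrow(m), dimnames = dimnames(m))
}
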