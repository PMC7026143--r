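# Genetic-code infrastructure shared by the NG86 and GY94 machinery.
# Everything here is memoised in a package environment: the standard code
# never changes, so tables are built once per session.

.gd <- new.env(parent = emptyenv())

NUC <- c("A", "C", "G", "T")

#' Genetic-code tables for the 61 sense codons
#'
#' Returns the cached standard-code tables used throughout the package:
#' codon strings, amino-acid translations, stop codons and index maps.
#'
#' @return A list with elements `codons` (61 sense codons), `aa` (their
#'   one-letter translations), `stops` (the 3 stop codons), `index`
#'   (named integer map codon -> 1..61, `NA` for stops) and `aa64`
#'   (translation for all 64 codons, `*` for stops).
#' @export
codon_tables <- function() {
  if (!is.null(.gd$codons)) {
    return(list(codons = .gd$codons, aa = .gd$aa, stops = .gd$stops,
                index = .gd$index, aa64 = .gd$aa64))
  }
  gc64 <- Biostrings::GENETIC_CODE
  all64 <- names(gc64)
  aa64 <- unname(gc64)
  names(aa64) <- all64
  sense <- all64[aa64 != "*"]
  aa <- aa64[sense]
  idx <- rep(NA_integer_, 64)
  names(idx) <- all64
  idx[sense] <- seq_along(sense)
  .gd$codons <- sense
  .gd$aa <- aa
  .gd$stops <- all64[aa64 == "*"]
  .gd$index <- idx
  .gd$aa64 <- aa64
  list(codons = sense, aa = aa, stops = .gd$stops, index = idx, aa64 = aa64)
}

is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
}

translate_codon <- function(codon) {
  ct <- codon_tables()
  unname(ct$aa64[codon])
}

is_stop_codon <- function(codon) {
  ct <- codon_tables()
  codon %in% ct$stops
}

# Single-nucleotide neighbour structure over the 61 sense codons:
# data.frame of (i, j, pos, transition, synonymous) for ordered pairs i != j
# differing at exactly one position, both sense.
codon_single_step_pairs <- function() {
  if (!is.null(.gd$step_pairs)) return(.gd$step_pairs)
  ct <- codon_tables()
  n <- length(ct$codons)
  mat <- do.call(rbind, strsplit(ct$codons, ""))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- list()
    for (pos in 1:3) {
      for (nuc in NUC) {
        if (nuc == mat[i, pos]) next
        tgt <- mat[i, ]
        tgt[pos] <- nuc
        codon_j <- paste(tgt, collapse = "")
        j <- ct$index[[codon_j]]
        if (is.na(j)) next  # change into a stop codon
        rows[[length(rows) + 1L]] <- data.frame(
          i = i, j = j, pos = pos,
          transition = is_transition(mat[i, pos], nuc),
          synonymous = ct$aa[i] == ct$aa[j],
          stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- do.call(rbind, rows)
  }
  .gd$step_pairs <- do.call(rbind, out)
  .gd$step_pairs
}
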