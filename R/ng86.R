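# Nei-Gojobori (1986) pairwise dN/dS with pathway averaging and JC69
# correction. Conventions:
#  * per-position site counts use denominator 3; single-nucleotide changes
#    into stop codons are excluded from the numerators, so s + n for a
#    codon equals 3 minus the stop-excluded fraction;
#  * multi-hit codon pairs average synonymous/nonsynonymous differences
#    over all orderings of single steps with equal weight, dropping
#    orderings that pass through a stop codon and renormalising; if every
#    ordering is blocked, all orderings are used with stop-involving
#    steps counted as nonsynonymous;
#  * p >= 3/4 saturates the JC69 correction and the rate is undefined
#    (serialised "NA").

#' Jukes-Cantor (1969) distance correction
#'
#' @param p Proportion of differences per site, `0 <= p < 3/4`.
#' @return `d = -(3/4) * log(1 - 4p/3)`; `NA` where `p >= 3/4`
#'   (saturation).
#' @export
jc69_correct <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("p must be >= 0")
  d <- ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  d[!is.na(p) & p == 0] <- 0
  d
}

#' NG86 synonymous/nonsynonymous site counts for one codon
#'
#' @param codon A sense codon over `A/C/G/T`.
#' @return Named numeric vector `c(s = ..., n = ...)`; `s` is the sum
#'   over the three positions of the fraction of single-nucleotide
#'   changes that are synonymous (changes to stop codons excluded from
#'   the numerator, denominator 3).
#' @export
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("masked codon: ambiguous or gapped codon '", codon, "'")
  if (is_stop_codon(codon))
    stop("masked codon: stop codon '", codon, "'")
  tab <- ng86_site_table()
  i <- codon_tables()$index[[codon]]
  c(s = tab$s[i], n = tab$n[i])
}

# Per-codon site counts for all 61 sense codons (memoised).
ng86_site_table <- function() {
  if (!is.null(.gd$ng86_sites)) return(.gd$ng86_sites)
  ct <- codon_tables()
  steps <- codon_single_step_pairs()
  s <- numeric(61)
  n <- numeric(61)
  for (i in 1:61) {
    st <- steps[steps$i == i, ]
    s[i] <- sum(st$synonymous) / 3
    n[i] <- sum(!st$synonymous) / 3
  }
  .gd$ng86_sites <- list(s = s, n = n)
  .gd$ng86_sites
}

# Pathway-averaged (sd, nd) for every ordered sense-codon pair (memoised
# 61 x 61 matrices). Endpoints are sense codons; intermediates must be.
ng86_diff_tables <- function() {
  if (!is.null(.gd$ng86_diffs)) return(.gd$ng86_diffs)
  ct <- codon_tables()
  chars <- strsplit(ct$codons, "")
  perms <- list(list(1L),
                list(c(1L, 2L), c(2L, 1L)),
                list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sd <- matrix(0, 61, 61)
  nd <- matrix(0, 61, 61)
  aa64 <- ct$aa64
  for (i in 1:61) {
    for (j in 1:61) {
      if (i == j) next
      diff_pos <- which(chars[[i]] != chars[[j]])
      k <- length(diff_pos)
      path_syn <- numeric(0)
      path_non <- numeric(0)
      blocked_syn <- numeric(0)
      blocked_non <- numeric(0)
      for (ord in perms[[k]]) {
        cur <- chars[[i]]
        syn <- 0
        non <- 0
        blocked <- FALSE
        for (p in diff_pos[ord]) {
          nxt <- cur
          nxt[p] <- chars[[j]][p]
          a1 <- aa64[[paste(cur, collapse = "")]]
          a2 <- aa64[[paste(nxt, collapse = "")]]
          if (a2 == "*" && !identical(paste(nxt, collapse = ""), ct$codons[j]))
            blocked <- TRUE
          if (a1 == a2 && a1 != "*") syn <- syn + 1 else non <- non + 1
          cur <- nxt
        }
        if (blocked) {
          blocked_syn <- c(blocked_syn, syn)
          blocked_non <- c(blocked_non, non)
        } else {
          path_syn <- c(path_syn, syn)
          path_non <- c(path_non, non)
        }
      }
      if (length(path_syn) > 0) {
        sd[i, j] <- mean(path_syn)
        nd[i, j] <- mean(path_non)
      } else {
        # all orderings pass through a stop: average over all of them,
        # stop-involving steps counted as nonsynonymous
        sd[i, j] <- mean(blocked_syn)
        nd[i, j] <- mean(blocked_non)
      }
    }
  }
  .gd$ng86_diffs <- list(sd = sd, nd = nd)
  .gd$ng86_diffs
}

#' NG86 pairwise substitution rates for two codon sequences
#'
#' Codon positions where either sequence carries a gap, an ambiguity
#' code or a stop codon are masked before counting. Sites are averaged
#' over the two sequences; differences at multi-hit codons are averaged
#' over single-step orderings (see package-level conventions).
#'
#' @param a_codons,b_codons Character vectors of codons (equal length).
#' @return A list of class `pairwise_rates`: `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `dS`, `dN`, `omega`, `n_codons` (codons compared) and
#'   `n_masked`. Saturated rates (`p >= 3/4`) and `omega` with `dS = 0`
#'   are `NA`.
#' @export
ng86_pairwise <- function(a_codons, b_codons) {
  if (length(a_codons) != length(b_codons))
    stop("sequences have different codon counts")
  a_codons <- toupper(a_codons)
  b_codons <- toupper(b_codons)
  ct <- codon_tables()
  ok <- codon_is_clean(a_codons) & codon_is_clean(b_codons) &
    !(a_codons %in% ct$stops) & !(b_codons %in% ct$stops)
  n_masked <- sum(!ok)
  a <- a_codons[ok]
  b <- b_codons[ok]
  if (length(a) == 0) stop("degenerate input: no comparable codons")
  sites <- ng86_site_table()
  ia <- unname(ct$index[a])
  ib <- unname(ct$index[b])
  S <- (sum(sites$s[ia]) + sum(sites$s[ib])) / 2
  N <- (sum(sites$n[ia]) + sum(sites$n[ib])) / 2
  diffs <- ng86_diff_tables()
  Sd <- sum(diffs$sd[cbind(ia, ib)])
  Nd <- sum(diffs$nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- if (is.na(pS)) NA_real_ else jc69_correct(pS)
  dN <- if (is.na(pN)) NA_real_ else jc69_correct(pN)
  omega <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 n_codons = length(a), n_masked = n_masked),
            class = "pairwise_rates")
}

#' NG86 rates for all sequence pairs of an alignment
#'
#' @param aln A `codon_alignment`. Columns with gaps/ambiguity are
#'   removed alignment-wide first (codeml `cleandata` behaviour); stop
#'   codons are masked per pair.
#' @param clean Apply [cleandata_filter()] first (default `TRUE`).
#' @return Data frame with one row per unordered pair: `seq1`, `seq2`,
#'   `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`.
#' @export
ng86_rates <- function(aln, clean = TRUE) {
  if (clean) aln <- cleandata_filter(aln)
  m <- codon_matrix(aln)
  taxa <- aln$taxa
  combs <- utils::combn(length(taxa), 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    r <- ng86_pairwise(m[i, ], m[j, ])
    data.frame(seq1 = taxa[i], seq2 = taxa[j], S = r$S, N = r$N,
               Sd = r$Sd, Nd = r$Nd, pS = r$pS, pN = r$pN,
               dS = r$dS, dN = r$dN, omega = r$omega,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
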