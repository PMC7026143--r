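# Goldman-Yang (1994) codon substitution model over the 61 sense codons
# with F3x4 frequencies. The rate matrix is scaled so the mean rate at
# equilibrium is one substitution per codon per unit branch length
# (codeml convention).

#' F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies are estimated over the
#' cleaned alignment and multiplied per codon; stop codons are zeroed
#' and the 61 sense-codon frequencies renormalised. With
#' `pseudocount = TRUE`, a position where some nucleotide is absent has
#' all four of its counts raised by 0.5 before normalisation -- the
#' likelihood machinery requires strictly positive frequencies, while
#' the plain estimate keeps the textbook behaviour (a single repeated
#' codon gets frequency 1).
#'
#' @param aln A `codon_alignment` (ideally cleaned).
#' @param pseudocount Apply the 0.5 pseudocount at positions with an
#'   absent nucleotide (default `FALSE`; [fit_branch_model()] turns it
#'   on).
#' @return Numeric vector of 61 sense-codon frequencies (sums to 1),
#'   named by codon.
#' @export
f3x4_frequencies <- function(aln, pseudocount = FALSE) {
  m <- codon_matrix(aln)
  if (ncol(m) < 1) stop("empty alignment")
  ct <- codon_tables()
  posfreq <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, NUC))
  for (p in 1:3) {
    chars <- substring(m, p, p)
    counts <- vapply(NUC, function(b) sum(chars == b), numeric(1))
    if (pseudocount && any(counts == 0)) counts <- counts + 0.5
    posfreq[p, ] <- counts / sum(counts)
  }
  cc <- strsplit(ct$codons, "")
  pi <- vapply(cc, function(ch) {
    posfreq[1, ch[1]] * posfreq[2, ch[2]] * posfreq[3, ch[3]]
  }, numeric(1))
  pi <- pi / sum(pi)
  names(pi) <- ct$codons
  pi
}

#' GY94 instantaneous rate matrix
#'
#' Off-diagonal rates are nonzero only for single-nucleotide changes:
#' `q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]`. The
#' diagonal makes rows sum to zero and the matrix is rescaled so
#' `-sum(pi_i q_ii) = 1` (one expected substitution per codon per unit
#' time).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param pi 61 sense-codon frequencies summing to 1.
#' @return A 61 x 61 rate matrix with attributes `pi`, `rho_syn` (the
#'   equilibrium fraction of substitutions that are synonymous) and
#'   `scale` (the pre-scaling mean rate).
#' @export
gy94_rate_matrix <- function(kappa, omega, pi) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (length(pi) != 61) stop("pi must have 61 entries")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(pi < 0)) stop("pi must be non-negative")
  # cached flat index vectors for the hot path
  if (is.null(.gd$step_idx)) {
    steps <- codon_single_step_pairs()
    .gd$step_idx <- list(
      i = steps$i, j = steps$j,
      flat = cbind(steps$i, steps$j),
      ti = steps$transition, syn = steps$synonymous)
  }
  sx <- .gd$step_idx
  pi_u <- unname(pi)
  rates <- pi_u[sx$j]
  rates[sx$ti] <- rates[sx$ti] * kappa
  rates[!sx$syn] <- rates[!sx$syn] * omega
  Q <- matrix(0, 61, 61)
  Q[sx$flat] <- rates
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi_u * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (mean rate 0)")
  Q <- Q / mu
  syn_flux <- sum(pi_u[sx$i[sx$syn]] * Q[sx$flat[sx$syn, , drop = FALSE]])
  attr(Q, "pi") <- pi
  attr(Q, "rho_syn") <- syn_flux
  attr(Q, "scale") <- mu
  Q
}

# Symmetrising eigendecomposition of a reversible Q. Returns the pieces
# needed to form P(t) cheaply: P(t) = U1 %*% (exp(lambda t) * U2).
gy94_eigen <- function(Q, pi = attr(Q, "pi")) {
  if (any(pi <= 0))
    stop("pi must be strictly positive for the eigendecomposition; ",
         "estimate frequencies with pseudocount = TRUE")
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2  # symmetrise against rounding
  eig <- eigen(B, symmetric = TRUE)
  list(U1 = eig$vectors / sp, U2 = t(eig$vectors) * rep(sp, each = 61),
       lambda = eig$values, Q = Q, pi = pi)
}

# Transition probability matrix from a gy94_eigen decomposition.
# Falls back to scaling-and-squaring if the spectral reconstruction is
# poor (should not happen for valid reversible Q).
transition_probs <- function(eig, t, tol = 1e-10) {
  if (t < 0) stop("branch length must be >= 0")
  if (t == 0) return(diag(61))
  P <- eig$U1 %*% (exp(eig$lambda * t) * eig$U2)
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-6) || any(P < -1e-6)) {
    P <- expm_ss(eig$Q * t)
    rs <- rowSums(P)
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

# Plain scaling-and-squaring Taylor matrix exponential (fallback path).
expm_ss <- function(A, order = 12L) {
  nrm <- max(abs(A))
  k <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 4L)
  A <- A / 2^k
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(order)) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}
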