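# Felsenstein pruning over 61 codon states, branch-model ML fitting and
# likelihood-ratio tests.
#
# Branch lengths are expected substitutions per codon (codeml
# convention). Branch omega classes are indices into
# params$omega_by_class, one per row of tree$edge.

# Compress alignment columns into unique site patterns.
site_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(uk, key)
  list(states = states[, idx, drop = FALSE],
       weights = as.numeric(table(key)[uk]))
}

#' Codon model parameter set
#'
#' @param kappa Transition/transversion ratio.
#' @param omega_by_class Numeric vector of dN/dS values, one per branch
#'   class.
#' @param pi 61 sense-codon frequencies.
#' @param branch_lengths Expected substitutions per codon, one per row
#'   of the tree's edge matrix.
#' @param branch_class Integer vector assigning each edge to an omega
#'   class (default all 1).
#' @return A list of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa, omega_by_class, pi, branch_lengths,
                               branch_class = NULL) {
  if (is.null(branch_class))
    branch_class <- rep(1L, length(branch_lengths))
  if (length(branch_class) != length(branch_lengths))
    stop("branch_class and branch_lengths lengths differ")
  if (any(branch_class < 1) || any(branch_class > length(omega_by_class)))
    stop("branch_class indexes outside omega_by_class")
  if (any(branch_lengths < 0)) stop("branch lengths must be >= 0")
  structure(list(kappa = kappa, omega_by_class = omega_by_class, pi = pi,
                 branch_lengths = branch_lengths,
                 branch_class = as.integer(branch_class)),
            class = "codon_model_params")
}

#' Pruning log-likelihood of a codon alignment on a tree
#'
#' Felsenstein's pruning algorithm over the 61 sense-codon states with
#' per-branch GY94 transition matrices; the root is weighted by the
#' equilibrium frequencies. Requires a rooted binary tree whose leaves
#' all have sequences in the (cleaned) alignment.
#'
#' @param tree Rooted binary [ape::phylo].
#' @param aln Cleaned `codon_alignment` (no gaps/ambiguity/stops).
#' @param params A `codon_model_params` (see [codon_model_params()]).
#' @return Log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, aln, params) {
  assert_rooted_binary(tree)
  missing <- setdiff(tree$tip.label, aln$taxa)
  if (length(missing) > 0)
    stop("missing leaf sequences: ", paste(missing, collapse = ", "))
  states <- encode_codon_states(aln)[tree$tip.label, , drop = FALSE]
  pat <- site_patterns(states)
  pruning_loglik_patterns(tree, pat$states, pat$weights, params)
}

# Internal: likelihood on pre-compressed patterns.
pruning_loglik_patterns <- function(tree, pstates, weights, params) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  npat <- ncol(pstates)
  if (any(params$branch_lengths < 0)) stop("branch length must be >= 0")
  eigs <- lapply(params$omega_by_class, function(w)
    gy94_eigen(gy94_rate_matrix(params$kappa, w, params$pi)))
  tr <- ape::reorder.phylo(tree, "postorder")
  # map reordered edges back to the caller's edge order for t/class lookup
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]), edge_key)
  partial <- vector("list", nnode)
  logscale <- vector("list", nnode)
  for (k in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[k, 1]
    child <- tr$edge[k, 2]
    e <- ord[k]
    P <- transition_probs(eigs[[params$branch_class[e]]],
                          params$branch_lengths[e])
    if (child <= ntip) {
      contr <- P[, pstates[child, ], drop = FALSE]
      ls <- numeric(npat)
    } else {
      contr <- P %*% partial[[child]]
      ls <- logscale[[child]]
    }
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contr
      logscale[[parent]] <- ls
    } else {
      partial[[parent]] <- partial[[parent]] * contr
      logscale[[parent]] <- logscale[[parent]] + ls
    }
    # rescale only when entries drift towards underflow (cheap check)
    pp <- partial[[parent]]
    if (min(pp) < 1e-250 || max(pp) < 1e-120) {
      mx <- apply(pp, 2L, max)
      mx[mx == 0] <- 1
      partial[[parent]] <- sweep(pp, 2L, mx, "/")
      logscale[[parent]] <- logscale[[parent]] + log(mx)
    }
  }
  root <- ntip + 1L
  site_l <- as.numeric(params$pi %*% partial[[root]])
  sum(weights * (log(site_l) + logscale[[root]]))
}

# Rough starting branch lengths: half the mean pairwise nucleotide
# p-distance, expressed per codon, spread over the tree depth.
init_branch_lengths <- function(tree, aln) {
  m <- codon_matrix(aln)
  n <- nrow(m)
  pd <- 0
  npair <- 0
  for (i in seq_len(min(n - 1, 5))) {
    for (j in (i + 1):min(n, i + 3)) {
      if (j > n) next
      pd <- pd + mean(m[i, ] != m[j, ])
      npair <- npair + 1
    }
  }
  pd <- if (npair > 0) pd / npair else 0.1
  depth <- max(node_edge_depths(tree), 1)
  rep(max(0.02, 1.5 * pd / depth), nrow(tree$edge))
}

#' Maximum-likelihood branch-model fit
#'
#' Jointly maximises the pruning log-likelihood over kappa, one omega
#' per branch class and all branch lengths with bounded quasi-Newton
#' (L-BFGS-B); kappa and omega are optimised on the log scale. The
#' first start uses a heuristic initialisation, further starts are
#' seeded random perturbations; the best fit is returned.
#'
#' @param tree Rooted binary [ape::phylo].
#' @param aln `codon_alignment`; cleaned internally.
#' @param branch_class_map Integer vector, one omega class per edge
#'   (rows of `tree$edge`). Default: a single class. Use
#'   `seq_len(nrow(tree$edge))` for a free-ratio model.
#' @param init Optional list with any of `kappa`, `omega`, `branch_lengths`.
#' @param bounds List of bounds: `kappa` in `[0.01, 100]`, `omega` in
#'   `[1e-4, 20]`, `t` in `[0, 50]`.
#' @param n_starts Number of optimiser starts (default 3).
#' @param seed Seed for the random restarts (default 1).
#' @param control Passed to [stats::optim()].
#' @return A list of class `likelihood_fit`: `lnL`, `params`
#'   (`codon_model_params`), `converged`, `n_iter`, `n_starts`.
#' @export
fit_branch_model <- function(tree, aln, branch_class_map = NULL, init = NULL,
                             bounds = list(kappa = c(0.01, 100),
                                           omega = c(1e-4, 20),
                                           t = c(0, 50)),
                             n_starts = 3L, seed = 1L, control = list()) {
  assert_rooted_binary(tree)
  aln <- cleandata_filter(aln, drop_stop_columns = TRUE)
  nedge <- nrow(tree$edge)
  if (is.null(branch_class_map)) branch_class_map <- rep(1L, nedge)
  if (length(branch_class_map) != nedge)
    stop("branch_class_map must have one entry per edge")
  branch_class_map <- as.integer(factor(branch_class_map))
  nclass <- max(branch_class_map)
  pi <- f3x4_frequencies(aln, pseudocount = TRUE)
  states <- encode_codon_states(aln)[tree$tip.label, , drop = FALSE]
  pat <- site_patterns(states)

  negll <- function(par) {
    kappa <- exp(par[1])
    omegas <- exp(par[1 + seq_len(nclass)])
    t <- par[-seq_len(1 + nclass)]
    p <- codon_model_params(kappa, omegas, pi, t, branch_class_map)
    ll <- tryCatch(pruning_loglik_patterns(tree, pat$states, pat$weights, p),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  k0 <- if (!is.null(init$kappa)) init$kappa else 2
  w0 <- if (!is.null(init$omega)) rep(init$omega, nclass) else rep(0.3, nclass)
  t0 <- if (!is.null(init$branch_lengths)) init$branch_lengths
        else init_branch_lengths(tree, aln)
  lower <- c(log(bounds$kappa[1]), rep(log(bounds$omega[1]), nclass),
             rep(bounds$t[1], nedge))
  upper <- c(log(bounds$kappa[2]), rep(log(bounds$omega[2]), nclass),
             rep(bounds$t[2], nedge))
  ctrl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)

  starts <- list(c(log(k0), log(w0), pmax(t0, 1e-6)))
  if (n_starts > 1) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- c(
        log(k0) + stats::rnorm(1, 0, 0.5),
        log(w0) + stats::rnorm(nclass, 0, 0.7),
        pmax(t0 * exp(stats::rnorm(nedge, 0, 0.5)), 1e-6))
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- stats::optim(st, negll, method = "L-BFGS-B",
                        lower = lower, upper = upper, control = ctrl)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- best$par
  params <- codon_model_params(exp(par[1]), exp(par[1 + seq_len(nclass)]),
                               pi, par[-seq_len(1 + nclass)],
                               branch_class_map)
  structure(list(lnL = -best$value, params = params,
                 converged = best$convergence == 0,
                 n_iter = best$counts[["function"]],
                 n_starts = length(starts), tree = tree),
            class = "likelihood_fit")
}

#' @export
print.likelihood_fit <- function(x, ...) {
  cat(sprintf(
    "likelihood_fit: lnL = %.4f, kappa = %.3f, omega = %s, %s\n",
    x$lnL, x$params$kappa,
    paste(signif(x$params$omega_by_class, 4), collapse = "/"),
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-branch dN and dS from a fitted branch model
#'
#' Partitions each branch's expected substitutions per codon into
#' synonymous and nonsynonymous flux under the fitted matrix, and
#' divides by the model-based numbers of synonymous/nonsynonymous sites
#' (per codon, computed at omega = 1 with the fitted kappa and pi).
#'
#' @param fit A `likelihood_fit`.
#' @return Data frame: `edge`, `parent`, `child`, `child_label` (tip
#'   label or ""), `class`, `t`, `omega`, `dN`, `dS`.
#' @export
branch_dnds <- function(fit) {
  p <- fit$params
  tree <- fit$tree
  Q1 <- gy94_rate_matrix(p$kappa, 1, p$pi)
  rho_syn1 <- attr(Q1, "rho_syn")   # = S/3, the fraction of syn sites
  rho <- vapply(p$omega_by_class, function(w)
    attr(gy94_rate_matrix(p$kappa, w, p$pi), "rho_syn"), numeric(1))
  cls <- p$branch_class
  t <- p$branch_lengths
  dS <- t * rho[cls] / rho_syn1
  dN <- t * (1 - rho[cls]) / (1 - rho_syn1)
  child <- tree$edge[, 2]
  ntip <- ape::Ntip(tree)
  data.frame(edge = seq_along(t), parent = tree$edge[, 1], child = child,
             child_label = ifelse(child <= ntip, tree$tip.label[child], ""),
             class = cls, t = t, omega = p$omega_by_class[cls],
             dN = dN, dS = dS, stringsAsFactors = FALSE)
}

#' Likelihood-ratio test between nested branch models
#'
#' @param null_fit,alt_fit `likelihood_fit` objects on the same data,
#'   null nested in alternative.
#' @param df Degrees of freedom (difference in parameter count).
#' @param n_tests Bonferroni correction count (default 1).
#' @param tol Tolerance for `lnL_alt < lnL_null` before flagging an
#'   optimiser failure (default 0.01).
#' @return A list of class `lrt_result`: `stat` (`2 * max(0, dlnL)`),
#'   `df`, `p` (chi-square upper tail), `p_adj` (`min(1, p * n_tests)`),
#'   `n_tests`.
#' @export
lrt <- function(null_fit, alt_fit, df, n_tests = 1L, tol = 0.01) {
  if (df < 1) stop("df must be >= 1")
  d <- alt_fit$lnL - null_fit$lnL
  if (d < -tol)
    warning(sprintf(
      "optimizer failure signal: alternative lnL below null by %.4g", -d))
  stat <- max(0, 2 * d)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(stat = stat, df = df, p = p,
                 p_adj = min(1, p * n_tests), n_tests = n_tests),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2dlnL = %.4f, df = %d, p = %.4g, p_adj = %.4g (n_tests = %d)\n",
              x$stat, x$df, x$p, x$p_adj, x$n_tests))
  invisible(x)
}
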