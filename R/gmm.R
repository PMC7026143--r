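# Univariate Gaussian mixtures by EM with BIC model selection, used to
# detect duplication peaks in dS (Ks) distributions. The EM is written
# in-package on purpose: the monotone lnL trace and the seeding are part
# of the contract (mclust serves only as a cross-check in the tests).

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# k-means++-style seeded choice of K initial centres.
gmm_init_centres <- function(values, K) {
  centres <- numeric(K)
  centres[1] <- values[sample.int(length(values), 1)]
  if (K > 1) {
    for (k in 2:K) {
      d2 <- vapply(values, function(v)
        min((v - centres[seq_len(k - 1)])^2), numeric(1))
      if (sum(d2) == 0) centres[k] <- values[sample.int(length(values), 1)]
      else centres[k] <- values[sample.int(length(values), 1, prob = d2)]
    }
  }
  sort(centres)
}

#' Fit a univariate Gaussian mixture by EM
#'
#' @param values Numeric sample (finite).
#' @param K Number of components (>= 1); requires `length(values) >= 3K`.
#' @param seed Seed for the k-means++-style initialisation.
#' @param tol EM stops when the lnL improvement drops below `tol`
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param sigma_floor Lower bound on component SDs (default 1e-3),
#'   preventing variance collapse.
#' @return A list of class `mixture_model`: `K`, `weights`, `means`,
#'   `sds`, `lnL`, `bic` (`-2 lnL + (3K - 1) log n`), `n`, `converged`,
#'   `n_iter`, `lnl_trace`, `seed`.
#' @export
fit_gmm_em <- function(values, K, seed = 1L, tol = 1e-6, max_iter = 500L,
                       sigma_floor = 1e-3) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (K < 1) stop("K must be >= 1")
  if (n < 3 * K) stop("need at least 3K observations (n = ", n, ", K = ", K, ")")

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  mu <- gmm_init_centres(values, K)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  sg <- rep(max(stats::sd(values) * sqrt((n - 1) / n), sigma_floor), K)
  if (K == 1) mu <- mean(values)
  w <- rep(1 / K, K)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k)
      log(w[k]) + stats::dnorm(values, mu[k], sg[k], log = TRUE),
      numeric(n))
    if (K == 1) logd <- matrix(logd, ncol = 1)
    lse <- logsumexp_rows(logd)
    lnl <- sum(lse)
    trace <- c(trace, lnl)
    if (it > 1 && abs(lnl - trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    nk[nk < 1e-300] <- 1e-300
    w <- nk / n
    mu <- colSums(resp * values) / nk
    sg <- sqrt(colSums(resp * (outer(values, mu, "-")^2)) / nk)
    sg <- pmax(sg, sigma_floor)
  }
  ord <- order(mu)
  structure(list(K = K, weights = w[ord], means = mu[ord], sds = sg[ord],
                 lnL = trace[length(trace)],
                 bic = -2 * trace[length(trace)] + (3 * K - 1) * log(n),
                 n = n, converged = converged, n_iter = length(trace),
                 lnl_trace = trace, seed = seed),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model: K = %d, lnL = %.3f, BIC = %.3f%s\n",
              x$K, x$lnL, x$bic, if (x$converged) "" else " (not converged)"))
  cat(sprintf("  means: %s\n", paste(signif(x$means, 4), collapse = ", ")))
  cat(sprintf("  sds:   %s\n", paste(signif(x$sds, 4), collapse = ", ")))
  cat(sprintf("  w:     %s\n", paste(signif(x$weights, 4), collapse = ", ")))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits `seeds_per_k` seeded EM runs per K, keeps the best lnL for each
#' K and returns the model minimising BIC.
#'
#' @param values Numeric sample.
#' @param k_min,k_max Range of K (default 1..4).
#' @param seeds_per_k EM restarts per K (default 10).
#' @param seed Root seed; per-run seeds are derived deterministically.
#' @param ... Passed to [fit_gmm_em()].
#' @return The minimal-BIC `mixture_model`, with attribute `bic_table`
#'   (data frame `K`, `lnL`, `bic`, `converged`).
#' @export
select_k_bic <- function(values, k_min = 1L, k_max = 4L, seeds_per_k = 10L,
                         seed = 1L, ...) {
  if (k_max < k_min || k_min < 1) stop("need k_max >= k_min >= 1")
  best_by_k <- list()
  for (K in k_min:k_max) {
    best <- NULL
    for (s in seq_len(seeds_per_k)) {
      run_seed <- as.integer((as.numeric(seed) * 1000 + K * 100 + s) %%
                               2000000011)
      fit <- fit_gmm_em(values, K, seed = run_seed, ...)
      if (is.null(best) || fit$lnL > best$lnL) best <- fit
    }
    best_by_k[[as.character(K)]] <- best
  }
  tab <- do.call(rbind, lapply(best_by_k, function(f)
    data.frame(K = f$K, lnL = f$lnL, bic = f$bic, converged = f$converged)))
  rownames(tab) <- NULL
  best <- best_by_k[[which.min(tab$bic)]]
  attr(best, "bic_table") <- tab
  best
}
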