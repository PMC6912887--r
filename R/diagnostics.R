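# Convergence diagnostics: rank-normalized split R-hat and a standard
# multi-chain effective sample size (Gelman et al. 2013, ch. 11; Vehtari et
# al. 2021 rank normalization).

rank_normalize <- function(x) {
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

split_chains <- function(x, chain) {
  out <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- floor(length(v) / 2)
    if (h < 2) return(list(v))
    out <- c(out, list(v[seq_len(h)]), list(v[h + seq_len(h)]))
  }
  out
}

rhat_basic <- function(chains) {
  m <- length(chains)
  n <- min(lengths(chains))
  if (m < 2 || n < 2) return(NA_real_)
  chains <- lapply(chains, function(v) v[seq_len(n)])
  means <- vapply(chains, mean, 0)
  vars <- vapply(chains, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split R-hat for one monitored quantity
#'
#' Rank-normalized split-chain potential scale reduction factor; the maximum
#' of the bulk statistic and the same statistic applied to folded
#' (median-centred absolute) draws, so both location and scale mixing are
#' monitored.
#'
#' @param x Numeric vector of draws (all chains concatenated).
#' @param chain Integer vector of chain ids, same length as `x`.
#' @return Scalar R-hat (1 indicates convergence; values > 1.1 flag trouble).
#' @export
rhat <- function(x, chain) {
  if (length(unique(x)) == 1L) return(1)
  bulk <- rhat_basic(split_chains(rank_normalize(x), chain))
  folded <- rhat_basic(split_chains(rank_normalize(abs(x - median(x))), chain))
  max(bulk, folded, na.rm = TRUE)
}

ess_basic <- function(x, chain) {
  if (var(x) == 0) return(length(x))
  chains <- split(x, chain)
  n <- min(lengths(chains))
  if (n < 4) return(NA_real_)
  m <- length(chains)
  rho <- rowMeans(vapply(chains, function(v) {
    a <- acf(v[seq_len(n)], lag.max = min(n - 2L, 200L), plot = FALSE,
             demean = TRUE)$acf[-1]
    as.numeric(a)
  }, numeric(min(n - 2L, 200L))))
  # Geyer-style truncation at the first negative pair sum
  tau <- 1
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, m * n / tau)
}

#' Posterior summary of retained draws
#'
#' Per-parameter posterior mean, standard deviation, and 2.5/50/97.5
#' percentiles (empirical quantiles, type 7), with split R-hat and effective
#' sample size when chain ids are supplied.
#'
#' @param draws Numeric matrix (iterations x parameters) or vector.
#' @param chain Optional integer chain ids (length `nrow(draws)`).
#' @param min_draws Minimum number of retained draws required (default 100).
#' @return Data frame with one row per parameter.
#' @export
summarize_draws <- function(draws, chain = NULL, min_draws = 100L) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L,
                                           dimnames = list(NULL, "x"))
  if (nrow(draws) < min_draws) {
    stop(sprintf("need at least %d retained draws, got %d",
                 min_draws, nrow(draws)), call. = FALSE)
  }
  if (is.null(chain)) chain <- rep(1L, nrow(draws))
  out <- data.frame(
    parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    mean = colMeans(draws),
    sd = apply(draws, 2L, sd),
    q2.5 = apply(draws, 2L, quantile, 0.025, names = FALSE),
    q50 = apply(draws, 2L, quantile, 0.5, names = FALSE),
    q97.5 = apply(draws, 2L, quantile, 0.975, names = FALSE),
    rhat = apply(draws, 2L, rhat, chain = chain),
    ess = apply(draws, 2L, ess_basic, chain = chain),
    row.names = NULL)
  out
}
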