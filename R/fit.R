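#' MCMC sampler settings
#'
#' Defaults follow the protocol used for the simulated-data analyses: two
#' chains of 25,000 adaptive Metropolis-within-Gibbs iterations, the first
#' 15,000 discarded as burn-in, and every fifth post-burn-in iteration
#' retained. For large real datasets (e.g. the goose analysis profile) use
#' `n_iter = 1e5, n_burn = 5e4, thin = 5`.
#'
#' @param n_chains Number of chains (default 2).
#' @param n_iter Iterations per chain (default 25000).
#' @param n_burn Burn-in iterations discarded per chain (default 15000).
#' @param thin Retain every `thin`-th post-burn-in iteration (default 5).
#' @param parameterization `"centered"` (year effects sampled on their
#'   natural logit scale, the default) or `"noncentered"` (standardized
#'   deviates; mixes better when the year-effect variances are very small).
#' @return Object of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 2L, n_iter = 25000L, n_burn = 15000L,
                         thin = 5L,
                         parameterization = c("centered", "noncentered")) {
  parameterization <- match.arg(parameterization)
  if (!(n_burn < n_iter)) stop("need n_burn < n_iter", call. = FALSE)
  if (!(thin >= 1)) stop("need thin >= 1", call. = FALSE)
  if (!(n_chains >= 1)) stop("need n_chains >= 1", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 parameterization = parameterization),
            class = "mcmc_control")
}

empty_marrays <- function(T) {
  cn <- c(paste0("occ", 2:T), "never")
  m <- matrix(0, T - 1L, T, dimnames = list(paste0("rel", 1:(T - 1L)), cn))
  structure(list(juv = m, ad = m, T = as.integer(T)), class = "marray_set")
}

# crude empirical initial values: survival proxies from the fraction of
# releases ever re-encountered (assuming detection near 0.5), sigma = 0.3,
# rho = 0, p = 0.5.
init_theta <- function(marrays, cfg) {
  T <- cfg$T
  ny <- T - 1L
  frac <- function(m) {
    tot <- sum(m)
    if (tot == 0) return(0.5)
    1 - sum(m[, T]) / tot
  }
  # invert P(ever re-encountered) = phi*p / (1 - phi*(1-p)) at p = 0.5
  q_ad <- frac(marrays$ad)
  q_juv <- frac(marrays$juv)
  phi0_ad <- min(0.95, max(0.05, 2 * q_ad / (1 + q_ad)))
  phi0_juv <- min(0.95, max(0.05, 2 * q_juv / (1 + q_juv)))
  mu0 <- c(qlogis(phi0_ad), qlogis(phi0_juv))
  s0 <- if (cfg$prior == 0L || cfg$sig_dist == 1L) log(0.3)
        else qlogis((0.3 - cfg$sig_lo) / (cfg$sig_hi - cfg$sig_lo))
  z0 <- if (cfg$prior == 0L) 0 else qlogis((0 - cfg$rho_lo) / (cfg$rho_hi - cfg$rho_lo))
  eta0 <- if (cfg$noncentered == 1L) rep(0, 2L * ny)
          else c(rep(mu0[1], ny), rep(mu0[2], ny))
  det0 <- if (cfg$det == 0L) 0 else c(0, qlogis(0.3 / cfg$sigp_hi),
                                      qlogis(0.3 / cfg$sigp_hi), rep(0, 2L * ny))
  c(mu0, s0, s0, z0, eta0, det0)
}

#' Fit the hierarchical age-structured CJS model
#'
#' Estimates the posterior of the age-structured Cormack-Jolly-Seber model
#' with bivariate normal year effects on logit survival, under either
#' covariance prior, by adaptive Metropolis-within-Gibbs on the marginalized
#' m-array likelihood (per-iteration cost is independent of the number of
#' marked individuals). Retained draws are pooled across chains after burn-in
#' and thinning; convergence is monitored by rank-normalized split R-hat on
#' all reported quantities and flagged (never silently dropped) when any
#' exceeds 1.1.
#'
#' @param marrays An [build_marrays()] result (or `NULL` with `T` supplied,
#'   for prior-only runs).
#' @param prior An [iw_prior()] or [separated_prior()] for the year-effect
#'   covariance matrix.
#' @param detection `"constant"` (single detection probability, flat prior;
#'   the simulation-study variant) or `"age_time"` (second-year vs adult
#'   detection classes with time random effects).
#' @param mcmc An [mcmc_control()].
#' @param seed Integer seed; chain k uses `seed + k - 1`.
#' @param prior_only If `TRUE` the likelihood is switched off and the chains
#'   sample the prior (useful for prior-predictive checks).
#' @param T Number of occasions, required only when `marrays` is `NULL`.
#' @param mu_sd,beta0_var,sigp_upper Hyperprior settings (see
#'   [cjs_logprior()]).
#' @return Object of class `cjs_corr`: list with `draws` (matrix of retained
#'   posterior draws on natural scales, pooled across chains), `chain`
#'   (chain id per draw), `summary` (data frame from [summarize_draws()]),
#'   `converged`, `max_rhat`, plus the configuration used.
#' @examples
#' d <- simulate_cmr(sim_config(T = 6, releases_per_occasion = 200, rho = 0.5),
#'                   seed = 1)
#' m <- build_marrays(d$histories)
#' fit <- cjs_corr(m, prior = separated_prior(),
#'                 mcmc = mcmc_control(n_iter = 2000, n_burn = 1000),
#'                 seed = 1)
#' coef(fit)["rho"]
#' @export
cjs_corr <- function(marrays, prior = separated_prior(),
                     detection = c("constant", "age_time"),
                     mcmc = mcmc_control(), seed = NULL,
                     prior_only = FALSE, T = NULL,
                     mu_sd = 1, beta0_var = 3, sigp_upper = 3) {
  detection <- match.arg(detection)
  if (is.null(marrays)) {
    if (is.null(T)) stop("supply `T` when `marrays` is NULL", call. = FALSE)
    marrays <- empty_marrays(T)
  }
  stopifnot(inherits(marrays, "marray_set"))
  if (!prior_only && sum(marrays$juv) + sum(marrays$ad) == 0) {
    stop("m-arrays are empty; use `prior_only = TRUE` for prior sampling",
         call. = FALSE)
  }
  cfg <- model_cfg(marrays$T, prior, detection = detection,
                   parameterization = mcmc$parameterization,
                   mu_sd = mu_sd, beta0_var = beta0_var,
                   sigp_upper = sigp_upper)
  theta0 <- init_theta(marrays, cfg)
  use_lik <- !prior_only
  n_keep <- ((mcmc$n_iter - mcmc$n_burn + mcmc$thin - 1L) %/% mcmc$thin)
  chains <- vector("list", mcmc$n_chains)
  for (k in seq_len(mcmc$n_chains)) {
    if (!is.null(seed)) set.seed(seed + k - 1L)
    init_k <- theta0
    if (k > 1L) init_k <- init_k + rnorm(length(init_k), 0, 0.1)
    # bounded jitter retries if an init lands outside the posterior support
    for (attempt in 1:20) {
      lp <- .logpost_cpp(init_k, cfg, marrays$juv, marrays$ad, use_lik)
      if (is.finite(sum(lp))) break
      init_k <- theta0 + rnorm(length(theta0), 0, 0.05 * attempt)
      if (attempt == 20) stop("could not find a finite starting value",
                              call. = FALSE)
    }
    chains[[k]] <- .run_mcmc_cpp(cfg, marrays$juv, marrays$ad, init_k,
                                 mcmc$n_iter, mcmc$n_burn, mcmc$thin, use_lik)
  }
  theta_draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(mcmc$n_chains), each = n_keep)
  draws <- constrain_draws(theta_draws, cfg)
  summ <- summarize_draws(draws, chain = chain_id, min_draws = 10L)
  # monitor the reported scalar parameters for convergence
  mon <- c("mu_ad", "mu_juv", "sigma2_ad", "sigma2_juv", "rho",
           if (detection == "constant") "p" else "beta0")
  max_rhat <- max(summ$rhat[summ$parameter %in% mon], na.rm = TRUE)
  structure(list(draws = draws, chain = chain_id, summary = summ,
                 converged = is.finite(max_rhat) && max_rhat <= 1.1,
                 max_rhat = max_rhat,
                 prior = prior, detection = detection, mcmc = mcmc,
                 seed = seed, T = marrays$T, prior_only = prior_only,
                 accept = lapply(chains, `[[`, "accept"),
                 logpost = unlist(lapply(chains, `[[`, "logpost")),
                 call = match.call()),
            class = "cjs_corr")
}

# Vectorized conversion of unconstrained draws to natural-scale quantities.
constrain_draws <- function(theta, cfg) {
  ny <- cfg$T - 1L
  tr_sig <- function(s) {
    if (cfg$prior == 0L || cfg$sig_dist == 1L) exp(s)
    else cfg$sig_lo + (cfg$sig_hi - cfg$sig_lo) * plogis(s)
  }
  sig_ad <- tr_sig(theta[, 3L])
  sig_juv <- tr_sig(theta[, 4L])
  rho <- if (cfg$prior == 0L) tanh(theta[, 5L])
         else cfg$rho_lo + (cfg$rho_hi - cfg$rho_lo) * plogis(theta[, 5L])
  mu_ad <- theta[, 1L]
  mu_juv <- theta[, 2L]
  if (cfg$noncentered == 1L) {
    u1 <- theta[, 5L + seq_len(ny), drop = FALSE]
    u2 <- theta[, 5L + ny + seq_len(ny), drop = FALSE]
    eta_ad <- mu_ad + sig_ad * u1
    eta_juv <- mu_juv + sig_juv * (rho * u1 + sqrt(pmax(0, 1 - rho^2)) * u2)
  } else {
    eta_ad <- theta[, 5L + seq_len(ny), drop = FALSE]
    eta_juv <- theta[, 5L + ny + seq_len(ny), drop = FALSE]
  }
  d0 <- 5L + 2L * ny
  out <- cbind(mu_ad = mu_ad, mu_juv = mu_juv,
               sigma_ad = sig_ad, sigma_juv = sig_juv,
               sigma2_ad = sig_ad^2, sigma2_juv = sig_juv^2, rho = rho)
  if (cfg$det == 0L) {
    out <- cbind(out, p = plogis(theta[, d0 + 1L]))
  } else {
    out <- cbind(out, beta0 = theta[, d0 + 1L],
                 sigma_p_sy = cfg$sigp_hi * plogis(theta[, d0 + 2L]),
                 sigma_p_ad = cfg$sigp_hi * plogis(theta[, d0 + 3L]))
    psy <- plogis(theta[, d0 + 1L] + theta[, d0 + 3L + seq_len(ny), drop = FALSE])
    pad <- plogis(theta[, d0 + 1L] + theta[, d0 + 3L + ny + seq_len(ny), drop = FALSE])
    colnames(psy) <- paste0("p_sy_", 2:cfg$T)
    colnames(pad) <- paste0("p_ad_", 2:cfg$T)
    out <- cbind(out, psy, pad)
  }
  phi_ad <- plogis(eta_ad)
  phi_juv <- plogis(eta_juv)
  colnames(phi_ad) <- paste0("phi_ad_", seq_len(ny))
  colnames(phi_juv) <- paste0("phi_juv_", seq_len(ny))
  cbind(out, phi_ad, phi_juv)
}

#' @export
print.cjs_corr <- function(x, ...) {
  cat(sprintf("Age-structured CJS fit (%s covariance prior%s)\n",
              if (inherits(x$prior, "iw_prior")) "inverse Wishart" else "separated",
              if (x$prior_only) ", prior only" else ""))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d retained draws\n",
              x$mcmc$n_chains, x$mcmc$n_iter, x$mcmc$n_burn, x$mcmc$thin,
              nrow(x$draws)))
  s <- x$summary
  key <- s[s$parameter %in% c("mu_ad", "mu_juv", "sigma2_ad", "sigma2_juv",
                              "rho", "p", "beta0"), ]
  print(cbind(key["parameter"], round(key[c("mean", "sd", "q2.5", "q50",
                                            "q97.5", "rhat")], 3)),
        row.names = FALSE)
  if (!x$converged) {
    cat(sprintf("  WARNING: max R-hat %.3f > 1.1 on monitored parameters\n",
                x$max_rhat))
  }
  invisible(x)
}

#' @export
summary.cjs_corr <- function(object, ...) {
  structure(list(summary = object$summary, converged = object$converged,
                 max_rhat = object$max_rhat, n_draws = nrow(object$draws),
                 prior = object$prior, detection = object$detection),
            class = "summary.cjs_corr")
}

#' @export
print.summary.cjs_corr <- function(x, ...) {
  cat(sprintf("Posterior summary (%d retained draws)\n", x$n_draws))
  print(cbind(x$summary["parameter"],
              round(x$summary[c("mean", "sd", "q2.5", "q50", "q97.5",
                                "rhat", "ess")], 3)),
        row.names = FALSE)
  cat(sprintf("max R-hat on monitored parameters: %.3f (%s)\n", x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.cjs_corr <- function(object, ...) {
  setNames(object$summary$mean, object$summary$parameter)
}

#' Credible interval for a fitted quantity
#'
#' @param object A [cjs_corr()] fit.
#' @param parameter Parameter name (default `"rho"`).
#' @param level Central interval mass (default 0.95).
#' @return Length-2 vector of empirical posterior quantiles.
#' @export
credible_interval <- function(object, parameter = "rho", level = 0.95) {
  stopifnot(inherits(object, "cjs_corr"))
  a <- (1 - level) / 2
  quantile(object$draws[, parameter], c(a, 1 - a), names = FALSE)
}

#' @export
plot.cjs_corr <- function(x, parameters = c("rho", "sigma2_ad", "sigma2_juv"),
                          ...) {
  parameters <- intersect(parameters, colnames(x$draws))
  op <- graphics::par(mfrow = c(length(parameters), 2),
                      mar = c(3.5, 3.5, 1.5, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  for (pn in parameters) {
    v <- x$draws[, pn]
    graphics::plot(v, type = "l", col = x$chain,
                   xlab = "retained iteration", ylab = pn, main = pn)
    graphics::plot(stats::density(v), main = "", xlab = pn, ylab = "density")
  }
  invisible(x)
}

#' Simulate posterior-predictive datasets from a fit
#'
#' Draws hyperparameters \eqn{(\mu, \Sigma)} from the retained posterior and
#' generates new capture-mark-recapture datasets from them, i.e. the
#' posterior predictive distribution of a replicate study.
#'
#' @param object A [cjs_corr()] fit with constant detection.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param releases_per_occasion,juvenile_fraction Release design of the
#'   simulated studies.
#' @param ... Unused.
#' @return List of `cmr_data` objects (invisibly a list even for `nsim = 1`).
#' @export
simulate.cjs_corr <- function(object, nsim = 1, seed = NULL,
                              releases_per_occasion = 100,
                              juvenile_fraction = 0.5, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  lapply(idx, function(i) {
    d <- object$draws[i, ]
    p <- if ("p" %in% names(d)) unname(d["p"]) else 0.5
    cfg <- sim_config(T = object$T,
                      releases_per_occasion = releases_per_occasion,
                      mu_ad = unname(d["mu_ad"]), mu_juv = unname(d["mu_juv"]),
                      sigma2_ad = unname(d["sigma2_ad"]),
                      sigma2_juv = unname(d["sigma2_juv"]),
                      rho = unname(d["rho"]),
                      juvenile_fraction = juvenile_fraction, p = p)
    simulate_cmr(cfg)
  })
}
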