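#' Parameter set for the hierarchical age-structured CJS model
#'
#' Collects all model parameters on their natural (constrained) scales:
#' logit-scale survival means, the covariance components of the year-effect
#' distribution, the T-1 logit-scale annual survival pairs, and the detection
#' block -- either a single constant detection probability, or the
#' age-class/time random-effect detection model
#' \eqn{\mathrm{logit}(p_{k,t}) = \beta_0 + \epsilon_{p_k,t}} with
#' class-specific standard deviations (the model used for long-lived geese
#' where second-year birds are detected at lower rates than adults).
#'
#' @param mu_ad,mu_juv Logit-scale survival means.
#' @param sigma_ad,sigma_juv Year-effect standard deviations (> 0).
#' @param rho Process correlation in (-1, 1).
#' @param eta_ad,eta_juv Logit-scale annual survival, length T-1.
#' @param p Constant detection probability (constant-p variant).
#' @param beta0,sigma_p_sy,sigma_p_ad,eps_p_sy,eps_p_ad Detection-variant
#'   parameters: intercept, class standard deviations, and length T-1
#'   logit-scale deviations for the second-year and adult detection classes.
#' @return Object of class `cjs_params`.
#' @export
cjs_params <- function(mu_ad, mu_juv, sigma_ad, sigma_juv, rho,
                       eta_ad, eta_juv, p = NULL,
                       beta0 = NULL, sigma_p_sy = NULL, sigma_p_ad = NULL,
                       eps_p_sy = NULL, eps_p_ad = NULL) {
  if (length(eta_ad) != length(eta_juv)) {
    stop("`eta_ad` and `eta_juv` must have equal length T-1", call. = FALSE)
  }
  det <- if (!is.null(p)) "constant" else "age_time"
  if (det == "age_time" &&
      (is.null(beta0) || is.null(sigma_p_sy) || is.null(sigma_p_ad) ||
       is.null(eps_p_sy) || is.null(eps_p_ad))) {
    stop("supply either `p` or the full age_time detection block", call. = FALSE)
  }
  structure(list(mu_ad = mu_ad, mu_juv = mu_juv,
                 sigma_ad = sigma_ad, sigma_juv = sigma_juv, rho = rho,
                 eta_ad = as.numeric(eta_ad), eta_juv = as.numeric(eta_juv),
                 p = p, beta0 = beta0,
                 sigma_p_sy = sigma_p_sy, sigma_p_ad = sigma_p_ad,
                 eps_p_sy = eps_p_sy, eps_p_ad = eps_p_ad,
                 detection = det, T = length(eta_ad) + 1L),
            class = "cjs_params")
}

# Internal: config list consumed by the C++ kernels.
model_cfg <- function(T, prior, detection = "constant",
                      parameterization = "centered",
                      mu_sd = 1, beta0_var = 3, sigp_upper = 3) {
  stopifnot(inherits(prior, "cov_prior"))
  iw <- inherits(prior, "iw_prior")
  list(T = as.integer(T),
       prior = if (iw) 0L else 1L,
       det = if (detection == "constant") 0L else 1L,
       sig_dist = if (!iw && prior$sigma_dist == "halfnormal") 1L else 0L,
       noncentered = if (parameterization == "noncentered") 1L else 0L,
       iw_df = if (iw) prior$df else 3,
       iw_scale = if (iw) prior$scale else diag(2),
       sig_lo = if (iw) 0 else prior$sigma_lower,
       sig_hi = if (iw) 5 else prior$sigma_upper,
       rho_lo = if (iw) -1 else prior$rho_lower,
       rho_hi = if (iw) 1 else prior$rho_upper,
       hn_sd = if (iw) 1 else sqrt(prior$sigma_hn_var),
       mu_sd = mu_sd,
       beta0_sd = sqrt(beta0_var),
       sigp_lo = 0, sigp_hi = sigp_upper)
}

n_par <- function(cfg) {
  5L + 2L * (cfg$T - 1L) + if (cfg$det == 0L) 1L else 3L + 2L * (cfg$T - 1L)
}

#' Log-likelihood of the model parameters given m-arrays
#'
#' The marginalized multinomial m-array likelihood evaluated at a
#' [cjs_params()] (see [marray_loglik()] for the underlying algebra). An
#' empty m-array gives 0.
#'
#' @param params A [cjs_params()].
#' @param marrays An [build_marrays()] result with matching T.
#' @return Scalar log-likelihood.
#' @export
cjs_loglik <- function(params, marrays) {
  if (params$T != marrays$T) {
    stop(sprintf("params imply T = %d but m-arrays have T = %d",
                 params$T, marrays$T), call. = FALSE)
  }
  T <- params$T
  if (params$detection == "constant") {
    p_sy <- p_ad <- rep_len(params$p, T - 1L)
  } else {
    p_sy <- plogis(params$beta0 + params$eps_p_sy)
    p_ad <- plogis(params$beta0 + params$eps_p_ad)
  }
  .marray_loglik_cpp(marrays$juv, marrays$ad,
                     plogis(params$eta_juv), plogis(params$eta_ad), p_sy, p_ad)
}

# Inverse Wishart log-density of a 2x2 covariance matrix (scale S_iw).
diwish2 <- function(Sigma, df, S_iw) {
  d <- det(Sigma)
  dS <- det(S_iw)
  if (d <= 0 || dS <= 0) return(-Inf)
  K <- 2
  lmg <- 0.5 * log(pi) + lgamma(df / 2) + lgamma(df / 2 - 0.5)
  0.5 * df * log(dS) - 0.5 * df * K * log(2) - lmg -
    0.5 * (df + K + 1) * log(d) - 0.5 * sum(diag(S_iw %*% solve(Sigma)))
}

#' Log-prior density of the model parameters
#'
#' Sum of: Normal(0, 1) log-densities for the two survival means; the
#' covariance prior log-density (inverse Wishart density on \eqn{\Sigma},
#' including the Jacobian of the map from matrix elements to
#' \eqn{(\sigma_{ad}, \sigma_{juv}, \rho)}, or the separated hyperprior
#' densities); the bivariate normal log-density of the T-1 year-effect pairs
#' given \eqn{(\mu, \Sigma)}; and the detection prior (flat on p for the
#' constant variant; normal/uniform hyperpriors for the age/time variant).
#' Parameters outside the prior support return `-Inf`.
#'
#' @param params A [cjs_params()].
#' @param prior An [iw_prior()] or [separated_prior()].
#' @param mu_sd Prior standard deviation of the survival means (default 1).
#' @param beta0_var Prior variance of the detection intercept (default 3;
#'   the precision reading of the same prior would be variance 1/3 -- pass
#'   `beta0_var = 1/3` for that interpretation).
#' @param sigp_upper Upper bound of the uniform priors on the detection-class
#'   standard deviations (default 3).
#' @return Scalar log prior density (possibly `-Inf`).
#' @export
cjs_logprior <- function(params, prior, mu_sd = 1, beta0_var = 3,
                         sigp_upper = 3) {
  s1 <- params$sigma_ad
  s2 <- params$sigma_juv
  r <- params$rho
  if (s1 <= 0 || s2 <= 0 || abs(r) >= 1) return(-Inf)
  lp <- dnorm(params$mu_ad, 0, mu_sd, log = TRUE) +
    dnorm(params$mu_juv, 0, mu_sd, log = TRUE)
  if (inherits(prior, "iw_prior")) {
    Sigma <- build_covariance(cov_spec(s1, s2, r))
    lp <- lp + diwish2(Sigma, prior$df, solve(prior$scale)) +
      log(4) + 2 * log(s1) + 2 * log(s2)
  } else {
    if (prior$sigma_dist == "uniform") {
      if (s1 <= prior$sigma_lower || s1 >= prior$sigma_upper ||
          s2 <= prior$sigma_lower || s2 >= prior$sigma_upper) return(-Inf)
      lp <- lp - 2 * log(prior$sigma_upper - prior$sigma_lower)
    } else {
      hs <- sqrt(prior$sigma_hn_var)
      lp <- lp + dnorm(s1, 0, hs, log = TRUE) + dnorm(s2, 0, hs, log = TRUE) +
        2 * log(2)
    }
    if (r <= prior$rho_lower || r >= prior$rho_upper) return(-Inf)
    lp <- lp - log(prior$rho_upper - prior$rho_lower)
  }
  # year-effect MVN layer
  r2 <- 1 - r^2
  x1 <- (params$eta_ad - params$mu_ad) / s1
  x2 <- (params$eta_juv - params$mu_juv) / s2
  ny <- length(x1)
  lp <- lp - ny * (log(2 * pi) + log(s1) + log(s2) + 0.5 * log(r2)) -
    0.5 * sum(x1^2 - 2 * r * x1 * x2 + x2^2) / r2
  # detection block
  if (params$detection == "constant") {
    if (params$p <= 0 || params$p >= 1) return(-Inf)
    # flat Uniform(0,1): contributes 0
  } else {
    if (params$sigma_p_sy <= 0 || params$sigma_p_sy >= sigp_upper ||
        params$sigma_p_ad <= 0 || params$sigma_p_ad >= sigp_upper) return(-Inf)
    lp <- lp + dnorm(params$beta0, 0, sqrt(beta0_var), log = TRUE) -
      2 * log(sigp_upper) +
      sum(dnorm(params$eps_p_sy, 0, params$sigma_p_sy, log = TRUE)) +
      sum(dnorm(params$eps_p_ad, 0, params$sigma_p_ad, log = TRUE))
  }
  lp
}

#' Map parameters between constrained and unconstrained scales
#'
#' `par_pack()` maps a [cjs_params()] to the unconstrained vector the sampler
#' works on; `par_unpack()` inverts it. Standard deviations use a log scale
#' under the inverse Wishart (and half-normal) priors and a scaled-logit
#' scale under bounded uniform priors; the correlation uses scaled tanh /
#' logit; probabilities use logit. `par_unpack()` attaches the summed
#' log-Jacobian of the inverse map as attribute `"log_jacobian"`. Boundary
#' values (|rho| = 1, p in {0, 1}) map to infinity and are rejected.
#'
#' @param params A [cjs_params()].
#' @param prior An [iw_prior()] or [separated_prior()].
#' @param ... Passed to [model_cfg] internals (`mu_sd`, `beta0_var`,
#'   `sigp_upper`).
#' @return `par_pack()`: numeric vector; `par_unpack()`: a [cjs_params()]
#'   with attribute `log_jacobian`.
#' @export
par_pack <- function(params, prior, ...) {
  cfg <- model_cfg(params$T, prior, detection = params$detection, ...)
  tr_sig <- function(s) {
    if (cfg$prior == 0L || cfg$sig_dist == 1L) log(s)
    else qlogis((s - cfg$sig_lo) / (cfg$sig_hi - cfg$sig_lo))
  }
  tr_rho <- function(r) {
    if (cfg$prior == 0L) atanh(r)
    else qlogis((r - cfg$rho_lo) / (cfg$rho_hi - cfg$rho_lo))
  }
  th <- c(params$mu_ad, params$mu_juv,
          tr_sig(params$sigma_ad), tr_sig(params$sigma_juv),
          tr_rho(params$rho), params$eta_ad, params$eta_juv)
  th <- c(th, if (params$detection == "constant") {
    qlogis(params$p)
  } else {
    c(params$beta0,
      qlogis(params$sigma_p_sy / cfg$sigp_hi),
      qlogis(params$sigma_p_ad / cfg$sigp_hi),
      params$eps_p_sy, params$eps_p_ad)
  })
  if (any(!is.finite(th))) {
    stop("boundary parameter value cannot be mapped to the unconstrained scale",
         call. = FALSE)
  }
  th
}

#' @rdname par_pack
#' @param theta Unconstrained parameter vector (layout produced by
#'   `par_pack()`).
#' @param T Number of occasions.
#' @param detection `"constant"` or `"age_time"`.
#' @export
par_unpack <- function(theta, T, prior, detection = "constant", ...) {
  cfg <- model_cfg(T, prior, detection = detection, ...)
  if (length(theta) != n_par(cfg)) {
    stop(sprintf("theta has length %d, expected %d", length(theta), n_par(cfg)),
         call. = FALSE)
  }
  u <- .unpack_cpp(as.numeric(theta), cfg)
  ny <- T - 1L
  if (detection == "constant") {
    pars <- cjs_params(u$mu_ad, u$mu_juv, u$sigma_ad, u$sigma_juv, u$rho,
                       u$eta_ad, u$eta_juv, p = u$p_ad[1])
  } else {
    d0 <- 5L + 2L * ny
    pars <- cjs_params(u$mu_ad, u$mu_juv, u$sigma_ad, u$sigma_juv, u$rho,
                       u$eta_ad, u$eta_juv,
                       beta0 = theta[d0 + 1L],
                       sigma_p_sy = cfg$sigp_hi * plogis(theta[d0 + 2L]),
                       sigma_p_ad = cfg$sigp_hi * plogis(theta[d0 + 3L]),
                       eps_p_sy = theta[d0 + 3L + seq_len(ny)],
                       eps_p_ad = theta[d0 + 3L + ny + seq_len(ny)])
  }
  attr(pars, "log_jacobian") <- u$log_jacobian
  pars
}
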