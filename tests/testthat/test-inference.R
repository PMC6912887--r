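test_that("summarize_draws handles degenerate and simple inputs", {
  const <- matrix(5, 200, 1, dimnames = list(NULL, "x"))
  s <- summarize_draws(const)
  expect_equal(s$mean, 5)
  expect_equal(s$q2.5, 5)
  expect_equal(s$q97.5, 5)
  # type-7 empirical quantiles: 2.5% of 1..100 is 3.475
  s2 <- summarize_draws(matrix(1:100, 100, 1), min_draws = 100)
  expect_true(s2$q2.5 >= 2 && s2$q2.5 <= 4)
  expect_error(summarize_draws(matrix(1:50, 50, 1)), "100")
  # two identical chains: R-hat ~ 1
  x <- rnorm(400)
  expect_equal(rhat(c(x, x), rep(1:2, each = 400)), 1, tolerance = 0.02)
})

test_that("prior-only chains reproduce the separated prior", {
  fit <- cjs_corr(NULL, T = 5, prior = separated_prior(), prior_only = TRUE,
                  seed = 61,
                  mcmc = mcmc_control(n_iter = 150000, n_burn = 10000,
                                      thin = 100))
  r <- fit$draws[, "rho"]
  ks <- suppressWarnings(stats::ks.test(r, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(fit$draws[, "sigma_ad"]), 2.5, tolerance = 0.1)
  expect_equal(mean(fit$draws[, "p"]), 0.5, tolerance = 0.05)
})

test_that("prior-only chains reproduce the inverse Wishart marginals", {
  fit <- cjs_corr(NULL, T = 5, prior = iw_prior(), prior_only = TRUE,
                  seed = 62,
                  mcmc = mcmc_control(n_iter = 300000, n_burn = 20000,
                                      thin = 50))
  # inverse-gamma(1, 1/2) variance marginal; tolerance reflects the Monte
  # Carlo error of a quantile of an autocorrelated heavy-tailed chain
  expect_equal(median(fit$draws[, "sigma2_ad"]), 0.5 / log(2), tolerance = 0.07)
  expect_equal(median(fit$draws[, "rho"]), 0, tolerance = 0.05)
})

test_that("fits are draw-for-draw reproducible under a fixed seed", {
  d <- simulate_cmr(sim_config(T = 5, releases_per_occasion = 80), seed = 63)
  m <- build_marrays(d$histories)
  ctrl <- mcmc_control(n_iter = 2000, n_burn = 1000)
  f1 <- cjs_corr(m, prior = separated_prior(), mcmc = ctrl, seed = 9)
  f2 <- cjs_corr(m, prior = separated_prior(), mcmc = ctrl, seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- cjs_corr(m, prior = separated_prior(), mcmc = ctrl, seed = 10)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("centered and noncentered samplers agree on the posterior", {
  d <- simulate_cmr(sim_config(T = 6, releases_per_occasion = 300, rho = 0.4),
                    seed = 64)
  m <- build_marrays(d$histories)
  fc <- cjs_corr(m, prior = separated_prior(), seed = 11,
                 mcmc = mcmc_control(n_iter = 60000, n_burn = 20000, thin = 10))
  fn <- cjs_corr(m, prior = separated_prior(), seed = 12,
                 mcmc = mcmc_control(n_iter = 60000, n_burn = 20000, thin = 10,
                                     parameterization = "noncentered"))
  for (par in c("rho", "sigma2_ad", "mu_ad", "p")) {
    i <- which(fc$summary$parameter == par)
    se <- sqrt(fc$summary$sd[i]^2 / fc$summary$ess[i] +
                 fn$summary$sd[i]^2 / fn$summary$ess[i])
    expect_lt(abs(fc$summary$mean[i] - fn$summary$mean[i]),
              4 * se + 0.01)
  }
})

test_that("the posterior matches an independent JAGS fit", {
  d <- simulate_cmr(sim_config(T = 6, releases_per_occasion = 250, rho = 0.5),
                    seed = 65)
  m <- build_marrays(d$histories)
  T <- m$T
  code <- "
  model {
    mu[1] ~ dnorm(0, 1)
    mu[2] ~ dnorm(0, 1)
    sig_ad ~ dunif(0, 5)
    sig_juv ~ dunif(0, 5)
    rho ~ dunif(-1, 1)
    Sigma[1,1] <- sig_ad * sig_ad
    Sigma[2,2] <- sig_juv * sig_juv
    Sigma[1,2] <- sig_ad * sig_juv * rho
    Sigma[2,1] <- Sigma[1,2]
    Omega[1:2,1:2] <- inverse(Sigma[,])
    for (t in 1:(T-1)) {
      eta[t,1:2] ~ dmnorm(mu[], Omega[,])
      phi_ad[t] <- ilogit(eta[t,1])
      phi_juv[t] <- ilogit(eta[t,2])
    }
    p ~ dunif(0, 1)
    q <- 1 - p
    for (r in 1:(T-1)) {
      pr_a[r,r] <- phi_ad[r] * p
      pr_j[r,r] <- phi_juv[r] * p
      for (cc in (r+1):(T-1)) {
        pr_a[r,cc] <- phi_ad[r] * prod(phi_ad[(r+1):cc]) * pow(q, cc-r) * p
        pr_j[r,cc] <- phi_juv[r] * prod(phi_ad[(r+1):cc]) * pow(q, cc-r) * p
      }
      for (cc in 1:(r-1)) { pr_a[r,cc] <- 0; pr_j[r,cc] <- 0 }
      pr_a[r,T] <- 1 - sum(pr_a[r,1:(T-1)])
      pr_j[r,T] <- 1 - sum(pr_j[r,1:(T-1)])
      ma[r,1:T] ~ dmulti(pr_a[r,1:T], Ra[r])
      mj[r,1:T] ~ dmulti(pr_j[r,1:T], Rj[r])
    }
  }"
  mod <- rjags::jags.model(
    textConnection(code),
    data = list(T = T, ma = m$ad, mj = m$juv,
                Ra = rowSums(m$ad), Rj = rowSums(m$juv)),
    n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1))
  update(mod, 5000)
  samp <- rjags::coda.samples(mod, c("rho", "sig_ad", "sig_juv"),
                              n.iter = 30000, thin = 5)
  jags_mean <- summary(samp)$statistics[, "Mean"]
  fit <- cjs_corr(m, prior = separated_prior(), seed = 13,
                  mcmc = mcmc_control(n_iter = 80000, n_burn = 20000, thin = 10))
  s <- fit$summary
  for (par in c("rho", "sigma_ad", "sigma_juv")) {
    jname <- c(rho = "rho", sigma_ad = "sig_ad", sigma_juv = "sig_juv")[par]
    i <- which(s$parameter == par)
    mcse <- s$sd[i] * sqrt(1 / s$ess[i] + 1 / 2000)
    expect_lt(abs(s$mean[i] - jags_mean[jname]), 4 * mcse + 0.01)
  }
})

test_that("the fit recovers a strong process correlation from rich data", {
  d <- simulate_cmr(sim_config(T = 30, releases_per_occasion = 5000,
                               rho = 0.8), seed = 66)
  m <- build_marrays(d$histories)
  fit <- cjs_corr(m, prior = separated_prior(), seed = 14)
  expect_true(fit$converged)
  # the data identify the realized correlation of the 29 generated
  # year-effect pairs; the process value 0.8 differs from it by sampling
  # noise of order (1 - rho^2)/sqrt(T - 3), so the estimate is compared to
  # the realized value and only the sign/strength to the process value
  realized <- cor(d$rates$eta_ad, d$rates$eta_juv)
  expect_lt(abs(coef(fit)["rho"] - realized), 0.15)
  expect_gt(unname(coef(fit)["rho"]), 0.5)
  ci <- credible_interval(fit, "rho")
  expect_true(ci[1] >= -1 && ci[2] <= 1 && ci[1] <= ci[2])
})

test_that("non-convergence is flagged, never silently dropped", {
  d <- simulate_cmr(sim_config(T = 5, releases_per_occasion = 60), seed = 67)
  m <- build_marrays(d$histories)
  # absurdly short chains cannot converge reliably; the flag must reflect it
  fit <- cjs_corr(m, prior = iw_prior(), seed = 15,
                  mcmc = mcmc_control(n_iter = 120, n_burn = 20, thin = 1))
  expect_type(fit$converged, "logical")
  expect_true(is.finite(fit$max_rhat))
  s <- summary(fit)
  expect_s3_class(s, "summary.cjs_corr")
})
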