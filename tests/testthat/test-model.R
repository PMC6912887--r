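test_that("empty m-arrays give zero log-likelihood", {
  pars <- random_interior_params(5, seed = 31)
  expect_equal(cjs_loglik(pars, cjscorr:::empty_marrays(5)), 0)
})

test_that("m-array likelihood equals brute-force latent-state enumeration", {
  for (case in 1:4) {
    T <- c(3, 3, 4, 4)[case]
    n <- c(2, 5, 3, 5)[case]
    h <- random_tiny_histories(T, n, seed = 100 + case)
    m <- build_marrays(h)
    pars <- random_interior_params(T, seed = 200 + case)
    expect_equal(cjs_loglik(pars, m),
                 dataset_loglik_oracle(h, plogis(pars$eta_juv),
                                       plogis(pars$eta_ad),
                                       rep(pars$p, T - 1)),
                 tolerance = 1e-10)
    # also for the age/time detection variant (second-year class at the
    # first post-release occasion of juvenile releases)
    pars2 <- random_interior_params(T, seed = 300 + case, detection = "age_time")
    p_sy <- plogis(pars2$beta0 + pars2$eps_p_sy)
    p_ad <- plogis(pars2$beta0 + pars2$eps_p_ad)
    expect_equal(cjs_loglik(pars2, m),
                 dataset_loglik_oracle(h, plogis(pars2$eta_juv),
                                       plogis(pars2$eta_ad), p_ad, p_sy),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to individual ordering", {
  d <- simulate_cmr(sim_config(T = 6, releases_per_occasion = 50), seed = 32)
  h <- d$histories
  set.seed(33)
  perm <- sample.int(nrow(h$y))
  h2 <- make_histories(h$y[perm, ], h$release[perm], h$age[perm])
  pars <- random_interior_params(6, seed = 34)
  expect_identical(cjs_loglik(pars, build_marrays(h)),
                   cjs_loglik(pars, build_marrays(h2)))
})

test_that("a never-seen-only row shifts the log-likelihood by its log mass", {
  h <- random_tiny_histories(4, 4, seed = 35)
  m <- build_marrays(h)
  pars <- random_interior_params(4, seed = 36)
  base <- cjs_loglik(pars, m)
  m2 <- m
  m2$ad[2, 4] <- m2$ad[2, 4] + 7
  pr_never <- marray_cell_probs(2, 4, "adult", plogis(pars$eta_juv),
                                plogis(pars$eta_ad), pars$p)["never"]
  expect_equal(cjs_loglik(pars, m2), base + 7 * log(unname(pr_never)),
               tolerance = 1e-10)
  # dimension mismatch is an error
  expect_error(cjs_loglik(random_interior_params(5, seed = 1), m), "T = ")
})

test_that("inverse Wishart log-density matches an independent evaluation", {
  # closed form at Sigma = I, df = 3, scale = I:
  # -(df K / 2) log 2 - log Gamma_2(df/2) - tr/2 = -2 log 2 - log pi - 1
  ref <- -2 * log(2) - log(pi) - 1
  expect_equal(cjscorr:::diwish2(diag(2), 3, diag(2)), ref, tolerance = 1e-12)
  # and the full prior density agrees between the R and C++ routes
  for (s in 1:5) {
    T <- 6
    pars <- random_interior_params(T, seed = 400 + s)
    for (prior in list(iw_prior(), separated_prior(),
                       separated_prior(sigma_dist = "halfnormal"))) {
      lp_r <- cjs_logprior(pars, prior)
      th <- par_pack(pars, prior)
      cfg <- cjscorr:::model_cfg(T, prior)
      cpp <- cjscorr:::.logpost_cpp(th, cfg, cjscorr:::empty_marrays(T)$juv,
                                    cjscorr:::empty_marrays(T)$ad, FALSE)
      lj <- attr(par_unpack(th, T, prior), "log_jacobian")
      expect_equal(lp_r, unname(cpp["logprior"]) - lj, tolerance = 1e-8)
    }
  }
})

test_that("separated prior support and flatness behave as specified", {
  pars <- random_interior_params(5, seed = 41)
  pars$sigma_ad <- 6  # above the Uniform(0, 5) upper bound
  expect_identical(cjs_logprior(pars, separated_prior()), -Inf)
  # changing rho (sigma and year effects fixed) moves the log prior only
  # through the MVN year-effect term
  p1 <- random_interior_params(5, seed = 42)
  p2 <- p1
  p1$rho <- 0.2
  p2$rho <- 0.6
  mvn <- function(p) {
    r2 <- 1 - p$rho^2
    x1 <- (p$eta_ad - p$mu_ad) / p$sigma_ad
    x2 <- (p$eta_juv - p$mu_juv) / p$sigma_juv
    -length(x1) * 0.5 * log(r2) -
      sum(x1^2 - 2 * p$rho * x1 * x2 + x2^2) / (2 * r2)
  }
  expect_equal(cjs_logprior(p2, separated_prior()) -
                 cjs_logprior(p1, separated_prior()),
               mvn(p2) - mvn(p1), tolerance = 1e-10)
})

test_that("constrained/unconstrained transforms round-trip", {
  expect_equal(par_unpack(par_pack(random_interior_params(4, seed = 50),
                                   separated_prior()), 4,
                          separated_prior())$rho,
               random_interior_params(4, seed = 50)$rho, tolerance = 1e-10)
  for (s in 1:10) {
    T <- sample(3:8, 1)
    for (prior in list(iw_prior(), separated_prior())) {
      pars <- random_interior_params(T, seed = 500 + s)
      back <- par_unpack(par_pack(pars, prior), T, prior)
      for (f in c("mu_ad", "mu_juv", "sigma_ad", "sigma_juv", "rho",
                  "eta_ad", "eta_juv", "p")) {
        expect_equal(back[[f]], pars[[f]], tolerance = 1e-10)
      }
    }
    pars2 <- random_interior_params(T, seed = 600 + s, detection = "age_time")
    back2 <- par_unpack(par_pack(pars2, iw_prior()), T, iw_prior(),
                        detection = "age_time")
    for (f in c("beta0", "sigma_p_sy", "sigma_p_ad", "eps_p_sy", "eps_p_ad")) {
      expect_equal(back2[[f]], pars2[[f]], tolerance = 1e-10)
    }
  }
  # boundary values are rejected for initialization
  bad <- random_interior_params(4, seed = 51)
  bad$rho <- 1
  expect_error(par_pack(bad, iw_prior()), "boundary")
  bad2 <- random_interior_params(4, seed = 52)
  bad2$p <- 1
  expect_error(par_pack(bad2, separated_prior()), "boundary")
})
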