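test_that("annual rates reduce to the design means when variance vanishes", {
  cfg <- sim_config(T = 6, sigma2_ad = 0, sigma2_juv = 0)
  r <- draw_annual_rates(cfg, seed = 1)
  expect_equal(r$phi_ad, rep(plogis(1), 5), tolerance = 1e-12)   # 0.731
  expect_equal(r$phi_juv, rep(plogis(-1), 5), tolerance = 1e-12) # 0.269
  expect_equal(plogis(r$eta_ad), r$phi_ad, tolerance = 1e-12)
})

test_that("perfect correlation aligns the standardized year effects", {
  cfg <- sim_config(T = 10, rho = 1, sigma2_ad = 0.1, sigma2_juv = 0.1)
  r <- draw_annual_rates(cfg, seed = 2)
  expect_equal(r$eta_ad - 1, r$eta_juv - (-1), tolerance = 1e-12)
})

test_that("latent states follow the survival process", {
  cfg <- sim_config(T = 5, releases_per_occasion = 40)
  certain <- list(phi_ad = rep(1, 4), phi_juv = rep(1, 4))
  z1 <- simulate_latent_states(certain, cfg, seed = 3)
  expect_true(all(z1$z[, 5] == 1))
  doomed <- list(phi_ad = rep(0, 4), phi_juv = rep(0, 4))
  z0 <- simulate_latent_states(doomed, cfg, seed = 3)
  post <- outer(z0$release, 1:5, `<`)
  expect_true(all(z0$z[post] == 0))
  # death is absorbing
  d <- simulate_cmr(sim_config(T = 8, releases_per_occasion = 100), seed = 4)
  z <- d$histories$z
  revived <- apply(z, 1, function(v) any(diff(v[which(v == 1)[1]:8]) > 0))
  expect_false(any(revived, na.rm = TRUE))
})

test_that("one-interval survival frequencies obey the binomial law", {
  cfg <- sim_config(T = 2, releases_per_occasion = 1e5, juvenile_fraction = 0,
                    sigma2_ad = 0, sigma2_juv = 0)
  st <- simulate_latent_states(draw_annual_rates(cfg, seed = 5), cfg, seed = 5)
  phi <- plogis(1)
  se <- sqrt(phi * (1 - phi) / 1e5)
  first_cohort <- st$release == 1  # occasion-2 releases are alive by construction
  expect_lt(abs(mean(st$z[first_cohort, 2]) - phi), 3 * se)
})

test_that("detections are Bernoulli thinnings of the latent states", {
  cfg <- sim_config(T = 6, releases_per_occasion = 200)
  st <- simulate_latent_states(draw_annual_rates(cfg, seed = 6), cfg, seed = 6)
  h1 <- simulate_detections(st, p = 1, seed = 7)
  post <- outer(st$release, 1:6, `<=`)
  expect_equal(h1$y[post], st$z[post])
  h0 <- simulate_detections(st, p = 0, seed = 7)
  strictly_post <- outer(st$release, 1:6, `<`)
  expect_true(all(h0$y[strictly_post] == 0))
  expect_true(all(h0$y[cbind(seq_along(st$release), st$release)] == 1))
  # detected fraction of known-alive occasions ~ p
  big <- sim_config(T = 2, releases_per_occasion = 1e5, sigma2_ad = 0,
                    sigma2_juv = 0, mu_ad = 20, mu_juv = 20)  # all survive
  stb <- simulate_latent_states(draw_annual_rates(big, seed = 8), big, seed = 8)
  hb <- simulate_detections(stb, p = 0.5, seed = 9)
  first_cohort <- stb$release == 1  # all alive at occasion 2 (mu = 20)
  expect_lt(abs(mean(hb$y[first_cohort, 2]) - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("simulated datasets are reproducible and structurally sound", {
  cfg <- sim_config(T = 10, releases_per_occasion = 100)
  d1 <- simulate_cmr(cfg, seed = 10)
  d2 <- simulate_cmr(cfg, seed = 10)
  expect_identical(d1$histories$y, d2$histories$y)
  expect_identical(d1$rates$eta_ad, d2$rates$eta_ad)
  expect_false(identical(d1$histories$y, simulate_cmr(cfg, seed = 11)$histories$y))
  expect_equal(nrow(d1$histories$y), 10 * 100)
  # no detections before release; detections imply alive
  pre <- outer(d1$histories$release, 1:10, `>`)
  expect_true(all(d1$histories$y[pre] == 0))
  expect_true(all(d1$histories$y <= d1$histories$z))
})

test_that("m-array cell frequencies match the analytic multinomial", {
  # constant survival, T = 3: every cell probability is in closed form
  cfg <- sim_config(T = 3, releases_per_occasion = 5000, sigma2_ad = 0,
                    sigma2_juv = 0)
  d <- simulate_cmr(cfg, seed = 12)
  m <- build_marrays(d$histories)
  for (age in c("juvenile", "adult")) {
    arr <- if (age == "juvenile") m$juv else m$ad
    for (r in 1:2) {
      n_r <- sum(arr[r, ])
      if (n_r == 0) next
      pr <- marray_cell_probs(r, 3, age, plogis(-1), plogis(1), 0.5)
      for (j in seq_along(pr)) {
        se <- sqrt(pr[j] * (1 - pr[j]) * n_r)
        expect_lt(abs(arr[r, j] - n_r * pr[j]), 3 * se + 1e-9)
      }
    }
  }
})
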