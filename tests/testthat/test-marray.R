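test_that("hand-built histories reduce to the expected m-arrays", {
  # one adult released at occasion 1, never seen again (T = 3)
  h <- make_histories(matrix(c(1L, 0L, 0L), 1, 3), 1, "adult")
  m <- build_marrays(h)
  expect_equal(unname(m$ad[1, ]), c(0, 0, 1))
  expect_true(all(m$juv == 0))
  # one juvenile released at 1, seen at 2 and 3: the re-encounter at 2
  # re-enters as an adult release
  h2 <- make_histories(matrix(c(1L, 1L, 1L), 1, 3), 1, "juvenile")
  m2 <- build_marrays(h2)
  expect_equal(unname(m2$juv[1, ]), c(1, 0, 0))
  expect_equal(unname(m2$ad[2, ]), c(0, 1, 0))
  expect_equal(sum(m2$juv) + sum(m2$ad), 2)
})

test_that("m-array bookkeeping conserves releases and re-encounters", {
  d <- simulate_cmr(sim_config(T = 8, releases_per_occasion = 120), seed = 21)
  h <- d$histories
  m <- build_marrays(h)
  # each juvenile row holds exactly the juveniles newly released there
  n_juv_rel <- tabulate(h$release[h$age == "juvenile"], nbins = 8)
  expect_equal(unname(rowSums(m$juv)), n_juv_rel[1:7])
  # total re-encounter events: one per (release, next re-encounter) pair
  pairs <- sum(pmax(rowSums(h$y) - 1, 0))
  expect_equal(sum(m$juv[, 1:7]) + sum(m$ad[, 1:7]), pairs)
  # adult row totals = new adult releases + re-encounters arriving there
  arrivals <- colSums(m$juv[, 1:7]) + colSums(m$ad[, 1:7])  # at occasions 2..8
  n_ad_rel <- tabulate(h$release[h$age == "adult"], nbins = 8)
  expect_equal(unname(rowSums(m$ad)), unname(n_ad_rel[1:7] + c(0, arrivals[1:6])))
})

test_that("malformed histories are rejected with their row index", {
  y <- matrix(c(0L, 1L, 1L,
                1L, 0L, 0L), 2, 3, byrow = TRUE)
  h <- make_histories(y, c(2, 1), c("adult", "adult"))
  h$y[1, 1] <- 1L  # detection before release
  h$release[1] <- 2L
  expect_error(build_marrays(h), "1")
})

test_that("cell probabilities enumerate the latent paths", {
  pr <- marray_cell_probs(1, 3, "adult", 0.5, 0.5, 0.5)
  expect_equal(unname(pr), c(0.25, 0.0625, 0.6875), tolerance = 1e-12)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # certain survival and detection: re-encountered immediately
  pr1 <- marray_cell_probs(2, 5, "adult", 1, 1, 1)
  expect_equal(unname(pr1["occ3"]), 1)
  # juvenile and adult rows differ only through the first interval
  prj <- marray_cell_probs(1, 6, "juvenile", 0.3, 0.7, 0.4)
  pra <- marray_cell_probs(1, 6, "adult", 0.3, 0.7, 0.4)
  expect_equal(unname(prj[1:5] / pra[1:5]), rep(0.3 / 0.7, 5), tolerance = 1e-12)
})

test_that("cell probability rows always sum to one", {
  set.seed(22)
  for (i in 1:25) {
    T <- sample(3:12, 1)
    phi_j <- runif(T - 1, 0.05, 0.95)
    phi_a <- runif(T - 1, 0.05, 0.95)
    p <- runif(T - 1, 0.05, 0.95)
    r <- sample.int(T - 1, 1)
    age <- sample(c("juvenile", "adult"), 1)
    pr <- marray_cell_probs(r, T, age, phi_j, phi_a, p)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
  expect_error(marray_cell_probs(1, 4, "adult", 0, 0.5, 0.5), "survival")
  expect_error(marray_cell_probs(1, 4, "adult", 0.5, 0.5, 1.5), "detection")
})

test_that("cell probabilities match the enumeration oracle per column", {
  # P(first re-encounter at c) = sum of history probabilities over all
  # histories whose first post-release detection is at c
  T <- 4
  phi_j <- c(0.3, 0.4, 0.5)
  phi_a <- c(0.7, 0.6, 0.8)
  p <- 0.45
  for (age in c("juvenile", "adult")) {
    pr <- marray_cell_probs(1, T, age, phi_j, phi_a, p)
    for (cc in 2:T) {
      # any continuation after the first re-encounter integrates to 1, so the
      # probability of "first seen at cc" is the marginal over histories with
      # y = 0 strictly between release and cc, marginalized by truncating at cc
      yy <- integer(cc)
      yy[1] <- 1L
      yy[cc] <- 1L
      expect_equal(unname(pr[cc - 1]),
                   history_prob_oracle(yy, 1, age, phi_j[seq_len(cc - 1)],
                                       phi_a[seq_len(cc - 1)],
                                       rep(p, cc - 1)),
                   tolerance = 1e-12)
    }
  }
})
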