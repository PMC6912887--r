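# Independent oracles used across the test files. These deliberately avoid
# the package's likelihood code paths: probabilities are obtained by explicit
# enumeration of the latent alive/dead process.

# Marginal probability of one encounter history by brute-force enumeration
# over the death occasion (the latent state is monotone: alive from release
# until death, dead afterwards). `p_sy`/`p_ad` are detection probabilities
# indexed by occasion 2..T (position t-1); a juvenile release is in the
# second-year detection class at its first post-release occasion.
history_prob_oracle <- function(y, tau, age, phi_juv, phi_ad, p_ad,
                                p_sy = p_ad) {
  T <- length(y)
  phi_at <- function(t) if (age == "juvenile" && t == tau) phi_juv[t] else phi_ad[t]
  p_at <- function(t) if (age == "juvenile" && t == tau + 1) p_sy[t - 1] else p_ad[t - 1]
  total <- 0
  for (k in tau:T) {  # k = last occasion alive
    pr <- 1
    if (k > tau) for (t in tau:(k - 1)) pr <- pr * phi_at(t)
    if (k < T) pr <- pr * (1 - phi_at(k))
    ok <- TRUE
    if (tau < T) {
      for (t in (tau + 1):T) {
        if (t <= k) {
          pr <- pr * (if (y[t] == 1) p_at(t) else 1 - p_at(t))
        } else if (y[t] == 1) {
          ok <- FALSE
        }
      }
    }
    if (ok) total <- total + pr
  }
  total
}

# Build an encounter_histories object from explicit rows.
make_histories <- function(y, release, age) {
  structure(list(y = y, release = as.integer(release), age = age,
                 T = ncol(y)),
            class = "encounter_histories")
}

# Sum of log history probabilities for a whole dataset (enumeration route).
dataset_loglik_oracle <- function(h, phi_juv, phi_ad, p_ad, p_sy = p_ad) {
  T <- h$T
  ll <- 0
  for (i in seq_len(nrow(h$y))) {
    if (h$release[i] >= T) next  # terminal releases carry no information
    ll <- ll + log(history_prob_oracle(h$y[i, ], h$release[i], h$age[i],
                                       phi_juv, phi_ad, p_ad, p_sy))
  }
  ll
}

# Random small dataset for likelihood-identity checks.
random_tiny_histories <- function(T, n, seed) {
  set.seed(seed)
  repeat {
    release <- sample.int(T - 1, n, replace = TRUE)
    age <- sample(c("juvenile", "adult"), n, replace = TRUE)
    y <- matrix(0L, n, T)
    for (i in seq_len(n)) {
      y[i, release[i]] <- 1L
      later <- seq_len(T)[seq_len(T) > release[i]]
      if (length(later)) y[i, later] <- rbinom(length(later), 1L, 0.5)
    }
    h <- make_histories(y, release, age)
    # need at least one re-encounter so the dataset is not degenerate
    if (sum(y) > n) return(h)
  }
}

random_interior_params <- function(T, seed, detection = "constant") {
  set.seed(seed)
  ny <- T - 1
  if (detection == "constant") {
    cjs_params(rnorm(1), rnorm(1), runif(1, 0.1, 2), runif(1, 0.1, 2),
               runif(1, -0.9, 0.9), rnorm(ny, 1, 0.5), rnorm(ny, -1, 0.5),
               p = runif(1, 0.2, 0.8))
  } else {
    cjs_params(rnorm(1), rnorm(1), runif(1, 0.1, 2), runif(1, 0.1, 2),
               runif(1, -0.9, 0.9), rnorm(ny, 1, 0.5), rnorm(ny, -1, 0.5),
               beta0 = rnorm(1), sigma_p_sy = runif(1, 0.1, 2),
               sigma_p_ad = runif(1, 0.1, 2),
               eps_p_sy = rnorm(ny, 0, 0.3), eps_p_ad = rnorm(ny, 0, 0.3))
  }
}
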