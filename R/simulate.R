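#' Simulation design for age-structured capture-mark-recapture data
#'
#' Holds the generative design used throughout the simulation experiments:
#' mean adult logit survival 1 (survival ~0.73) and mean juvenile logit
#' survival -1 (survival ~0.27), temporal variances 0.1 on the logit scale
#' for both age classes, a process correlation `rho`, a constant detection
#' probability of 0.5, and cohorts of newly marked individuals released at
#' every occasion, split evenly between age classes.
#'
#' @param T Number of release occasions (>= 2).
#' @param releases_per_occasion Newly marked individuals released at each
#'   occasion (>= 1).
#' @param mu_ad,mu_juv Means of adult and juvenile logit-scale survival.
#' @param sigma2_ad,sigma2_juv Temporal variances of the logit-scale year
#'   effects (>= 0; 0 gives constant survival).
#' @param rho Process correlation in \eqn{[-1, 1]}.
#' @param juvenile_fraction Fraction of each release cohort marked as
#'   juveniles (default 0.5).
#' @param p Detection probability in (0, 1).
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(T = 5, releases_per_occasion = 20)
#' d <- simulate_cmr(cfg, seed = 1)
#' @export
sim_config <- function(T = 10, releases_per_occasion = 100,
                       mu_ad = 1, mu_juv = -1,
                       sigma2_ad = 0.1, sigma2_juv = 0.1, rho = 0,
                       juvenile_fraction = 0.5, p = 0.5) {
  if (!(is.numeric(T) && length(T) == 1L && T >= 2)) {
    stop("invalid `T`: need T >= 2", call. = FALSE)
  }
  if (!(releases_per_occasion >= 1)) {
    stop("invalid `releases_per_occasion`: need >= 1", call. = FALSE)
  }
  if (!(sigma2_ad >= 0 && sigma2_juv >= 0)) {
    stop("invalid variance: sigma2 must be >= 0", call. = FALSE)
  }
  if (!(abs(rho) <= 1)) stop("invalid `rho`: must be in [-1, 1]", call. = FALSE)
  if (!(p > 0 && p < 1)) stop("invalid `p`: must be in (0, 1)", call. = FALSE)
  if (!(juvenile_fraction >= 0 && juvenile_fraction <= 1)) {
    stop("invalid `juvenile_fraction`: must be in [0, 1]", call. = FALSE)
  }
  structure(list(T = as.integer(T),
                 releases_per_occasion = as.integer(releases_per_occasion),
                 mu_ad = mu_ad, mu_juv = mu_juv,
                 sigma2_ad = sigma2_ad, sigma2_juv = sigma2_juv, rho = rho,
                 juvenile_fraction = juvenile_fraction, p = p),
            class = "sim_config")
}

#' Draw correlated annual survival probabilities
#'
#' Draws the T-1 interval-specific survival pairs from the bivariate normal
#' year-effect model: \eqn{(\mathrm{logit}\,\phi_{ad,t},
#' \mathrm{logit}\,\phi_{juv,t}) \sim N(\mu, \Sigma)}. The draw is generated
#' through the Cholesky construction
#' \eqn{\eta_{juv} = \mu_{juv} + \sigma_{juv}(\rho z_1 + \sqrt{1-\rho^2} z_2)},
#' which degrades gracefully to the rank-1 case at \eqn{|\rho| = 1} and to
#' constant survival at \eqn{\sigma = 0}.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return An object of class `annual_rates`: list with `phi_ad`, `phi_juv`
#'   (probability scale, length T-1), the logit-scale draws `eta_ad`,
#'   `eta_juv`, and the generating `rho`.
#' @export
draw_annual_rates <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ny <- cfg$T - 1L
  z1 <- rnorm(ny)
  z2 <- rnorm(ny)
  s1 <- sqrt(cfg$sigma2_ad)
  s2 <- sqrt(cfg$sigma2_juv)
  eta_ad <- cfg$mu_ad + s1 * z1
  eta_juv <- cfg$mu_juv + s2 * (cfg$rho * z1 + sqrt(max(0, 1 - cfg$rho^2)) * z2)
  structure(list(phi_ad = plogis(eta_ad), phi_juv = plogis(eta_juv),
                 eta_ad = eta_ad, eta_juv = eta_juv, rho = cfg$rho),
            class = "annual_rates")
}

# Release schedule implied by a sim_config: one row per individual.
release_schedule <- function(cfg) {
  n_juv <- round(cfg$releases_per_occasion * cfg$juvenile_fraction)
  n_ad <- cfg$releases_per_occasion - n_juv
  release <- rep(seq_len(cfg$T), each = cfg$releases_per_occasion)
  age <- rep(rep(c("juvenile", "adult"), times = c(n_juv, n_ad)), times = cfg$T)
  list(release = release, age = age)
}

#' Simulate latent alive/dead states
#'
#' Conditional on release, each individual survives interval t (occasion t to
#' t+1) as a Bernoulli trial with the juvenile rate for its first interval if
#' released as a juvenile, and the adult rate thereafter (juveniles recruit to
#' the adult class after surviving one interval). Death is absorbing.
#'
#' @param rates An [draw_annual_rates()] result (or any list with `phi_ad`,
#'   `phi_juv` of length T-1).
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return List with integer matrix `z` (individuals x occasions; 1 = alive,
#'   0 before release or after death), `release`, and `age`.
#' @export
simulate_latent_states <- function(rates, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sched <- release_schedule(cfg)
  n <- length(sched$release)
  T <- cfg$T
  z <- matrix(0L, n, T)
  z[cbind(seq_len(n), sched$release)] <- 1L
  juv <- sched$age == "juvenile"
  for (t in seq_len(T - 1L)) {
    alive <- z[, t] == 1L
    phi <- ifelse(juv & sched$release == t, rates$phi_juv[t], rates$phi_ad[t])
    surv <- rbinom(n, 1L, phi)
    z[, t + 1L] <- pmax(as.integer(alive) * surv, z[, t + 1L])
  }
  list(z = z, release = sched$release, age = sched$age)
}

#' Simulate detections conditional on latent states
#'
#' The release occasion is an encounter by construction; at every later
#' occasion an alive individual is detected as a Bernoulli(p) trial and a dead
#' (or not-yet-released) individual is never detected.
#'
#' @param states Result of [simulate_latent_states()].
#' @param p Detection probability.
#' @param seed Optional integer seed.
#' @return An object of class `encounter_histories`: list with 0/1 matrix `y`
#'   (individuals x occasions), `release`, `age`, and `T`.
#' @export
simulate_detections <- function(states, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- states$z
  n <- nrow(z)
  T <- ncol(z)
  post <- outer(states$release, seq_len(T), `<`)  # strictly after release
  y <- matrix(rbinom(n * T, 1L, p), n, T) * z * post
  y[cbind(seq_len(n), states$release)] <- 1L
  structure(list(y = y, release = states$release, age = states$age, T = T,
                 z = z),
            class = "encounter_histories")
}

#' Simulate a complete capture-mark-recapture dataset
#'
#' Composition of [draw_annual_rates()], [simulate_latent_states()] and
#' [simulate_detections()]; fully reproducible from `(cfg, seed)`.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (drives all three stages through one
#'   RNG stream).
#' @return List of class `cmr_data` with elements `histories`
#'   (an `encounter_histories`) and `rates` (the generating `annual_rates`).
#' @export
simulate_cmr <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rates <- draw_annual_rates(cfg)
  states <- simulate_latent_states(rates, cfg)
  hist <- simulate_detections(states, cfg$p)
  structure(list(histories = hist, rates = rates, config = cfg),
            class = "cmr_data")
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat(sprintf("encounter_histories: %d individuals, %d occasions (%d juvenile, %d adult releases)\n",
              nrow(x$y), x$T, sum(x$age == "juvenile"), sum(x$age == "adult")))
  invisible(x)
}

#' @export
print.cmr_data <- function(x, ...) {
  print(x$histories)
  cat(sprintf("generating rho = %.3f\n", x$rates$rho))
  invisible(x)
}
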