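#' Replicated simulation experiment for process-correlation estimation
#'
#' Runs one cell of the factorial design: `V` replicate datasets at a given
#' number of occasions and releases per occasion, each with its own process
#' correlation drawn from Uniform(-1, 1), fitted under one or both covariance
#' priors, and scored against the generating truth. Per-replicate seeds are
#' derived deterministically from the master seed (a multiplicative-counter
#' scheme), so cells are reproducible and can be run independently; the data
#' seed for a replicate does not depend on the prior, so both priors see the
#' same dataset. Completed replicates can be checkpointed to CSV and are
#' skipped on restart.
#'
#' @param T Number of occasions.
#' @param releases Newly marked individuals per occasion.
#' @param priors Character vector, subset of `c("iw", "separated")`.
#' @param V Number of replicates (>= 1).
#' @param seed Master seed.
#' @param mcmc An [mcmc_control()].
#' @param juvenile_fraction Cohort split (default 0.5).
#' @param checkpoint_dir Optional directory for per-replicate resumable
#'   checkpoints.
#' @param verbose Print one line per replicate.
#' @return Data frame of class `study_result` with one row per
#'   (replicate, prior): `T`, `releases`, `prior`, `replicate`, `seed`,
#'   `rho_true`, `rho_mean`, `rho_lo`, `rho_hi`, `covered`, `max_rhat`,
#'   `converged`.
#' @examples
#' \donttest{
#' res <- run_cell(10, 100, priors = "separated", V = 2, seed = 1,
#'                 mcmc = mcmc_control(n_iter = 2000, n_burn = 1000))
#' coverage_table(res)
#' }
#' @export
run_cell <- function(T, releases, priors = c("iw", "separated"), V, seed,
                     mcmc = mcmc_control(), juvenile_fraction = 0.5,
                     checkpoint_dir = NULL, verbose = FALSE) {
  priors <- match.arg(priors, c("iw", "separated"), several.ok = TRUE)
  stopifnot(V >= 1)
  rows <- list()
  for (v in seq_len(V)) {
    data_seed <- derive_seed(seed, T, releases, v, 0L)
    set.seed(data_seed)
    rho_true <- runif(1, -1, 1)
    cfg <- sim_config(T = T, releases_per_occasion = releases, rho = rho_true,
                      juvenile_fraction = juvenile_fraction)
    dat <- simulate_cmr(cfg)
    marr <- build_marrays(dat$histories)
    for (pr in priors) {
      ck <- if (!is.null(checkpoint_dir)) {
        file.path(checkpoint_dir, sprintf("cell_T%d_n%d_%s_rep%03d.csv",
                                          T, releases, pr, v))
      }
      if (!is.null(ck) && file.exists(ck)) {
        rows[[length(rows) + 1L]] <- read.csv(ck)
        next
      }
      fit_seed <- derive_seed(seed, T, releases, v, if (pr == "iw") 1L else 2L)
      prior <- if (pr == "iw") iw_prior() else separated_prior()
      row <- tryCatch({
        fit <- cjs_corr(marr, prior = prior, mcmc = mcmc, seed = fit_seed)
        ci <- credible_interval(fit, "rho", 0.95)
        data.frame(T = T, releases = releases, prior = pr, replicate = v,
                   seed = fit_seed, rho_true = rho_true,
                   rho_mean = unname(coef(fit)["rho"]),
                   rho_lo = ci[1], rho_hi = ci[2],
                   covered = rho_true >= ci[1] & rho_true <= ci[2],
                   max_rhat = fit$max_rhat, converged = fit$converged,
                   failed = FALSE)
      }, error = function(e) {
        data.frame(T = T, releases = releases, prior = pr, replicate = v,
                   seed = fit_seed, rho_true = rho_true,
                   rho_mean = NA_real_, rho_lo = NA_real_, rho_hi = NA_real_,
                   covered = NA, max_rhat = NA_real_, converged = FALSE,
                   failed = TRUE)
      })
      if (!is.null(ck)) {
        dir.create(dirname(ck), showWarnings = FALSE, recursive = TRUE)
        write.csv(row, ck, row.names = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
      if (verbose) {
        message(sprintf("T=%d n=%d %s rep %d/%d: rho %.2f -> %.2f [%.2f, %.2f]",
                        T, releases, pr, v, V, rho_true, row$rho_mean,
                        row$rho_lo, row$rho_hi))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_result", "data.frame")
  out
}

#' Run the full factorial simulation study
#'
#' All combinations of `occasions` and `releases` for each requested prior
#' (the headline design is 3 occasion levels x 3 release levels x 2 priors
#' with 1000 replicates per cell; `V = 100` is the desk-scale default).
#'
#' @param occasions,releases Design levels (defaults `c(10, 20, 30)` and
#'   `c(100, 1000, 5000)`).
#' @inheritParams run_cell
#' @return A `study_result` data frame covering all cells.
#' @export
run_study <- function(occasions = c(10, 20, 30),
                      releases = c(100, 1000, 5000),
                      priors = c("iw", "separated"), V = 100, seed = 1,
                      mcmc = mcmc_control(), checkpoint_dir = NULL,
                      verbose = FALSE) {
  out <- list()
  for (T in occasions) {
    for (n in releases) {
      out[[length(out) + 1L]] <- run_cell(T, n, priors = priors, V = V,
                                          seed = seed, mcmc = mcmc,
                                          checkpoint_dir = checkpoint_dir,
                                          verbose = verbose)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("study_result", "data.frame")
  res
}

# Deterministic per-replicate seeds below 2^31, collision-free within a study.
derive_seed <- function(master, T, releases, rep, stream) {
  m <- 2147483647
  s <- master %% m
  for (k in c(T, releases, rep, stream)) {
    s <- (s * 69069 + k + 1) %% m
  }
  as.integer(s) + 1L
}

scored <- function(results) {
  results[!results$failed & results$converged, , drop = FALSE]
}

agg_cells <- function(results, f, value_name) {
  use <- scored(results)
  if (nrow(use) == 0L) stop("no scored replicates", call. = FALSE)
  key <- interaction(use$prior, use$T, use$releases, drop = TRUE)
  agg <- do.call(rbind, lapply(split(use, key), function(d) {
    data.frame(prior = d$prior[1], T = d$T[1], releases = d$releases[1],
               value = f(d), n_replicates = nrow(d))
  }))
  names(agg)[names(agg) == "value"] <- value_name
  excl <- results[results$failed | !results$converged, ]
  attr(agg, "excluded") <- nrow(excl)
  rownames(agg) <- NULL
  agg
}

reshape_cells <- function(agg, value_name) {
  out <- list()
  for (pr in unique(agg$prior)) {
    d <- agg[agg$prior == pr, ]
    Ts <- sort(unique(d$T))
    ns <- sort(unique(d$releases))
    m <- matrix(NA_real_, length(ns), length(Ts),
                dimnames = list(releases = ns, occasions = Ts))
    for (i in seq_len(nrow(d))) {
      m[as.character(d$releases[i]), as.character(d$T[i])] <- d[[value_name]][i]
    }
    out[[pr]] <- m
  }
  out
}

#' Bias and coverage tables from study results
#'
#' `abs_error_table()` reports, per (prior, occasions, releases) cell, the
#' mean over replicates of the absolute difference between the generating
#' process correlation and the posterior mean. `coverage_table()` reports the
#' fraction of replicates whose 95% credible interval contains the
#' generating value. Only converged, non-failed replicates enter the
#' aggregates; the number excluded is attached as attribute `"excluded"`.
#'
#' @param results A `study_result` data frame.
#' @param wide If `TRUE` (default) return a list of releases x occasions
#'   matrices, one per prior (the layout of the published tables); otherwise
#'   a tidy data frame.
#' @return See `wide`.
#' @export
abs_error_table <- function(results, wide = TRUE) {
  agg <- agg_cells(results, function(d) mean(abs(d$rho_true - d$rho_mean)),
                   "abs_error")
  if (!wide) return(agg)
  out <- reshape_cells(agg, "abs_error")
  attr(out, "excluded") <- attr(agg, "excluded")
  out
}

#' @rdname abs_error_table
#' @export
coverage_table <- function(results, wide = TRUE) {
  agg <- agg_cells(results, function(d) mean(d$covered), "coverage")
  if (!wide) return(agg)
  out <- reshape_cells(agg, "coverage")
  attr(out, "excluded") <- attr(agg, "excluded")
  out
}

#' Per-replicate truth-versus-estimate scatter data
#'
#' One row per scored replicate with the generating and estimated process
#' correlation, suitable for plotting against the 1:1 line (the inverse
#' Wishart prior shows attenuation: a fitted slope of estimate on truth
#' below 1).
#'
#' @param results A `study_result` data frame.
#' @return Data frame with columns `rho_true`, `rho_mean`, `prior`, `T`,
#'   `releases` (empty input gives an empty data frame).
#' @export
scatter_data <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    return(data.frame(rho_true = numeric(), rho_mean = numeric(),
                      prior = character(), T = integer(),
                      releases = integer()))
  }
  use <- scored(results)
  data.frame(rho_true = use$rho_true, rho_mean = use$rho_mean,
             prior = use$prior, T = use$T, releases = use$releases)
}
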