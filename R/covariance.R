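#' Covariance specification for bivariate year effects
#'
#' A `cov_spec` bundles the standard deviations of adult and juvenile
#' logit-scale annual survival effects together with their process
#' correlation, and induces the 2x2 covariance matrix
#' \deqn{\Sigma = \begin{pmatrix} \sigma_{ad}^2 & \sigma_{ad}\sigma_{juv}\rho \\
#'   \sigma_{ad}\sigma_{juv}\rho & \sigma_{juv}^2 \end{pmatrix}.}
#'
#' @param sigma_ad Standard deviation of adult logit-survival year effects
#'   (logit units, > 0).
#' @param sigma_juv Standard deviation of juvenile logit-survival year
#'   effects (> 0).
#' @param rho Process correlation between the two year effects, in
#'   \eqn{[-1, 1]}.
#' @return An object of class `cov_spec`.
#' @examples
#' s <- cov_spec(sqrt(0.1), sqrt(0.1), 0.5)
#' build_covariance(s)
#' @export
cov_spec <- function(sigma_ad, sigma_juv, rho) {
  if (!is.numeric(sigma_ad) || length(sigma_ad) != 1L || !is.finite(sigma_ad) ||
      sigma_ad <= 0) {
    stop("invalid `sigma_ad`: must be a single finite value > 0", call. = FALSE)
  }
  if (!is.numeric(sigma_juv) || length(sigma_juv) != 1L || !is.finite(sigma_juv) ||
      sigma_juv <= 0) {
    stop("invalid `sigma_juv`: must be a single finite value > 0", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) > 1) {
    stop("invalid `rho`: must be a single value in [-1, 1]", call. = FALSE)
  }
  structure(list(sigma_ad = sigma_ad, sigma_juv = sigma_juv, rho = rho),
            class = "cov_spec")
}

#' @export
print.cov_spec <- function(x, ...) {
  cat(sprintf("cov_spec: sigma_ad = %.4g, sigma_juv = %.4g, rho = %.4g\n",
              x$sigma_ad, x$sigma_juv, x$rho))
  invisible(x)
}

#' Build the 2x2 covariance matrix from a `cov_spec`
#'
#' @param spec A [cov_spec()].
#' @return A symmetric 2x2 matrix with rows/columns `c("ad", "juv")`.
#' @export
build_covariance <- function(spec) {
  if (!inherits(spec, "cov_spec")) {
    spec <- do.call(cov_spec, as.list(spec)[c("sigma_ad", "sigma_juv", "rho")])
  }
  off <- spec$sigma_ad * spec$sigma_juv * spec$rho
  matrix(c(spec$sigma_ad^2, off, off, spec$sigma_juv^2), 2L, 2L,
         dimnames = list(c("ad", "juv"), c("ad", "juv")))
}

#' Decompose a 2x2 covariance matrix into a `cov_spec`
#'
#' Inverse of [build_covariance()]: \eqn{\sigma_k = \sqrt{\Sigma_{kk}}},
#' \eqn{\rho = \Sigma_{12} / (\sigma_1 \sigma_2)}.
#'
#' @param Sigma A symmetric positive semi-definite 2x2 matrix.
#' @return A [cov_spec()].
#' @export
cov_from_matrix <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  if (!all(dim(Sigma) == c(2L, 2L))) stop("`Sigma` must be 2x2", call. = FALSE)
  if (abs(Sigma[1, 2] - Sigma[2, 1]) > 1e-8 * (1 + abs(Sigma[1, 2]))) {
    stop("`Sigma` must be symmetric", call. = FALSE)
  }
  s1 <- sqrt(Sigma[1, 1])
  s2 <- sqrt(Sigma[2, 2])
  cov_spec(s1, s2, Sigma[1, 2] / (s1 * s2))
}
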