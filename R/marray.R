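#' Reduce encounter histories to age-structured m-arrays
#'
#' Builds the juvenile and adult m-arrays that support the marginalized
#' multinomial CJS likelihood. Row r of each array counts individuals
#' released (or re-released) at occasion r; column c counts those first
#' re-encountered at occasion c (c > r), and the final column those never
#' re-encountered. Every re-encounter of a surviving animal re-enters the
#' bookkeeping as a new adult release, so the juvenile array holds only
#' first-interval releases of animals marked as juveniles.
#'
#' @param histories An `encounter_histories` object (see [simulate_cmr()]),
#'   or any list with 0/1 matrix `y`, integer `release`, and character `age`
#'   (`"juvenile"`/`"adult"`).
#' @return An object of class `marray_set`: list with matrices `juv` and `ad`
#'   (rows = release occasions 1..T-1; columns `occ2..occT` then `never`) and
#'   the number of occasions `T`.
#' @examples
#' d <- simulate_cmr(sim_config(T = 5, releases_per_occasion = 30), seed = 1)
#' m <- build_marrays(d$histories)
#' rowSums(m$juv) + rowSums(m$ad)  # row totals = releases into each row
#' @export
build_marrays <- function(histories) {
  y <- histories$y
  release <- as.integer(histories$release)
  T <- ncol(y)
  if (T < 2L) stop("need at least 2 occasions", call. = FALSE)
  bad <- which(vapply(seq_len(nrow(y)), function(i) {
    r <- release[i]
    r < 1L || r > T || (r > 1L && any(y[i, seq_len(r - 1L)] == 1L)) ||
      y[i, r] != 1L
  }, logical(1)))
  if (length(bad)) {
    stop(sprintf("malformed encounter history in row(s) %s (detection before release, or release not an encounter)",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  juv <- as.integer(histories$age == "juvenile")
  m <- .build_marray_cpp(matrix(as.integer(y), nrow(y), T), release, juv, T)
  cn <- c(paste0("occ", 2:T), "never")
  rn <- paste0("rel", 1:(T - 1L))
  dimnames(m$juv) <- list(rn, cn)
  dimnames(m$ad) <- list(rn, cn)
  structure(list(juv = m$juv, ad = m$ad, T = T), class = "marray_set")
}

#' @export
print.marray_set <- function(x, ...) {
  cat(sprintf("marray_set: %d occasions; %d juvenile and %d adult releases\n",
              x$T, sum(x$juv), sum(x$ad)))
  invisible(x)
}

#' Multinomial cell probabilities for one m-array release row
#'
#' Standard CJS m-array algebra marginalizing the latent alive/dead states:
#' the probability that an individual released at occasion r is first
#' re-encountered at occasion c is the product of surviving every interval in
#' between, being missed at every intermediate occasion, and being detected
#' at c. The first interval uses the juvenile survival rate for juvenile
#' rows; survival is at the adult rate thereafter. The never-re-encountered
#' cell is the complement, so each row sums to 1 exactly.
#'
#' @param release Release occasion r (1 <= r <= T-1).
#' @param T Number of occasions.
#' @param age `"juvenile"` or `"adult"` (age class at release).
#' @param phi_juv,phi_ad Interval survival probabilities, length T-1 vectors
#'   or scalars (recycled), values in (0, 1].
#' @param p Detection probability at occasions 2..T: scalar or length T-1
#'   vector.
#' @param p_sy Optional separate detection probability applying at the first
#'   occasion after a juvenile release (the "second-year" detection class of
#'   the age-structured detection variant); defaults to `p`.
#' @return Named probability vector of length T (`occ2..occT`, `never`).
#' @examples
#' marray_cell_probs(1, 3, "adult", 0.5, 0.5, 0.5)
#' @export
marray_cell_probs <- function(release, T, age = c("adult", "juvenile"),
                              phi_juv, phi_ad, p, p_sy = NULL) {
  age <- match.arg(age)
  if (release < 1 || release > T - 1) {
    stop("`release` must be in 1..T-1", call. = FALSE)
  }
  phi_juv <- rep_len(phi_juv, T - 1L)
  phi_ad <- rep_len(phi_ad, T - 1L)
  p_ad <- rep_len(p, T - 1L)
  p_sy <- if (is.null(p_sy)) p_ad else rep_len(p_sy, T - 1L)
  if (any(c(phi_juv, phi_ad) <= 0) || any(c(phi_juv, phi_ad) > 1)) {
    stop("survival probabilities must be in (0, 1]", call. = FALSE)
  }
  if (any(c(p_ad, p_sy) < 0) || any(c(p_ad, p_sy) > 1)) {
    stop("detection probabilities must be in [0, 1]", call. = FALSE)
  }
  out <- .cell_probs_cpp(as.integer(release), as.integer(T),
                         age == "juvenile", phi_juv, phi_ad, p_sy, p_ad)
  names(out) <- c(paste0("occ", 2:T), "never")
  out
}

#' Marginalized multinomial log-likelihood of an m-array set
#'
#' Sum over both age classes and all release rows of the multinomial
#' log-mass of the observed first-re-encounter counts under
#' [marray_cell_probs()]. The multinomial coefficient is omitted (it does not
#' involve the parameters), so the value equals the sum over individuals of
#' their latent-state-marginalized history log-probabilities.
#'
#' @param marrays An [build_marrays()] result.
#' @param phi_juv,phi_ad Interval survival probabilities (scalar or length
#'   T-1).
#' @param p Detection probability (scalar or length T-1, occasions 2..T).
#' @param p_sy Optional second-year detection class probabilities (see
#'   [marray_cell_probs()]).
#' @return Scalar log-likelihood.
#' @export
marray_loglik <- function(marrays, phi_juv, phi_ad, p, p_sy = NULL) {
  T <- marrays$T
  phi_juv <- rep_len(phi_juv, T - 1L)
  phi_ad <- rep_len(phi_ad, T - 1L)
  p_ad <- rep_len(p, T - 1L)
  p_sy <- if (is.null(p_sy)) p_ad else rep_len(p_sy, T - 1L)
  if (nrow(marrays$juv) != T - 1L || ncol(marrays$juv) != T) {
    stop("m-array dimensions inconsistent with T", call. = FALSE)
  }
  .marray_loglik_cpp(marrays$juv, marrays$ad, phi_juv, phi_ad, p_sy, p_ad)
}
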