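#' Amplitude-adjusted Fourier transform surrogate of a time series
#'
#' Generates a resampled series with exactly the same marginal distribution
#' as the input (the output is a permutation of the input values) and
#' approximately the same power spectrum, but with randomized Fourier phases.
#' Independently surrogated series are therefore uncorrelated in expectation
#' while each retains its own autocorrelation structure — the null model of
#' "unrelated species with unchanged individual dynamics".
#'
#' The procedure: (1) Gaussianize by mapping the ranks of the input onto a
#' sorted standard-normal sample; (2) randomize the Fourier phases of the
#' Gaussianized series under Hermitian symmetry (the mean bin untouched; for
#' even length the Nyquist bin is kept real, with a random sign); (3) map the
#' ranks of the phase-randomized series back onto the sorted original values.
#' Ties in ranks are broken at random.
#'
#' @param x numeric series, length >= 3, positive variance.
#' @return a numeric series of the same length: a permutation of `x`.
#' @examples
#' set.seed(1)
#' x <- rnorm(32)
#' s <- aaft_surrogate(x)
#' identical(sort(s), sort(x))
#' @export
aaft_surrogate <- function(x) {
  x <- as.vector(x, mode = "double")
  n <- length(x)
  if (n < 3L) stop("series too short to surrogate (need length >= 3)")
  if (anyNA(x)) stop("series contains missing values")
  if (stats::sd(x) == 0) stop("cannot surrogate constant series")

  r <- rank(x, ties.method = "random")
  g <- sort(stats::rnorm(n))[r]          # normal-scores Gaussianization

  f <- stats::fft(g)
  half <- (n - 1L) %/% 2L
  rot <- rep(1 + 0i, n)
  if (half > 0L) {
    phases <- stats::runif(half, 0, 2 * pi)
    rot[2L:(half + 1L)] <- exp(1i * phases)
    rot[n:(n - half + 1L)] <- Conj(rot[2L:(half + 1L)])
  }
  if (n %% 2L == 0L)                     # Nyquist bin stays real
    rot[n %/% 2L + 1L] <- sample(c(-1, 1), 1L)
  gp <- Re(stats::fft(f * rot, inverse = TRUE)) / n

  sort(x)[rank(gp, ties.method = "random")]
}

#' Bootstrap confidence interval for the compensatory effect
#'
#' Instantiates the null hypothesis of unrelated species by applying
#' [aaft_surrogate()] independently to every species column, `n` times.
#' Surrogates preserve each species' values exactly, so per-species means and
#' sds — and hence `S_pop` and `SAE`'s ingredients — are unchanged; only the
#' between-species covariances are scrambled.  For surrogate dataset i the
#' community stability `S_com_ip^(i)` is computed, giving
#' `SAE^(i) = S_com_ip^(i) / S_pop` (with `S_pop` from the original data) and
#' `CPE^(i) = S_com / S_com_ip^(i)`.  The confidence interval for CPE is
#' taken from empirical quantiles (linear interpolation of order statistics)
#' of the `CPE^(i)`.
#'
#' A constant species column cannot be surrogated and is carried through
#' unchanged, with a warning (it contributes nothing to any covariance).
#'
#' @param X a [community_matrix()].
#' @param n number of surrogate datasets (the reference analysis uses 1000).
#' @param ci_levels two quantile levels, default `c(0.025, 0.975)`.
#' @param seed optional integer seed, recorded in the result.
#' @return a list of class `bootstrap_result`: `cpe_point`, `ci`,
#'   `ci_levels`, `cpe_samples`, `sae_samples`, `s_com_ip_samples`,
#'   `n_surrogates`, `seed`.
#' @export
bootstrap_cpe <- function(X, n = 1000L, ci_levels = c(0.025, 0.975),
                          seed = NULL) {
  stopifnot_community(X)
  if (n < 1L) stop("need at least 1 surrogate")
  if (length(ci_levels) != 2L || any(ci_levels <= 0) || any(ci_levels >= 1) ||
      ci_levels[1] >= ci_levels[2])
    stop("'ci_levels' must be two increasing probabilities in (0, 1)")
  if (!is.null(seed)) set.seed(seed)

  d <- decompose_stability(X)
  V <- X$values
  constant <- apply(V, 2L, stats::sd) == 0
  if (all(constant))
    stop("degenerate community: all species constant in time")
  if (any(constant))
    warning(sum(constant), " constant species column(s) carried through ",
            "surrogates unchanged")
  mu_tot <- sum(colMeans(V))

  s_ip <- vapply(seq_len(n), function(i) {
    Vs <- V
    for (j in which(!constant)) Vs[, j] <- aaft_surrogate(V[, j])
    mu_tot / stats::sd(rowSums(Vs))
  }, numeric(1))

  cpe_samples <- d$S_com / s_ip
  ci <- stats::quantile(cpe_samples, probs = ci_levels, names = FALSE,
                        type = 7)
  structure(
    list(cpe_point = d$CPE,
         ci = ci,
         ci_levels = ci_levels,
         cpe_samples = cpe_samples,
         sae_samples = s_ip / d$S_pop,
         s_com_ip_samples = s_ip,
         n_surrogates = as.integer(n),
         seed = seed),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf("CPE = %.*g, %g%% CI [%.*g, %.*g] (%d AAFT surrogates)\n",
              digits, x$cpe_point, round(100 * diff(x$ci_levels), 1),
              digits, x$ci[1], digits, x$ci[2], x$n_surrogates))
  invisible(x)
}
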