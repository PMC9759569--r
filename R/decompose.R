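#' Temporal moments of a community matrix
#'
#' Sample means, standard deviations, variances and the full species-by-species
#' covariance matrix of a plot's abundance series, computed through time with
#' the sample (T - 1) denominator, so that `cov(x, x) = var(x)` exactly.
#' Also returns the community totals: `mu_tot = sum(means)`,
#' `v_tot = sum(cov)` (the variance of the summed series) and
#' `sigma_tot = sqrt(v_tot)`.
#'
#' @param X a [community_matrix()].
#' @return a list of class `moment_set` with elements `means`, `sds`,
#'   `variances`, `cov`, `mu_tot`, `v_tot`, `sigma_tot`.
#' @export
species_moments <- function(X) {
  stopifnot_community(X)
  V <- X$values
  means <- colMeans(V)
  covm <- stats::cov(V)
  variances <- diag(covm)
  if (all(variances == 0))
    stop("degenerate community: zero total variance")
  structure(
    list(means = means,
         sds = sqrt(variances),
         variances = variances,
         cov = covm,
         mu_tot = sum(means),
         v_tot = sum(covm),
         sigma_tot = sqrt(max(sum(covm), 0))),
    class = "moment_set"
  )
}

# Shared kernel: all closed-form components from first/second moments.
# mu: species means; sigma: species sds; v_tot: variance of the total.
components_from_moments <- function(mu, sigma, v_tot) {
  S <- length(mu)
  mu_tot <- sum(mu)
  sum_sd <- sum(sigma)
  sum_v <- sum(sigma^2)
  if (v_tot <= 0)
    stop("degenerate community: zero total variance")
  if (sum_sd <= 0)
    stop("degenerate community: all species constant in time")
  sigma_tot <- sqrt(v_tot)
  sae <- sum_sd / sqrt(sum_v)
  cpe <- sqrt(sum_v) / sigma_tot
  structure(
    list(S_com = mu_tot / sigma_tot,
         S_pop = mu_tot / sum_sd,
         Phi = sum_sd / sigma_tot,
         SAE = sae,
         CPE = cpe,
         var_ratio = v_tot / sum_v,
         SAE_even = sqrt(S),
         EVN = sae / sqrt(S),
         theta = v_tot / sum_sd^2,
         S_com_ip = mu_tot / sqrt(sum_v),
         S = S),
    class = "stability_components"
  )
}

#' Decompose community temporal stability
#'
#' Computes community stability `S_com` (the inverse coefficient of variation
#' of summed abundance) and its multiplicative decomposition
#' `S_com = CPE * SAE * S_pop`:
#'
#' * `S_pop  = mu_tot / sum(sigma_i)` — population stability, the stability a
#'   perfectly synchronous community would have;
#' * `Phi    = sum(sigma_i) / sigma_tot` — the Loreau-de Mazancourt asynchrony
#'   index, `S_com / S_pop`;
#' * `SAE    = sum(sigma_i) / sqrt(sum(sigma_i^2))` — the statistical-averaging
#'   (portfolio) effect, the part of `Phi` a community of independently
#'   fluctuating species would already have; bounded by `sqrt(S)`;
#' * `CPE    = sqrt(sum(sigma_i^2)) / sigma_tot` — the compensatory effect, the
#'   remainder of `Phi`; `CPE > 1` indicates negative covariances
#'   (compensation), `CPE < 1` synchrony; equals `1/sqrt(var_ratio)`;
#' * `SAE_even = sqrt(S)` and `EVN = SAE / sqrt(S)` — the purely statistical
#'   ceiling of SAE and the evenness-of-variances penalty on it;
#' * `theta = sigma_tot^2 / (sum(sigma_i))^2` — the classic community-wide
#'   synchrony statistic, equal to `1/Phi^2`;
#' * `var_ratio = sigma_tot^2 / sum(sigma_i^2)` — the classic variance ratio.
#'
#' A single-species plot returns the degenerate decomposition
#' `Phi = SAE = CPE = 1` (with a message); downstream analysis excludes such
#' plots by default via its `min_richness` filter.
#'
#' @param X a [community_matrix()].
#' @return a list of class `stability_components` with fields `S_com`,
#'   `S_pop`, `Phi`, `SAE`, `CPE`, `var_ratio`, `SAE_even`, `EVN`, `theta`,
#'   `S_com_ip` (stability under independent populations) and `S` (richness).
#' @examples
#' X <- community_matrix(cbind(a = c(2, 4, 2, 4), b = c(1, 3, 3, 1)))
#' d <- decompose_stability(X)
#' all.equal(d$S_com, d$Phi * d$S_pop)
#' @export
decompose_stability <- function(X) {
  m <- species_moments(X)
  if (length(m$means) == 1L)
    message("plot ", X$plot_id,
            ": single species; Phi = SAE = CPE = 1 by construction")
  components_from_moments(m$means, m$sds, m$v_tot)
}

#' @export
print.stability_components <- function(x, digits = 4, ...) {
  cat("Community stability decomposition (S = ", x$S, " species)\n", sep = "")
  cat(sprintf("  S_com = %.*g = CPE (%.*g) x SAE (%.*g) x S_pop (%.*g)\n",
              digits, x$S_com, digits, x$CPE, digits, x$SAE,
              digits, x$S_pop))
  cat(sprintf("  asynchrony Phi = %.*g   variance ratio = %.*g   theta = %.*g\n",
              digits, x$Phi, digits, x$var_ratio, digits, x$theta))
  cat(sprintf("  SAE_even = sqrt(S) = %.*g   evenness effect EVN = %.*g\n",
              digits, x$SAE_even, digits, x$EVN))
  invisible(x)
}

#' Classic variance ratio
#'
#' `var_ratio = sigma_tot^2 / sum(sigma_i^2)`, the ratio of the variance of
#' the community total to its expectation under independent population
#' fluctuations.  Values above 1 indicate synchrony, below 1 compensation;
#' the compensatory effect of [decompose_stability()] is `1/sqrt(var_ratio)`.
#'
#' @inheritParams decompose_stability
#' @return a single number.
#' @export
variance_ratio <- function(X) {
  m <- species_moments(X)
  sum_v <- sum(m$variances)
  if (sum_v <= 0)
    stop("degenerate community: all species constant in time")
  m$v_tot / sum_v
}

#' Loreau-de Mazancourt synchrony statistic
#'
#' `theta = sigma_tot^2 / (sum(sigma_i))^2`, in (0, 1]: 1 at perfect
#' synchrony, `1/S` for `S` independent species of equal variance.  Related
#' to the asynchrony index by `theta = 1/Phi^2`.
#'
#' @inheritParams decompose_stability
#' @return a single number.
#' @export
loreau_theta <- function(X) {
  m <- species_moments(X)
  if (m$v_tot <= 0)
    stop("degenerate community: zero total variance")
  m$v_tot / sum(m$sds)^2
}
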