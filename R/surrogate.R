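#' Rescale a series to reference moments
#'
#' Affine transform of a donor or monoculture series so that its mean and
#' standard deviation match a reference species, while every correlation with
#' any other series is preserved:
#' `Z = (z - mean(z)) / sd(z) * ref_sd + ref_mean`.
#'
#' @param z numeric series with positive variance.
#' @param ref_mean,ref_sd target mean and standard deviation (`ref_sd >= 0`;
#'   `ref_sd = 0` yields a constant series at `ref_mean`).
#' @return numeric series of the same length.
#' @export
rescale_to_reference <- function(z, ref_mean, ref_sd) {
  sz <- stats::sd(z)
  if (is.na(sz) || sz == 0)
    stop("constant donor series cannot be rescaled")
  if (ref_sd < 0)
    stop("'ref_sd' must be non-negative")
  (z - mean(z)) / sz * ref_sd + ref_mean
}

#' Surrogate community stability from donor plots
#'
#' Builds the surrogate covariance matrix `C` whose diagonal holds the focal
#' plot's species variances and whose off-diagonal entry `C[i, j]` is the
#' covariance between the focal series of species i and a rescaled series
#' `Z_j` of species j taken from another plot of the same site.  Because the
#' donor grew in a different plot, `cov(x_i, Z_j)` retains covariance driven
#' by the shared environment but not covariance driven by interactions within
#' the focal plot.  The surrogate community stability is
#' `S_com_sur = mu_tot / sqrt(sum(C))`.
#'
#' When several donor plots contain species j (with positive variance), one
#' is chosen uniformly at random.  When none does, species j contributes zero
#' off-diagonal covariance (an independence fallback, with a warning) and its
#' donor is recorded as `"none"`.  `C` is used exactly as constructed — it is
#' not symmetrized, so `C[i, j]` and `C[j, i]` generally differ.
#'
#' @param focal a [community_matrix()].
#' @param donors list of `community_matrix` objects from the same site,
#'   covering the same time points (the focal plot itself is ignored if
#'   present, matched by `plot_id`).
#' @return a list with `S_com_sur`, the matrix `C`, and `donor_map` (named
#'   character vector, species -> donor plot id or `"none"`).
#' @seealso [secondary_decompose()] for the `CPE_env`/`CPE_int` split and
#'   repeat averaging.
#' @export
surrogate_stability_from_plots <- function(focal, donors) {
  stopifnot_community(focal)
  donors <- Filter(function(d) d$plot_id != focal$plot_id, donors)
  m <- species_moments(focal)
  V <- focal$values
  S <- ncol(V)
  Tn <- nrow(V)
  C <- diag(m$variances, nrow = S)
  dimnames(C) <- list(focal$species, focal$species)
  donor_map <- setNames(rep("none", S), focal$species)

  for (j in seq_len(S)) {
    sp <- focal$species[j]
    eligible <- Filter(function(d) {
      k <- match(sp, d$species)
      !is.na(k) && nrow(d$values) == Tn && stats::sd(d$values[, k]) > 0
    }, donors)
    if (length(eligible) == 0L) {
      warning("no donor plot for species '", sp,
              "'; treating it as independent (zero covariances)")
      next
    }
    pick <- eligible[[sample.int(length(eligible), 1L)]]
    donor_map[sp] <- pick$plot_id
    zj <- pick$values[, match(sp, pick$species)]
    Zj <- rescale_to_reference(zj, m$means[j], m$sds[j])
    cz <- stats::cov(V, Zj)[, 1L]
    C[-j, j] <- cz[-j]
  }

  v_sur <- sum(C)
  if (v_sur <= 0)
    stop("non-positive surrogate variance (sum of C = ", signif(v_sur, 4), ")")
  list(S_com_sur = m$mu_tot / sqrt(v_sur), C = C, donor_map = donor_map)
}

#' Surrogate community stability from monocultures
#'
#' Each focal species' monoculture series is rescaled to the species' mean
#' and sd in the mixture ([rescale_to_reference()]); the rescaled series are
#' summed and `S_com_sur = mean(Y_tot) / sd(Y_tot)`.  Monocultures fluctuate
#' with the environment but without interspecific interaction, so their
#' correlations estimate what mixture correlations would be absent
#' interactions.  When a species has several monocultures one is chosen
#' uniformly at random; a species with none is an error (the donor-plot
#' method is the fallback for such data).
#'
#' @param X a [community_matrix()].
#' @param monocultures named list, species -> list of numeric series (each
#'   the length of `X`'s series) or a single numeric series.
#' @return a list with `S_com_sur` and `mono_pick` (which monoculture was
#'   used per species, by index).
#' @export
surrogate_stability_from_monocultures <- function(X, monocultures) {
  stopifnot_community(X)
  m <- species_moments(X)
  Tn <- nrow(X$values)
  Ytot <- numeric(Tn)
  mono_pick <- setNames(integer(length(X$species)), X$species)
  for (j in seq_along(X$species)) {
    sp <- X$species[j]
    ys <- monocultures[[sp]]
    if (is.null(ys))
      stop("no monoculture available for species '", sp, "'")
    if (is.numeric(ys)) ys <- list(ys)
    k <- sample.int(length(ys), 1L)
    mono_pick[sp] <- k
    y <- ys[[k]]
    if (length(y) != Tn)
      stop("monoculture series for '", sp, "' has length ", length(y),
           ", expected ", Tn)
    Ytot <- Ytot + rescale_to_reference(y, m$means[j], m$sds[j])
  }
  sdY <- stats::sd(Ytot)
  if (sdY <= 0)
    stop("non-positive surrogate variance (constant surrogate total)")
  list(S_com_sur = m$mu_tot / sdY, mono_pick = mono_pick)
}

#' Split the compensatory effect into environmental and interaction parts
#'
#' Uses a surrogate community stability `S_com_sur` — community stability
#' with interaction-driven covariance removed but environment-driven
#' covariance retained — to split the compensatory effect:
#' `CPE_env = S_com_sur / S_com_ip` and `CPE_int = S_com / S_com_sur`,
#' so that `CPE_env * CPE_int = CPE` for a single surrogate draw.
#' Donor selection is random, so the construction is repeated and the
#' ratios averaged (arithmetic mean by default, matching common practice;
#' a geometric mean is available since the quantities are multiplicative).
#'
#' @param X a [community_matrix()].
#' @param source for `method = "donor_plot"`, a list of donor
#'   `community_matrix` objects; for `method = "monoculture"`, a named list
#'   species -> monoculture series (see
#'   [surrogate_stability_from_monocultures()]).
#' @param method `"donor_plot"` or `"monoculture"`.
#' @param n_repeats number of random surrogate draws to average; defaults to
#'   100 for monocultures and 1 for donor plots.
#' @param seed optional integer seed, recorded in the result.
#' @param average `"arithmetic"` (default) or `"geometric"` mean across
#'   repeats.
#' @return a list of class `secondary_components`: `S_com_sur`, `S_com_ip`,
#'   `CPE_env`, `CPE_int`, `method`, `n_repeats`, `seed`, and the per-repeat
#'   vectors in `repeats`.
#' @export
secondary_decompose <- function(X, source,
                                method = c("donor_plot", "monoculture"),
                                n_repeats = NULL, seed = NULL,
                                average = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  average <- match.arg(average)
  if (is.null(n_repeats))
    n_repeats <- if (method == "monoculture") 100L else 1L
  if (n_repeats < 1L) stop("'n_repeats' must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  d <- decompose_stability(X)
  sur <- numeric(n_repeats)
  failed <- 0L
  for (r in seq_len(n_repeats)) {
    res <- tryCatch(
      if (method == "donor_plot")
        surrogate_stability_from_plots(X, source)$S_com_sur
      else
        surrogate_stability_from_monocultures(X, source)$S_com_sur,
      error = function(e) NA_real_
    )
    if (is.na(res)) failed <- failed + 1L
    sur[r] <- res
  }
  if (all(is.na(sur)))
    stop("all ", n_repeats, " surrogate repeats failed")
  if (failed > 0L)
    warning(failed, " of ", n_repeats, " surrogate repeats failed; ",
            "means taken over the rest")
  sur <- sur[!is.na(sur)]

  cpe_env <- sur / d$S_com_ip
  cpe_int <- d$S_com / sur
  avg <- if (average == "arithmetic") mean else function(v) exp(mean(log(v)))
  structure(
    list(S_com_sur = avg(sur),
         S_com_ip = d$S_com_ip,
         CPE_env = avg(cpe_env),
         CPE_int = avg(cpe_int),
         CPE = d$CPE,
         method = method,
         n_repeats = n_repeats,
         seed = seed,
         average = average,
         repeats = list(S_com_sur = sur, CPE_env = cpe_env,
                        CPE_int = cpe_int)),
    class = "secondary_components"
  )
}

#' @export
print.secondary_components <- function(x, digits = 4, ...) {
  cat("Secondary decomposition of CPE (", x$method, ", ",
      x$n_repeats, " repeats)\n", sep = "")
  cat(sprintf("  CPE = %.*g   CPE_env = %.*g   CPE_int = %.*g\n",
              digits, x$CPE, digits, x$CPE_env, digits, x$CPE_int))
  cat(sprintf("  S_com_sur = %.*g   S_com_ip = %.*g\n",
              digits, x$S_com_sur, digits, x$S_com_ip))
  invisible(x)
}
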