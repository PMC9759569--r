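test_that("rescaling hits the reference moments exactly and preserves correlation", {
  z <- c(0, 2, 5, 1, 7, 3)
  out <- rescale_to_reference(z, ref_mean = 10, ref_sd = 1)
  expect_equal(mean(out), 10, tolerance = 1e-12)
  expect_equal(stats::sd(out), 1, tolerance = 1e-12)
  expect_equal(order(out), order(z))
  w <- stats::rnorm(6)
  expect_equal(stats::cor(out, w), stats::cor(z, w), tolerance = 1e-12)

  # identity when the series already has the reference moments
  expect_equal(rescale_to_reference(out, 10, 1), out, tolerance = 1e-12)
  # degenerate target
  expect_equal(rescale_to_reference(z, 3, 0), rep(3, 6))
  expect_error(rescale_to_reference(rep(1, 5), 0, 1), "constant donor")
})

test_that("self-donor limit reproduces the focal covariance and CPE_int = 1", {
  set.seed(11)
  focal <- random_community(4, 20, plot_id = "p1")
  twin <- cm(focal$values, plot_id = "p2")  # identical series, other plot
  res <- surrogate_stability_from_plots(focal, list(twin))
  m <- species_moments(focal)
  d <- decompose_stability(focal)
  expect_equal(res$C, m$cov, tolerance = 1e-10)
  expect_equal(res$S_com_sur, d$S_com, tolerance = 1e-10)
  expect_true(all(res$donor_map == "p2"))

  sec <- secondary_decompose(focal, list(twin), method = "donor_plot",
                             n_repeats = 1, seed = 1)
  expect_equal(sec$CPE_int, 1, tolerance = 1e-10)
  expect_equal(sec$CPE_env, d$CPE, tolerance = 1e-10)
})

test_that("orthogonal donors give the independence limit CPE_env = 1", {
  # focal uses contrasts 1:2, donor uses contrasts 3:4 of the same basis,
  # so every donor series is exactly uncorrelated with every focal series
  basis <- stats::contr.poly(16)
  mk <- function(cols, id) {
    vals <- apply(basis[, cols, drop = FALSE], 2,
                  function(b) b / stats::sd(b) + 10)
    colnames(vals) <- c("spA", "spB")
    cm(vals, plot_id = id)
  }
  focal <- mk(1:2, "p1")
  donor <- mk(3:4, "p2")
  res <- surrogate_stability_from_plots(focal, list(donor))
  expect_equal(res$C[1, 2], 0, tolerance = 1e-12)
  expect_equal(res$C[2, 1], 0, tolerance = 1e-12)
  d <- decompose_stability(focal)
  expect_equal(res$S_com_sur, d$S_com_ip, tolerance = 1e-10)

  sec <- secondary_decompose(focal, list(donor), method = "donor_plot",
                             n_repeats = 1, seed = 1)
  expect_equal(sec$CPE_env, 1, tolerance = 1e-10)
  expect_equal(sec$CPE_int, d$CPE, tolerance = 1e-10)
})

test_that("species with no donor falls back to independence with a warning", {
  set.seed(3)
  focal <- random_community(3, 15, plot_id = "p1")
  donor_vals <- focal$values[, 1:2] + matrix(stats::rnorm(30), 15, 2)
  donor <- cm(abs(donor_vals), species = focal$species[1:2], plot_id = "p2")
  expect_warning(res <- surrogate_stability_from_plots(focal, list(donor)),
                 "no donor plot for species 'sp3'")
  expect_identical(unname(res$donor_map["sp3"]), "none")
  expect_equal(unname(res$C[1:2, 3]), c(0, 0))
  # diagonal always holds the focal variances
  expect_equal(diag(res$C), species_moments(focal)$variances,
               tolerance = 1e-12)
})

test_that("monoculture surrogates reproduce the self and independence limits", {
  set.seed(21)
  X <- random_community(4, 20)
  d <- decompose_stability(X)

  self_monos <- setNames(lapply(seq_len(4), function(i) X$values[, i]),
                         X$species)
  res <- surrogate_stability_from_monocultures(X, self_monos)
  expect_equal(res$S_com_sur, d$S_com, tolerance = 1e-10)

  basis <- stats::contr.poly(20)
  orth_monos <- setNames(lapply(1:4, function(i) basis[, i] + 5), X$species)
  res2 <- surrogate_stability_from_monocultures(X, orth_monos)
  expect_equal(res2$S_com_sur, d$S_com_ip, tolerance = 1e-10)

  expect_error(surrogate_stability_from_monocultures(X, self_monos[1:3]),
               "no monoculture available")
})

test_that("surrogate stabilities are invariant to affine-rescaled donors", {
  set.seed(5)
  focal <- random_community(3, 18, plot_id = "p1")
  donor <- random_community(3, 18, plot_id = "p2")
  donor_scaled <- cm(donor$values * 3.7 + 2, plot_id = "p2",
                     check_negative = FALSE)
  set.seed(99); r1 <- surrogate_stability_from_plots(focal, list(donor))
  set.seed(99); r2 <- surrogate_stability_from_plots(focal, list(donor_scaled))
  expect_equal(r1$S_com_sur, r2$S_com_sur, tolerance = 1e-10)
})

test_that("secondary decomposition multiplies back to CPE", {
  set.seed(8)
  focal <- random_community(4, 16, plot_id = "p1")
  donors <- lapply(2:4, function(i) {
    D <- random_community(4, 16, plot_id = paste0("p", i))
    cm(D$values, species = focal$species, plot_id = D$plot_id)
  })
  d <- decompose_stability(focal)
  sec <- secondary_decompose(focal, donors, method = "donor_plot",
                             n_repeats = 1, seed = 4)
  expect_rel_equal(sec$CPE_env * sec$CPE_int, d$CPE)

  # geometric averaging keeps the product identity across many repeats
  secg <- secondary_decompose(focal, donors, method = "donor_plot",
                              n_repeats = 25, seed = 4,
                              average = "geometric")
  expect_rel_equal(secg$CPE_env * secg$CPE_int, d$CPE)

  # reproducibility: same seed, same repeats
  secb <- secondary_decompose(focal, donors, method = "donor_plot",
                              n_repeats = 25, seed = 4,
                              average = "geometric")
  expect_identical(secg$repeats, secb$repeats)
})

test_that("non-positive surrogate variance is an error", {
  # three near-identical focal species whose donors are all near-perfectly
  # anticorrelated with them: sum(C) ~ 3 v - 6 v < 0
  a <- c(1, 3, 2, 4, 1, 3)
  e1 <- c(0, 1e-3, 0, -1e-3, 0, 1e-3); e2 <- rev(e1)
  focal <- cm(cbind(spA = a, spB = a + e1, spC = a + e2))
  donor <- cm(cbind(spA = 10 - a + e2, spB = 10 - a, spC = 10 - a + e1),
              plot_id = "p2")
  expect_error(surrogate_stability_from_plots(focal, list(donor)),
               "non-positive surrogate variance")
})
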