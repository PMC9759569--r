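test_that("diversity indices match direct evaluation", {
  X <- cm(cbind(a = c(2, 4), b = c(4, 2)))      # equal means
  dv <- diversity_indices(X)
  expect_equal(dv$richness, 2L)
  expect_equal(dv$shannon, log(2), tolerance = 1e-12)
  expect_equal(dv$inv_simpson, 2, tolerance = 1e-12)

  X1 <- cm(cbind(a = c(1, 2, 3)))
  dv1 <- diversity_indices(X1)
  expect_equal(dv1$shannon, 0)
  expect_equal(dv1$inv_simpson, 1)

  # means (3, 1): q = (0.75, 0.25)
  X2 <- cm(cbind(a = c(2, 4), b = c(1, 1)))
  dv2 <- diversity_indices(X2)
  expect_equal(dv2$shannon, -0.75 * log(0.75) - 0.25 * log(0.25),
               tolerance = 1e-12)
  expect_equal(dv2$inv_simpson, 1.6, tolerance = 1e-12)
  expect_lte(dv2$inv_simpson, dv2$richness)
  expect_lte(exp(dv2$shannon), dv2$richness)
})

test_that("component table filters by richness and keeps log identities", {
  set.seed(12)
  plots <- c(lapply(1:3, function(i) {
    X <- random_community(i + 1, 15, plot_id = paste0("p", i))
    cm(X$values, plot_id = X$plot_id, site_id = "s1")
  }), list(cm(cbind(a = c(1, 2, 3, 4, 2, 1, 3, 2, 4, 1, 2, 3)),
              plot_id = "mono", site_id = "s1")))
  expect_message(tab <- component_table(plots), "excluded: richness 1")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$log10_Phi, tab$log10_SAE + tab$log10_CPE,
               tolerance = 1e-12)
  expect_equal(tab$log10_S_com, tab$log10_Phi + tab$log10_S_pop,
               tolerance = 1e-12)
  expect_error(component_table(plots, min_richness = 10),
               "no plots passed")
})

test_that("site summaries average log quantities with the plot-level SE", {
  tab <- data.frame(site = c("A", "A", "B"), plot = c("p1", "p2", "p3"),
                    log10_SAE = c(0.1, 0.3, 0.2),
                    log10_CPE = c(0, 0, 0.1),
                    shannon = c(1, 2, 1.5))
  expect_message(s <- site_summaries(tab), "single plot")
  expect_equal(s$log10_SAE[s$site == "A"], 0.2)
  expect_equal(s$se_log10_SAE[s$site == "A"], 0.1, tolerance = 1e-12)
  expect_true(is.na(s$se_log10_SAE[s$site == "B"]))
  expect_equal(s$n_plots, c(2L, 1L))

  # identical plots: SE collapses to zero
  tab2 <- data.frame(site = "A", plot = c("p1", "p2"),
                     log10_SAE = c(0.25, 0.25), shannon = c(1, 1))
  s2 <- site_summaries(tab2)
  expect_equal(s2$se_log10_SAE, 0)
  expect_error(site_summaries(data.frame()), "nonempty")
})

# Exact fixture: SAE = sqrt(S) (EVN = 1) while CPE and S_pop are constant
# across richness, so log10(SAE) lies exactly on a slope-1/2 line in
# log10(S) and the other slopes vanish.
baseline_records <- function() {
  S <- c(2, 4, 8, 16)
  df <- data.frame(
    site = paste0("s", seq_along(S)),
    log10_richness = log10(S),
    shannon = log(S),
    log10_inv_simpson = log10(S),
    log10_SAE = 0.5 * log10(S),
    log10_CPE = rep(log10(1.1), length(S)),
    log10_S_pop = rep(0.4, length(S)))
  df$log10_Phi <- df$log10_SAE + df$log10_CPE
  df$log10_S_com <- df$log10_Phi + df$log10_S_pop
  df
}

test_that("regressions recover the statistical baseline slope of 1/2", {
  # exact points: lm warns about the "essentially perfect fit"
  tab <- suppressWarnings(
    fit_component_regressions(baseline_records(), index = "richness"))
  sl <- function(r) tab$slope[tab$response == r]
  expect_equal(sl("log10_SAE"), 0.5, tolerance = 1e-12)
  expect_equal(sl("log10_CPE"), 0, tolerance = 1e-12)
  expect_equal(sl("log10_S_pop"), 0, tolerance = 1e-12)
  expect_equal(sl("log10_Phi"), 0.5, tolerance = 1e-12)
  expect_equal(sl("log10_S_com"), 0.5, tolerance = 1e-12)
})

test_that("slope additivity holds for fitted tables and flags perturbations", {
  set.seed(33)
  plots <- unlist(lapply(1:5, function(s) lapply(1:3, function(p) {
    X <- random_community(sample(2:9, 1), 12, plot_id = paste0("p", s, p))
    cm(X$values, plot_id = X$plot_id, site_id = paste0("site", s))
  })), recursive = FALSE)
  tab <- component_table(plots)
  for (idx in c("richness", "shannon", "invsimpson")) {
    fit <- fit_component_regressions(tab, index = idx)
    chk <- check_slope_additivity(fit)
    expect_true(chk$pass)
    expect_lt(max(abs(chk$residuals)), 1e-10)
  }
  site_fit <- fit_component_regressions(site_summaries(tab))
  expect_true(check_slope_additivity(site_fit)$pass)

  bad <- fit_component_regressions(tab)
  bad$slope[bad$response == "log10_SAE"] <-
    bad$slope[bad$response == "log10_SAE"] + 0.01
  chk <- check_slope_additivity(bad)
  expect_false(chk$pass)
  expect_equal(abs(chk$residuals[["phi_vs_sae_cpe"]]), 0.01,
               tolerance = 1e-10)
})

test_that("regression guards against degenerate designs", {
  df <- baseline_records()
  df$log10_richness <- 0
  expect_error(fit_component_regressions(df), "degenerate predictor")
  expect_error(fit_component_regressions(baseline_records()[1:2, ]),
               "at least 3 units")
})
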