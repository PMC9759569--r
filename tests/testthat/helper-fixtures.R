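# Fixtures are built in code; cm() silences the routine per-plot log notes
# (short series, dropped species) that are irrelevant to most tests.

cm <- function(...) suppressMessages(community_matrix(...))

toy_two_species <- function() {
  cm(cbind(a = c(2, 4, 2, 4), b = c(1, 3, 3, 1)))
}

# S mutually orthogonal equal-variance series with positive means:
# columns of an orthogonal contrast basis have zero mean and zero pairwise
# sample covariance; rescale to common sd and shift to a positive mean.
orthogonal_community <- function(S, T_len = 4L * S, mean_val = 10,
                                 sd_val = 1, plot_id = "orth") {
  stopifnot(T_len > S)
  basis <- stats::contr.poly(T_len)[, seq_len(S), drop = FALSE]
  vals <- apply(basis, 2L, function(b) b / stats::sd(b) * sd_val + mean_val)
  colnames(vals) <- paste0("sp", seq_len(S))
  cm(vals, plot_id = plot_id)
}

# Random positive community: lognormal noise around species-specific means.
random_community <- function(S, T_len, plot_id = "rnd") {
  mu <- stats::runif(S, 2, 20)
  vals <- sapply(seq_len(S), function(i)
    mu[i] * stats::rlnorm(T_len, sdlog = stats::runif(1, 0.1, 0.6)))
  colnames(vals) <- paste0("sp", seq_len(S))
  cm(vals, plot_id = plot_id)
}

expect_rel_equal <- function(object, expected, tol = 1e-10) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-300), tol)
}
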