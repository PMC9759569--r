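#' Diversity indices from temporal mean abundances
#'
#' Relative abundances are taken from the time-averaged species abundances,
#' `q_i = mu_i / mu_tot`.  Richness counts species with positive mean;
#' Shannon's H uses the natural log; inverse Simpson is `1 / sum(q_i^2)`.
#'
#' @param X a [community_matrix()].
#' @return a list with `richness`, `shannon`, `inv_simpson`.
#' @export
diversity_indices <- function(X) {
  stopifnot_community(X)
  mu <- colMeans(X$values)
  q <- mu[mu > 0]
  if (length(q) == 0L) stop("no species with positive mean abundance")
  list(richness = length(q),
       shannon = as.numeric(vegan::diversity(q, index = "shannon")),
       inv_simpson = as.numeric(vegan::diversity(q, index = "invsimpson")))
}

#' Per-plot component table
#'
#' Runs [decompose_stability()] and [diversity_indices()] on every plot and
#' returns one tidy row per plot: identifiers, diversity, the raw components,
#' and their log10 transforms (log10 of richness and inverse Simpson too;
#' Shannon is left untransformed as it already embeds a log).  Plots below
#' `min_richness` retained species are excluded (the degenerate
#' single-species decomposition is well defined but uninformative for
#' diversity analysis), with a message.
#'
#' @param plots list of [community_matrix()] objects (or a dataset from
#'   [read_long_table()]).
#' @param min_richness minimum number of retained species (default 2).
#' @return a data.frame, one row per retained plot.
#' @export
component_table <- function(plots, min_richness = 2L) {
  if (inherits(plots, "stability_dataset")) plots <- plots$plots
  if (is_community_matrix(plots)) plots <- list(plots)
  if (length(plots) == 0L) stop("no plots supplied")

  rows <- lapply(plots, function(X) {
    if (length(X$species) < min_richness) {
      message("plot ", X$plot_id, " excluded: richness ",
              length(X$species), " < ", min_richness)
      return(NULL)
    }
    d <- suppressMessages(decompose_stability(X))
    dv <- diversity_indices(X)
    data.frame(site = X$site_id, plot = X$plot_id,
               richness = dv$richness, shannon = dv$shannon,
               inv_simpson = dv$inv_simpson,
               S_com = d$S_com, S_pop = d$S_pop, Phi = d$Phi,
               SAE = d$SAE, CPE = d$CPE, EVN = d$EVN, theta = d$theta,
               log10_richness = log10(dv$richness),
               log10_inv_simpson = log10(dv$inv_simpson),
               log10_S_com = log10(d$S_com), log10_S_pop = log10(d$S_pop),
               log10_Phi = log10(d$Phi), log10_SAE = log10(d$SAE),
               log10_CPE = log10(d$CPE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no plots passed the richness filter")
  rownames(out) <- NULL
  out
}

.log_cols <- c("log10_S_com", "log10_S_pop", "log10_Phi", "log10_SAE",
               "log10_CPE", "log10_CPE_env", "log10_CPE_int",
               "log10_richness", "log10_inv_simpson", "shannon")

#' Site-level means and standard errors
#'
#' Averages each log10-transformed quantity (and untransformed Shannon)
#' across the plots of each site, with the standard error across plots
#' (`sd / sqrt(n)`).  Diversity is aggregated the same way: mean of per-plot
#' log10 richness / log10 inverse Simpson / Shannon.  A site with a single
#' plot gets `NA` standard errors, with a message.
#'
#' @param records a per-plot data.frame from [component_table()].
#' @return a data.frame with one row per site: `site`, `n_plots`, the mean
#'   of each log10 column, and matching `se_*` columns.
#' @export
site_summaries <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a nonempty per-plot data.frame")
  cols <- intersect(.log_cols, names(records))
  out <- lapply(split(records, records$site), function(df) {
    n <- nrow(df)
    if (n == 1L) message("site ", df$site[1], " has a single plot; SE is NA")
    means <- vapply(df[cols], mean, numeric(1))
    ses <- if (n > 1L) vapply(df[cols], stats::sd, numeric(1)) / sqrt(n)
           else rep(NA_real_, length(cols))
    row <- data.frame(site = df$site[1], n_plots = n,
                      stringsAsFactors = FALSE)
    row[cols] <- as.list(means)
    row[paste0("se_", cols)] <- as.list(ses)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Regress log10 stability components on diversity
#'
#' Ordinary least squares of each log10 component on a diversity predictor:
#' log10 richness, untransformed Shannon H, or log10 inverse Simpson.  Units
#' are sites (means across plots; the survey-data design) or individual
#' plots (the experimental design, where richness is manipulated per plot).
#' The fits are unweighted.  Because OLS is linear in the response and
#' `log10(Phi) = log10(SAE) + log10(CPE)` and
#' `log10(S_com) = log10(Phi) + log10(S_pop)` hold row by row, the fitted
#' slopes satisfy the same additivity exactly; [check_slope_additivity()]
#' verifies this.
#'
#' @param records per-plot ([component_table()]) or per-site
#'   ([site_summaries()]) data.frame.
#' @param index `"richness"`, `"shannon"`, or `"invsimpson"`.
#' @return a data.frame of class `regression_table`: one row per response
#'   with `response`, `slope`, `intercept`, `p_value` (two-sided t-test on
#'   the slope), `n`, plus attributes `index` and `predictor`.
#' @export
fit_component_regressions <- function(records,
                                      index = c("richness", "shannon",
                                                "invsimpson")) {
  index <- match.arg(index)
  pred_col <- switch(index,
                     richness = "log10_richness",
                     shannon = "shannon",
                     invsimpson = "log10_inv_simpson")
  if (!pred_col %in% names(records))
    stop("records lack predictor column '", pred_col, "'")
  if (nrow(records) < 3L)
    stop("need at least 3 units to fit regressions")
  x <- records[[pred_col]]
  if (stats::sd(x) == 0) stop("degenerate predictor: zero variance")

  responses <- intersect(
    c("log10_S_com", "log10_S_pop", "log10_Phi", "log10_SAE", "log10_CPE",
      "log10_CPE_env", "log10_CPE_int"),
    names(records))
  rows <- lapply(responses, function(resp) {
    fit <- stats::lm(records[[resp]] ~ x)
    sm <- summary(fit)$coefficients
    data.frame(response = resp,
               slope = sm[2L, 1L], intercept = sm[1L, 1L],
               p_value = sm[2L, 4L], n = length(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "index") <- index
  attr(out, "predictor") <- pred_col
  class(out) <- c("regression_table", "data.frame")
  out
}

#' Check slope additivity of a fitted regression table
#'
#' The decomposition is multiplicative, so on the log10 scale the fitted
#' slopes must satisfy `slope(Phi) = slope(SAE) + slope(CPE)` and
#' `slope(S_com) = slope(Phi) + slope(S_pop)` up to floating-point error;
#' a material residual indicates the table was not fit on a consistent
#' component set.
#'
#' @param table a `regression_table` from [fit_component_regressions()].
#' @param tol residual tolerance (default 1e-8).
#' @return a list with `pass` (logical) and `residuals` (named numeric).
#' @export
check_slope_additivity <- function(table, tol = 1e-8) {
  sl <- function(resp) {
    i <- match(resp, table$response)
    if (is.na(i)) stop("regression table lacks response '", resp, "'")
    table$slope[i]
  }
  res <- c(
    phi_vs_sae_cpe = sl("log10_Phi") - sl("log10_SAE") - sl("log10_CPE"),
    scom_vs_phi_spop = sl("log10_S_com") - sl("log10_Phi") - sl("log10_S_pop")
  )
  list(pass = all(abs(res) < tol), residuals = res)
}
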