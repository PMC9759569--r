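#' Construct a community matrix
#'
#' A community matrix is one plot's species-by-time abundance record: a
#' numeric matrix with `T` rows (years, in order) and `S` columns (species),
#' holding biomass (g/m^2) or percent cover.  Absences are coded 0; percent
#' cover may sum above 100 because of vertically overlapping canopies, which
#' is harmless since every quantity computed from the matrix is a ratio.
#'
#' Species with no nonzero abundance at any time point carry no information
#' about fluctuations and are dropped at construction (with a message noting
#' which).  Missing values are an error: the framework assumes complete
#' annual series, and gap handling is the caller's responsibility.
#'
#' @param values numeric T x S matrix, rows = time points, columns = species.
#' @param species optional character vector of species names (defaults to
#'   column names, or `sp1..spS`).
#' @param times optional vector of time labels (defaults to row names, or
#'   `1..T`).
#' @param plot_id,site_id identifiers recorded for provenance.
#' @param check_negative error on negative abundances (default `TRUE`).
#'   Simulated Gaussian communities are constructed with `FALSE` since their
#'   draws are not truncated at zero.
#' @return an object of class `community_matrix`: a list with elements
#'   `values`, `species`, `times`, `plot_id`, `site_id`.
#' @examples
#' X <- community_matrix(cbind(a = c(2, 4, 2, 4), b = c(1, 3, 3, 1)))
#' decompose_stability(X)
#' @export
community_matrix <- function(values, species = NULL, times = NULL,
                             plot_id = "plot1", site_id = "site1",
                             check_negative = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    stop("community matrix needs at least 2 time points (got ", nrow(values), ")")
  if (ncol(values) < 1L)
    stop("community matrix needs at least 1 species")
  if (anyNA(values) || any(!is.finite(values)))
    stop("community matrix contains missing or non-finite abundances")
  if (check_negative && any(values < 0))
    stop("negative abundances are not allowed")

  if (is.null(species)) {
    species <- colnames(values)
    if (is.null(species)) species <- paste0("sp", seq_len(ncol(values)))
  }
  if (length(species) != ncol(values))
    stop("length of 'species' must match the number of columns")
  if (is.null(times)) {
    times <- rownames(values)
    if (is.null(times)) times <- seq_len(nrow(values))
  }
  if (length(times) != nrow(values))
    stop("length of 'times' must match the number of rows")
  species <- as.character(species)
  if (anyDuplicated(species))
    stop("duplicate species names")

  empty <- colSums(values != 0) == 0L
  if (any(empty)) {
    message("plot ", plot_id, ": dropping ", sum(empty),
            " species never observed: ",
            paste(species[empty], collapse = ", "))
    values <- values[, !empty, drop = FALSE]
    species <- species[!empty]
    if (ncol(values) == 0L)
      stop("all species are absent at every time point")
  }
  if (nrow(values) < 10L)
    message("plot ", plot_id, ": short series (T = ", nrow(values),
            "); component estimates will be noisy")

  dimnames(values) <- list(as.character(times), species)
  structure(
    list(values = values, species = species, times = times,
         plot_id = as.character(plot_id), site_id = as.character(site_id)),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("<community_matrix> site ", x$site_id, ", plot ", x$plot_id, ": ",
      length(x$species), " species x ", nrow(x$values), " time points\n",
      sep = "")
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$values)

is_community_matrix <- function(x) inherits(x, "community_matrix")

stopifnot_community <- function(X) {
  if (!is_community_matrix(X))
    stop("expected a 'community_matrix'; see community_matrix()")
  invisible(X)
}
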