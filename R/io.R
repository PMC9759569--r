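#' Read a long-format abundance table
#'
#' Reads a CSV with columns `site, plot, year, species, abundance` and pivots
#' it into one [community_matrix()] per plot.  Duplicate
#' (plot, year, species) rows are summed (with a message giving the count);
#' species unrecorded in a year are filled with 0 (absence); within each
#' site, years not shared by every plot are dropped by an inner join so that
#' all plots of a site cover the same years (required by the donor-plot
#' surrogate construction).  Negative abundances and non-numeric years are
#' errors.
#'
#' @param path CSV file path.
#' @param min_years drop plots with fewer shared years than this (default 2).
#' @return a list of class `stability_dataset`: `plots` (list of
#'   `community_matrix`), `sites` (plot -> site lookup), `source` (the path).
#' @export
read_long_table <- function(path, min_years = 2L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "plot", "year", "species", "abundance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  year_num <- suppressWarnings(as.numeric(df$year))
  if (anyNA(year_num))
    stop("non-numeric year at row(s): ",
         paste(utils::head(which(is.na(year_num)), 5L), collapse = ", "))
  df$year <- year_num
  if (anyNA(df$abundance) || !is.numeric(df$abundance))
    stop("abundance must be numeric with no missing values")
  if (any(df$abundance < 0))
    stop("negative abundance at row(s): ",
         paste(utils::head(which(df$abundance < 0), 5L), collapse = ", "))

  key <- paste(df$site, df$plot, df$year, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    message("summed ", n_dup, " duplicated (plot, year, species) row(s)")
    df <- stats::aggregate(abundance ~ site + plot + year + species,
                           data = df, FUN = sum)
  }

  plots <- list()
  for (site in unique(df$site)) {
    dsite <- df[df$site == site, ]
    years_by_plot <- tapply(dsite$year, dsite$plot, unique)
    shared <- sort(Reduce(intersect, years_by_plot))
    dropped <- length(unique(dsite$year)) - length(shared)
    if (dropped > 0L)
      message("site ", site, ": dropped ", dropped,
              " year(s) not shared by all plots")
    if (length(shared) < min_years) {
      message("site ", site, " skipped: only ", length(shared),
              " shared year(s)")
      next
    }
    dsite <- dsite[dsite$year %in% shared, ]
    for (plot in unique(dsite$plot)) {
      dp <- dsite[dsite$plot == plot, ]
      species <- sort(unique(dp$species))
      vals <- matrix(0, length(shared), length(species),
                     dimnames = list(shared, species))
      vals[cbind(match(dp$year, shared), match(dp$species, species))] <-
        dp$abundance
      id <- paste0(site, ":", plot)
      plots[[id]] <- community_matrix(vals, species = species,
                                      times = shared, plot_id = plot,
                                      site_id = site)
    }
  }
  if (length(plots) == 0L) stop("no usable plots in ", path)
  structure(
    list(plots = unname(plots),
         sites = vapply(plots, function(p) p$site_id, character(1)),
         source = path),
    class = "stability_dataset"
  )
}

#' @export
print.stability_dataset <- function(x, ...) {
  cat("<stability_dataset> ", length(x$plots), " plots across ",
      length(unique(x$sites)), " site(s) from ", x$source, "\n", sep = "")
  invisible(x)
}

#' Split a dataset into site-wise plot lists
#'
#' Convenience for the donor-plot surrogate workflow: returns a named list,
#' site -> list of that site's `community_matrix` plots.
#'
#' @param dataset a `stability_dataset` from [read_long_table()].
#' @return named list of lists of `community_matrix`.
#' @export
plots_by_site <- function(dataset) {
  if (!inherits(dataset, "stability_dataset"))
    stop("'dataset' must come from read_long_table()")
  split(dataset$plots, vapply(dataset$plots, function(p) p$site_id,
                              character(1)))
}

#' Write a component table to CSV with a JSON metadata mirror
#'
#' Writes the tidy per-unit table as CSV (full double precision) and, next
#' to it, a `.json` mirror carrying the records plus provenance metadata
#' (package version, timestamp, and any seed supplied).
#'
#' @param records nonempty data.frame (e.g. from [component_table()]).
#' @param path output CSV path; the JSON mirror replaces the extension with
#'   `.json`.
#' @param seed optional seed to record in the metadata.
#' @return `path`, invisibly.
#' @export
write_components <- function(records, path, seed = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a nonempty data.frame")
  utils::write.csv(records, path, row.names = FALSE)
  meta <- list(
    package = "stabdecomp",
    version = as.character(utils::packageVersion("stabdecomp")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    n_records = nrow(records),
    records = records
  )
  json_path <- sub("\\.[A-Za-z0-9]+$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a simulated site as a long-format CSV
#'
#' Emits the same `site, plot, year, species, abundance` layout that
#' [read_long_table()] consumes, enabling round-trips through the file
#' interface.  Simulated abundances are untruncated Gaussian draws and may
#' be slightly negative; they are written as-is, and re-reading such a file
#' requires `allow_negative = TRUE` semantics not offered by the strict
#' reader — round-trip tests use scenarios whose draws stay positive.
#'
#' @param sim result of [simulate_site()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(sim, path) {
  rows <- do.call(rbind, lapply(sim$plots, function(p) {
    data.frame(site = p$site_id, plot = p$plot_id,
               year = rep(as.numeric(p$times), times = length(p$species)),
               species = rep(p$species, each = nrow(p$values)),
               abundance = as.vector(p$values),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
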