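#' Site-year observation set
#'
#' One row per site-year (one moor in one breeding season): the density
#' index of each prey, the number of deliveries of each prey observed at
#' the nest, and the watch effort in hours. Counts may be `NULL` for a
#' design-only object (densities and effort without simulated/observed
#' deliveries).
#'
#' @param densities numeric matrix, site-years x prey, all >= 0.
#' @param counts integer matrix of the same shape, all >= 0, or `NULL`.
#' @param effort numeric vector of watch hours per site-year, all > 0.
#' @param site_year_id character labels, one per row.
#' @param prey character vector of prey names (defaults to
#'   `colnames(densities)`).
#' @return An object of class `msfr_data`.
#' @export
msfr_data <- function(densities, counts = NULL, effort,
                      site_year_id = NULL, prey = colnames(densities)) {
  densities <- as.matrix(densities)
  S <- nrow(densities)
  if (is.null(prey)) prey <- paste0("prey", seq_len(ncol(densities)))
  colnames(densities) <- prey
  check_nonnegative(densities, "densities")
  check_positive(effort, "effort")
  if (length(effort) != S)
    stop("'effort' must have one entry per site-year", call. = FALSE)
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (!identical(dim(counts), dim(densities)))
      stop("'counts' and 'densities' must have identical dimensions",
           call. = FALSE)
    if (any(!is.finite(counts)) || any(counts < 0) ||
        any(counts != round(counts)))
      stop("'counts' must be non-negative integers", call. = FALSE)
    storage.mode(counts) <- "integer"
    colnames(counts) <- prey
  }
  if (is.null(site_year_id)) site_year_id <- paste0("sy", seq_len(S))
  structure(list(densities = densities, counts = counts,
                 effort = as.numeric(effort),
                 site_year_id = as.character(site_year_id), prey = prey),
            class = "msfr_data")
}

#' @export
print.msfr_data <- function(x, ...) {
  cat("msfr_data:", nrow(x$densities), "site-years,",
      length(x$prey), "prey (", paste(x$prey, collapse = ", "), ")\n")
  cat(if (is.null(x$counts)) "design only (no counts)\n" else
    paste0("total deliveries: ", sum(x$counts), "\n"))
  invisible(x)
}

#' @export
as.data.frame.msfr_data <- function(x, ...) {
  df <- data.frame(site_year_id = x$site_year_id,
                   stats::setNames(as.data.frame(x$densities),
                                   paste0("density_", x$prey)))
  if (!is.null(x$counts))
    df <- cbind(df, stats::setNames(as.data.frame(x$counts),
                                    paste0("count_", x$prey)))
  df$effort_hours <- x$effort
  df
}

#' Read / write site-year observations as CSV
#'
#' The schema is one row per site-year with columns `site_year_id`,
#' `density_<prey>`, `count_<prey>` (optional), and `effort_hours`. Prey
#' names and order are taken from the `density_` columns.
#'
#' @param path CSV file path.
#' @return `read_msfr_csv` returns an [msfr_data] object;
#'   `write_msfr_csv` invisibly returns `path`.
#' @export
read_msfr_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("site_year_id", "effort_hours")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed observation CSV '", path, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  dcols <- grep("^density_", names(df), value = TRUE)
  if (!length(dcols))
    stop("malformed observation CSV '", path, "': no density_<prey> columns",
         call. = FALSE)
  prey <- sub("^density_", "", dcols)
  ccols <- paste0("count_", prey)
  counts <- if (all(ccols %in% names(df)))
    as.matrix(df[ccols]) else NULL
  bad <- which(!stats::complete.cases(df[c(dcols, "effort_hours")]))
  if (length(bad))
    stop("malformed observation CSV '", path, "': missing values in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  msfr_data(densities = as.matrix(df[dcols]), counts = counts,
            effort = df$effort_hours, site_year_id = df$site_year_id,
            prey = prey)
}

#' @rdname read_msfr_csv
#' @param data an [msfr_data] object.
#' @export
write_msfr_csv <- function(data, path) {
  stopifnot(inherits(data, "msfr_data"))
  df <- as.data.frame(data)
  dbl <- vapply(df, is.double, logical(1L))
  # full precision so write -> read round-trips exactly
  df[dbl] <- lapply(df[dbl], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict an observation set to a single prey species
#'
#' Used by the single-species fit: keeps one prey's density and count
#' columns so the generalised single-species response can be fitted
#' ignoring alternative prey.
#'
#' @param data an [msfr_data] object.
#' @param prey prey name or index to keep.
#' @return An [msfr_data] object with one prey.
#' @export
subset_prey <- function(data, prey) {
  stopifnot(inherits(data, "msfr_data"))
  if (is.character(prey)) prey <- match(prey, data$prey)
  if (is.na(prey)) stop("unknown prey species", call. = FALSE)
  msfr_data(densities = data$densities[, prey, drop = FALSE],
            counts = if (is.null(data$counts)) NULL else
              data$counts[, prey, drop = FALSE],
            effort = data$effort, site_year_id = data$site_year_id,
            prey = data$prey[prey])
}
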