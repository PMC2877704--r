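#' Synthetic study design specification
#'
#' The sampling frame of the emulated field study: a small number of
#' site-year combinations (default 11, matching the moor-year structure of
#' the hen-harrier data), per-prey density ranges in each prey's native
#' index units, and a watch-effort range in hours. Default density ranges:
#' grouse chicks 5-208 per km^2 (up to the predator-free equilibrium),
#' pipits 2-20 per km of transect, voles 0.1-4 per 100 trap-nights — the
#' ranges spanned by the study's reported scenarios.
#'
#' @param n_site_years number of site-year rows (>= 0).
#' @param density_ranges named list of `c(low, high)` per prey.
#' @param effort_range watch hours per site-year, `c(low, high)`.
#' @param log_uniform draw densities log-uniformly instead of uniformly.
#' @param seed design RNG seed.
#' @return A `design_spec` object.
#' @export
design_spec <- function(n_site_years = 11L,
                        density_ranges = list(grouse = c(5, 208),
                                              pipit = c(2, 20),
                                              vole = c(0.1, 4)),
                        effort_range = c(50, 400),
                        log_uniform = FALSE, seed = 1L) {
  stopifnot(n_site_years >= 0L, length(effort_range) == 2L,
            effort_range[1] > 0, effort_range[1] < effort_range[2])
  for (p in names(density_ranges)) {
    r <- density_ranges[[p]]
    if (length(r) != 2L || r[1] <= 0 || r[1] >= r[2])
      stop("density range for '", p, "' must be positive with low < high",
           call. = FALSE)
  }
  structure(list(n_site_years = as.integer(n_site_years),
                 density_ranges = density_ranges,
                 effort_range = effort_range,
                 log_uniform = isTRUE(log_uniform),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Generate a study design (densities and effort, no counts)
#'
#' Densities are drawn independently per prey, uniformly (or log-uniformly)
#' within the spec's ranges; effort uniformly within its range. Fully
#' deterministic given the spec's seed.
#'
#' @param spec a [design_spec].
#' @return An [msfr_data] object with `counts = NULL`.
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  prey <- names(spec$density_ranges)
  S <- spec$n_site_years
  if (S == 0L)
    return(msfr_data(densities = matrix(numeric(0), 0L, length(prey),
                                        dimnames = list(NULL, prey)),
                     effort = numeric(0), site_year_id = character(0),
                     prey = prey))
  set.seed(spec$seed)
  dens <- vapply(prey, function(p) {
    r <- spec$density_ranges[[p]]
    if (spec$log_uniform) exp(stats::runif(S, log(r[1]), log(r[2])))
    else stats::runif(S, r[1], r[2])
  }, numeric(S))
  if (S == 1L) dens <- matrix(dens, 1L, dimnames = list(NULL, prey))
  eff <- stats::runif(S, spec$effort_range[1], spec$effort_range[2])
  msfr_data(densities = dens, effort = eff,
            site_year_id = sprintf("sy%02d", seq_len(S)), prey = prey)
}

#' Default synthetic truth
#'
#' The generator's ground truth: the posterior-mean multispecies
#' parameters of the hen-harrier fit ([table1_msfr_params]) with moderate
#' negative-binomial overdispersion (`k = 5` per prey; the study does not
#' report its fitted dispersion, so this is a fixed, documented choice).
#'
#' @param k per-prey dispersion (recycled); `Inf` gives Poisson counts.
#' @return A `truth_record`: list with `params` ([msfr_params]) and `k`.
#' @export
default_truth <- function(k = 5) {
  params <- table1_msfr_params()
  structure(list(params = params, k = rep_len(k, params$n_prey)),
            class = "truth_record")
}

#' Simulate delivery counts for a design
#'
#' Counts are drawn independently per site-year and prey from a negative
#' binomial with mean `MSFR rate x effort` and the truth's dispersion;
#' `k = Inf` uses the Poisson limit.
#'
#' @param design an [msfr_data] (counts ignored if present).
#' @param truth a `truth_record` (see [default_truth]) or a list with
#'   `params` and `k`.
#' @param seed simulation seed.
#' @return An [msfr_data] with simulated counts.
#' @export
simulate_counts <- function(design, truth = default_truth(), seed = 1L) {
  stopifnot(inherits(design, "msfr_data"))
  params <- truth$params
  k <- rep_len(truth$k, params$n_prey)
  mu <- msfr_response(design$densities, params) * design$effort
  set.seed(seed)
  counts <- mu
  for (j in seq_len(ncol(mu))) {
    counts[, j] <- if (is.infinite(k[j]))
      stats::rpois(nrow(mu), mu[, j])
    else stats::rnbinom(nrow(mu), size = k[j], mu = mu[, j])
  }
  msfr_data(densities = design$densities, counts = counts,
            effort = design$effort, site_year_id = design$site_year_id,
            prey = design$prey)
}

#' Serialize / restore a truth record as JSON
#'
#' @param truth a `truth_record`.
#' @param path JSON file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(a = as.list(truth$params$a),
                            t = as.list(truth$params$t),
                            m = as.list(truth$params$m),
                            k = stats::setNames(as.list(truth$k),
                                                truth$params$prey)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- msfr_params(a = unlist(x$a), t = unlist(x$t), m = unlist(x$m),
                        prey = names(x$a))
  structure(list(params = params, k = unname(unlist(x$k))),
            class = "truth_record")
}
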